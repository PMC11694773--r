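# Readers and writers for the pipeline's standard formats: NIfTI volumes,
# Visium-style tissue positions, 10x Matrix-Market count triplets, GMT
# gene sets, YAML poses/configs, VTK image exports and tidy CSV results.

#' Read / write density volumes as NIfTI
#'
#' Volumes are stored with the voxel spacing in the NIfTI pixdim field,
#' in micrometres. \code{readDensityImage} returns a
#' \linkS4class{DensityImage}; label/mask volumes round-trip through the
#' same files as numeric grids.
#'
#' @param path file path (.nii or .nii.gz).
#' @param image a \linkS4class{DensityImage}.
#' @return \code{readDensityImage}: a \linkS4class{DensityImage};
#'   \code{writeDensityImage}: the path, invisibly.
#' @export
readDensityImage <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  densityImage(array(as.numeric(img), dim(img)), spacing = sp)
}

#' @rdname readDensityImage
#' @export
writeDensityImage <- function(image, path) {
  stopifnot(is(image, "DensityImage"))
  nii <- RNifti::asNifti(image@values)
  RNifti::pixdim(nii) <- rep(image@spacing, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a label volume (remodeling map or VOI set) as NIfTI
#'
#' @param x a \linkS4class{RemodelingMap}, \linkS4class{VOISet} or
#'   \linkS4class{BoneMask}.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing (um) when \code{x} carries none.
#' @return the path, invisibly.
#' @export
writeLabelVolume <- function(x, path, spacing = 10.5) {
  vals <- imageValues(x)
  if (is.logical(vals)) vals <- array(as.integer(vals), dim(vals))
  sp <- tryCatch(voxelSpacing(x), error = function(e) spacing)
  nii <- RNifti::asNifti(vals)
  RNifti::pixdim(nii) <- rep(sp, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read Visium-style tissue positions
#'
#' Reads the tissue_positions CSV (barcode, in_tissue, array_row,
#' array_col, pixel_row, pixel_col) and converts pixel coordinates to
#' section micrometres via a scale factor.
#'
#' @param path CSV path (with or without header).
#' @param umPerPixel micrometres per pixel of the pixel coordinates.
#' @param inTissueOnly keep only in-tissue spots.
#' @param diameter spot capture diameter, um.
#' @return a spot table (see \code{\link{spotTable}}).
#' @export
readTissuePositions <- function(path, umPerPixel = 1, inTissueOnly = TRUE,
                                diameter = 55) {
  first <- readLines(path, n = 1)
  hasHeader <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.csv(path, header = hasHeader, stringsAsFactors = FALSE)
  if (!hasHeader)
    names(df) <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pixel_row", "pixel_col")[seq_len(ncol(df))]
  if (inTissueOnly) df <- df[df$in_tissue == 1, , drop = FALSE]
  st <- spotTable(df$barcode, df$pixel_col * umPerPixel,
                  df$pixel_row * umPerPixel, diameter = diameter)
  st$array_row <- df$array_row; st$array_col <- df$array_col
  st
}

#' Read / write a section pose as YAML
#'
#' The pose file stores the 4x4 homogeneous matrix (row-major list of
#' rows, um) and the section thickness.
#'
#' @param path YAML file path.
#' @param pose a \linkS4class{SectionPose}.
#' @return \code{readSectionPose}: a \linkS4class{SectionPose}.
#' @export
readSectionPose <- function(path) {
  y <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(y$matrix, as.numeric))
  sectionPose(matrix = m, thickness = y$thickness %||% 5)
}

#' @rdname readSectionPose
#' @export
writeSectionPose <- function(pose, path) {
  stopifnot(is(pose, "SectionPose"))
  yaml::write_yaml(list(matrix = lapply(seq_len(4),
                                        function(i) pose@matrix[i, ]),
                        thickness = pose@thickness), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write 10x-convention count triplets
#'
#' Matrix-Market \code{matrix.mtx} plus \code{features.tsv} and
#' \code{barcodes.tsv} in a directory.
#'
#' @param dir directory containing (or to receive) the three files.
#' @param x a count container (see \code{\link{spotCountMatrix}}).
#' @return \code{readTenxCounts}: a \code{SummarizedExperiment}.
#' @export
readTenxCounts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)
  spotCountMatrix(as(m, "CsparseMatrix"), geneIds = feats[[1]],
                  barcodes = bcs[[1]])
}

#' @rdname readTenxCounts
#' @export
writeTenxCounts <- function(x, dir) {
  m <- spotCounts(x)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(as(m, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' gene ids.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors.
#' @return \code{readGmt}: named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, n, sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a strain field as VTK image data (.vti)
#'
#' ASCII VTK XML ImageData with cell-data arrays \code{eff_sim} and (when
#' present) \code{eff_actual} in microstrain, for rendering in ParaView.
#'
#' @param field a \linkS4class{StrainField}.
#' @param path output .vti path.
#' @return the path, invisibly.
#' @export
writeStrainVti <- function(field, path) {
  stopifnot(is(field, "StrainField"))
  d <- dim(field@effSim)
  sp <- field@spacing
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%g %g %g" Spacing="%g %g %g">',
            d[1], d[2], d[3], field@origin[1], field@origin[2],
            field@origin[3], sp, sp, sp),
    sprintf('    <Piece Extent="0 %d 0 %d 0 %d">', d[1], d[2], d[3]),
    '      <CellData Scalars="eff_sim">'), con)
  writeArr <- function(name, a) {
    writeLines(sprintf('        <DataArray type="Float32" Name="%s" format="ascii">',
                       name), con)
    writeLines(paste(format(as.vector(a), trim = TRUE), collapse = " "), con)
    writeLines("        </DataArray>", con)
  }
  writeArr("eff_sim", field@effSim)
  if (length(field@effActual)) writeArr("eff_actual", field@effActual)
  writeLines(c("      </CellData>", "    </Piece>", "  </ImageData>",
               "</VTKFile>"), con)
  invisible(path)
}

#' Write a spot table as CSV
#'
#' Columns: barcode, x, y, (x3, y3, z3,) mean_eff_ue, region — the tidy
#' per-spot output of the spot-integration stage.
#'
#' @param spots a spot table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  out <- spots
  if (!is.null(out$mean_eff)) names(out)[names(out) == "mean_eff"] <-
    "mean_eff_ue"
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-region barcode lists
#'
#' One CSV per region (Loupe-compatible: columns Barcode, Region) listing
#' the spots assigned to each strain region.
#'
#' @param spots a spot table with region labels.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeRegionBarcodes <- function(spots, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in setdiff(unique(spots$region), "unassigned")) {
    df <- data.frame(Barcode = spots$barcode[spots$region == r], Region = r)
    write.csv(df, file.path(dir, paste0("region_", r, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Write tidy morphometry results
#'
#' @param results data.frame with columns voi, week, bvtv_pct,
#'   bfr_pct_per_day, brr_pct_per_day (as assembled by the caller).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeMorphometryCsv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}
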