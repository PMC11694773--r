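# Embedding of the 2D spot grid into the 3D strain field, per-spot strain
# summaries, strain-region classification, and spot-level QC.

#' Construct a spot table
#'
#' Tidy per-spot table for a spatial gene-expression section: one row per
#' 55-um capture spot with its 2D section coordinates (um). Downstream
#' steps add 3D coordinates, UMI/gene counts, the mean local effective
#' strain and the strain-region label.
#'
#' @param barcode character vector of unique spot barcodes.
#' @param x,y spot center coordinates on the section, um.
#' @param diameter spot capture diameter, um (Visium: 55).
#' @return data.frame with columns barcode, x, y, diameter.
#' @export
spotTable <- function(barcode, x, y, diameter = 55) {
  stopifnot(length(barcode) == length(x), length(x) == length(y))
  if (anyDuplicated(barcode)) stop("spot barcodes must be unique")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("spot centers must be finite")
  if (diameter <= 0) stop("'diameter' must be > 0")
  data.frame(barcode = as.character(barcode), x = as.numeric(x),
             y = as.numeric(y), diameter = diameter,
             stringsAsFactors = FALSE)
}

.pose_apply <- function(pose, xyz) {
  # xyz: n x 3 matrix in section coordinates (um)
  t(pose@matrix[1:3, 1:3] %*% t(xyz)) +
    matrix(pose@matrix[1:3, 4], nrow(xyz), 3, byrow = TRUE)
}

.pose_invert <- function(pose, xyz) {
  t(t(pose@matrix[1:3, 1:3]) %*% t(xyz - matrix(pose@matrix[1:3, 4],
                                                nrow(xyz), 3, byrow = TRUE)))
}

#' Embed section spots into volume coordinates
#'
#' Applies the rigid section pose to each spot's 2D center (z = 0 on the
#' section plane), giving 3D physical coordinates in the volume frame.
#' The inverse pose recovers the 2D centers exactly (rigid round trip).
#'
#' @param spots a spot table (see \code{\link{spotTable}}).
#' @param pose a \linkS4class{SectionPose}.
#' @return The spot table with columns x3, y3, z3 (um) added.
#' @export
embedSection <- function(spots, pose) {
  stopifnot(is.data.frame(spots), is(pose, "SectionPose"))
  p3 <- .pose_apply(pose, cbind(spots$x, spots$y, 0))
  spots$x3 <- p3[, 1]; spots$y3 <- p3[, 2]; spots$z3 <- p3[, 3]
  spots
}

#' Classify spots into strain regions
#'
#' Region thresholds follow the strain-stratified analysis convention:
#' low strain below 500 ue, high strain above 1000 ue, reference between.
#' Values exactly at a boundary are folded into the reference region so
#' that the three labels partition all assigned spots. Undefined strains
#' (spots without bone elements in their footprint) give "unassigned".
#'
#' @param meanEff numeric vector of per-spot mean effective strain, ue
#'   (NA for undefined).
#' @param low,high region thresholds, ue.
#' @return character vector with values "low", "reference", "high",
#'   "unassigned".
#' @examples
#' classifyStrainRegion(c(400, 750, 1200, NA))
#' @export
classifyStrainRegion <- function(meanEff, low = 500, high = 1000) {
  if (any(meanEff < 0, na.rm = TRUE))
    stop("effective strain cannot be negative (domain error)")
  out <- rep("unassigned", length(meanEff))
  ok <- !is.na(meanEff)
  out[ok & meanEff < low] <- "low"
  out[ok & meanEff > high] <- "high"
  out[ok & meanEff >= low & meanEff <= high] <- "reference"
  out
}

#' Summarize the strain field per spot
#'
#' For each embedded spot, the footprint is a disk of radius diameter/2
#' around the spot center in the section plane, extruded through the
#' section thickness. The per-spot strain is the arithmetic mean of
#' \code{effActual} over bone-mask elements whose centers fall inside the
#' footprint; spots whose footprint contains no bone element get NA and
#' region "unassigned" (spots over soft tissue are excluded rather than
#' assigned zero strain).
#'
#' @param spots an embedded spot table (see \code{\link{embedSection}}).
#' @param field a scaled \linkS4class{StrainField} (effActual present).
#' @param boneMask a \linkS4class{BoneMask} on the same element grid.
#' @param pose the \linkS4class{SectionPose} used for embedding.
#' @param low,high strain-region thresholds, ue.
#' @return The spot table with columns mean_eff (ue) and region added.
#' @export
spotStrain <- function(spots, field, boneMask, pose, low = 500, high = 1000) {
  stopifnot(is.data.frame(spots), is(field, "StrainField"),
            is(boneMask, "BoneMask"), is(pose, "SectionPose"))
  if (!identical(dim(field@effSim), dim(boneMask@values)) ||
      !isTRUE(all.equal(field@spacing, boneMask@spacing)))
    stop("strain field and bone mask grids differ (geometry error)")
  if (is.null(spots$x3))
    spots <- embedSection(spots, pose)
  eff <- effActual(field)
  bone <- which(boneMask@values)
  if (length(bone) == 0L) {
    spots$mean_eff <- NA_real_
    spots$region <- "unassigned"
    return(spots)
  }
  dims <- dim(eff)
  idx <- arrayInd(bone, dims)
  centers <- sweep((idx - 0.5) * field@spacing, 2, field@origin, "+")
  sec <- .pose_invert(pose, centers)     # element centers in section frame
  inSlab <- abs(sec[, 3]) <= pose@thickness / 2
  sec <- sec[inSlab, , drop = FALSE]
  effBone <- eff[bone][inSlab]
  radius <- spots$diameter / 2
  meanEff <- vapply(seq_len(nrow(spots)), function(s) {
    d2 <- (sec[, 1] - spots$x[s])^2 + (sec[, 2] - spots$y[s])^2
    hit <- d2 <= radius[s]^2
    if (!any(hit)) NA_real_ else mean(effBone[hit])
  }, numeric(1))
  spots$mean_eff <- meanEff
  spots$region <- classifyStrainRegion(meanEff, low = low, high = high)
  spots
}

#' Quality-control filter for spots
#'
#' Retains spots with at least \code{minUmis} UMIs and at least
#' \code{minGenes} detected genes (inclusive thresholds; a spot at exactly
#' 500 UMIs and 250 genes passes). Per-spot totals are computed from the
#' count matrix; removed barcodes are reported in the "removed" attribute.
#'
#' @param spots a spot table.
#' @param counts a \link[SummarizedExperiment]{SummarizedExperiment} of
#'   UMI counts (genes x spots) containing every spot barcode.
#' @param minUmis,minGenes inclusive QC thresholds.
#' @return The filtered spot table with columns n_umis and n_genes filled;
#'   \code{attr(, "removed")} lists removed barcodes.
#' @export
qcFilterSpots <- function(spots, counts, minUmis = 500, minGenes = 250) {
  stopifnot(is.data.frame(spots))
  m <- spotCounts(counts)
  missing <- setdiff(spots$barcode, colnames(m))
  if (length(missing))
    stop("spot barcode(s) absent from the count matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  m <- m[, spots$barcode, drop = FALSE]
  spots$n_umis <- as.integer(Matrix::colSums(m))
  spots$n_genes <- as.integer(Matrix::colSums(m > 0))
  keep <- spots$n_umis >= minUmis & spots$n_genes >= minGenes
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- spots$barcode[!keep]
  out
}

#' Per-region QC medians
#'
#' Median UMI and gene counts per strain region, the standard section
#' quality summary (even-count medians are the mean of the middle two).
#'
#' @param spots a spot table with n_umis, n_genes and region columns.
#' @param regions which regions to summarize (default: all present).
#' @return data.frame with columns region, n_spots, median_umis,
#'   median_genes.
#' @export
regionQcStats <- function(spots, regions = NULL) {
  stopifnot(is.data.frame(spots), !is.null(spots$region))
  if (is.null(regions)) regions <- unique(spots$region)
  empty <- regions[!regions %in% spots$region]
  if (length(empty))
    stop("no spots in region(s): ", paste(empty, collapse = ", "))
  do.call(rbind, lapply(regions, function(r) {
    s <- spots[spots$region == r, ]
    data.frame(region = r, n_spots = nrow(s),
               median_umis = median(s$n_umis),
               median_genes = median(s$n_genes))
  }))
}
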