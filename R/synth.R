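# Synthetic fixtures with exact ground truth: callus phantom time series,
# striped strain fields, hexagonal spot grids, and NB count simulations
# with planted strain-dependent effects.

#' Phantom specification
#'
#' Parameters of the idealized femur-defect phantom: a cortical tube with
#' a mid-shaft defect gap that fills with callus according to a per-frame
#' schedule. The phantom is deliberately an idealized tube-with-gap, not
#' an anatomically realistic femur: its purpose is exact, cheap ground
#' truth for every downstream stage. Bone-phase densities sit above the
#' 395 mg HA/cm^3 segmentation threshold, soft tissue below it.
#'
#' @param dims voxel grid dimensions.
#' @param spacing voxel edge, um.
#' @param rInner,rOuter cortical inner/outer radii, um.
#' @param rPeriph outer radius of the periphery VOIs, um.
#' @param gapHalf half-height of the defect gap, um.
#' @param callusOuter per-frame callus outer radii, um (frame 1 = baseline).
#' @param callusInner per-frame cleared-core radii, um (an increase models
#'   resorption).
#' @param intervalDays days between consecutive frames.
#' @param densityCortex,densityCallus,densitySoft phase densities,
#'   mg HA/cm^3.
#' @param noiseSd density noise standard deviation (default 0, keeping
#'   ground truth exact); kept well below the threshold margin if used.
#' @param seed RNG seed (used only when noiseSd > 0).
#' @return list of phantom parameters for
#'   \code{\link{makePhantomTimeseries}}.
#' @export
phantomSpec <- function(dims = c(36, 36, 48), spacing = 10.5,
                        rInner = 70, rOuter = 120, rPeriph = 170,
                        gapHalf = 80,
                        callusOuter = c(0, 60, 100, 140),
                        callusInner = c(0, 0, 0, 40),
                        intervalDays = 7,
                        densityCortex = 1200, densityCallus = 700,
                        densitySoft = 100, noiseSd = 0, seed = 1L) {
  if (rInner >= rOuter) stop("rInner must be < rOuter (spec error)")
  if (rOuter >= rPeriph) stop("rOuter must be < rPeriph (spec error)")
  if (length(callusInner) != length(callusOuter))
    stop("callus schedules must have equal length (spec error)")
  if (min(densityCortex, densityCallus) < 395 || densitySoft >= 395)
    stop("bone phases must be >= 395 and soft tissue < 395 mg HA/cm^3")
  if (2 * gapHalf >= dims[3] * spacing)
    stop("defect gap exceeds the axial extent (spec error)")
  list(dims = as.integer(dims), spacing = spacing, rInner = rInner,
       rOuter = rOuter, rPeriph = rPeriph, gapHalf = gapHalf,
       callusOuter = callusOuter, callusInner = callusInner,
       intervalDays = intervalDays, densityCortex = densityCortex,
       densityCallus = densityCallus, densitySoft = densitySoft,
       noiseSd = noiseSd, seed = as.integer(seed))
}

# voxel-center cylindrical coordinates of the phantom grid
.phantom_geom <- function(spec) {
  d <- spec$dims; h <- spec$spacing
  cx <- d[1] * h / 2; cy <- d[2] * h / 2; cz <- d[3] * h / 2
  x <- (seq_len(d[1]) - 0.5) * h
  y <- (seq_len(d[2]) - 0.5) * h
  z <- (seq_len(d[3]) - 0.5) * h
  r <- sqrt(outer((x - cx)^2, (y - cy)^2, "+"))        # nx x ny
  rad <- array(r, d)                                   # broadcast over z
  axial <- array(rep(abs(z - cz), each = d[1] * d[2]), d)
  list(rad = rad, axial = axial)
}

.phantom_bone_mask <- function(spec, geom, frame) {
  inGap <- geom$axial <= spec$gapHalf
  cortex <- !inGap & geom$rad <= spec$rOuter & geom$rad > spec$rInner
  callus <- inGap & geom$rad <= spec$callusOuter[frame] &
    geom$rad > spec$callusInner[frame]
  list(cortex = cortex, callus = callus, bone = cortex | callus)
}

#' Generate a phantom time series with exact remodeling ground truth
#'
#' Builds one density volume per schedule frame plus, per consecutive
#' frame pair, the exact voxel index sets of formation (bone gained),
#' quiescence (bone kept) and resorption (bone lost). Frames are
#' pre-registered by construction (same grid). Also returns the phantom's
#' VOI labels: DC = defect gap core, DP = gap periphery, FC = cortical
#' tube plus medullary cavity, FP = cortex periphery.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{images} (list of
#'   \linkS4class{DensityImage}), \code{masks} (list of exact
#'   \linkS4class{BoneMask}), \code{vois} (validated
#'   \linkS4class{VOISet}), and \code{truth}: per interval, a list with
#'   integer index vectors \code{formation}, \code{quiescent},
#'   \code{resorption}.
#' @export
makePhantomTimeseries <- function(spec = phantomSpec()) {
  geom <- .phantom_geom(spec)
  nF <- length(spec$callusOuter)
  if (spec$noiseSd > 0) set.seed(spec$seed)
  images <- vector("list", nF)
  masks <- vector("list", nF)
  boneIdx <- vector("list", nF)
  for (f in seq_len(nF)) {
    ph <- .phantom_bone_mask(spec, geom, f)
    dens <- array(spec$densitySoft, spec$dims)
    dens[ph$cortex] <- spec$densityCortex
    dens[ph$callus] <- spec$densityCallus
    if (spec$noiseSd > 0)
      dens <- dens + array(rnorm(length(dens), 0, spec$noiseSd), spec$dims)
    images[[f]] <- densityImage(dens, spacing = spec$spacing)
    masks[[f]] <- new("BoneMask", values = ph$bone, spacing = spec$spacing,
                      origin = c(0, 0, 0), threshold = 395)
    boneIdx[[f]] <- which(ph$bone)
  }
  truth <- lapply(seq_len(nF - 1L), function(f) {
    a <- boneIdx[[f]]; b <- boneIdx[[f + 1L]]
    list(formation = setdiff(b, a), quiescent = intersect(a, b),
         resorption = setdiff(a, b))
  })
  inGap <- geom$axial <= spec$gapHalf
  lab <- array(0L, spec$dims)
  lab[inGap & geom$rad <= spec$rOuter] <- VOI_CODES[["DC"]]
  lab[inGap & geom$rad > spec$rOuter & geom$rad <= spec$rPeriph] <-
    VOI_CODES[["DP"]]
  lab[!inGap & geom$rad <= spec$rOuter] <- VOI_CODES[["FC"]]
  lab[!inGap & geom$rad > spec$rOuter & geom$rad <= spec$rPeriph] <-
    VOI_CODES[["FP"]]
  vois <- validateVois(voiSet(lab), images[[1]])
  list(images = images, masks = masks, vois = vois, truth = truth,
       spec = spec)
}

#' Striped strain field with known region labels
#'
#' Piecewise-constant effective-strain field in axial bands — the fixture
#' for strain-region classification: each band's region label is known in
#' closed form. The bands tile the axial extent in order.
#'
#' @param dims element grid dimensions; \code{dims[3]} must be divisible
#'   by the number of bands.
#' @param bandValues effective strain per band, ue.
#' @param spacing element edge, um.
#' @return list with \code{field} (a scaled \linkS4class{StrainField}
#'   with \code{fResultant = fApplied = 1}), \code{bandIndex} (per-element
#'   band number) and \code{regionByBand} (label per band).
#' @export
makeStrainStripes <- function(dims, bandValues, spacing = 10.5) {
  nb <- length(bandValues)
  if (dims[3] %% nb != 0)
    stop("bands must tile the axial extent evenly (spec error)")
  per <- dims[3] %/% nb
  band <- rep(seq_len(nb), each = per)
  eff <- array(rep(bandValues[band], each = dims[1] * dims[2]), dims)
  bandIndex <- array(rep(band, each = dims[1] * dims[2]), dims)
  field <- new("StrainField", effSim = eff, effActual = eff,
               fResultant = 1, fApplied = 1, spacing = spacing,
               origin = c(0, 0, 0))
  list(field = field, bandIndex = bandIndex,
       regionByBand = classifyStrainRegion(bandValues))
}

#' Hexagonal spot grid over a rectangle
#'
#' Visium-like spot layout: rows offset by half the pitch, ~100 um
#' center-to-center, 55 um capture diameter.
#'
#' @param xRange,yRange section-coordinate extents, um.
#' @param pitch center-to-center spacing, um.
#' @param diameter capture diameter, um.
#' @return a spot table (see \code{\link{spotTable}}).
#' @export
makeSpotGrid <- function(xRange, yRange, pitch = 100, diameter = 55) {
  ys <- seq(yRange[1], yRange[2], by = pitch * sqrt(3) / 2)
  rows <- lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) pitch / 2 else 0
    xs <- seq(xRange[1] + off, xRange[2], by = pitch)
    if (!length(xs)) return(NULL)
    data.frame(x = xs, y = ys[r])
  })
  g <- do.call(rbind, rows)
  spotTable(sprintf("SPOT-%04d", seq_len(nrow(g))), g$x, g$y,
            diameter = diameter)
}

#' Count-simulation specification
#'
#' Parameters of the NB spot-count simulator: log-normal baseline means,
#' NB dispersion (variance = mean + phi * mean^2), log-normal spot size
#' factors, and a planted-effect table assigning log2 fold changes to
#' genes in spots of one region (the "contrast" region) relative to all
#' others.
#'
#' @param nGenes number of genes.
#' @param meanlog,sdlog log-normal parameters of baseline means.
#' @param dispersion NB dispersion phi (scalar or per-gene vector).
#' @param sfSdlog log-normal sd of spot size factors.
#' @param effects NULL or data.frame with columns \code{gene} (id) and
#'   \code{log2fc}; optionally \code{set} naming a gene set.
#' @param effectRegion region label whose spots receive the planted
#'   effects.
#' @param seed RNG seed; output is bit-for-bit reproducible.
#' @return list of simulation parameters.
#' @export
countSimSpec <- function(nGenes = 2000, meanlog = log(5), sdlog = 1.25,
                         dispersion = 0.1, sfSdlog = 0.3, effects = NULL,
                         effectRegion = "high", seed = 1L) {
  if (any(dispersion <= 0)) stop("dispersions must be > 0 (spec error)")
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects), all(c("gene", "log2fc") %in%
                                            names(effects)))
    if (any(!is.finite(effects$log2fc)))
      stop("planted log2fc must be finite (spec error)")
  }
  list(nGenes = as.integer(nGenes), meanlog = meanlog, sdlog = sdlog,
       dispersion = dispersion, sfSdlog = sfSdlog, effects = effects,
       effectRegion = effectRegion, seed = as.integer(seed))
}

#' Simulate NB spot counts with planted effects
#'
#' Draws counts[g, s] ~ NB(mean = sf_s * mu_g * 2^(lfc_g * [region_s ==
#' effectRegion]), variance = mean + phi_g * mean^2). The returned truth
#' table records every generative parameter.
#'
#' @param spots a spot table with \code{region} labels.
#' @param spec a \code{\link{countSimSpec}}.
#' @return list with \code{counts} (a \code{SummarizedExperiment}; gene
#'   ids \code{gene0001}, ...) and \code{truth} (mu, phi, size factors,
#'   effect table and the effect-region indicator per spot).
#' @export
simulateCounts <- function(spots, spec = countSimSpec()) {
  stopifnot(is.data.frame(spots), !is.null(spots$region))
  set.seed(spec$seed)
  nG <- spec$nGenes; nS <- nrow(spots)
  genes <- sprintf("gene%04d", seq_len(nG))
  mu <- rlnorm(nG, spec$meanlog, spec$sdlog)
  phi <- rep_len(spec$dispersion, nG)
  sf <- rlnorm(nS, 0, spec$sfSdlog)
  sf <- sf / exp(mean(log(sf)))
  lfc <- setNames(rep(0, nG), genes)
  if (!is.null(spec$effects)) {
    if (!all(spec$effects$gene %in% genes))
      stop("effect table names unknown genes (spec error)")
    lfc[spec$effects$gene] <- spec$effects$log2fc
  }
  inContrast <- spots$region == spec$effectRegion
  mus <- outer(mu, sf) * 2^(outer(lfc, as.numeric(inContrast)))
  counts <- matrix(rnbinom(nG * nS, size = rep(1 / phi, nS), mu = mus),
                   nrow = nG, dimnames = list(genes, spots$barcode))
  se <- spotCountMatrix(counts)
  metadata(se)$simulation <- spec
  list(counts = se,
       truth = list(mu = setNames(mu, genes), phi = setNames(phi, genes),
                    sizeFactors = setNames(sf, spots$barcode),
                    log2fc = lfc, inContrast = setNames(inContrast,
                                                        spots$barcode)))
}
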