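# Voxel image filtering, segmentation and VOI bookkeeping.

# 1D convolution of a 3D array along `axis` with kernel k (odd length),
# zero padding. Used for both the image and the renormalization weights.
.conv1d_axis <- function(a, k, axis) {
  d <- dim(a)
  half <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(k)) {
    off <- j - half - 1L            # source offset relative to target
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idx_t <- which(keep)
    idx_s <- src[keep]
    if (axis == 1L)
      out[idx_t, , ] <- out[idx_t, , ] + k[j] * a[idx_s, , ]
    else if (axis == 2L)
      out[, idx_t, ] <- out[, idx_t, ] + k[j] * a[, idx_s, ]
    else
      out[, , idx_t] <- out[, , idx_t] + k[j] * a[, , idx_s]
  }
  out
}

.gauss_kernel1d <- function(sigma, support) {
  x <- seq(-support, support)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian filter a density image
#'
#' Smooths the volume with a truncated, renormalized Gaussian kernel: the
#' kernel is cut to a (2*support+1)^3 window and its weights normalized to
#' sum to one. At the image border the kernel is renormalized over the
#' voxels actually present (no padding assumption), so constant images are
#' preserved everywhere. Defaults match the standard micro-CT
#' preprocessing (sigma 1.2 voxels, support 1).
#'
#' @param image a \linkS4class{DensityImage}.
#' @param sigma Gaussian standard deviation in voxels (> 0).
#' @param support kernel half-width in voxels (integer >= 1).
#' @return A filtered \linkS4class{DensityImage} of the same shape.
#' @examples
#' img <- densityImage(array(500, c(5, 5, 5)))
#' flt <- gaussianFilterImage(img)
#' all(imageValues(flt) == 500)
#' @export
gaussianFilterImage <- function(image, sigma = 1.2, support = 1) {
  stopifnot(is(image, "DensityImage"))
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a positive number of voxels")
  support <- as.integer(support)
  if (is.na(support) || support < 1L)
    stop("'support' must be an integer >= 1")
  k <- .gauss_kernel1d(sigma, support)
  num <- image@values
  den <- array(1, dim(num))
  for (ax in 1:3) {
    num <- .conv1d_axis(num, k, ax)
    den <- .conv1d_axis(den, k, ax)
  }
  densityImage(num / den, spacing = image@spacing, origin = image@origin)
}

#' Segment bone by density threshold
#'
#' Marks voxels with (filtered) density greater than or equal to the
#' threshold as bone. The comparison is inclusive: a voxel exactly at the
#' threshold is bone. The default, 395 mg HA/cm^3, is the standard
#' mineralized-tissue threshold for in vivo mouse micro-CT.
#'
#' @param image a \linkS4class{DensityImage} (normally Gaussian filtered).
#' @param threshold density threshold, mg HA/cm^3.
#' @return A \linkS4class{BoneMask} recording the threshold used.
#' @examples
#' img <- densityImage(array(c(394, 395, 396, 100), c(2, 2, 1)))
#' # 3D grids only:
#' img <- densityImage(array(c(394, 395, 396, 100, 0, 0, 500, 200), c(2, 2, 2)))
#' sum(imageValues(thresholdBone(img)))
#' @export
thresholdBone <- function(image, threshold = 395) {
  stopifnot(is(image, "DensityImage"))
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  if (length(image@values) == 0L) stop("empty image")
  new("BoneMask", values = image@values >= threshold,
      spacing = image@spacing, origin = image@origin,
      threshold = as.numeric(threshold))
}

#' Validate a VOI label grid and fill per-VOI volumes
#'
#' Checks that the label grid matches the image geometry and uses only the
#' codes 0 (outside), 1 (DC), 2 (DP), 3 (FC), 4 (FP) — the four
#' nonoverlapping analysis volumes — and fills the per-VOI voxel counts.
#' The geometric construction of the VOIs is an input to this package, not
#' synthesized here (except by the phantom generator).
#'
#' @param vois a \linkS4class{VOISet}.
#' @param image the \linkS4class{DensityImage} (or \linkS4class{BoneMask})
#'   the labels refer to.
#' @return The \linkS4class{VOISet} with \code{voiVolumes} filled.
#' @export
validateVois <- function(vois, image) {
  stopifnot(is(vois, "VOISet"))
  if (!identical(dim(vois@labels), dim(imageValues(image))))
    stop("VOI label grid shape does not match the image (geometry error)")
  lab <- as.integer(vois@labels)
  bad <- setdiff(unique(lab), 0:4)
  if (length(bad))
    stop("unknown VOI label code(s): ", paste(bad, collapse = ", "))
  vols <- vapply(VOI_CODES, function(code) sum(lab == code), integer(1))
  vois@volumes <- vols
  vois
}

#' Construct a VOISet from a label grid
#'
#' @param labels 3D integer array with codes 0..4 (see
#'   \linkS4class{VOISet}).
#' @return A \linkS4class{VOISet} (volumes unfilled until
#'   \code{\link{validateVois}}).
#' @export
voiSet <- function(labels) {
  storage.mode(labels) <- "integer"
  new("VOISet", labels = labels)
}
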