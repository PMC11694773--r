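# Time-lapsed bone morphometrics: remodeling classification, BV/TV,
# formation/resorption rates, defect size.

#' Classify remodeling between two registered scans
#'
#' Voxel-wise set logic on two registered bone masks: formation = bone at
#' the later time point only, resorption = bone at the earlier time point
#' only, quiescence = bone at both. The three class counts sum to the size
#' of the union of the two masks.
#'
#' @param maskT1,maskT2 \linkS4class{BoneMask}s at the earlier and later
#'   time point (same shape, pre-registered).
#' @param intervalDays time between the two scans, days (> 0).
#' @return A \linkS4class{RemodelingMap}.
#' @examples
#' a <- array(FALSE, c(3, 3, 3)); b <- a
#' a[1:2, 1, 1] <- TRUE; b[2:3, 1, 1] <- TRUE
#' m1 <- new("BoneMask", values = a, spacing = 10.5, origin = c(0,0,0), threshold = 395)
#' m2 <- new("BoneMask", values = b, spacing = 10.5, origin = c(0,0,0), threshold = 395)
#' remodelingCounts(classifyRemodeling(m1, m2, 7))
#' @export
classifyRemodeling <- function(maskT1, maskT2, intervalDays) {
  stopifnot(is(maskT1, "BoneMask"), is(maskT2, "BoneMask"))
  if (!identical(dim(maskT1@values), dim(maskT2@values)))
    stop("masks have different shapes (geometry error)")
  if (!is.finite(intervalDays) || intervalDays <= 0)
    stop("'intervalDays' must be > 0")
  a <- maskT1@values; b <- maskT2@values
  lab <- array(REMODEL_CODES[["none"]], dim(a))
  lab[b & !a] <- REMODEL_CODES[["formation"]]
  lab[a & b]  <- REMODEL_CODES[["quiescent"]]
  lab[a & !b] <- REMODEL_CODES[["resorption"]]
  counts <- c(formation = sum(b & !a), quiescent = sum(a & b),
              resorption = sum(a & !b))
  new("RemodelingMap", labels = lab, intervalDays = as.numeric(intervalDays),
      counts = as.integer(counts) |> setNames(names(counts)))
}

.tv_reference <- function(volumes) {
  # DC and DP are normalized by the DC volume, FC and FP by the FC volume
  c(DC = volumes[["DC"]], DP = volumes[["DC"]],
    FC = volumes[["FC"]], FP = volumes[["FC"]])
}

#' Bone volume fractions per VOI
#'
#' BV/TV per VOI, in percent, with bone volumes normalized to the central
#' VOIs that represent the total volume of intact bone: DC/DC, DP/DC,
#' FC/FC, FP/FC.
#'
#' @param mask a \linkS4class{BoneMask}.
#' @param vois a validated \linkS4class{VOISet} (see
#'   \code{\link{validateVois}}).
#' @return named numeric vector \code{c(DC=, DP=, FC=, FP=)} of BV/TV in
#'   percent.
#' @export
boneVolumeFractions <- function(mask, vois) {
  stopifnot(is(mask, "BoneMask"), is(vois, "VOISet"))
  if (!identical(dim(mask@values), dim(vois@labels)))
    stop("mask and VOI shapes differ (geometry error)")
  if (length(vois@volumes) == 0L)
    vois <- validateVois(vois, mask)
  tv <- .tv_reference(vois@volumes)
  if (any(tv == 0))
    stop("zero-volume normalizing VOI (undefined ratio): ",
         paste(names(tv)[tv == 0], collapse = ", "))
  bv <- vapply(VOI_CODES, function(code)
    sum(mask@values & vois@labels == code), numeric(1))
  100 * bv / tv
}

#' Bone formation and resorption rates per VOI
#'
#' BFR and BRR in percent of the reference volume per day:
#' BFR = 100 * |formation in VOI| / TV_ref / interval and
#' BRR = -100 * |resorption in VOI| / TV_ref / interval, with TV_ref the
#' DC volume for DC/DP and the FC volume for FC/FP (same normalizers as
#' BV/TV). BRR is reported as a non-positive number.
#'
#' @param remodeling a \linkS4class{RemodelingMap}.
#' @param vois a validated \linkS4class{VOISet}.
#' @return list with numeric vectors \code{bfr} and \code{brr} (percent
#'   per day, named DC/DP/FC/FP) and \code{tvReference}.
#' @export
formationResorptionRates <- function(remodeling, vois) {
  stopifnot(is(remodeling, "RemodelingMap"), is(vois, "VOISet"))
  if (!identical(dim(remodeling@labels), dim(vois@labels)))
    stop("remodeling map and VOI shapes differ (geometry error)")
  if (length(vois@volumes) == 0L)
    stop("VOI volumes unfilled; run validateVois() first")
  tv <- .tv_reference(vois@volumes)
  if (any(tv == 0))
    stop("zero-volume normalizing VOI (undefined ratio): ",
         paste(names(tv)[tv == 0], collapse = ", "))
  dt <- remodeling@intervalDays
  form <- vapply(VOI_CODES, function(code)
    sum(remodeling@labels == REMODEL_CODES[["formation"]] &
          vois@labels == code), numeric(1))
  reso <- vapply(VOI_CODES, function(code)
    sum(remodeling@labels == REMODEL_CODES[["resorption"]] &
          vois@labels == code), numeric(1))
  list(bfr = 100 * form / tv / dt,
       brr = -100 * reso / tv / dt,
       tvReference = tv)
}

#' Defect size from defect volume and adjacent cortical areas
#'
#' h = 2 * DC / (CSA_P + CSA_D), where DC is the defect-center volume at
#' the baseline scan (mm^3) and CSA_P, CSA_D the proximal and distal
#' cortical cross-sectional areas directly adjacent to the defect (mm^2).
#'
#' @param dcVolume defect volume, mm^3.
#' @param csaP,csaD proximal and distal cross-sectional areas, mm^2.
#' @return defect size h, mm.
#' @examples
#' defectSize(0.34, 0.5, 0.5)   # 0.68 mm
#' @export
defectSize <- function(dcVolume, csaP, csaD) {
  if (!is.finite(csaP + csaD) || csaP + csaD <= 0)
    stop("CSA_P + CSA_D must be > 0 (undefined ratio)")
  2 * dcVolume / (csaP + csaD)
}
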