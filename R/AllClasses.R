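#' @import methods
#' @importFrom stats median sd pchisq pt p.adjust optimize rnbinom rlnorm
#'   rnorm runif setNames lowess approx quantile dnbinom t.test
#' @importFrom utils read.csv write.csv read.delim
NULL

VOI_CODES <- c(DC = 1L, DP = 2L, FC = 3L, FP = 4L)
REMODEL_CODES <- c(none = 0L, formation = 1L, quiescent = 2L, resorption = 3L)

.check_grid3d <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    return("'values' must be a 3D array")
  NULL
}

#' DensityImage: a 3D mineral-density volume
#'
#' Container for a calibrated micro-CT density volume (mg HA/cm^3) on an
#' isotropic voxel grid. The third array index is the axial (loading)
#' direction of the femur. Physical coordinates of voxel centers are
#' \code{origin + (index - 0.5) * spacing} (1-based indexing), in
#' micrometres.
#'
#' @slot values 3D numeric array of densities (mg HA/cm^3).
#' @slot spacing voxel edge length in micrometres (isotropic; default 10.5).
#' @slot origin physical coordinate (um) of the corner of voxel (1,1,1).
#' @export
setClass("DensityImage",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = 10.5, origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- .check_grid3d(object@values)
    if (!is.null(msg)) return(msg)
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      return("'spacing' must be a single positive number (um)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("'origin' must be a finite length-3 vector (um)")
    if (any(!is.finite(object@values)))
      return("density values must all be finite")
    TRUE
  })

#' Construct a DensityImage
#'
#' @param values 3D numeric array (mg HA/cm^3).
#' @param spacing isotropic voxel edge length, um.
#' @param origin physical coordinate of the corner of the first voxel, um.
#' @return A \linkS4class{DensityImage}.
#' @examples
#' img <- densityImage(array(500, c(4, 4, 4)))
#' dim(imageValues(img))
#' @export
densityImage <- function(values, spacing = 10.5, origin = c(0, 0, 0)) {
  new("DensityImage", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' BoneMask: segmented bone voxels
#'
#' Boolean grid marking mineralized-tissue voxels, produced by thresholding
#' a (filtered) \linkS4class{DensityImage}; remembers the threshold used.
#'
#' @slot values 3D logical array, same shape as the source image.
#' @slot spacing voxel edge length (um).
#' @slot origin grid origin (um).
#' @slot threshold density threshold used (mg HA/cm^3).
#' @export
setClass("BoneMask",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    msg <- .check_grid3d(object@values)
    if (!is.null(msg)) return(msg)
    if (!is.logical(object@values)) return("'values' must be logical")
    if (anyNA(object@values)) return("mask may not contain NA")
    TRUE
  })

#' VOISet: volumes-of-interest labels
#'
#' Integer label grid with codes 0 = outside, 1 = DC (defect center),
#' 2 = DP (defect periphery), 3 = FC (fracture cortex + medullary cavity),
#' 4 = FP (cortex periphery). The four VOIs are pairwise disjoint by
#' construction of the single-label grid.
#'
#' @slot labels 3D integer array with codes 0..4.
#' @slot volumes named integer vector of per-VOI voxel counts (filled by
#'   \code{\link{validateVois}}).
#' @export
setClass("VOISet",
  representation(labels = "array", volumes = "integer"),
  prototype(volumes = integer(0)),
  validity = function(object) {
    msg <- .check_grid3d(object@labels)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' RemodelingMap: formation / quiescence / resorption labels
#'
#' Per-voxel remodeling classification between two registered time points:
#' formation (bone at the later scan only), quiescence (bone at both),
#' resorption (bone at the earlier scan only).
#'
#' @slot labels 3D integer array with codes 0 none, 1 formation,
#'   2 quiescent, 3 resorption.
#' @slot intervalDays time between the two frames, days.
#' @slot counts named integer vector of class counts.
#' @export
setClass("RemodelingMap",
  representation(labels = "array", intervalDays = "numeric",
                 counts = "integer"),
  validity = function(object) {
    msg <- .check_grid3d(object@labels)
    if (!is.null(msg)) return(msg)
    if (object@intervalDays <= 0) return("'intervalDays' must be > 0")
    TRUE
  })

#' FEModel: voxel-hexahedral finite-element model
#'
#' Linear-elastic micro-FE model built from a density image: one 8-node
#' hexahedral element per voxel, per-element Young's modulus, a single
#' global Poisson ratio, and a uniaxial-compression boundary-condition
#' specification (bottom slice fixed, top slice displaced axially).
#'
#' @slot moduli 3D numeric array of Young's moduli (GPa); every element > 0.
#' @slot poisson global Poisson ratio.
#' @slot spacing element edge length (um).
#' @slot compressionFraction prescribed top-slice axial displacement as a
#'   fraction of model height (default 0.01).
#' @slot plateMask logical array marking voxels replaced by 20 GPa capping
#'   plate material.
#' @export
setClass("FEModel",
  representation(moduli = "array", poisson = "numeric", spacing = "numeric",
                 compressionFraction = "numeric", plateMask = "array"),
  validity = function(object) {
    msg <- .check_grid3d(object@moduli)
    if (!is.null(msg)) return(msg)
    if (any(object@moduli <= 0) || any(!is.finite(object@moduli)))
      return("all element moduli must be finite and > 0")
    if (object@poisson < 0 || object@poisson >= 0.5)
      return("'poisson' must lie in [0, 0.5)")
    if (object@compressionFraction <= 0 || object@compressionFraction > 0.05)
      return("'compressionFraction' must lie in (0, 0.05]")
    if (any(dim(object@moduli) < 2L))
      return("FE use requires at least 2 voxels per axis")
    TRUE
  })

#' StrainField: per-element effective strain
#'
#' Result of the unit uniaxial-compression simulation: per-element
#' effective strain \code{effSim} (microstrain) and the resultant axial
#' reaction force \code{fResultant} (N) summed over top-surface nodes.
#' After \code{\link{scaleStrains}}, \code{effActual} holds the field
#' rescaled to an applied force.
#'
#' @slot effSim 3D array, effective strain from the unit simulation (ue).
#' @slot effActual 3D array, strain scaled to the applied force (ue); may
#'   be an empty array before scaling.
#' @slot fResultant resultant reaction force of the unit simulation (N).
#' @slot fApplied applied force used for the scaling (N; NA before scaling).
#' @slot spacing element edge (um).
#' @slot origin grid origin (um).
#' @export
setClass("StrainField",
  representation(effSim = "array", effActual = "array",
                 fResultant = "numeric", fApplied = "numeric",
                 spacing = "numeric", origin = "numeric"),
  prototype(fApplied = NA_real_, origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- .check_grid3d(object@effSim)
    if (!is.null(msg)) return(msg)
    if (any(object@effSim < 0)) return("effective strains must be >= 0")
    TRUE
  })

#' LoadPrescription: individualized loading parameters
#'
#' Parameters and result of the adaptive load optimization: the target
#' median effective strain, the force clamp, and the overstrain safety
#' rule (reduce the load 1 N at a time while more than
#' \code{overstrainVoxelLimit} bone voxels exceed
#' \code{overstrainThreshold}).
#'
#' @slot fApplied applied force (N); filled by \code{\link{optimizeLoad}}.
#' @slot targetMedianStrain target median effective strain (ue).
#' @slot fMin,fMax force clamp bounds (N; defaults 8 and 16).
#' @slot overstrainThreshold failure-risk strain threshold (ue; 10000).
#' @slot overstrainVoxelLimit maximum tolerated overstrained voxels (100).
#' @slot decrement force reduction step (N; 1).
#' @slot overstrainCount overstrained bone voxels at the returned load.
#' @export
setClass("LoadPrescription",
  representation(fApplied = "numeric", targetMedianStrain = "numeric",
                 fMin = "numeric", fMax = "numeric",
                 overstrainThreshold = "numeric",
                 overstrainVoxelLimit = "numeric", decrement = "numeric",
                 overstrainCount = "integer"),
  prototype(fApplied = NA_real_, fMin = 8, fMax = 16,
            overstrainThreshold = 10000, overstrainVoxelLimit = 100,
            decrement = 1, overstrainCount = NA_integer_),
  validity = function(object) {
    if (object@decrement <= 0) return("'decrement' must be > 0")
    if (object@fMin > object@fMax) return("'fMin' must be <= 'fMax'")
    TRUE
  })

#' Construct a LoadPrescription
#'
#' @param targetMedianStrain target median effective strain, ue.
#' @param fMin,fMax force clamp, N.
#' @param overstrainThreshold strain above which a voxel counts as
#'   overstrained, ue.
#' @param overstrainVoxelLimit tolerated number of overstrained voxels.
#' @param decrement load reduction step, N.
#' @return A \linkS4class{LoadPrescription}.
#' @export
loadPrescription <- function(targetMedianStrain, fMin = 8, fMax = 16,
                             overstrainThreshold = 10000,
                             overstrainVoxelLimit = 100, decrement = 1) {
  new("LoadPrescription", targetMedianStrain = targetMedianStrain,
      fMin = fMin, fMax = fMax, overstrainThreshold = overstrainThreshold,
      overstrainVoxelLimit = overstrainVoxelLimit, decrement = decrement)
}

#' SectionPose: rigid pose of a histological section in the volume
#'
#' Rigid transform (rotation + translation, homogeneous 4x4 matrix)
#' mapping 2D section-plane coordinates (um, z = 0 on the section) into
#' volume physical coordinates (um), plus the section thickness.
#'
#' @slot matrix 4x4 homogeneous rigid transform; rotation block orthonormal
#'   with determinant +1.
#' @slot thickness section thickness, um (default 5).
#' @export
setClass("SectionPose",
  representation(matrix = "matrix", thickness = "numeric"),
  prototype(thickness = 5),
  validity = function(object) {
    m <- object@matrix
    if (!all(dim(m) == c(4L, 4L))) return("pose must be a 4x4 matrix")
    R <- m[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      return("rotation block must be orthonormal")
    if (det(R) < 0) return("rotation must be proper (determinant +1)")
    if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 0)
      return("last row must be (0,0,0,1)")
    if (object@thickness <= 0) return("'thickness' must be > 0")
    TRUE
  })

#' Construct a SectionPose
#'
#' @param matrix 4x4 homogeneous rigid transform (um).
#' @param thickness section thickness, um.
#' @return A \linkS4class{SectionPose}.
#' @examples
#' sectionPose()                       # identity pose
#' sectionPose(translation = c(0, 0, 500))
#' @param rotation optional 3x3 rotation used (with \code{translation}) to
#'   build the matrix when \code{matrix} is missing.
#' @param translation optional length-3 translation (um).
#' @export
sectionPose <- function(matrix = NULL, rotation = diag(3),
                        translation = c(0, 0, 0), thickness = 5) {
  if (is.null(matrix)) {
    matrix <- diag(4)
    matrix[1:3, 1:3] <- rotation
    matrix[1:3, 4] <- translation
  }
  new("SectionPose", matrix = matrix, thickness = thickness)
}

## ---- accessors ----

#' Grid accessors
#'
#' \code{imageValues} returns the raw 3D array of a volume object;
#' \code{voxelSpacing} its isotropic voxel edge (um); \code{voxelOrigin}
#' its grid origin (um).
#'
#' @param x a \linkS4class{DensityImage}, \linkS4class{BoneMask},
#'   \linkS4class{VOISet}, \linkS4class{RemodelingMap} or
#'   \linkS4class{StrainField}.
#' @return \code{imageValues}: 3D array; \code{voxelSpacing}: numeric(1);
#'   \code{voxelOrigin}: numeric(3).
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname imageValues
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname imageValues
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname imageValues
setMethod("imageValues", "DensityImage", function(x) x@values)
#' @rdname imageValues
setMethod("imageValues", "BoneMask", function(x) x@values)
#' @rdname imageValues
setMethod("imageValues", "VOISet", function(x) x@labels)
#' @rdname imageValues
setMethod("imageValues", "RemodelingMap", function(x) x@labels)
#' @rdname imageValues
setMethod("voxelSpacing", "DensityImage", function(x) x@spacing)
#' @rdname imageValues
setMethod("voxelSpacing", "BoneMask", function(x) x@spacing)
#' @rdname imageValues
setMethod("voxelSpacing", "StrainField", function(x) x@spacing)
#' @rdname imageValues
setMethod("voxelOrigin", "DensityImage", function(x) x@origin)
#' @rdname imageValues
setMethod("voxelOrigin", "BoneMask", function(x) x@origin)
#' @rdname imageValues
setMethod("voxelOrigin", "StrainField", function(x) x@origin)

#' Strain-field accessors
#'
#' @param x a \linkS4class{StrainField}.
#' @return \code{effSim} and \code{effActual}: 3D arrays of effective
#'   strain in microstrain (\code{effActual} errors if the field has not
#'   been scaled yet); \code{fResultant}: the unit-simulation resultant
#'   force (N).
#' @export
setGeneric("effSim", function(x) standardGeneric("effSim"))
#' @rdname effSim
#' @export
setGeneric("effActual", function(x) standardGeneric("effActual"))
#' @rdname effSim
#' @export
setGeneric("fResultant", function(x) standardGeneric("fResultant"))
#' @rdname effSim
setMethod("effSim", "StrainField", function(x) x@effSim)
#' @rdname effSim
setMethod("effActual", "StrainField", function(x) {
  if (length(x@effActual) == 0L)
    stop("strain field has not been scaled yet; call scaleStrains()")
  x@effActual
})
#' @rdname effSim
setMethod("fResultant", "StrainField", function(x) x@fResultant)

#' Per-VOI voxel counts
#'
#' @param x a \linkS4class{VOISet} (after \code{\link{validateVois}}).
#' @return named integer vector with elements DC, DP, FC, FP.
#' @export
setGeneric("voiVolumes", function(x) standardGeneric("voiVolumes"))
#' @rdname voiVolumes
setMethod("voiVolumes", "VOISet", function(x) x@volumes)

#' Remodeling class counts
#'
#' @param x a \linkS4class{RemodelingMap}.
#' @return named integer vector (formation, quiescent, resorption).
#' @export
setGeneric("remodelingCounts", function(x) standardGeneric("remodelingCounts"))
#' @rdname remodelingCounts
setMethod("remodelingCounts", "RemodelingMap", function(x) x@counts)

## ---- show methods ----

setMethod("show", "DensityImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityImage: %d x %d x %d voxels, %.3g um spacing\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  density range [%.1f, %.1f] mg HA/cm^3\n",
              min(object@values), max(object@values)))
})

setMethod("show", "BoneMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BoneMask: %d x %d x %d voxels, %d bone (threshold %.0f mg HA/cm^3)\n",
              d[1], d[2], d[3], sum(object@values), object@threshold))
})

setMethod("show", "VOISet", function(object) {
  cat("VOISet:", paste(dim(object@labels), collapse = " x "), "voxels\n")
  if (length(object@volumes))
    cat("  volumes:", paste(names(object@volumes), object@volumes,
                            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RemodelingMap", function(object) {
  cat(sprintf("RemodelingMap over %.3g days:\n", object@intervalDays))
  cat("  ", paste(names(object@counts), object@counts, sep = "=",
                  collapse = ", "), "\n")
})

setMethod("show", "FEModel", function(object) {
  d <- dim(object@moduli)
  cat(sprintf("FEModel: %d x %d x %d hexahedral elements (%.3g um), nu=%.2f\n",
              d[1], d[2], d[3], object@spacing, object@poisson))
  cat(sprintf("  moduli [%.3g, %.3g] GPa; %.1f%% axial compression; %d plate voxels\n",
              min(object@moduli), max(object@moduli),
              100 * object@compressionFraction, sum(object@plateMask)))
})

setMethod("show", "StrainField", function(object) {
  d <- dim(object@effSim)
  cat(sprintf("StrainField: %d x %d x %d elements, F_resultant = %.4g N\n",
              d[1], d[2], d[3], object@fResultant))
  cat(sprintf("  eff_sim median %.0f ue", median(object@effSim)))
  if (length(object@effActual))
    cat(sprintf("; eff_actual median %.0f ue at F_applied = %.3g N",
                median(object@effActual), object@fApplied))
  cat("\n")
})

setMethod("show", "LoadPrescription", function(object) {
  cat(sprintf("LoadPrescription: target %.0f ue, clamp [%g, %g] N\n",
              object@targetMedianStrain, object@fMin, object@fMax))
  if (!is.na(object@fApplied))
    cat(sprintf("  optimized F_applied = %g N (%d overstrained voxels)\n",
                object@fApplied, object@overstrainCount))
})

setMethod("show", "SectionPose", function(object) {
  cat(sprintf("SectionPose: %.3g um section; translation (%.1f, %.1f, %.1f) um\n",
              object@thickness, object@matrix[1, 4], object@matrix[2, 4],
              object@matrix[3, 4]))
})
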