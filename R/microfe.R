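# Voxel-hexahedral linear-elastic micro-FE: mesh from a density image,
# uniaxial compression solve, effective strain, force scaling, adaptive
# load optimization.
#
# Internal unit system: lengths mm, moduli MPa, forces N, displacements mm.
# The public API takes spacing in um and moduli in GPa.

#' @importFrom Matrix sparseMatrix forceSymmetric crossprod Diagonal
NULL

# Local corner order of the trilinear hexahedron: natural coordinates
# (-1,-1,-1),(1,-1,-1),(1,1,-1),(-1,1,-1),(-1,-1,1),(1,-1,1),(1,1,1),(-1,1,1)
HEX_NAT <- matrix(c(-1, -1, -1,   1, -1, -1,   1,  1, -1,  -1,  1, -1,
                    -1, -1,  1,   1, -1,  1,   1,  1,  1,  -1,  1,  1),
                  nrow = 8, byrow = TRUE)

# Shape-function derivatives wrt natural coordinates at (xi, eta, zeta): 8 x 3
.hex_dN <- function(xi, eta, zeta) {
  g <- HEX_NAT
  cbind(g[, 1] * (1 + g[, 2] * eta) * (1 + g[, 3] * zeta),
        (1 + g[, 1] * xi) * g[, 2] * (1 + g[, 3] * zeta),
        (1 + g[, 1] * xi) * (1 + g[, 2] * eta) * g[, 3]) / 8
}

# 6x6 isotropic elasticity matrix (engineering shear strains), E = 1
.elastic_C_unit <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  C
}

# Strain-displacement matrix (6 x 24) for a cube of edge h at a natural point
.hex_B <- function(xi, eta, zeta, h) {
  dN <- .hex_dN(xi, eta, zeta) * (2 / h)   # d/dx = d/dxi * 2/h for a cube
  B <- matrix(0, 6, 24)
  ix <- 3 * (0:7) + 1
  B[1, ix]     <- dN[, 1]
  B[2, ix + 1] <- dN[, 2]
  B[3, ix + 2] <- dN[, 3]
  B[4, ix]     <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
  B[5, ix + 1] <- dN[, 3]; B[5, ix + 2] <- dN[, 2]
  B[6, ix]     <- dN[, 3]; B[6, ix + 2] <- dN[, 1]
  B
}

#' Stiffness matrix of a cubic 8-node hexahedral element
#'
#' Standard isoparametric trilinear hexahedron with 2 x 2 x 2 Gauss
#' quadrature. Because all voxel elements are congruent cubes, the matrix
#' for arbitrary (E, h) is the unit matrix scaled by E * h.
#'
#' @param E Young's modulus (any unit; output stiffness is in E*h units).
#' @param nu Poisson ratio.
#' @param h element edge length.
#' @return 24 x 24 symmetric stiffness matrix (dof order: node-major,
#'   x/y/z within node).
#' @export
hexElementStiffness <- function(E = 1, nu = 0.3, h = 1) {
  gp <- 1 / sqrt(3)
  C <- .elastic_C_unit(nu)
  ke <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (a in c(-gp, gp)) for (b in c(-gp, gp)) for (c in c(-gp, gp)) {
    B <- .hex_B(a, b, c, h)
    ke <- ke + t(B) %*% C %*% B * detJ
  }
  E * (ke + t(ke)) / 2
}

#' Build a voxel micro-FE model from a density image
#'
#' Converts every voxel to a linear hexahedral element. Bone voxels (per
#' the mask) get a modulus from a linear density-to-modulus calibration
#' E = slope * density; soft-tissue voxels are assigned a fixed small
#' modulus (default 0.003 GPa) so the system stays positive definite; and
#' soft-tissue voxels on the top and bottom slices are replaced by stiff
#' capping-plate material (default 20 GPa) to suppress edge effects of the
#' marrow cavity and callus under the prescribed displacement.
#'
#' @param image a \linkS4class{DensityImage}.
#' @param mask a \linkS4class{BoneMask} aligned with the image.
#' @param slope density-to-modulus calibration, GPa per mg HA/cm^3. The
#'   default (1/60) maps 1200 mg HA/cm^3 cortical bone to 20 GPa; supply
#'   the calibration appropriate to your scanner.
#' @param softModulus Young's modulus of non-bone tissue, GPa.
#' @param plateModulus Young's modulus of the capping plates, GPa.
#' @param poisson global Poisson ratio (not density dependent).
#' @param compressionFraction prescribed axial compression of the top
#'   slice as a fraction of model height (default 0.01, i.e. 1\%).
#' @param crop optional list of three index ranges to crop image and mask
#'   to a region of interest before meshing.
#' @return An \linkS4class{FEModel}.
#' @export
buildFEModel <- function(image, mask, slope = 1 / 60, softModulus = 0.003,
                         plateModulus = 20, poisson = 0.3,
                         compressionFraction = 0.01, crop = NULL) {
  stopifnot(is(image, "DensityImage"), is(mask, "BoneMask"))
  vals <- image@values; bone <- mask@values
  if (!identical(dim(vals), dim(bone)))
    stop("image and mask are not aligned (geometry error)")
  if (!is.null(crop)) {
    stopifnot(is.list(crop), length(crop) == 3L)
    vals <- vals[crop[[1]], crop[[2]], crop[[3]], drop = FALSE]
    bone <- bone[crop[[1]], crop[[2]], crop[[3]], drop = FALSE]
  }
  E <- array(softModulus, dim(vals))
  if (any(bone)) {
    Eb <- slope * vals[bone]
    if (any(!is.finite(Eb)) || any(Eb <= 0))
      stop("density-to-modulus mapping produced non-positive moduli ",
           "(material error)")
    E[bone] <- Eb
  }
  nz <- dim(vals)[3]
  plate <- array(FALSE, dim(vals))
  plate[, , c(1L, nz)] <- !bone[, , c(1L, nz)]
  E[plate] <- plateModulus
  new("FEModel", moduli = E, poisson = poisson, spacing = mask@spacing,
      compressionFraction = compressionFraction, plateMask = plate)
}

# Node/dof bookkeeping for an nx x ny x nz element grid.
.fe_mesh <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  nid <- function(i, j, k) i + (j - 1L) * nnx + (k - 1L) * nnx * nny
  eg <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  # corner offsets matching HEX_NAT order (x ~ xi, y ~ eta, z ~ zeta)
  off <- (HEX_NAT + 1L) / 2L
  nodes <- sapply(seq_len(8), function(c)
    nid(eg$i + off[c, 1], eg$j + off[c, 2], eg$k + off[c, 3]))
  storage.mode(nodes) <- "integer"
  list(nx = nx, ny = ny, nz = nz, nNodes = nnx * nny * nnz,
       elemNodes = nodes, nid = nid, nnx = nnx, nny = nny, nnz = nnz)
}

#' Solve the uniaxial compression problem
#'
#' Assembles the global stiffness matrix (one trilinear hexahedral element
#' per voxel, a single unit element matrix scaled per element by E),
#' applies the uniaxial boundary conditions — bottom-slice nodes fixed in
#' all directions, top-slice nodes prescribed an axial displacement of
#' \code{compressionFraction} times the model height with in-plane motion
#' free — and solves the linear system by sparse Cholesky factorization.
#'
#' Per element, the strain tensor is evaluated at the centroid from the
#' trilinear shape-function gradients and converted to the effective
#' strain EFF = sqrt(2U/E), U the strain-energy density, which combines
#' volumetric and deviatoric contributions. The resultant force is the sum
#' of axial nodal reactions over the top surface.
#'
#' @param model an \linkS4class{FEModel}.
#' @param compressionFraction override of the model's prescribed
#'   compression fraction.
#' @param details if TRUE, return a list with the strain field, the nodal
#'   displacement matrix (nNodes x 3, mm), and the summed top/bottom axial
#'   reactions (N).
#' @param tol retained for interface compatibility; the direct sparse
#'   solve is exact to factorization accuracy and does not iterate.
#' @return A \linkS4class{StrainField} (effSim in microstrain,
#'   fResultant in N), or a list when \code{details = TRUE}.
#' @export
solveUniaxial <- function(model, compressionFraction = NULL,
                          details = FALSE, tol = 1e-8) {
  stopifnot(is(model, "FEModel"))
  cf <- if (is.null(compressionFraction)) model@compressionFraction
        else compressionFraction
  dims <- dim(model@moduli)
  mesh <- .fe_mesh(dims)
  h_mm <- model@spacing / 1000
  E_MPa <- as.vector(model@moduli) * 1000
  keu <- hexElementStiffness(E = 1, nu = model@poisson, h = 1)

  nel <- length(E_MPa)
  elemDof <- matrix(0L, nel, 24L)
  elemDof[, seq(1, 24, 3)] <- 3L * (mesh$elemNodes - 1L) + 1L
  elemDof[, seq(2, 24, 3)] <- 3L * (mesh$elemNodes - 1L) + 2L
  elemDof[, seq(3, 24, 3)] <- 3L * mesh$elemNodes

  scale <- E_MPa * h_mm                 # ke = E * h * ke_unit for a cube
  kev <- as.vector(keu)                 # column-major, 576
  rloc <- rep(seq_len(24), times = 24)
  cloc <- rep(seq_len(24), each = 24)
  ii <- as.vector(t(elemDof[, rloc]))   # element-major ordering
  jj <- as.vector(t(elemDof[, cloc]))
  xx <- rep(kev, times = nel) * rep(scale, each = 576L)
  nDof <- 3L * mesh$nNodes
  # the element matrix is symmetric, so keeping one orientation of each
  # off-diagonal pair assembles the upper triangle exactly
  keep <- ii <= jj
  K <- sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                    dims = c(nDof, nDof), symmetric = TRUE)
  rm(ii, jj, xx, keep)

  # boundary conditions
  nnx <- mesh$nnx; nny <- mesh$nny; nnz <- mesh$nnz
  planeNodes <- function(k) {
    ij <- expand.grid(i = seq_len(nnx), j = seq_len(nny))
    mesh$nid(ij$i, ij$j, k)
  }
  bottom <- planeNodes(1L)
  top <- planeNodes(nnz)
  height_mm <- mesh$nz * h_mm
  delta <- -cf * height_mm              # compression: top moves down

  u <- numeric(nDof)
  fixedDof <- c(3L * (bottom - 1L) + 1L, 3L * (bottom - 1L) + 2L,
                3L * bottom)
  presDof <- 3L * top
  u[presDof] <- delta
  constrained <- c(fixedDof, presDof)
  free <- setdiff(seq_len(nDof), constrained)

  rhs <- -K[free, presDof, drop = FALSE] %*% u[presDof]
  chol <- Matrix::Cholesky(forceSymmetric(K[free, free]), super = TRUE)
  u[free] <- as.vector(Matrix::solve(chol, rhs, system = "A"))

  r <- as.vector(K %*% u)               # reactions at constrained dofs
  fTop <- sum(r[3L * top])
  fBottom <- sum(r[3L * bottom])
  fRes <- abs(fTop)
  if (fRes <= 0) stop("zero resultant force (solver error)")

  # centroid strain and effective strain per element
  B0 <- .hex_B(0, 0, 0, h_mm)
  Ue <- matrix(u[t(elemDof)], nrow = nel, ncol = 24, byrow = TRUE)
  eps <- Ue %*% t(B0)                   # nel x 6, engineering strains
  Cu <- .elastic_C_unit(model@poisson)
  eff <- sqrt(pmax(rowSums((eps %*% Cu) * eps), 0)) * 1e6
  field <- new("StrainField", effSim = array(eff, dims),
               effActual = array(numeric(0), c(0L, 0L, 0L)),
               fResultant = fRes, spacing = model@spacing,
               origin = c(0, 0, 0))
  if (!details) return(field)
  list(field = field,
       displacements = matrix(u, ncol = 3, byrow = TRUE),
       fTop = fTop, fBottom = fBottom,
       equilibriumResidual = abs(fTop + fBottom) / abs(fTop))
}

#' Scale simulated strains to an applied force
#'
#' The micro-FE problem is linear, so the strain field under an applied
#' force follows from the unit simulation by
#' eps_actual = (F_applied / F_resultant) * eps_simulation, element-wise.
#' Re-scaling replaces any previous scaling; it never compounds.
#'
#' @param field a \linkS4class{StrainField} from \code{\link{solveUniaxial}}.
#' @param fApplied applied force, N.
#' @return The field with \code{effActual} filled.
#' @export
scaleStrains <- function(field, fApplied) {
  stopifnot(is(field, "StrainField"))
  if (!is.finite(field@fResultant) || field@fResultant <= 0)
    stop("non-positive resultant force (scaling error)")
  field@effActual <- (fApplied / field@fResultant) * field@effSim
  field@fApplied <- fApplied
  field
}

#' Optimize the applied load for a target median strain
#'
#' Individualized loading: scale the applied force so that the median
#' effective strain over bone elements reaches the target, clamp the force
#' to the prescribed bounds (default 8 to 16 N), then apply the structural
#' failure-risk rule — while more than \code{overstrainVoxelLimit} bone
#' voxels exceed \code{overstrainThreshold} (default 10,000 ue) at the
#' current force and a further reduction stays within the clamp, reduce
#' the force by \code{decrement} (default 1 N).
#'
#' @param field a \linkS4class{StrainField} (unit simulation).
#' @param prescription a \linkS4class{LoadPrescription} with the target
#'   median strain and safety parameters.
#' @param boneMask a \linkS4class{BoneMask}; the median and the overstrain
#'   count are taken over bone elements only.
#' @param singleStep if TRUE apply the 1 N reduction at most once instead
#'   of iterating to a fixed point.
#' @return The prescription with \code{fApplied} and the overstrain count
#'   at the returned load filled in.
#' @export
optimizeLoad <- function(field, prescription, boneMask, singleStep = FALSE) {
  stopifnot(is(field, "StrainField"), is(prescription, "LoadPrescription"),
            is(boneMask, "BoneMask"))
  if (!identical(dim(field@effSim), dim(boneMask@values)))
    stop("strain field and bone mask shapes differ (geometry error)")
  effBone <- field@effSim[boneMask@values]
  med <- median(effBone)
  if (!is.finite(med) || med <= 0)
    stop("median simulated strain over bone is not positive ",
         "(optimization error)")
  p <- prescription
  f <- field@fResultant * p@targetMedianStrain / med
  f <- min(max(f, p@fMin), p@fMax)
  overs <- function(force) sum(effBone * force / field@fResultant >
                                 p@overstrainThreshold)
  n_over <- overs(f)
  while (n_over > p@overstrainVoxelLimit && f - p@decrement >= p@fMin) {
    f <- f - p@decrement
    n_over <- overs(f)
    if (singleStep) break
  }
  p@fApplied <- f
  p@overstrainCount <- as.integer(n_over)
  p
}
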