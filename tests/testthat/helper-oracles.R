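# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: direct loops, dense algebra,
# higher-order quadrature.

# Brute-force truncated-Gaussian smoothing: per-voxel window sum with
# edge renormalization.
oracle_gaussian3d <- function(a, sigma, support) {
  d <- dim(a)
  w1 <- exp(-(-support:support)^2 / (2 * sigma^2))
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0; wt <- 0
    for (di in -support:support) for (dj in -support:support)
      for (dk in -support:support) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        w <- w1[di + support + 1] * w1[dj + support + 1] *
          w1[dk + support + 1]
        acc <- acc + w * a[ii, jj, kk]
        wt <- wt + w
      }
    out[i, j, k] <- acc / wt
  }
  out
}

# Dense direct FE oracle: independent isoparametric assembly with 3x3x3
# Gauss quadrature and a dense solve. moduli in GPa, spacing um; same
# boundary conditions as the package solver (bottom fixed, top axial
# displacement, in-plane free). Returns nodal displacements (mm) and the
# summed axial reactions.
oracle_fe_dense <- function(moduli, spacing, nu, compression) {
  d <- dim(moduli)
  h <- spacing / 1000
  nn <- d + 1L
  nid <- function(i, j, k) i + (j - 1) * nn[1] + (k - 1) * nn[1] * nn[2]
  nNodes <- prod(nn)
  ndof <- 3 * nNodes
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  gnat <- corners * 2 - 1
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  Cmat <- function(E, nu) {
    l <- E * nu / ((1 + nu) * (1 - 2 * nu)); m <- E / (2 * (1 + nu))
    C <- diag(c(rep(2 * m, 3), rep(m, 3)))
    C[1:3, 1:3] <- C[1:3, 1:3] + l
    C
  }
  ke_for <- function(E) {
    ke <- matrix(0, 24, 24)
    C <- Cmat(E * 1000, nu)   # MPa
    for (ia in 1:3) for (ib in 1:3) for (ic in 1:3) {
      xi <- gp[ia]; eta <- gp[ib]; zeta <- gp[ic]
      dN <- cbind(gnat[, 1] * (1 + gnat[, 2] * eta) * (1 + gnat[, 3] * zeta),
                  (1 + gnat[, 1] * xi) * gnat[, 2] * (1 + gnat[, 3] * zeta),
                  (1 + gnat[, 1] * xi) * (1 + gnat[, 2] * eta) * gnat[, 3]) / 8
      dNx <- dN * 2 / h
      B <- matrix(0, 6, 24)
      for (nloc in 1:8) {
        c0 <- 3 * (nloc - 1)
        B[1, c0 + 1] <- dNx[nloc, 1]
        B[2, c0 + 2] <- dNx[nloc, 2]
        B[3, c0 + 3] <- dNx[nloc, 3]
        B[4, c0 + 1] <- dNx[nloc, 2]; B[4, c0 + 2] <- dNx[nloc, 1]
        B[5, c0 + 2] <- dNx[nloc, 3]; B[5, c0 + 3] <- dNx[nloc, 2]
        B[6, c0 + 1] <- dNx[nloc, 3]; B[6, c0 + 3] <- dNx[nloc, 1]
      }
      ke <- ke + t(B) %*% C %*% B * gw[ia] * gw[ib] * gw[ic] * (h / 2)^3
    }
    ke
  }
  K <- matrix(0, ndof, ndof)
  for (ex in seq_len(d[1])) for (ey in seq_len(d[2])) for (ez in seq_len(d[3])) {
    nodes <- sapply(1:8, function(c)
      nid(ex + corners[c, 1], ey + corners[c, 2], ez + corners[c, 3]))
    dofs <- as.vector(rbind(3 * (nodes - 1) + 1, 3 * (nodes - 1) + 2,
                            3 * nodes))
    ke <- ke_for(moduli[ex, ey, ez])
    K[dofs, dofs] <- K[dofs, dofs] + ke
  }
  bottom <- top <- integer(0)
  for (i in seq_len(nn[1])) for (j in seq_len(nn[2])) {
    bottom <- c(bottom, nid(i, j, 1))
    top <- c(top, nid(i, j, nn[3]))
  }
  u <- numeric(ndof)
  delta <- -compression * d[3] * h
  pres <- 3 * top
  u[pres] <- delta
  fixed <- c(3 * (bottom - 1) + 1, 3 * (bottom - 1) + 2, 3 * bottom)
  free <- setdiff(seq_len(ndof), c(fixed, pres))
  u[free] <- solve(K[free, free], -K[free, pres, drop = FALSE] %*% u[pres])
  r <- K %*% u
  list(displacements = matrix(u, ncol = 3, byrow = TRUE),
       fTop = sum(r[3 * top]), fBottom = sum(r[3 * bottom]))
}

# Direct enumeration of spot footprint membership: loops over every
# element and spot, transforming centers with the inverse rigid pose.
oracle_spot_means <- function(spots, effArr, boneArr, spacing, pose_t,
                              thickness, Rmat = diag(3)) {
  d <- dim(effArr)
  n <- nrow(spots)
  sums <- numeric(n); cnts <- integer(n)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!boneArr[i, j, k]) next
    p <- as.vector(t(Rmat) %*% (c(i - 0.5, j - 0.5, k - 0.5) * spacing -
                                  pose_t))
    if (abs(p[3]) > thickness / 2) next
    for (s in seq_len(n)) {
      if ((p[1] - spots$x[s])^2 + (p[2] - spots$y[s])^2 <=
          (spots$diameter[s] / 2)^2) {
        sums[s] <- sums[s] + effArr[i, j, k]
        cnts[s] <- cnts[s] + 1L
      }
    }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

# Voxel-by-voxel remodeling count oracle.
oracle_remodeling_counts <- function(a, b) {
  f <- q <- r <- 0L
  for (v in seq_along(a)) {
    if (a[v] && b[v]) q <- q + 1L
    else if (b[v]) f <- f + 1L
    else if (a[v]) r <- r + 1L
  }
  c(formation = f, quiescent = q, resorption = r)
}

make_mask <- function(values, spacing = 10.5, threshold = 395) {
  new("BoneMask", values = values, spacing = spacing, origin = c(0, 0, 0),
      threshold = threshold)
}

make_field <- function(eff, spacing = 10.5, fRes = 1, actual = FALSE) {
  new("StrainField", effSim = eff,
      effActual = if (actual) eff else array(numeric(0), c(0, 0, 0)),
      fResultant = fRes, fApplied = if (actual) fRes else NA_real_,
      spacing = spacing, origin = c(0, 0, 0))
}
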