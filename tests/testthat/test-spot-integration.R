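test_that("section embedding applies the rigid pose and round-trips", {
  spots <- spotTable(c("A", "B"), c(100, 1), c(200, 0))
  id <- embedSection(spots, sectionPose())
  expect_equal(unlist(id[1, c("x3", "y3", "z3")], use.names = FALSE),
               c(100, 200, 0))

  tr <- embedSection(spots, sectionPose(translation = c(0, 0, 500)))
  expect_equal(tr$z3, c(500, 500))

  rot90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # 90 deg about z
  rt <- embedSection(spotTable("S", 1, 0), sectionPose(rotation = rot90))
  expect_equal(unlist(rt[1, c("x3", "y3", "z3")], use.names = FALSE),
               c(0, 1, 0), tolerance = 1e-12)

  # round trip through the inverse pose
  pose <- sectionPose(rotation = rot90, translation = c(10, -20, 30))
  emb <- embedSection(spots, pose)
  back <- mechanomics:::.pose_invert(pose, cbind(emb$x3, emb$y3, emb$z3))
  expect_equal(back[, 1], spots$x, tolerance = 1e-9)
  expect_equal(back[, 2], spots$y, tolerance = 1e-9)

  expect_error(sectionPose(rotation = matrix(2 * diag(3), 3)), "orthonormal")
})

test_that("strain-region classification follows the 500/1000 ue convention", {
  expect_equal(classifyStrainRegion(c(1200, 400, 750)),
               c("high", "low", "reference"))
  # boundary values fold into reference to preserve the partition
  expect_equal(classifyStrainRegion(c(500, 1000)),
               c("reference", "reference"))
  expect_equal(classifyStrainRegion(NA), "unassigned")
  expect_error(classifyStrainRegion(-5), "negative")

  # labels partition all assigned spots
  set.seed(8)
  eff <- runif(200, 0, 2000)
  lab <- classifyStrainRegion(eff)
  expect_true(all(lab %in% c("low", "reference", "high")))
  expect_identical(sum(lab == "low") + sum(lab == "reference") +
                     sum(lab == "high"), 200L)
})

test_that("spot strain averages eff_actual over bone elements in the footprint", {
  # uniform field: every spot sees the constant
  dims <- c(12, 12, 1)
  stripes <- makeStrainStripes(dims, 750)
  bone <- make_mask(array(TRUE, dims))
  pose <- sectionPose(thickness = 10.5)
  spots <- spotTable(c("u1", "u2"), c(40, 80), c(40, 80))
  got <- spotStrain(spots, stripes$field, bone, pose)
  expect_equal(got$mean_eff, c(750, 750))
  expect_equal(got$region, c("reference", "reference"))

  # constructed footprint: 10 elements at 2000 ue + 10 at 0 -> mean 1000
  dims <- c(20, 1, 1)
  eff <- array(c(rep(2000, 10), rep(0, 10)), dims)
  field <- make_field(eff, actual = TRUE)
  spots <- spotTable("c", 105, 5.25, diameter = 210)
  got <- spotStrain(spots, field, make_mask(array(TRUE, dims)),
                    sectionPose(thickness = 10.5))
  expect_equal(got$mean_eff, 1000)
  expect_equal(got$region, "reference")

  # footprint over pure soft tissue: undefined mean, unassigned region
  none <- spotStrain(spots, field, make_mask(array(FALSE, dims)),
                     sectionPose(thickness = 10.5))
  expect_true(is.na(none$mean_eff))
  expect_equal(none$region, "unassigned")
})

test_that("striped fields give region labels equal to the enumeration oracle", {
  dims <- c(24, 24, 24)
  stripes <- makeStrainStripes(dims, c(200, 750, 1500))
  bone <- array(TRUE, dims)
  pose <- sectionPose(translation = c(0, 126, 0),
                      rotation = matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3),
                      thickness = 12)
  spots <- makeSpotGrid(c(30, 220), c(30, 220))
  got <- spotStrain(spots, stripes$field, make_mask(bone), pose)

  # oracle: element centers transformed by the inverse pose by hand
  R <- pose@matrix[1:3, 1:3]; tr <- pose@matrix[1:3, 4]
  eff <- effActual(stripes$field)
  d <- dim(eff)
  exp_mean <- rep(NA_real_, nrow(spots))
  sums <- numeric(nrow(spots)); cnt <- integer(nrow(spots))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- t(R) %*% (c(i - 0.5, j - 0.5, k - 0.5) * 10.5 - tr)
    if (abs(p[3]) > 6) next
    for (s in seq_len(nrow(spots))) {
      if ((p[1] - spots$x[s])^2 + (p[2] - spots$y[s])^2 <= 27.5^2) {
        sums[s] <- sums[s] + eff[i, j, k]; cnt[s] <- cnt[s] + 1L
      }
    }
  }
  exp_mean[cnt > 0] <- sums[cnt > 0] / cnt[cnt > 0]
  expect_equal(got$mean_eff, exp_mean)
  expect_equal(got$region, classifyStrainRegion(exp_mean))
  expect_true(any(got$region != "unassigned"))

  # shrinking the footprint never adds qualifying elements
  small <- spots; small$diameter <- 30
  gotS <- spotStrain(small, stripes$field, make_mask(bone), pose)
  expect_true(all(is.na(gotS$mean_eff) | !is.na(got$mean_eff)))
})

test_that("QC filtering is inclusive at 500 UMIs / 250 genes", {
  nG <- 600
  mkcol <- function(numis, ngenes) {
    v <- integer(nG)
    v[seq_len(ngenes)] <- 1L
    v[1] <- v[1] + as.integer(numis - ngenes)
    v
  }
  m <- cbind(a = mkcol(500, 250), b = mkcol(499, 300), c = mkcol(500, 249),
             d = mkcol(3000, 400), e = mkcol(120, 80))
  rownames(m) <- sprintf("g%03d", seq_len(nG))
  se <- spotCountMatrix(m)
  spots <- spotTable(colnames(m), 1:5, 1:5)
  kept <- qcFilterSpots(spots, se)
  expect_equal(kept$barcode, c("a", "d"))
  expect_equal(attr(kept, "removed"), c("b", "c", "e"))
  expect_equal(kept$n_umis, c(500L, 3000L))
  expect_equal(kept$n_genes, c(250L, 400L))

  expect_error(qcFilterSpots(spotTable("zz", 1, 1), se), "absent")
})

test_that("per-region QC medians use the even-count convention", {
  spots <- data.frame(barcode = letters[1:6],
                      region = c("high", "high", "low", "low", "low", "ref1"),
                      n_umis = c(100L, 300L, 1L, 2L, 3L, 3602L),
                      n_genes = c(50L, 70L, 1L, 2L, 3L, 2670L))
  st <- regionQcStats(spots, c("high", "low", "ref1"))
  expect_equal(st$median_umis, c(200, 2, 3602))
  expect_equal(st$median_genes, c(60, 2, 2670))
  expect_error(regionQcStats(spots, "absent"), "no spots")
})
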