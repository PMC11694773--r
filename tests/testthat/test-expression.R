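sim_counts_matrix <- function(nG, sizes, mu, phi, lfc = NULL,
                              groups = NULL, seed = 1) {
  set.seed(seed)
  nS <- length(sizes)
  mus <- outer(mu, sizes)
  if (!is.null(lfc))
    mus <- mus * 2^(outer(lfc, as.numeric(groups == levels(factor(groups))[2])))
  m <- matrix(rnbinom(nG * nS, size = 1 / phi, mu = mus), nG,
              dimnames = list(sprintf("g%04d", 1:nG), sprintf("s%03d", 1:nS)))
  m
}

test_that("median-of-ratios size factors recover exact proportionality", {
  m <- matrix(c(2, 4, 10, 6, 4, 8, 20, 12), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("A", "B")))
  se <- estimateSpotSizeFactors(spotCountMatrix(m))
  sf <- spotSizeFactors(se)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  ident <- spotCountMatrix(cbind(A = c(5, 8, 2), B = c(5, 8, 2),
                                 C = c(5, 8, 2)) |>
                             `rownames<-`(paste0("g", 1:3)))
  expect_equal(unname(spotSizeFactors(estimateSpotSizeFactors(ident))),
               rep(1, 3))
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  m <- sim_counts_matrix(300, c(0.6, 1, 1.5, 0.9, 1.2, 0.8), mu = rep(20, 300),
                         phi = 0.1, seed = 5)
  mine <- spotSizeFactors(estimateSpotSizeFactors(spotCountMatrix(m)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))      # same geometric-mean-1 convention
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("planted size factors {0.5, 1, 2} are recovered within 5%", {
  truth <- rep(c(0.5, 1, 2), each = 8)
  m <- sim_counts_matrix(800, truth, mu = exp(rnorm(800, log(30), 1)),
                         phi = 0.05, seed = 17)
  sf <- spotSizeFactors(estimateSpotSizeFactors(spotCountMatrix(m)))
  expect_lt(max(abs(sf / truth - 1)), 0.05)
  # the pooled deconvolution variant is approximate; hold it to 10%
  sfp <- spotSizeFactors(estimateSpotSizeFactors(spotCountMatrix(m),
                                                 method = "pooled"))
  expect_lt(max(abs(sfp / truth - 1)), 0.10)
})

test_that("low-expression filtering applies both inclusive criteria", {
  m <- rbind(zero = rep(0L, 20),
             boundary = c(rep(0L, 19), 10L),     # total 10, 5% detection
             lowtot = c(rep(0L, 18), 4L, 5L),    # total 9
             rare = c(rep(0L, 19), 50L),         # 5% detection, total 50
             common = rep(1L, 20))
  colnames(m) <- paste0("s", 1:20)
  elig <- filterLowExpression(m)
  expect_equal(unname(elig),
               c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("the NB LRT is null on identical groups and calibrated overall", {
  # identical counts in both groups with equal size factors
  y <- c(5L, 9L, 2L, 7L)
  m <- rbind(matrix(rep(c(y, y), each = 12), nrow = 12, byrow = FALSE))
  m <- matrix(rep(c(y, y), 12), nrow = 12, byrow = TRUE)
  rownames(m) <- paste0("g", 1:12); colnames(m) <- paste0("s", 1:8)
  se <- spotCountMatrix(m)
  spotSizeFactors(se) <- 1
  de <- nbLrtDE(se, rep(c("A", "B"), each = 4))
  expect_equal(de$log2fc, rep(0, 12), tolerance = 1e-6)
  expect_true(all(de$pvalue > 0.99))

  # type-I error of the LRT near nominal on a null simulation with known
  # dispersion
  m2 <- sim_counts_matrix(1500, rep(1, 60), mu = exp(rnorm(1500, log(25), 1)),
                          phi = 0.05, seed = 23)
  se2 <- estimateSpotSizeFactors(spotCountMatrix(m2))
  de2 <- nbLrtDE(se2, rep(c("A", "B"), each = 30))
  frac <- mean(de2$pvalue < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.08)
  expect_identical(sum(de2$is_deg & de2$filtered), 0L)
})

test_that("the NB LRT is invariant to rescaling one spot's counts", {
  m <- sim_counts_matrix(120, rep(1, 16), mu = rep(40, 120), phi = 0.1,
                         seed = 9)
  g <- rep(c("A", "B"), each = 8)
  de1 <- nbLrtDE(estimateSpotSizeFactors(spotCountMatrix(m)), g)
  m2 <- m; m2[, 3] <- 3L * m2[, 3]
  de2 <- nbLrtDE(estimateSpotSizeFactors(spotCountMatrix(m2)), g)
  # rescaling changes the realized counts, so invariance is approximate
  expect_lt(max(abs(de2$log2fc - de1$log2fc), na.rm = TRUE), 0.05)
  expect_gt(cor(-log10(de1$pvalue), -log10(de2$pvalue),
                use = "complete.obs"), 0.99)
})

test_that("fold-change estimates track the DESeq2 oracle on planted effects", {
  nG <- 250
  lfc <- c(rep(2, 25), rep(-1.5, 25), rep(0, nG - 50))
  grp <- rep(c("A", "B"), each = 15)
  m <- sim_counts_matrix(nG, rep(1, 30), mu = rep(50, nG), phi = 0.08,
                         lfc = lfc, groups = grp, seed = 31)
  se <- estimateSpotSizeFactors(spotCountMatrix(m))
  de <- nbLrtDE(se, grp)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(m, S4Vectors::DataFrame(
      condition = factor(grp)), ~condition)
    DESeq2::sizeFactors(dds) <- spotSizeFactors(se)
    dds <- DESeq2::DESeq(dds, test = "LRT", reduced = ~1, quiet = TRUE)
    ref <- DESeq2::results(dds)
  })
  ok <- !is.na(de$log2fc) & !is.na(ref$log2FoldChange)
  expect_gt(cor(de$log2fc[ok], ref$log2FoldChange[ok]), 0.95)
  # planted genes recovered by both routes
  expect_gt(mean(de$is_deg[1:50]), 0.8)
})

test_that("CV ranking reproduces the hand-computed fixture ordering", {
  m <- rbind(gFlat = c(4, 4, 4, 4),
             gNoisy = c(1, 3, 1, 3),
             gMid = c(10, 10, 10, 14),
             gMid2 = c(5, 5, 7, 7),
             gBig = c(100, 90, 110, 100),
             gZero = c(0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  se <- spotCountMatrix(m)
  spotSizeFactors(se) <- 1
  rk <- cvRanking(se, colnames(m), topK = 3)
  expect_equal(rk$gene, c("gFlat", "gBig", "gMid", "gMid2", "gNoisy"))
  expect_equal(rk$cv[1], 0)
  expect_equal(rk$cv[rk$gene == "gNoisy"], sd(c(1, 3, 1, 3)) / 2)
  expect_false("gZero" %in% rk$gene)     # undetected gene excluded
  expect_equal(nrow(attr(rk, "top")), 3)

  # invariant under uniform rescaling of the region's normalized values
  se2 <- spotCountMatrix(m * 5L)
  spotSizeFactors(se2) <- 1
  expect_equal(cvRanking(se2, colnames(m))$gene, rk$gene)

  expect_error(cvRanking(se, colnames(m)[1:2]), "3 spots")
})

test_that("gene-set scores detect planted shifts and stay null under permutation", {
  set.seed(77)
  nG <- 200; nS <- 30
  grp <- rep(c("A", "B"), each = 15)
  mu <- exp(rnorm(nG, log(30), 0.2))
  lfc <- rep(0, nG); lfc[1:20] <- 1    # planted set, +1 log2 unit
  m <- sim_counts_matrix(nG, rep(1, nS), mu = mu, phi = 0.02, lfc = lfc,
                         groups = grp, seed = 78)
  se <- estimateSpotSizeFactors(spotCountMatrix(m))
  sets <- list(planted = rownames(m)[1:20],
               tiny = rownames(m)[1])
  expect_warning(res <- geneSetScore(se, grp, sets), "tiny")
  expect_equal(res$set, "planted")
  expect_lt(res$pvalue[1], 0.01)
  expect_equal(res$direction[1], 1)

  # a null set in effect-free data scores null, and permuted labels give
  # uniform-ish p values
  m0 <- sim_counts_matrix(nG, rep(1, nS), mu = mu, phi = 0.02, seed = 79)
  se0 <- estimateSpotSizeFactors(spotCountMatrix(m0))
  nullset <- list(random = rownames(m0)[101:130])
  expect_gt(geneSetScore(se0, grp, nullset)$pvalue, 0.05)
  pvals <- replicate(400, {
    rs <- list(random = sample(rownames(m0), 30))
    geneSetScore(se0, sample(grp), rs)$pvalue
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
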