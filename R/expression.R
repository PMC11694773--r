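# Strain- and group-stratified expression statistics: normalization,
# NB likelihood-ratio differential expression, CV ranking, gene-set
# scoring. The computations are defined here independently rather than
# delegated, so that every step is inspectable and testable.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Build a spot count container
#'
#' Wraps a genes x spots UMI count matrix in a
#' \link[SummarizedExperiment]{SummarizedExperiment} with assay
#' \code{counts}; size factors live in \code{colData(x)$size_factor}.
#'
#' @param counts genes x spots matrix (dense or \code{Matrix} sparse) of
#'   non-negative integer UMI counts.
#' @param geneIds,barcodes optional dimension names (default: taken from
#'   the matrix).
#' @return A \code{SummarizedExperiment}.
#' @export
spotCountMatrix <- function(counts, geneIds = rownames(counts),
                            barcodes = colnames(counts)) {
  if (is.null(geneIds) || is.null(barcodes))
    stop("gene ids and barcodes are required")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  rownames(counts) <- geneIds
  colnames(counts) <- barcodes
  SummarizedExperiment(assays = list(counts = counts))
}

#' Extract the count matrix
#'
#' @param x a \code{SummarizedExperiment} built by
#'   \code{\link{spotCountMatrix}} (or a bare matrix, returned as is).
#' @return the genes x spots count matrix.
#' @export
spotCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) return(assay(x, "counts"))
  x
}

#' Per-spot size factors
#'
#' @param x a \code{SummarizedExperiment} after
#'   \code{\link{estimateSpotSizeFactors}}.
#' @return numeric vector of size factors (geometric mean 1).
#' @export
spotSizeFactors <- function(x) {
  sf <- colData(x)$size_factor
  if (is.null(sf))
    stop("size factors not estimated; run estimateSpotSizeFactors()")
  sf
}

#' @rdname spotSizeFactors
#' @param value numeric vector of positive size factors.
#' @export
`spotSizeFactors<-` <- function(x, value) {
  if (any(value <= 0)) stop("size factors must be > 0")
  colData(x)$size_factor <- rep_len(value, ncol(x))
  x
}

#' Estimate spot size factors
#'
#' Scaling normalization for UMI counts. The default is the
#' median-of-ratios estimator: each spot's factor is the median ratio of
#' its counts to a geometric-mean pseudo-reference spot, over genes
#' expressed in every spot. The pooled variant sums spots into sliding
#' pools (ordered by library size), estimates a median-of-ratios factor
#' per pool against the mean expression profile, and deconvolves per-spot
#' factors by least squares — more stable when single-spot ratios are
#' dominated by zeros. Factors are rescaled to geometric mean 1.
#'
#' @param x a \code{SummarizedExperiment} of counts.
#' @param method "ratio" (median-of-ratios) or "pooled"
#'   (pool-and-deconvolve).
#' @param poolSize pool width for the pooled method.
#' @return \code{x} with \code{colData(x)$size_factor} filled.
#' @export
estimateSpotSizeFactors <- function(x, method = c("ratio", "pooled"),
                                    poolSize = 10) {
  method <- match.arg(method)
  m <- as.matrix(spotCounts(x))
  n <- ncol(m)
  if (method == "ratio") {
    common <- rowSums(m > 0) == n
    if (!any(common))
      stop("no gene is expressed in every spot (normalization error)")
    lc <- log(m[common, , drop = FALSE])
    logref <- rowMeans(lc)
    sf <- exp(apply(lc - logref, 2, median))
  } else {
    ord <- order(colSums(m))
    ref <- rowMeans(m)
    # two sliding window widths break the degeneracy of a single
    # circulant pooling pattern
    widths <- unique(pmin(pmax(c(poolSize, poolSize + 1L), 2L), n))
    rows <- list(); b <- numeric(0)
    for (k in widths) for (s in seq_len(n)) {
      sel <- ord[(s + seq_len(k) - 2L) %% n + 1L]
      pooled <- rowSums(m[, sel, drop = FALSE])
      use <- ref > 0 & pooled > 0
      if (!any(use)) stop("empty pool profile (normalization error)")
      row <- numeric(n); row[sel] <- 1 / k
      rows[[length(rows) + 1L]] <- row
      b <- c(b, median(pooled[use] / (k * ref[use])))
    }
    A <- do.call(rbind, rows)
    sf <- as.vector(qr.solve(rbind(A, 1), c(b, n)))
    if (any(sf <= 0))
      stop("pooled deconvolution gave non-positive factors; ",
           "use method = 'ratio'")
  }
  sf <- sf / exp(mean(log(sf)))
  colData(x)$size_factor <- sf
  x
}

#' Flag genes with sufficient expression for testing
#'
#' A gene is eligible when its total count reaches \code{minTotal} and it
#' is detected (count > 0) in at least \code{minFracDetected} of spots
#' (both thresholds inclusive). This independent filter stands before the
#' differential-expression test; the defaults are deliberately mild.
#'
#' @param x count container or matrix.
#' @param minTotal minimum total count over all spots.
#' @param minFracDetected minimum fraction of spots with a nonzero count.
#' @return named logical vector of gene eligibility.
#' @export
filterLowExpression <- function(x, minTotal = 10, minFracDetected = 0.05) {
  m <- spotCounts(x)
  tot <- Matrix::rowSums(m)
  det <- Matrix::rowSums(m > 0) / ncol(m)
  elig <- tot >= minTotal & det >= minFracDetected
  names(elig) <- rownames(m)
  elig
}

## ---- NB fitting internals ----

.nb_ll <- function(y, mu, phi) {
  if (phi < 1e-10) {
    mu <- pmax(mu, 1e-300)
    return(sum(y * log(mu) - mu - lgamma(y + 1)))
  }
  sum(dnbinom(y, size = 1 / phi, mu = pmax(mu, 1e-300), log = TRUE))
}

# ML of the mean parameter q (mu = sf * q) for fixed dispersion phi.
.nb_fit_mean <- function(y, sf, phi, iter = 50L, tol = 1e-12) {
  if (sum(y) == 0) return(0)
  q <- sum(y) / sum(sf)
  for (i in seq_len(iter)) {
    mu <- sf * q
    w <- 1 / (1 + phi * mu)
    score <- sum((y - mu) * w)
    info <- sum(mu * w)
    step <- score / info
    # Fisher scoring on log q
    q <- q * exp(max(min(step, 3), -3))
    if (abs(step) < tol) break
  }
  q
}

# Profile-likelihood ML dispersion for the full (two-group) model.
.nb_ml_dispersion <- function(y, sf, g1, g2) {
  prof <- function(logphi) {
    phi <- exp(logphi)
    q1 <- .nb_fit_mean(y[g1], sf[g1], phi)
    q2 <- .nb_fit_mean(y[g2], sf[g2], phi)
    .nb_ll(y[g1], sf[g1] * q1, phi) + .nb_ll(y[g2], sf[g2] * q2, phi)
  }
  opt <- optimize(prof, interval = c(log(1e-8), log(50)),
                  maximum = TRUE, tol = 1e-4)
  exp(opt$maximum)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' Per eligible gene, fits an NB generalized linear model with log link
#' and size-factor offsets: the full model has a separate mean per group,
#' the null model a common mean. Gene-wise dispersions are estimated by
#' profile maximum likelihood and shrunk on the log scale toward a lowess
#' mean-dispersion trend with prior weight d0/(d0 + df) (d0 = 8 prior
#' degrees of freedom), to stabilize small-sample estimates. The p value
#' comes from the chi-squared(1) distribution of twice the log-likelihood
#' difference; BH adjustment is applied across eligible genes. A gene is
#' called differentially expressed when FDR < \code{alpha} and
#' |log2 fold change| > \code{lfcCutoff} (defaults 0.05 and 0.5). Fold
#' changes are raw fitted-mean ratios; no shrinkage is applied to them.
#'
#' @param x count container with size factors estimated.
#' @param groupLabels factor-like vector over spots with exactly two
#'   levels (>= 2 spots each); fold change is level 2 vs level 1.
#' @param eligibility logical vector from
#'   \code{\link{filterLowExpression}}; NULL computes it with defaults.
#' @param alpha FDR cutoff for the DEG call.
#' @param lfcCutoff absolute log2-fold-change cutoff for the DEG call.
#' @param priorDf prior degrees of freedom of the dispersion shrinkage.
#' @return data.frame with one row per gene: baseMean (mean normalized
#'   count), log2fc, dispersion, pvalue, fdr, is_deg, filtered.
#' @export
nbLrtDE <- function(x, groupLabels, eligibility = NULL, alpha = 0.05,
                    lfcCutoff = 0.5, priorDf = 8) {
  m <- as.matrix(spotCounts(x))
  sf <- spotSizeFactors(x)
  grp <- factor(groupLabels)
  if (nlevels(grp) != 2L) stop("exactly two groups are required")
  if (any(table(grp) < 2L)) stop("each group needs >= 2 spots (design error)")
  if (is.null(eligibility)) eligibility <- filterLowExpression(x)
  g1 <- which(grp == levels(grp)[1]); g2 <- which(grp == levels(grp)[2])
  genes <- rownames(m)
  nG <- nrow(m)
  norm <- sweep(m, 2, sf, "/")
  baseMean <- rowMeans(norm)
  idx <- which(eligibility)

  phiHat <- rep(NA_real_, nG)
  for (g in idx)
    phiHat[g] <- .nb_ml_dispersion(m[g, ], sf, g1, g2)

  # lowess trend of log dispersion against log mean, then shrink
  df <- ncol(m) - 2
  w <- priorDf / (priorDf + df)
  phiShr <- phiHat
  if (length(idx) >= 10) {
    lmu <- log(baseMean[idx]); lph <- log(pmax(phiHat[idx], 1e-8))
    trend <- if (length(unique(round(lmu, 8))) < 5) {
      rep(median(lph), length(lmu))     # degenerate mean spread
    } else {
      tr <- lowess(lmu, lph, f = 0.5)
      approx(tr$x, tr$y, xout = lmu, rule = 2)$y
    }
    phiShr[idx] <- exp((1 - w) * lph + w * trend)
  }

  log2fc <- pvalue <- rep(NA_real_, nG)
  for (g in idx) {
    y <- m[g, ]; phi <- phiShr[g]
    q1 <- .nb_fit_mean(y[g1], sf[g1], phi)
    q2 <- .nb_fit_mean(y[g2], sf[g2], phi)
    q0 <- .nb_fit_mean(y, sf, phi)
    llFull <- .nb_ll(y[g1], sf[g1] * q1, phi) +
      .nb_ll(y[g2], sf[g2] * q2, phi)
    llNull <- .nb_ll(y, sf * q0, phi)
    dev <- max(2 * (llFull - llNull), 0)
    pvalue[g] <- pchisq(dev, df = 1, lower.tail = FALSE)
    log2fc[g] <- log2(max(q2, 1e-8) / max(q1, 1e-8))
  }
  fdr <- rep(NA_real_, nG)
  ok <- !is.na(pvalue)
  fdr[ok] <- p.adjust(pvalue[ok], method = "BH")
  isDeg <- !is.na(fdr) & fdr < alpha & abs(log2fc) > lfcCutoff
  data.frame(gene = genes, baseMean = baseMean, log2fc = log2fc,
             dispersion = phiShr, pvalue = pvalue, fdr = fdr,
             is_deg = isDeg, filtered = !eligibility,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by coefficient of variation within a region
#'
#' On size-factor-normalized counts restricted to one strain region's
#' spots, computes per-gene mean, sample standard deviation and
#' CV = sd/mean for genes detected in at least \code{minDetectFrac} of
#' the region's spots, and ranks ascending by CV: the most consistently
#' expressed genes — the region's functionally significant markers —
#' rank first. Ties are broken by higher mean, then gene id.
#'
#' @param x count container with size factors.
#' @param regionBarcodes barcodes of the region's spots (>= 3).
#' @param topK how many top genes to keep in the "top" attribute.
#' @param minDetectFrac minimum detection fraction within the region.
#' @return data.frame (gene, mean, sd, cv, rank) sorted by rank;
#'   \code{attr(, "top")} holds the first \code{topK} rows.
#' @export
cvRanking <- function(x, regionBarcodes, topK = 25, minDetectFrac = 0.5) {
  m <- as.matrix(spotCounts(x))
  sf <- spotSizeFactors(x)
  sel <- match(regionBarcodes, colnames(m))
  if (anyNA(sel)) stop("unknown barcode(s) in region")
  if (length(sel) < 3L) stop("region needs >= 3 spots (group-size error)")
  nm <- sweep(m[, sel, drop = FALSE], 2, sf[sel], "/")
  det <- rowSums(nm > 0) / ncol(nm)
  keep <- det >= minDetectFrac
  nm <- nm[keep, , drop = FALSE]
  mu <- rowMeans(nm)
  ok <- mu > 0
  nm <- nm[ok, , drop = FALSE]; mu <- mu[ok]
  sdv <- apply(nm, 1, sd)
  cv <- sdv / mu
  ord <- order(cv, -mu, rownames(nm))
  out <- data.frame(gene = rownames(nm)[ord], mean = mu[ord], sd = sdv[ord],
                    cv = cv[ord], rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "top") <- utils::head(out, topK)
  out
}

#' Score gene sets on group mean-expression ratios
#'
#' For each gene, the per-group mean of normalized expression is formed
#' and the log2 ratio r_g = log2((mean2 + c)/(mean1 + c)) computed with a
#' pseudo-count c (default 0.5) guarding zero means. Each gene set with at
#' least two member genes present is scored by the two-sample t statistic
#' of its members' ratios against all non-member ratios (two-sided p from
#' the t distribution), BH-adjusted across sets; the direction is the
#' sign of the member-vs-background mean difference.
#'
#' @param x count container with size factors.
#' @param groupLabels two-level grouping over spots (ratio: level 2 vs 1).
#' @param geneSets named list of character vectors of gene ids (e.g. from
#'   \code{\link{readGmt}}).
#' @param pseudo pseudo-count c.
#' @return data.frame (set, n_genes, stat, pvalue, fdr, direction); sets
#'   with fewer than two present genes are skipped with a warning.
#' @export
geneSetScore <- function(x, groupLabels, geneSets, pseudo = 0.5) {
  m <- as.matrix(spotCounts(x))
  sf <- spotSizeFactors(x)
  grp <- factor(groupLabels)
  if (nlevels(grp) != 2L) stop("exactly two groups are required")
  nm <- sweep(m, 2, sf, "/")
  m1 <- rowMeans(nm[, grp == levels(grp)[1], drop = FALSE])
  m2 <- rowMeans(nm[, grp == levels(grp)[2], drop = FALSE])
  r <- log2((m2 + pseudo) / (m1 + pseudo))
  names(r) <- rownames(m)
  rows <- lapply(names(geneSets), function(sn) {
    members <- intersect(geneSets[[sn]], names(r))
    if (length(members) < 2L) {
      warning("gene set '", sn, "' has < 2 genes present; skipped")
      return(NULL)
    }
    inset <- names(r) %in% members
    tt <- t.test(r[inset], r[!inset])
    data.frame(set = sn, n_genes = length(members),
               stat = unname(tt$statistic), pvalue = tt$p.value,
               direction = sign(mean(r[inset]) - mean(r[!inset])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no scorable gene set")
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out[, c("set", "n_genes", "stat", "pvalue", "fdr", "direction")]
}
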