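#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median across genes of the ratio of
#' the sample's count to the gene's geometric mean across samples; genes with
#' any zero count are excluded from the reference set. If no gene is nonzero
#' in every sample, falls back to total-count ratio normalization (relative
#' to the geometric mean of library sizes) with a warning.
#'
#' @param counts Count matrix, genes x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_fmt("degenerate input: sample(s) with zero total count: %s",
             paste(colnames(counts)[lib == 0], collapse = ", "))
  loggm <- rowMeans(log(counts))
  use <- is.finite(loggm)
  if (!any(use)) {
    warn_fmt(paste0("no gene has nonzero counts in every sample; ",
                    "falling back to total-count ratio normalization"))
    f <- lib / exp(mean(log(lib)))
  } else {
    f <- apply(counts[use, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - loggm[use])))
  }
  stats::setNames(f, colnames(counts))
}

#' Pooled moment estimate of the NB dispersion
#'
#' Method-of-moments estimate of a single common dispersion alpha
#' (variance = mu + alpha * mu^2) on size-factor-normalized counts. Each
#' (gene, group) cell contributes its variance excess `v - m` against `m^2`,
#' pooled in ratio form across all cells, which weights cells by the
#' information they carry about alpha and stays unbiased when group means
#' differ within a gene. Floored at zero.
#'
#' @param counts Count matrix, genes x samples.
#' @param groups Group label per sample (within-group variances only).
#' @param size_factors Optional; estimated by [estimate_size_factors()] if
#'   omitted.
#' @return A single dispersion value alpha >= 0.
#' @export
estimate_dispersion <- function(counts, groups, size_factors = NULL) {
  sf <- size_factors %||% estimate_size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  groups <- as.character(groups)
  keep <- names(table(groups))[table(groups) >= 2]
  if (!length(keep)) stop_fmt("need at least one group with >= 2 replicates")
  num <- 0; den <- 0
  for (g in keep) {
    qg <- q[, groups == g, drop = FALSE]
    m <- rowMeans(qg)
    v <- apply(qg, 1, stats::var)
    ok <- is.finite(m) & is.finite(v) & m > 0
    num <- num + sum(v[ok] - m[ok])
    den <- den + sum(m[ok]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Exact conditional NB p-value for one gene
#'
#' Conditional two-group test: given the total `ka + kb` of the (rounded,
#' normalized) group sums, the p-value is the sum of the probabilities of all
#' splits that are as or less probable than the observed one under the null
#' of equal per-replicate means, with group sums distributed
#' NB(n * mu0, size = n / alpha). With `dispersion = 0` this reduces to the
#' conditional binomial (Poisson) test.
#'
#' @param ka,kb Non-negative integer group sums.
#' @param n_a,n_b Number of replicates behind each sum.
#' @param dispersion Common NB dispersion alpha >= 0.
#' @return p-value in (0, 1]; 1 when both sums are zero.
#' @export
nb_exact_pvalue <- function(ka, kb, n_a, n_b, dispersion) {
  s <- ka + kb
  if (s == 0) return(1)
  mu0 <- s / (n_a + n_b)
  k <- 0:s
  if (dispersion <= 0) {
    lp <- stats::dbinom(k, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    lp <- stats::dnbinom(k, mu = n_a * mu0, size = n_a / dispersion,
                         log = TRUE) +
      stats::dnbinom(s - k, mu = n_b * mu0, size = n_b / dispersion,
                     log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  # relative tolerance so ties at the observed probability are included
  min(1, sum(pr[pr <= pr[ka + 1] * (1 + 1e-7)]))
}

#' Two-group exact NB test across genes
#'
#' Applies [nb_exact_pvalue()] gene by gene to size-factor-normalized counts.
#' Normalized pseudo-counts are rounded to the nearest integer (half away
#' from zero) before conditioning. Genes with zero counts in both groups get
#' p = 1 and are flagged `untested`.
#'
#' @param counts_a,counts_b Count matrices (genes x replicates) or vectors
#'   (single gene) for the two groups.
#' @param size_factors_a,size_factors_b Per-sample size factors (default 1).
#' @param dispersion Common NB dispersion alpha >= 0.
#' @return `data.frame`: `gene_id`, `base_mean` (mean normalized count),
#'   `log2fc` (B over A, pseudocount 0.5), `pvalue`, `untested`.
#' @export
nb_test <- function(counts_a, counts_b, size_factors_a = NULL,
                    size_factors_b = NULL, dispersion = 0) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1)
  if (nrow(counts_a) != nrow(counts_b))
    stop_fmt("count matrices must have the same genes")
  if (dispersion < 0) stop_fmt("dispersion must be >= 0")
  sfa <- size_factors_a %||% rep(1, ncol(counts_a))
  sfb <- size_factors_b %||% rep(1, ncol(counts_b))
  qa <- sweep(counts_a, 2, sfa, "/")
  qb <- sweep(counts_b, 2, sfb, "/")
  ka <- rowSums(round_half_up(qa))
  kb <- rowSums(round_half_up(qb))
  p <- vapply(seq_along(ka), function(i)
    nb_exact_pvalue(ka[i], kb[i], ncol(counts_a), ncol(counts_b), dispersion),
    numeric(1))
  untested <- ka + kb == 0
  p[untested] <- 1
  data.frame(
    gene_id = rownames(counts_a) %||% sprintf("g%d", seq_along(ka)),
    base_mean = (rowMeans(qa) * ncol(qa) + rowMeans(qb) * ncol(qb)) /
      (ncol(qa) + ncol(qb)),
    log2fc = log2((rowMeans(qb) + 0.5) / (rowMeans(qa) + 0.5)),
    pvalue = p,
    untested = untested,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR values, clipped at 1 and position-stable. `NA`/`NaN` inputs
#' are propagated with a warning; the number of tests excludes them.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (!all(ok)) warn_fmt("%d NA/NaN p-value(s) propagated unadjusted",
                         sum(!ok))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' A gene is called iff FDR < `fdr_threshold` (strict) and
#' |log2 fold change| >= `lfc_threshold` (i.e. fold change >= 2 at the
#' default). Untested genes are never called. Direction is `"up"` when group
#' B exceeds group A.
#'
#' @param res Result table from [nb_test()].
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @return `res` with added `fdr`, `call`, `direction` columns.
#' @export
call_deg <- function(res, fdr_threshold = 0.01, lfc_threshold = 1) {
  if (fdr_threshold <= 0 || lfc_threshold <= 0)
    stop_fmt("thresholds must be positive")
  res$fdr <- NA_real_
  tested <- !res$untested
  res$fdr[tested] <- bh_adjust(res$pvalue[tested])
  res$call <- tested & !is.na(res$fdr) & res$fdr < fdr_threshold &
    abs(res$log2fc) >= lfc_threshold
  res$direction <- ifelse(res$call, ifelse(res$log2fc > 0, "up", "down"),
                          NA_character_)
  res
}

#' Run the three trio contrasts for one hybrid and tissue
#'
#' Builds the contrasts P1_vs_P2, F1_vs_P1 and F1_vs_P2 (log2 fold changes
#' are the second-named group over the first: P2 over P1, F1 over P1, F1 over
#' P2), normalizes across all nine samples of the tissue, estimates a common
#' dispersion if not supplied, and applies the exact NB test with the DE
#' call rule.
#'
#' @param counts Count matrix covering the hybrid's samples.
#' @param samples Sample sheet (`sample_id`, `hybrid`, `genotype`, `tissue`,
#'   `replicate`).
#' @param hybrid,tissue Which trio to test.
#' @param fdr_threshold,lfc_threshold Call thresholds (see [call_deg()]).
#' @param dispersion Optional common dispersion; estimated by
#'   [estimate_dispersion()] across the genotype groups when `NULL`.
#' @param size_factors Optional named per-sample factors for the tissue.
#' @return Named list of called DE tables (one per contrast label), with
#'   attributes `size_factors` and `dispersion`.
#' @export
trio_de <- function(counts, samples, hybrid, tissue,
                    fdr_threshold = 0.01, lfc_threshold = 1,
                    dispersion = NULL, size_factors = NULL) {
  sub <- samples[samples$hybrid == hybrid & samples$tissue == tissue, ]
  for (g in c("P1", "P2", "F1"))
    if (sum(sub$genotype == g) < 2)
      stop_fmt("hybrid %s tissue %s: genotype %s has < 2 replicates",
               hybrid, tissue, g)
  cts <- counts[, sub$sample_id, drop = FALSE]
  sf <- size_factors %||% estimate_size_factors(cts)
  sf <- sf[sub$sample_id]
  disp <- dispersion %||% estimate_dispersion(cts, sub$genotype, sf)
  ids <- function(g) sub$sample_id[sub$genotype == g]
  run <- function(a, b) {
    res <- nb_test(counts[, ids(a), drop = FALSE],
                   counts[, ids(b), drop = FALSE],
                   sf[ids(a)], sf[ids(b)], disp)
    call_deg(res, fdr_threshold, lfc_threshold)
  }
  out <- list(P1_vs_P2 = run("P1", "P2"),
              F1_vs_P1 = run("P1", "F1"),
              F1_vs_P2 = run("P2", "F1"))
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- disp
  out
}
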