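#' Build the three trio DEG sets for one hybrid and tissue
#'
#' DEG2P comes from the P1_vs_P2 contrast, DEGP1 from F1_vs_P1 and DEGP2 from
#' F1_vs_P2. Inputs may be called DE tables (from [trio_de()] /
#' [call_deg()]) or plain character vectors of gene ids. Duplicated ids are
#' deduplicated with a warning.
#'
#' @param de_calls Named list with elements `P1_vs_P2`, `F1_vs_P1`,
#'   `F1_vs_P2`.
#' @param hybrid,tissue Identifiers carried into the bundle.
#' @return A `deg_bundle` list: `hybrid`, `tissue`, `DEG2P`, `DEGP1`,
#'   `DEGP2`.
#' @export
build_trio_sets <- function(de_calls, hybrid, tissue) {
  labels <- c("P1_vs_P2", "F1_vs_P1", "F1_vs_P2")
  miss <- setdiff(labels, names(de_calls))
  if (length(miss))
    stop_fmt("hybrid %s tissue %s: missing contrast(s): %s",
             hybrid, tissue, paste(miss, collapse = ", "))
  as_set <- function(x, label) {
    genes <- if (is.data.frame(x)) x$gene_id[x$call] else as.character(x)
    if (anyDuplicated(genes)) {
      warn_fmt("hybrid %s tissue %s contrast %s: duplicated gene ids removed",
               hybrid, tissue, label)
      genes <- unique(genes)
    }
    genes
  }
  out <- list(hybrid = hybrid, tissue = tissue,
              DEG2P = as_set(de_calls$P1_vs_P2, "P1_vs_P2"),
              DEGP1 = as_set(de_calls$F1_vs_P1, "F1_vs_P1"),
              DEGP2 = as_set(de_calls$F1_vs_P2, "F1_vs_P2"))
  class(out) <- "deg_bundle"
  out
}

#' Derive the F1-unique DEG set (DEGFu)
#'
#' Under the default `both_parents` rule a gene is F1-unique when the F1
#' differs from each parent while the parents do not differ:
#' DEGFu = (DEGP1 intersect DEGP2) minus DEG2P. The laxer `either_parent`
#' rule uses the union instead of the intersection. The rule is recorded on
#' the bundle.
#'
#' @param bundle A `deg_bundle` from [build_trio_sets()].
#' @param rule `"both_parents"` (default) or `"either_parent"`.
#' @return The bundle with `DEGFu` and `degfu_rule` added.
#' @export
derive_degfu <- function(bundle, rule = c("both_parents", "either_parent")) {
  rule <- match.arg(rule)
  core <- if (rule == "both_parents") intersect(bundle$DEGP1, bundle$DEGP2)
          else union(bundle$DEGP1, bundle$DEGP2)
  bundle$DEGFu <- setdiff(core, bundle$DEG2P)
  bundle$degfu_rule <- rule
  bundle
}

#' Derive tissue-specific F1-unique sets (DEGFu-sp)
#'
#' Within one hybrid, a gene is kept in a tissue's DEGFu-sp iff it appears in
#' the DEGFu of exactly that one tissue context. With a single tissue,
#' DEGFu-sp equals DEGFu. `allow_shared = TRUE` disables the specificity
#' filter.
#'
#' @param bundles List of `deg_bundle`s (one per tissue) of the same hybrid,
#'   each already carrying `DEGFu`.
#' @return The bundles with `DEGFu_sp` added to each.
#' @param allow_shared If `TRUE`, `DEGFu_sp` is set equal to `DEGFu`.
#' @export
derive_degfu_sp <- function(bundles, allow_shared = FALSE) {
  if (!length(bundles)) stop_fmt("at least one tissue bundle required")
  hy <- unique(vapply(bundles, `[[`, "", "hybrid"))
  if (length(hy) != 1)
    stop_fmt("bundles mix hybrids: %s", paste(hy, collapse = ", "))
  if (any(!vapply(bundles, function(b) !is.null(b$DEGFu), TRUE)))
    stop_fmt("run derive_degfu() on every bundle first")
  occ <- table(unlist(lapply(bundles, `[[`, "DEGFu")))
  for (i in seq_along(bundles)) {
    fu <- bundles[[i]]$DEGFu
    bundles[[i]]$DEGFu_sp <- if (allow_shared) fu
                             else fu[occ[fu] == 1]
  }
  bundles
}

#' Additive vs non-additive partition of F1-unique genes
#'
#' For each gene, the F1 replicates are compared against the
#' per-replicate-pair mid-parent construct (P1_r + P2_r) / 2, both on the
#' log2(normalized count + 0.5) scale; BH correction is applied across the
#' tested genes. A gene is non-additive iff FDR < `fdr_threshold` and
#' |log2(F1 / mid-parent)| >= `lfc_threshold`, signed up/down; otherwise it
#' is additive. Genes with zero F1 and zero mid-parent signal are classified
#' additive and flagged uninformative.
#'
#' With the default `method = "moderated"` the per-gene variance is
#' empirically moderated across the tested genes (limma's moderated
#' t-statistic), which is the standard remedy for 3-replicate designs where
#' the per-gene variance estimate is too unstable for a plain t-test; with
#' fewer than 10 tested genes, or `method = "welch"`, a per-gene Welch
#' t-test is used instead.
#'
#' @param counts Count matrix.
#' @param samples Sample sheet.
#' @param genes Gene ids to test (typically a tissue's DEGFu-sp).
#' @param hybrid,tissue Which trio the genes belong to.
#' @param size_factors Optional named per-sample factors (estimated across
#'   the tissue's nine samples when `NULL`).
#' @param fdr_threshold,lfc_threshold Non-additivity thresholds (defaults
#'   0.05 and 1).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return `data.frame`: `gene_id`, `hybrid`, `tissue`, `log2_f1_vs_mp`,
#'   `pvalue`, `fdr`, `class` (additive / nonadditive_up /
#'   nonadditive_down), `uninformative`.
#' @export
additivity_test <- function(counts, samples, genes, hybrid, tissue,
                            size_factors = NULL, fdr_threshold = 0.05,
                            lfc_threshold = 1,
                            method = c("moderated", "welch")) {
  method <- match.arg(method)
  sub <- samples[samples$hybrid == hybrid & samples$tissue == tissue, ]
  for (g in c("P1", "P2", "F1"))
    if (sum(sub$genotype == g) < 2)
      stop_fmt("hybrid %s tissue %s: genotype %s has < 2 replicates",
               hybrid, tissue, g)
  if (!length(genes))
    return(data.frame(gene_id = character(), hybrid = character(),
                      tissue = character(), log2_f1_vs_mp = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      class = character(), uninformative = logical(),
                      stringsAsFactors = FALSE))
  cts <- counts[, sub$sample_id, drop = FALSE]
  sf <- size_factors %||% estimate_size_factors(cts)
  q <- sweep(cts, 2, sf[sub$sample_id], "/")
  ids <- function(g) {
    s <- sub[sub$genotype == g, ]
    s$sample_id[order(s$replicate)]
  }
  p1 <- q[genes, ids("P1"), drop = FALSE]
  p2 <- q[genes, ids("P2"), drop = FALSE]
  f1 <- q[genes, ids("F1"), drop = FALSE]
  npair <- min(ncol(p1), ncol(p2))
  mp <- (p1[, seq_len(npair), drop = FALSE] +
           p2[, seq_len(npair), drop = FALSE]) / 2
  lfc <- log2((rowMeans(f1) + 0.5) /
                ((rowMeans(p1) + rowMeans(p2)) / 2 + 0.5))
  lx <- log2(cbind(f1, mp) + 0.5)
  uninf <- rowSums(cbind(f1, mp)) == 0
  pv <- rep(1, length(genes))
  if (method == "moderated" && sum(!uninf) >= 10) {
    design <- cbind(intercept = 1,
                    f1 = rep(c(1, 0), c(ncol(f1), ncol(mp))))
    fit <- limma::eBayes(limma::lmFit(lx[!uninf, , drop = FALSE], design))
    pv[!uninf] <- fit$p.value[, "f1"]
  } else {
    for (i in which(!uninf)) {
      x <- lx[i, seq_len(ncol(f1))]
      y <- lx[i, ncol(f1) + seq_len(ncol(mp))]
      if (stats::var(x) + stats::var(y) == 0) {
        pv[i] <- if (mean(x) == mean(y)) 1 else 0
      } else {
        pv[i] <- stats::t.test(x, y)$p.value
      }
    }
  }
  fdr <- bh_adjust(pv)
  cls <- ifelse(fdr < fdr_threshold & abs(lfc) >= lfc_threshold & !uninf,
                ifelse(lfc > 0, "nonadditive_up", "nonadditive_down"),
                "additive")
  data.frame(gene_id = genes, hybrid = hybrid, tissue = tissue,
             log2_f1_vs_mp = lfc, pvalue = pv, fdr = fdr, class = cls,
             uninformative = uninf, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Full trio classification for one or more hybrids
#'
#' Runs the three DE contrasts per (hybrid, tissue), derives DEGFu and
#' DEGFu-sp, and partitions each tissue's DEGFu-sp into additive and
#' non-additive genes.
#'
#' @param counts Count matrix covering all samples.
#' @param samples Sample sheet.
#' @param hybrids Hybrids to process (default: all in the sheet).
#' @param degfu_rule Rule for [derive_degfu()].
#' @param de_fdr,de_lfc DE call thresholds.
#' @param add_fdr,add_lfc Non-additivity thresholds.
#' @param add_method Additivity test engine (see [additivity_test()]).
#' @param allow_shared Passed to [derive_degfu_sp()].
#' @return `list(bundles, additivity)`: per-hybrid lists of per-tissue
#'   bundles, and the combined additivity table.
#' @export
classify_trio <- function(counts, samples, hybrids = NULL,
                          degfu_rule = "both_parents",
                          de_fdr = 0.01, de_lfc = 1,
                          add_fdr = 0.05, add_lfc = 1,
                          add_method = "moderated",
                          allow_shared = FALSE) {
  hybrids <- hybrids %||% unique(samples$hybrid)
  bundles <- list()
  add_rows <- list()
  for (hy in hybrids) {
    tissues <- unique(samples$tissue[samples$hybrid == hy])
    hb <- list()
    for (ts in tissues) {
      de <- trio_de(counts, samples, hy, ts, de_fdr, de_lfc)
      b <- build_trio_sets(de, hy, ts)
      b <- derive_degfu(b, degfu_rule)
      b$size_factors <- attr(de, "size_factors")
      hb[[ts]] <- b
    }
    hb <- derive_degfu_sp(hb, allow_shared = allow_shared)
    for (ts in tissues) {
      add_rows[[paste(hy, ts)]] <- additivity_test(
        counts, samples, hb[[ts]]$DEGFu_sp, hy, ts,
        size_factors = hb[[ts]]$size_factors,
        fdr_threshold = add_fdr, lfc_threshold = add_lfc,
        method = add_method)
    }
    bundles[[hy]] <- hb
  }
  additivity <- do.call(rbind, add_rows)
  rownames(additivity) <- NULL
  list(bundles = bundles, additivity = additivity)
}

#' Summary tables of the trio classification
#'
#' Produces the per-(hybrid, tissue) DEG set counts, the non-additive DEG
#' (NDEG) counts split by direction, and the per-tissue percent ratio of
#' NDEGs to DEGFu-sp pooled over hybrids (rounded half-up to 2 decimals;
#' `NA` when the denominator is zero).
#'
#' @param bundles Per-hybrid bundle lists from [classify_trio()].
#' @param additivity Additivity table from [classify_trio()].
#' @return `list(deg_counts, ndeg_counts, tissue_percent, totals)`.
#' @export
summarize_classification <- function(bundles, additivity) {
  deg_rows <- list(); ndeg_rows <- list()
  for (hy in names(bundles)) for (ts in names(bundles[[hy]])) {
    b <- bundles[[hy]][[ts]]
    deg_rows[[paste(hy, ts)]] <- data.frame(
      hybrid = hy, tissue = ts,
      deg2p = length(b$DEG2P), degp1 = length(b$DEGP1),
      degp2 = length(b$DEGP2), degfu_sp = length(b$DEGFu_sp),
      stringsAsFactors = FALSE)
    a <- additivity[additivity$hybrid == hy & additivity$tissue == ts, ]
    if (nrow(a) && !all(a$gene_id %in% b$DEGFu_sp))
      stop_fmt("additivity table and bundles disagree for %s %s", hy, ts)
    ndeg_rows[[paste(hy, ts)]] <- data.frame(
      hybrid = hy, tissue = ts,
      up = sum(a$class == "nonadditive_up"),
      down = sum(a$class == "nonadditive_down"),
      total = sum(a$class != "additive"), stringsAsFactors = FALSE)
  }
  deg_counts <- do.call(rbind, deg_rows)
  ndeg_counts <- do.call(rbind, ndeg_rows)
  rownames(deg_counts) <- rownames(ndeg_counts) <- NULL
  summarize_cells(deg_counts, ndeg_counts)
}

# shared arithmetic for computed and fixture-supplied count cells
summarize_cells <- function(deg_counts, ndeg_counts) {
  stopifnot(all(c("hybrid", "tissue", "degfu_sp") %in% names(deg_counts)),
            all(c("hybrid", "tissue", "up", "down") %in% names(ndeg_counts)))
  ndeg_counts$total <- ndeg_counts$up + ndeg_counts$down
  per_tissue_fu <- tapply(deg_counts$degfu_sp, deg_counts$tissue, sum)
  per_tissue_nd <- tapply(ndeg_counts$total, ndeg_counts$tissue, sum)
  tiss <- sort(unique(deg_counts$tissue))
  pct <- ifelse(per_tissue_fu[tiss] > 0,
                round_half_up(100 * per_tissue_nd[tiss] / per_tissue_fu[tiss],
                              2),
                NA_real_)
  tissue_percent <- data.frame(
    tissue = tiss,
    degfu_sp = as.integer(per_tissue_fu[tiss]),
    ndeg = as.integer(per_tissue_nd[tiss]),
    percent = as.numeric(pct), stringsAsFactors = FALSE, row.names = NULL)
  per_hybrid <- do.call(rbind, lapply(split(deg_counts, deg_counts$hybrid),
    function(d) data.frame(hybrid = d$hybrid[1],
                           degfu_sp_total = sum(d$degfu_sp),
                           stringsAsFactors = FALSE)))
  rownames(per_hybrid) <- NULL
  type <- tissue_type(deg_counts$tissue)
  fu_by_type <- tapply(deg_counts$degfu_sp, type, sum)
  nd_by_type <- tapply(ndeg_counts$total, tissue_type(ndeg_counts$tissue), sum)
  totals <- list(
    degfu_sp_grand_total = sum(deg_counts$degfu_sp),
    degfu_sp_by_hybrid = per_hybrid,
    degfu_sp_by_tissue_type = fu_by_type,
    ndeg_total = sum(ndeg_counts$total),
    ndeg_up = sum(ndeg_counts$up),
    ndeg_down = sum(ndeg_counts$down),
    ndeg_by_tissue_type = nd_by_type)
  list(deg_counts = deg_counts, ndeg_counts = ndeg_counts,
       tissue_percent = tissue_percent, totals = totals)
}

#' Precision and recall against the planted truth
#'
#' Scores the classification end to end: the F1-unique class is evaluated as
#' membership in DEGFu-sp against genes planted with equal parents and a
#' deviating F1 (classes `f1_unique`, `nonadd_up`, `nonadd_down`); the
#' non-additive up/down classes are evaluated against the sign of the
#' planted log2(F1 / mid-parent) among those genes.
#'
#' @param truth Truth table from [simulate_trio_counts()].
#' @param classification Result of [classify_trio()] for the same hybrid.
#' @param hybrid Hybrid id to score.
#' @return `data.frame`: `class`, `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
recovery_metrics <- function(truth, classification, hybrid) {
  fam <- c("f1_unique", "nonadd_up", "nonadd_down")
  key <- function(g, t) paste(g, t, sep = "@")
  bundles <- classification$bundles[[hybrid]]
  pred_fu <- unlist(lapply(bundles, function(b) key(b$DEGFu_sp, b$tissue)))
  tr <- truth[truth$tissue %in% names(bundles), ]
  true_fu <- key(tr$gene_id[tr$class %in% fam], tr$tissue[tr$class %in% fam])
  add <- classification$additivity[classification$additivity$hybrid == hybrid, ]
  pred_up <- key(add$gene_id[add$class == "nonadditive_up"],
                 add$tissue[add$class == "nonadditive_up"])
  pred_dn <- key(add$gene_id[add$class == "nonadditive_down"],
                 add$tissue[add$class == "nonadditive_down"])
  up_rows <- tr$class %in% fam & tr$log2_f1_vs_mp > 0
  dn_rows <- tr$class %in% fam & tr$log2_f1_vs_mp < 0
  true_up <- key(tr$gene_id[up_rows], tr$tissue[up_rows])
  true_dn <- key(tr$gene_id[dn_rows], tr$tissue[dn_rows])
  score <- function(cls, pred, truth_set) {
    tp <- length(intersect(pred, truth_set))
    data.frame(class = cls, tp = tp, fp = length(pred) - tp,
               fn = length(truth_set) - tp,
               precision = if (length(pred)) tp / length(pred) else NA_real_,
               recall = if (length(truth_set)) tp / length(truth_set)
                        else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(score("f1_unique", pred_fu, true_fu),
               score("nonadditive_up", pred_up, true_up),
               score("nonadditive_down", pred_dn, true_dn))
  rownames(out) <- NULL
  out
}
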