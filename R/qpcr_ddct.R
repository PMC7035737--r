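#' Livak 2^-ddCt relative quantification
#'
#' Replicates are averaged on the Ct scale before differencing (the standard
#' Livak convention, amplification efficiency fixed at 2):
#' dCt = mean(Ct_target) - mean(Ct_reference) per (sample, gene);
#' ddCt = dCt_sample - dCt_calibrator; RQ = 2^-ddCt. The calibrator sample's
#' own RQ is 1 by construction.
#'
#' @param ct Long Ct table: `sample`, `gene_id`, `ct_target`,
#'   `ct_reference`, `replicate`. Ct values must lie in (0, 45].
#' @param calibrator Sample id used as calibrator; must be present for every
#'   gene.
#' @return `data.frame`: `sample`, `gene_id`, `delta_ct`, `delta_delta_ct`,
#'   `rq`, `delta_ct_sd`, `n_replicates`.
#' @export
ddct <- function(ct, calibrator) {
  need <- c("sample", "gene_id", "ct_target", "ct_reference", "replicate")
  if (!all(need %in% names(ct)))
    stop_fmt("Ct table must have columns: %s", paste(need, collapse = ", "))
  bad_ref <- is.na(ct$ct_reference)
  if (any(bad_ref))
    stop_fmt("missing reference Ct for: %s",
             paste(utils::head(unique(paste(ct$sample[bad_ref],
                                            ct$gene_id[bad_ref])), 5),
                   collapse = "; "))
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(is.na(ct$ct_target)) || any(vals <= 0 | vals > 45))
    stop_fmt("Ct values must lie in (0, 45]")
  agg <- do.call(rbind, lapply(
    split(ct, list(ct$sample, ct$gene_id), drop = TRUE), function(d)
      data.frame(sample = d$sample[1], gene_id = d$gene_id[1],
                 delta_ct = mean(d$ct_target) - mean(d$ct_reference),
                 delta_ct_sd = stats::sd(d$ct_target - d$ct_reference),
                 n_replicates = nrow(d), stringsAsFactors = FALSE)))
  cal <- agg[agg$sample == calibrator, ]
  missing_cal <- setdiff(unique(agg$gene_id), cal$gene_id)
  if (length(missing_cal) || !nrow(cal))
    stop_fmt("calibrator %s missing for gene(s): %s", calibrator,
             paste(c(missing_cal, if (!nrow(cal)) "(all)"), collapse = ", "))
  agg$delta_delta_ct <- agg$delta_ct -
    cal$delta_ct[match(agg$gene_id, cal$gene_id)]
  agg$rq <- 2^(-agg$delta_delta_ct)
  out <- agg[, c("sample", "gene_id", "delta_ct", "delta_delta_ct", "rq",
                 "delta_ct_sd", "n_replicates")]
  rownames(out) <- NULL
  out
}

#' Concordance between qPCR RQ and RNA-seq fold changes
#'
#' For one (sample, calibrator) comparison, checks per-gene sign agreement
#' between log2(RQ) and the RNA-seq log2 fold change of the same contrast,
#' and reports the overall agreement fraction.
#'
#' @param rq Output of [ddct()].
#' @param de DE table with `gene_id` and `log2fc` for the matching contrast
#'   (the `sample` group over the calibrator group).
#' @param sample Which sample's RQ values to compare.
#' @return `list(per_gene, agreement)`.
#' @export
rq_concordance <- function(rq, de, sample) {
  r <- rq[rq$sample == sample, ]
  shared <- intersect(r$gene_id, de$gene_id)
  if (!length(shared))
    stop_fmt("no shared genes between RQ table and DE table")
  lrq <- log2(r$rq[match(shared, r$gene_id)])
  lfc <- de$log2fc[match(shared, de$gene_id)]
  agree <- sign(lrq) == sign(lfc)
  per_gene <- data.frame(gene_id = shared, log2_rq = lrq,
                         rnaseq_log2fc = lfc, agree = agree,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene, agreement = mean(agree))
}
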