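#' Build an interval index over a QTL catalogue
#'
#' Chromosome names are normalized case-insensitively with an optional
#' leading "chr" stripped, so gene and QTL tables with different naming
#' conventions interoperate. Duplicate QTL ids are an error.
#'
#' @param qtls `data.frame`: `qtl_id`, `trait`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return A `qtl_index` object.
#' @export
build_qtl_index <- function(qtls) {
  need <- c("qtl_id", "trait", "chrom", "start", "end")
  if (!all(need %in% names(qtls)))
    stop_fmt("QTL catalogue must have columns: %s",
             paste(need, collapse = ", "))
  if (anyDuplicated(qtls$qtl_id))
    stop_fmt("duplicate QTL ids: %s",
             paste(unique(qtls$qtl_id[duplicated(qtls$qtl_id)]),
                   collapse = ", "))
  if (any(qtls$start > qtls$end)) stop_fmt("QTL interval with start > end")
  gr <- if (nrow(qtls))
    GenomicRanges::GRanges(normalize_chrom(qtls$chrom),
                           IRanges::IRanges(qtls$start, qtls$end))
  else GenomicRanges::GRanges()
  out <- list(gr = gr, qtls = qtls)
  class(out) <- "qtl_index"
  out
}

normalize_chrom <- function(x) sub("^chr", "", tolower(as.character(x)))

#' Map genes onto QTL intervals
#'
#' A gene hits a QTL iff their 1-based inclusive intervals share at least
#' one bp (`any_overlap`, the default) or the gene lies fully inside the
#' QTL (`contained`). Genes on chromosomes absent from the catalogue are
#' left unmapped with a warning.
#'
#' @param genes Gene catalogue subset (`gene_id`, `chrom`, `start`, `end`).
#' @param index A `qtl_index` from [build_qtl_index()].
#' @param rule Overlap rule.
#' @param label Optional source gene-set label recorded on the hits.
#' @return `data.frame` of hit QTLs: `qtl_id`, `trait`, `chrom`, `start`,
#'   `end`, `n_genes`, `genes` (semicolon-joined, sorted), `label`.
#' @export
map_genes_to_qtl <- function(genes, index, rule = c("any_overlap",
                                                    "contained"),
                             label = NA_character_) {
  rule <- match.arg(rule)
  stopifnot(inherits(index, "qtl_index"))
  empty <- data.frame(qtl_id = character(), trait = character(),
                      chrom = character(), start = integer(),
                      end = integer(), n_genes = integer(),
                      genes = character(), label = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(genes) || !length(index$gr)) return(empty)
  gchrom <- normalize_chrom(genes$chrom)
  known <- gchrom %in% GenomeInfoDb_seqlevels(index$gr)
  if (any(!known))
    warn_fmt("%d gene(s) on chromosome(s) absent from the QTL catalogue: %s",
             sum(!known),
             paste(unique(genes$chrom[!known]), collapse = ", "))
  genes <- genes[known, , drop = FALSE]
  if (!nrow(genes)) return(empty)
  ggr <- GenomicRanges::GRanges(gchrom[known],
                                IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(
    ggr, index$gr, type = if (rule == "contained") "within" else "any")
  if (!length(ov)) return(empty)
  hit_genes <- split(genes$gene_id[S4Vectors::queryHits(ov)],
                     S4Vectors::subjectHits(ov))
  qi <- as.integer(names(hit_genes))
  out <- index$qtls[qi, c("qtl_id", "trait", "chrom", "start", "end")]
  out$n_genes <- vapply(hit_genes, function(g) length(unique(g)), 1L)
  out$genes <- vapply(hit_genes,
                      function(g) paste(sort(unique(g)), collapse = ";"), "")
  out$label <- label
  out <- out[order(out$qtl_id), ]
  rownames(out) <- NULL
  out
}

# thin wrapper so the seqlevels accessor resolves without importing
# GenomeInfoDb directly (re-exported through GenomicRanges)
GenomeInfoDb_seqlevels <- function(gr) {
  as.character(GenomicRanges::seqnames(GenomicRanges::seqinfo(gr)))
}

#' Filter QTL hits by trait and intersect across experiments
#'
#' Restricts each experiment's hits to the given trait categories (error on
#' unknown names, listing the valid ones), reports the QTL ids hit in every
#' experiment, and tallies the common QTLs per chromosome.
#'
#' @param hits_by_experiment Named list of hit tables from
#'   [map_genes_to_qtl()].
#' @param traits Optional trait categories to keep (default: all).
#' @return `list(common, per_chromosome, per_experiment)`.
#' @export
filter_and_intersect <- function(hits_by_experiment, traits = NULL) {
  if (!length(hits_by_experiment)) stop_fmt("at least one experiment required")
  valid <- unique(unlist(lapply(hits_by_experiment, `[[`, "trait")))
  if (!is.null(traits)) {
    bad <- setdiff(traits, valid)
    if (length(bad))
      stop_fmt("unknown trait(s): %s; valid categories: %s",
               paste(bad, collapse = ", "), paste(sort(valid),
                                                  collapse = ", "))
    hits_by_experiment <- lapply(hits_by_experiment, function(h)
      h[h$trait %in% traits, , drop = FALSE])
  }
  sets <- lapply(hits_by_experiment, `[[`, "qtl_id")
  common_ids <- Reduce(intersect, sets)
  first <- hits_by_experiment[[1]]
  common <- first[first$qtl_id %in% common_ids,
                  c("qtl_id", "trait", "chrom", "start", "end")]
  rownames(common) <- NULL
  tally <- if (nrow(common)) {
    t0 <- table(common$chrom)
    data.frame(chrom = names(t0), n_qtl = as.integer(t0),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), n_qtl = integer(),
                    stringsAsFactors = FALSE)
  list(common = common, per_chromosome = tally,
       per_experiment = vapply(sets, length, 1L))
}
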