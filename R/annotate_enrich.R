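#' Default functional keyword categories
#'
#' Editable keyword lists for the heterosis-relevant functional groups
#' typically screened in rice hybrid transcriptomes: kinases, synthases,
#' NBS-LRR / resistance proteins and transcription factors. Matching is
#' case-insensitive on whole words.
#'
#' @return Named list category -> character vector of keywords.
#' @export
default_keyword_categories <- function() {
  list(kinase = c("kinase"),
       synthase = c("synthase"),
       resistance = c("NBS-LRR", "disease resistance", "LRR receptor"),
       transcription_factor = c("transcription factor"))
}

#' Keyword-based functional categorization
#'
#' Assigns every gene each category whose keyword list matches its free-text
#' functional description (multi-label; case-insensitive whole-word match).
#'
#' @param annotations `data.frame`: `gene_id`, `description` (ids unique).
#' @param categories Named list category -> keywords;
#'   [default_keyword_categories()] by default.
#' @return `list(assignments, counts)`: long gene/category table and
#'   per-category gene counts.
#' @export
keyword_categorize <- function(annotations,
                               categories = default_keyword_categories()) {
  if (anyDuplicated(annotations$gene_id))
    stop_fmt("duplicate gene ids in annotation table")
  if (any(!lengths(categories)))
    stop_fmt("every category needs at least one keyword")
  rows <- list()
  counts <- stats::setNames(integer(length(categories)), names(categories))
  for (cat_name in names(categories)) {
    kw <- categories[[cat_name]]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw)
    pattern <- paste0("\\b(", paste(esc, collapse = "|"), ")\\b")
    hit <- grepl(pattern, annotations$description, ignore.case = TRUE,
                 perl = TRUE)
    counts[cat_name] <- sum(hit)
    if (any(hit))
      rows[[cat_name]] <- data.frame(gene_id = annotations$gene_id[hit],
                                     category = cat_name,
                                     stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows)
                 else data.frame(gene_id = character(),
                                 category = character(),
                                 stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments, counts = counts)
}

#' Overlap report for named gene lists
#'
#' Intersections, sizes and per-list membership for any number of gene
#' lists, including Venn-style counts of every membership pattern.
#'
#' @param sets Named list of character vectors.
#' @return `list(sizes, intersection, membership, venn)`; `venn` has one row
#'   per membership pattern with its exclusive count.
#' @export
set_overlap <- function(sets) {
  if (!length(sets)) stop_fmt("at least one set required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_fmt("sets must be named")
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, names(sets)))
  pattern <- apply(membership, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  venn <- if (length(all_genes)) {
    t0 <- table(pattern)
    data.frame(pattern = names(t0), count = as.integer(t0),
               stringsAsFactors = FALSE)
  } else data.frame(pattern = character(), count = integer(),
                    stringsAsFactors = FALSE)
  list(sizes = vapply(sets, length, 1L),
       intersection = Reduce(intersect, sets),
       membership = as.data.frame(membership),
       venn = venn)
}

#' Hypergeometric term over-representation test
#'
#' One-sided (upper tail) hypergeometric p-value per term for the query's
#' overlap with the term's gene set in the universe, BH-corrected across
#' terms and sorted by FDR.
#'
#' @param query Character vector of query gene ids (must lie in `universe`).
#' @param universe Character vector of background gene ids.
#' @param term2gene `data.frame`: `term`, `gene_id`.
#' @return `data.frame`: `term`, `term_size`, `overlap`, `pvalue`, `fdr`.
#' @export
hypergeom_enrich <- function(query, universe, term2gene) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop_fmt("query gene(s) outside the universe: %s",
             paste(utils::head(outside, 10), collapse = ", "))
  if (!all(c("term", "gene_id") %in% names(term2gene)))
    stop_fmt("term2gene must have columns term, gene_id")
  t2g <- term2gene[term2gene$gene_id %in% universe, , drop = FALSE]
  dropped <- nrow(term2gene) - nrow(t2g)
  if (dropped)
    warn_fmt("%d term-gene pair(s) outside the universe ignored", dropped)
  terms <- split(unique(t2g)[, "gene_id"], unique(t2g)[, "term"])
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tg <- terms[[tm]]
    k <- length(intersect(query, tg))
    p <- stats::phyper(k - 1, length(tg), n_u - length(tg), n_q,
                       lower.tail = FALSE)
    data.frame(term = tm, term_size = length(tg), overlap = k,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(term = character(), term_size = integer(),
               overlap = integer(), pvalue = numeric(),
               stringsAsFactors = FALSE)
  out$fdr <- if (nrow(out)) bh_adjust(out$pvalue) else numeric()
  out <- out[order(out$fdr, out$pvalue, out$term), ]
  rownames(out) <- NULL
  out
}
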