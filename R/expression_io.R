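#' Write a count matrix and its sample sheet
#'
#' Tab-delimited UTF-8 text with a '#'-prefixed header line.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param samples Sample sheet `data.frame`; must contain a `sample_id`
#'   column matching the matrix columns.
#' @param counts_path,sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(counts, samples, counts_path, sheet_path) {
  check_counts_samples(counts, samples)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_hash(df, counts_path)
  write_tsv_hash(samples, sheet_path)
  invisible(c(counts_path, sheet_path))
}

#' Read a count matrix and its sample sheet
#'
#' Validates that counts are non-negative integers (naming the offending gene
#' and sample otherwise) and that the sheet and matrix describe the same
#' samples (naming any mismatch).
#'
#' @param counts_path,sheet_path Paths written by [write_counts()] (or any
#'   tab-delimited equivalents; a leading '#' on the header is optional).
#' @return `list(counts = matrix, samples = data.frame)`.
#' @export
read_counts <- function(counts_path, sheet_path) {
  df <- read_tsv_hash(counts_path)
  if (names(df)[1] != "gene_id")
    stop_fmt("format error: first column of %s must be gene_id", counts_path)
  samples <- read_tsv_hash(sheet_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  if (!is.numeric(counts)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(counts), nrow(counts)))), arr.ind = TRUE)[1, ]
    stop_fmt("format error: non-numeric count at gene %s, sample %s",
             rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  off <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(off))
    stop_fmt("format error: non-integer or negative count at gene %s, sample %s",
             rownames(counts)[off[1, 1]], colnames(counts)[off[1, 2]])
  storage.mode(counts) <- "integer"
  check_counts_samples(counts, samples)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  rownames(samples) <- NULL
  list(counts = counts, samples = samples)
}

check_counts_samples <- function(counts, samples) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("count matrix must have gene and sample dimnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate gene ids in count matrix")
  if (!"sample_id" %in% names(samples))
    stop_fmt("sample sheet must contain a sample_id column")
  if (anyDuplicated(samples$sample_id))
    stop_fmt("duplicate sample ids in sample sheet")
  miss <- setdiff(colnames(counts), samples$sample_id)
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(miss) || length(extra))
    stop_fmt("consistency error: %s%s",
             if (length(miss)) paste0("samples missing from sheet: ",
                                      paste(miss, collapse = ", ")) else "",
             if (length(extra)) paste0(" samples missing from matrix: ",
                                       paste(extra, collapse = ", ")) else "")
  invisible(TRUE)
}

#' Read a gene catalogue (TSV, GFF3 or BED)
#'
#' Internal coordinates are 1-based inclusive; BED input (0-based half-open)
#' is converted at the boundary. GFF3 input keeps gene-level features only.
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`; default guessed from the
#'   file extension.
#' @return Gene catalogue `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`).
#' @export
read_gene_catalog <- function(path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               gff = "gff3", gff3 = "gff3", bed = "bed", "tsv")
  if (format == "tsv") {
    df <- read_tsv_hash(path)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop_fmt("catalogue must have columns: %s", paste(need, collapse = ", "))
    if (is.null(df$strand)) df$strand <- "."
    if (is.null(df$length)) df$length <- df$end - df$start + 1L
    cat_df <- df[, c("gene_id", "chrom", "start", "end", "strand", "length")]
  } else {
    gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3"
                              else "bed")
    if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    ids <- if (format == "gff3") gr$ID else gr$name
    # rtracklayer already returns 1-based inclusive coordinates
    cat_df <- data.frame(gene_id = as.character(ids),
                         chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr),
                         strand = as.character(GenomicRanges::strand(gr)),
                         length = GenomicRanges::width(gr),
                         stringsAsFactors = FALSE)
  }
  validate_catalog(cat_df)
  cat_df
}

validate_catalog <- function(cat_df) {
  if (anyDuplicated(cat_df$gene_id)) stop_fmt("duplicate gene ids in catalogue")
  if (any(cat_df$start > cat_df$end)) stop_fmt("catalogue has start > end")
  if (any(cat_df$length < 1)) stop_fmt("catalogue has gene length < 1")
  invisible(TRUE)
}

#' Write a gene catalogue as TSV or BED
#'
#' BED output converts to 0-based half-open coordinates.
#'
#' @param catalog Gene catalogue `data.frame`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return Invisibly, `path`.
#' @export
write_gene_catalog <- function(catalog, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_hash(catalog, path)
  } else {
    bed <- data.frame(catalog$chrom, catalog$start - 1L, catalog$end,
                      catalog$gene_id, 0L, catalog$strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Compute FPKM
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (length(g) * total counts(s)).
#'
#' @param counts Count matrix, genes x samples.
#' @param catalog Gene catalogue providing the `length` used for
#'   normalization (union-exon length; end - start + 1 for single-exon
#'   synthetic genes).
#' @return Numeric matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, catalog) {
  len <- catalog$length[match(rownames(counts), catalog$gene_id)]
  if (anyNA(len))
    stop_fmt("annotation error: no catalogue length for gene(s): %s",
             paste(utils::head(rownames(counts)[is.na(len)], 5),
                   collapse = ", "))
  lib <- colSums(counts)
  if (any(lib == 0))
    stop_fmt("degenerate input: zero library size in sample(s): %s",
             paste(colnames(counts)[lib == 0], collapse = ", "))
  counts * 1e9 / outer(len, lib)
}

#' Replicate-correlation quality control
#'
#' Pearson correlation of log2(FPKM + 1) for every within-condition replicate
#' pair; a condition is (hybrid, genotype, tissue). Pairs with r below the
#' threshold (strict `<`) are flagged; constant expression vectors make r
#' undefined and are flagged with reason `"zero variance"`.
#'
#' @param expr Expression (FPKM) matrix, genes x samples.
#' @param samples Sample sheet with `sample_id`, `genotype`, `tissue`,
#'   `replicate` and optionally `hybrid`.
#' @param threshold Flagging threshold for r (default 0.8).
#' @return `list(pairs, summary)`: per-pair r with flags, and per-condition
#'   minimum/median r.
#' @export
replicate_qc <- function(expr, samples, threshold = 0.8) {
  if (!"hybrid" %in% names(samples)) samples$hybrid <- "NA"
  key <- paste(samples$hybrid, samples$genotype, samples$tissue, sep = ":")
  groups <- split(samples$sample_id, key)
  if (any(lengths(groups) < 2))
    stop_fmt("conditions with < 2 replicates: %s",
             paste(names(groups)[lengths(groups) < 2], collapse = ", "))
  lx <- log2(expr + 1)
  pair_rows <- list()
  for (cond in names(groups)) {
    ids <- groups[[cond]]
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- lx[, cmb[1, j]]; b <- lx[, cmb[2, j]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        r <- NA_real_; reason <- "zero variance"
      } else {
        r <- stats::cor(a, b); reason <- ""
      }
      flagged <- is.na(r) || r < threshold
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        condition = cond, sample_a = cmb[1, j], sample_b = cmb[2, j],
        r = r, flagged = flagged,
        reason = if (flagged && reason == "") sprintf("r < %g", threshold)
                 else reason,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  summ <- do.call(rbind, lapply(split(pairs, pairs$condition), function(d)
    data.frame(condition = d$condition[1], n_pairs = nrow(d),
               min_r = suppressWarnings(min(d$r, na.rm = TRUE)),
               median_r = stats::median(d$r, na.rm = TRUE),
               n_flagged = sum(d$flagged), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}
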