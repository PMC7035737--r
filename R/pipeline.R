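#' Default run configuration
#'
#' A flat list controlling [run_pipeline()]. With no input paths the
#' pipeline runs on synthetic data for two hybrids (each hybrid's generator
#' seed is derived from the run seed by a fixed offset so one seed governs
#' every stochastic stage).
#'
#' @param seed Run seed.
#' @param hybrids Hybrid ids to simulate/analyze.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @param ... Overrides for any default entry (DE thresholds `de_fdr`,
#'   `de_lfc`; DEGFu rule `degfu_rule`; additivity thresholds `add_fdr`,
#'   `add_lfc`; overlap rule `overlap_rule`; generator settings `n_genes`,
#'   `tissues`, `effect_log2fc`, `nb_dispersion`; input paths
#'   `counts_path`/`sheet_path`, `catalog_path`, `qtl_path`, `pheno_path`,
#'   `annotation_path`, `ct_path`, `ct_calibrator`; `n_qtl`, `qtl_traits`).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(seed = 1L, hybrids = c("HYB1", "HYB2"),
                       out_dir = NULL, ...) {
  cfg <- list(seed = as.integer(seed), hybrids = hybrids, out_dir = out_dir,
              n_genes = 2000L, n_chromosomes = 12L,
              tissues = c("0-L", "0-S", "0-P", "0-Z"),
              n_replicates = 3L, nb_dispersion = 0.1, effect_log2fc = 2,
              de_fdr = 0.01, de_lfc = 1, degfu_rule = "both_parents",
              add_fdr = 0.05, add_lfc = 1, overlap_rule = "any_overlap",
              n_qtl = 100L,
              qtl_traits = c("TBIOMYLD", "BIOMYLD", "FGRNB", "GRNB", "PNNB",
                             "SDSPCENT", "TGRWT"),
              counts_path = NULL, sheet_path = NULL, catalog_path = NULL,
              qtl_path = NULL, pheno_path = NULL, annotation_path = NULL,
              ct_path = NULL, ct_calibrator = "P1")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_fmt("unknown config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$de_fdr <= 0 || cfg$de_lfc <= 0 || cfg$add_fdr <= 0 ||
      cfg$add_lfc <= 0)
    stop_fmt("thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full trio heterosis pipeline
#'
#' Executes the stages in dependency order (simulate or load inputs;
#' replicate QC on FPKM; DE + trio classification; summary tables; phenotype
#' heterosis; QTL mapping; annotation categorization; qPCR quantification;
#' truth recovery when simulating). Each stage's outcome is recorded; a
#' stage whose inputs are absent is marked "skipped" and the rest still run,
#' and a stage failure is reported with the stage name without aborting
#' later independent stages.
#'
#' @param config A [run_config()] object.
#' @return A report bundle: result tables per stage, `status` table,
#'   resolved `config` and `config_hash`. Written to `config$out_dir` as
#'   TSV/JSON when set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = unclass(config), config_hash = config_hash(config))
  status <- list()
  note <- function(stage, state, message = "") {
    status[[stage]] <<- data.frame(stage = stage, status = state,
                                   message = message,
                                   stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, enabled, expr, skip_msg = "no input") {
    if (!enabled) { note(stage, "skipped", skip_msg); return(NULL) }
    tryCatch({ v <- force(expr); note(stage, "ok"); v },
             error = function(e) {
               note(stage, "failed", conditionMessage(e)); NULL
             })
  }

  # -- inputs: simulate or load -------------------------------------------
  sims <- NULL; catalog <- NULL; counts <- NULL; samples <- NULL
  truth <- NULL
  data_in <- run_stage("input", TRUE, {
    if (!is.null(config$counts_path)) {
      io <- read_counts(config$counts_path, config$sheet_path)
      catalog <- read_gene_catalog(config$catalog_path)
      counts <- io$counts
      samples <- io$samples
    } else {
      sims <- list()
      for (i in seq_along(config$hybrids)) {
        sc <- sim_config(n_genes = config$n_genes,
                         n_chromosomes = config$n_chromosomes,
                         tissues = config$tissues,
                         n_replicates = config$n_replicates,
                         nb_dispersion = config$nb_dispersion,
                         effect_log2fc = config$effect_log2fc,
                         seed = config$seed + 1000L * i)
        if (is.null(catalog)) catalog <- simulate_annotation(sc)
        sims[[config$hybrids[i]]] <-
          simulate_trio_counts(catalog, sc, hybrid = config$hybrids[i])
      }
      counts <- do.call(cbind, lapply(sims, `[[`, "counts"))
      samples <- do.call(rbind, lapply(sims, `[[`, "samples"))
      rownames(samples) <- NULL
      truth <- lapply(sims, `[[`, "truth")
    }
    TRUE
  })
  if (is.null(data_in)) {
    report$status <- do.call(rbind, status)
    return(report)
  }

  # -- replicate QC --------------------------------------------------------
  report$qc <- run_stage("qc", TRUE, {
    fpkm <- compute_fpkm(counts, catalog)
    replicate_qc(fpkm, samples)
  })

  # -- DE + classification -------------------------------------------------
  cls <- run_stage("classify", TRUE,
    classify_trio(counts, samples, hybrids = config$hybrids,
                  degfu_rule = config$degfu_rule,
                  de_fdr = config$de_fdr, de_lfc = config$de_lfc,
                  add_fdr = config$add_fdr, add_lfc = config$add_lfc))
  report$classification <- cls
  report$summary <- run_stage("summary", !is.null(cls),
                              summarize_classification(cls$bundles,
                                                       cls$additivity),
                              skip_msg = "classification failed")

  # -- phenotype heterosis --------------------------------------------------
  report$heterosis <- run_stage("heterosis", TRUE, {
    pheno <- if (!is.null(config$pheno_path)) read_tsv_hash(config$pheno_path)
    else simulate_traits(
      data.frame(cross = rep(config$hybrids, each = 2),
                 trait = rep(c("grain_yield", "panicle_length"),
                             length(config$hybrids)),
                 p1_mean = 8, p2_mean = 12, mph = 60,
                 stringsAsFactors = FALSE),
      seed = config$seed + 77L)
    heterosis_table(pheno)
  })

  # -- QTL mapping -----------------------------------------------------------
  report$qtl <- run_stage("qtlmap",
    !is.null(cls) && (!is.null(config$qtl_path) || is.null(config$counts_path)),
    {
      qtls <- if (!is.null(config$qtl_path)) read_tsv_hash(config$qtl_path)
      else simulate_qtl_catalog(catalog, config$n_qtl, config$qtl_traits,
                                seed = config$seed + 99L)
      index <- build_qtl_index(qtls)
      hits <- list()
      for (hy in config$hybrids) {
        genes <- unique(unlist(lapply(cls$bundles[[hy]], `[[`, "DEGFu_sp")))
        hits[[hy]] <- map_genes_to_qtl(
          catalog[catalog$gene_id %in% genes, ], index,
          rule = config$overlap_rule, label = hy)
      }
      c(list(hits = hits), filter_and_intersect(hits))
    }, skip_msg = "no QTL catalogue")

  # -- annotation ------------------------------------------------------------
  report$annotation <- run_stage("annotate", !is.null(config$annotation_path),
    {
      ann <- read_tsv_hash(config$annotation_path)
      keyword_categorize(ann)
    }, skip_msg = "no annotation table")

  # -- qPCR -------------------------------------------------------------------
  report$qpcr <- run_stage("qpcr",
    !is.null(config$ct_path) || !is.null(truth),
    {
      ct <- if (!is.null(config$ct_path)) read_tsv_hash(config$ct_path)
      else simulate_qpcr(truth[[1]], seed = config$seed + 55L)
      ddct(ct, config$ct_calibrator)
    }, skip_msg = "no Ct table")

  # -- truth recovery ----------------------------------------------------------
  report$recovery <- run_stage("recovery", !is.null(truth) && !is.null(cls), {
    out <- lapply(config$hybrids, function(hy)
      cbind(hybrid = hy, recovery_metrics(truth[[hy]], cls, hy)))
    do.call(rbind, out)
  }, skip_msg = "no planted truth")

  report$status <- do.call(rbind, status)
  rownames(report$status) <- NULL

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# write the tabular parts of a report bundle
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    write_tsv_hash(df, file.path(dir, paste0(name, ".tsv")))
  wr(report$status, "status")
  wr(report$summary$deg_counts, "deg_counts")
  wr(report$summary$ndeg_counts, "ndeg_counts")
  wr(report$summary$tissue_percent, "tissue_percent")
  wr(report$heterosis, "heterosis")
  wr(report$qtl$common, "qtl_common")
  wr(report$qpcr, "qpcr_rq")
  wr(report$recovery, "recovery")
  meta <- list(config = report$config, config_hash = report$config_hash)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE),
             file.path(dir, "run_metadata.json"))
  invisible(dir)
}

#' Summary arithmetic from externally supplied count cells
#'
#' Fixture mode: recomputes the classification summary tables from printed
#' per-(hybrid, tissue) count cells without gene-level data. Expects the full
#' two-hybrid by eight-tissue design. Returns per-hybrid DEGFu-sp totals and
#' the grand total, per-tissue-type sums pooled over stages and hybrids,
#' NDEG totals split by direction, and the per-tissue percent ratio of NDEGs
#' to DEGFu-sp (half-up, 2 decimals; undefined when the denominator is 0).
#'
#' @param deg_cells `data.frame`: `hybrid`, `tissue`, `deg2p`, `degp1`,
#'   `degp2`, `degfu_sp` (2 hybrids x 8 tissues).
#' @param ndeg_cells `data.frame`: `hybrid`, `tissue`, `up`, `down` (same
#'   design).
#' @return As [summarize_classification()], with `deg_totals` per hybrid.
#' @export
fixture_report <- function(deg_cells, ndeg_cells) {
  check_cells <- function(cells, what) {
    if (length(unique(cells$hybrid)) != 2 ||
        length(unique(cells$tissue)) != 8 || nrow(cells) != 16)
      stop_fmt("%s must contain 2 hybrids x 8 tissues (16 cells), got %d rows",
               what, nrow(cells))
  }
  check_cells(deg_cells, "deg_cells")
  check_cells(ndeg_cells, "ndeg_cells")
  out <- summarize_cells(deg_cells, ndeg_cells)
  out$deg_totals <- do.call(rbind, lapply(
    split(deg_cells, deg_cells$hybrid), function(d)
      data.frame(hybrid = d$hybrid[1], deg2p = sum(d$deg2p),
                 degp1 = sum(d$degp1), degp2 = sum(d$degp2),
                 degfu_sp = sum(d$degfu_sp), stringsAsFactors = FALSE)))
  rownames(out$deg_totals) <- NULL
  out
}

#' Load the bundled example summary cells and trait means
#'
#' Per-(hybrid, tissue) DEG/NDEG count cells and agronomic trait summaries
#' from a published two-hybrid neo-tetraploid rice trio experiment, shipped
#' as package fixtures for [fixture_report()] and [heterosis_table()].
#'
#' @return `list(deg_cells, ndeg_cells, traits)`.
#' @export
load_example_cells <- function() {
  p <- function(f) system.file("extdata", f, package = "trioHeterosis",
                               mustWork = TRUE)
  list(deg_cells = read_tsv_hash(p("example_deg_counts.tsv")),
       ndeg_cells = read_tsv_hash(p("example_ndeg_counts.tsv")),
       traits = read_tsv_hash(p("example_trait_means.tsv")))
}
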