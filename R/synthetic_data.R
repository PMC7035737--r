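#' Configuration for a synthetic trio expression experiment
#'
#' Builds and validates the configuration used by [simulate_annotation()] and
#' [simulate_trio_counts()]. A "trio" is a parent-parent-F1 hybrid design; the
#' simulator plants genes of known expression classes so that every downstream
#' stage (differential expression, F1-unique classification, additivity
#' partitioning) can be scored against ground truth.
#'
#' Planted classes (fractions in `class_fractions`, effect size
#' `effect_log2fc = e`, baseline mean `m`):
#' \describe{
#'   \item{null}{P1 = P2 = F1 = m.}
#'   \item{parent_diff}{P1/P2 = 2^e (symmetric around m); F1 equals the high
#'     parent (dominance), so the gene differs between parents but is not
#'     F1-unique.}
#'   \item{additive}{P1/P2 = 2^e; F1 sits exactly at the mid-parent value.}
#'   \item{f1_unique}{P1 = P2 = m; F1 = m * 2^(+/- e), direction alternating
#'     deterministically across genes.}
#'   \item{nonadd_up, nonadd_down}{P1 = P2 = m; F1 = mid-parent * 2^(+e) or
#'     2^(-e).}
#' }
#'
#' Class labels are allocated deterministically by largest-remainder
#' apportionment, not sampled, so per-tissue truth counts are exact. The
#' non-null block of genes rotates across tissues so that a gene carries an
#' effect in (at most) one tissue context when the per-tissue non-null load
#' times the number of tissues does not exceed the gene count;
#' `shared_across_tissues` deliberately copies a fraction of each tissue's
#' F1-unique-type genes into the next tissue to exercise the
#' tissue-specificity filter.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes genes are laid out on.
#' @param chrom_length Chromosome length in bp.
#' @param tissues Character vector of tissue context codes
#'   (`"<stage>-<organ>"`; default four organs at two stages).
#' @param n_replicates Biological replicates per genotype and tissue (>= 2).
#' @param nb_mean_log_range Range (log10) from which baseline expression means
#'   are drawn uniformly.
#' @param nb_dispersion Negative-binomial dispersion alpha >= 0
#'   (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param class_fractions Named proportions over the six planted classes;
#'   must sum to 1.
#' @param effect_log2fc Planted absolute log2 fold change (>= 0).
#' @param shared_across_tissues Fraction of each tissue's F1-unique-type genes
#'   whose effect is copied into the following tissue context.
#' @param size_factor_range Range for per-sample library size factors, drawn
#'   log-uniformly.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_chromosomes = 12L,
                       chrom_length = 3e7,
                       tissues = c("0-L", "0-S", "0-P", "0-Z",
                                   "5-L", "5-S", "5-P", "5-Z"),
                       n_replicates = 3L,
                       nb_mean_log_range = c(1.5, 3.5),
                       nb_dispersion = 0.1,
                       class_fractions = c(null = 0.80, parent_diff = 0.05,
                                           f1_unique = 0.04, nonadd_up = 0.03,
                                           nonadd_down = 0.03, additive = 0.05),
                       effect_log2fc = 2,
                       shared_across_tissues = 0,
                       size_factor_range = c(0.5, 2),
                       seed = 1L) {
  classes <- c("null", "parent_diff", "f1_unique", "nonadd_up",
               "nonadd_down", "additive")
  if (n_genes < 1) stop_fmt("n_genes must be >= 1")
  if (n_chromosomes < 1) stop_fmt("n_chromosomes must be >= 1")
  if (!length(tissues)) stop_fmt("at least one tissue context is required")
  if (anyDuplicated(tissues)) stop_fmt("tissue codes must be unique")
  if (n_replicates < 2) stop_fmt("design error: n_replicates must be >= 2")
  if (nb_dispersion < 0) stop_fmt("nb_dispersion must be >= 0")
  if (effect_log2fc < 0) stop_fmt("effect_log2fc must be >= 0")
  if (!setequal(names(class_fractions), classes))
    stop_fmt("class_fractions must be named exactly: %s",
             paste(classes, collapse = ", "))
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop_fmt("class_fractions must be non-negative and sum to 1")
  if (shared_across_tissues < 0 || shared_across_tissues > 1)
    stop_fmt("shared_across_tissues must be in [0, 1]")
  if (length(nb_mean_log_range) != 2 || diff(nb_mean_log_range) < 0)
    stop_fmt("nb_mean_log_range must be an increasing pair")
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0)
    stop_fmt("size_factor_range must be a positive increasing pair")
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              tissues = tissues,
              n_replicates = as.integer(n_replicates),
              nb_mean_log_range = nb_mean_log_range,
              nb_dispersion = nb_dispersion,
              class_fractions = class_fractions,
              effect_log2fc = effect_log2fc,
              shared_across_tissues = shared_across_tissues,
              size_factor_range = size_factor_range,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene catalogue
#'
#' Lays out non-overlapping single-exon genes on equal-length chromosomes.
#' Coordinates are 1-based inclusive; lengths are at least 200 bp. Each
#' chromosome is divided into equal slots, one gene per slot, which guarantees
#' non-overlap and gives a deterministic sizing error when too many genes are
#' requested.
#'
#' @param config A [sim_config()] object.
#' @return A gene catalogue `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  nc <- config$n_chromosomes
  per_chrom <- rep(n %/% nc, nc) + c(rep(1L, n %% nc), rep(0L, nc - n %% nc))
  min_len <- 200L
  withr::with_seed(config$seed + 11L, {
    recs <- vector("list", nc)
    gi <- 0L
    for (k in seq_len(nc)) {
      m <- per_chrom[k]
      if (m == 0L) next
      slot <- floor(config$chrom_length / m)
      if (slot < min_len + 2L)
        stop_fmt(paste0("sizing error: %d genes do not fit on chromosome %d ",
                        "(slot %d bp < minimum gene footprint %d bp)"),
                 m, k, slot, min_len + 2L)
      max_len <- min(5000L, slot - 1L)
      len <- sample(min_len:max_len, m, replace = TRUE)
      offset <- vapply(slot - len, function(room) sample.int(room, 1L),
                       integer(1))
      start <- (seq_len(m) - 1L) * slot + offset
      recs[[k]] <- data.frame(
        gene_id = sprintf("G%05d", gi + seq_len(m)),
        chrom = sprintf("chr%02d", k),
        start = start,
        end = start + len - 1L,
        strand = sample(c("+", "-"), m, replace = TRUE),
        stringsAsFactors = FALSE)
      gi <- gi + m
    }
    cat_df <- do.call(rbind, recs)
  })
  cat_df$length <- cat_df$end - cat_df$start + 1L
  # stable gene-id ordering (G00001 ... ), chromosome blocks already ordered
  rownames(cat_df) <- NULL
  cat_df
}

# largest-remainder apportionment of n items to named fractions
class_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  need <- n - sum(base)
  if (need > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# per-tissue planted class labels: deterministic rotation of the non-null
# block so effects land in different genes in different tissue contexts
allocate_classes <- function(config) {
  n <- config$n_genes
  counts <- class_counts(config$class_fractions, n)
  eff_classes <- c("parent_diff", "f1_unique", "nonadd_up", "nonadd_down",
                   "additive")
  block <- rep(eff_classes, counts[eff_classes])
  b <- length(block)
  out <- list()
  for (k in seq_along(config$tissues)) {
    lab <- rep("null", n)
    if (b > 0) {
      idx <- ((k - 1L) * b + seq_len(b) - 1L) %% n + 1L
      lab[idx] <- block
    }
    out[[config$tissues[k]]] <- lab
  }
  out
}

#' Simulate trio counts with planted truth
#'
#' Generates negative-binomial fragment counts for P1, P2 and F1 across all
#' tissue contexts and replicates of one hybrid, with per-sample library size
#' factors drawn log-uniformly, and records the planted truth per
#' (gene, tissue).
#'
#' @param catalog Gene catalogue from [simulate_annotation()].
#' @param config A [sim_config()] object.
#' @param hybrid Hybrid identifier used in sample ids and the sample sheet.
#' @return A list of class `trio_sim` with elements `counts` (integer matrix,
#'   genes x samples), `samples` (sample sheet with the drawn
#'   `true_size_factor`), and `truth` (per gene and tissue: planted `class`,
#'   `log2_p1_vs_p2`, `log2_f1_vs_mp`).
#' @export
simulate_trio_counts <- function(catalog, config, hybrid = "HYB1") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(catalog) || !nrow(catalog)) stop_fmt("empty gene catalogue")
  if (config$n_replicates < 1) stop_fmt("design error: zero replicates")
  n <- nrow(catalog)
  tissues <- config$tissues
  reps <- config$n_replicates
  genotypes <- c("P1", "P2", "F1")
  e <- config$effect_log2fc
  alpha <- config$nb_dispersion

  samples <- expand.grid(replicate = seq_len(reps), genotype = genotypes,
                         tissue = tissues, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "tissue", "replicate")]
  samples$hybrid <- hybrid
  samples$sample_id <- sprintf("%s.%s.%s.r%d", hybrid, samples$genotype,
                               samples$tissue, samples$replicate)
  samples <- samples[, c("sample_id", "hybrid", "genotype", "tissue",
                         "replicate")]

  labels <- allocate_classes(config)
  # deterministic alternating sign for f1_unique genes, per tissue
  truth <- list()
  mu <- array(0, dim = c(n, 3, length(tissues)),
              dimnames = list(catalog$gene_id, genotypes, tissues))

  withr::with_seed(config$seed + 23L, {
    base_mu <- 10^stats::runif(n, config$nb_mean_log_range[1],
                               config$nb_mean_log_range[2])
    sfr <- config$size_factor_range
    samples$true_size_factor <-
      exp(stats::runif(nrow(samples), log(sfr[1]), log(sfr[2])))

    for (t in seq_along(tissues)) {
      lab <- labels[[t]]
      lp <- numeric(n)           # planted log2(P1/P2)
      lf <- numeric(n)           # planted log2(F1/mid-parent)
      hi <- base_mu * 2^(e / 2)
      lo <- base_mu * 2^(-e / 2)
      mp_split <- (hi + lo) / 2
      p1 <- base_mu; p2 <- base_mu; f1 <- base_mu

      i <- lab == "parent_diff"
      p1[i] <- hi[i]; p2[i] <- lo[i]; f1[i] <- hi[i]
      lp[i] <- e; lf[i] <- log2(hi[i] / mp_split[i])

      i <- lab == "additive"
      p1[i] <- hi[i]; p2[i] <- lo[i]; f1[i] <- mp_split[i]
      lp[i] <- e; lf[i] <- 0

      i <- which(lab == "f1_unique")
      if (length(i)) {
        dir <- rep_len(c(1, -1), length(i))
        f1[i] <- base_mu[i] * 2^(dir * e)
        lf[i] <- dir * e
      }
      i <- lab == "nonadd_up"
      f1[i] <- base_mu[i] * 2^e; lf[i] <- e
      i <- lab == "nonadd_down"
      f1[i] <- base_mu[i] * 2^(-e); lf[i] <- -e

      # optional cross-tissue sharing of F1-unique-type effects (copied from
      # the previous tissue context, so those genes are no longer specific)
      s <- config$shared_across_tissues
      if (s > 0 && t > 1) {
        fam_prev <- which(labels[[t - 1]] %in%
                            c("f1_unique", "nonadd_up", "nonadd_down"))
        n_share <- floor(s * length(fam_prev))
        if (n_share > 0) {
          shared <- fam_prev[seq_len(n_share)]
          prev <- truth[[tissues[t - 1]]]
          lab[shared] <- prev$class[shared]
          lp[shared] <- prev$log2_p1_vs_p2[shared]
          lf[shared] <- prev$log2_f1_vs_mp[shared]
          mpv <- base_mu[shared]
          p1[shared] <- mpv; p2[shared] <- mpv
          f1[shared] <- mpv * 2^lf[shared]
        }
      }

      mu[, "P1", t] <- p1; mu[, "P2", t] <- p2; mu[, "F1", t] <- f1
      truth[[tissues[t]]] <- data.frame(
        gene_id = catalog$gene_id, tissue = tissues[t], class = lab,
        log2_p1_vs_p2 = lp, log2_f1_vs_mp = lf, stringsAsFactors = FALSE)
    }

    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(catalog$gene_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      m <- mu[, samples$genotype[j], samples$tissue[j]] *
        samples$true_size_factor[j]
      counts[, j] <- if (alpha > 0)
        stats::rnbinom(n, mu = m, size = 1 / alpha)
      else
        stats::rpois(n, m)
    }
  })

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(counts = counts, samples = samples, truth = truth,
              hybrid = hybrid, config = config)
  class(out) <- "trio_sim"
  out
}

#' Simulate agronomic trait tables with planted heterosis
#'
#' Draws per-plant Gaussian trait values for P1, P2 and F1 of each cross so
#' that the population mid-parent heterosis equals the planted `mph`
#' percentage; high-parent heterosis follows from the parent means.
#'
#' @param effects `data.frame` with columns `cross`, `trait`, `p1_mean`,
#'   `p2_mean`, `mph` (planted mid-parent heterosis, percent) and optionally
#'   `cv` (per-plant coefficient of variation, default 0.05).
#' @param n_plants Plants per line (>= 3).
#' @param seed Integer seed.
#' @return Long `data.frame`: `cross`, `line` (P1/P2/F1), `trait`, `plant`,
#'   `value`.
#' @export
simulate_traits <- function(effects, n_plants = 15L, seed = 1L) {
  if (n_plants < 3) stop_fmt("n_plants must be >= 3")
  need <- c("cross", "trait", "p1_mean", "p2_mean", "mph")
  if (!all(need %in% names(effects)))
    stop_fmt("effects must have columns: %s", paste(need, collapse = ", "))
  cv <- effects$cv %||% NULL
  if (is.null(cv)) cv <- rep(0.05, nrow(effects))
  f1_mean <- (effects$p1_mean + effects$p2_mean) / 2 * (1 + effects$mph / 100)
  if (any(effects$p1_mean <= 0) || any(effects$p2_mean <= 0) ||
      any(f1_mean <= 0))
    stop_fmt("config error: non-positive trait mean for a positive-valued trait")
  withr::with_seed(seed, {
    rows <- vector("list", nrow(effects))
    for (i in seq_len(nrow(effects))) {
      means <- c(P1 = effects$p1_mean[i], P2 = effects$p2_mean[i],
                 F1 = f1_mean[i])
      vals <- lapply(names(means), function(ln)
        stats::rnorm(n_plants, means[[ln]], cv[i] * means[[ln]]))
      rows[[i]] <- data.frame(
        cross = effects$cross[i],
        line = rep(names(means), each = n_plants),
        trait = effects$trait[i],
        plant = rep(seq_len(n_plants), 3),
        value = unlist(vals), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Simulate a QTL catalogue with known gene membership
#'
#' Each simulated QTL interval covers an exact, recorded set of consecutive
#' genes on one chromosome: interval ends are drawn between the covered genes
#' and their neighbours, so overlap-based mapping must recover the membership
#' exactly.
#'
#' @param catalog Gene catalogue ([simulate_annotation()]).
#' @param n_qtl Number of QTL intervals (>= 1).
#' @param traits Non-empty character vector of trait categories, assigned
#'   cyclically.
#' @param seed Integer seed.
#' @param genes_per_qtl Inclusive range for the number of genes per interval.
#' @return `data.frame`: `qtl_id`, `trait`, `chrom`, `start`, `end`,
#'   `n_genes_true`, `genes_true` (semicolon-joined gene ids).
#' @export
simulate_qtl_catalog <- function(catalog, n_qtl, traits, seed = 1L,
                                 genes_per_qtl = c(1L, 20L)) {
  if (is.null(catalog) || !nrow(catalog)) stop_fmt("empty gene catalogue")
  if (n_qtl < 1) stop_fmt("n_qtl must be >= 1")
  if (!length(traits)) stop_fmt("traits must be non-empty")
  by_chrom <- split(catalog[order(catalog$chrom, catalog$start), ],
                    catalog$chrom[order(catalog$chrom, catalog$start)])
  chroms <- names(by_chrom)
  withr::with_seed(seed + 31L, {
    rows <- vector("list", n_qtl)
    for (q in seq_len(n_qtl)) {
      cg <- by_chrom[[sample(length(chroms), 1L,
                             prob = vapply(by_chrom, nrow, 1L))]]
      k <- sample(genes_per_qtl[1]:min(genes_per_qtl[2], nrow(cg)), 1L)
      i0 <- sample.int(nrow(cg) - k + 1L, 1L)
      first <- cg[i0, ]; last <- cg[i0 + k - 1L, ]
      left <- if (i0 > 1L) cg$end[i0 - 1L] + 1L else 1L
      right <- if (i0 + k - 1L < nrow(cg)) cg$start[i0 + k] - 1L
               else last$end + 1000L
      start <- if (left < first$start)
        sample(left:first$start, 1L) else first$start
      end <- if (right > last$end) sample(last$end:right, 1L) else last$end
      rows[[q]] <- data.frame(
        qtl_id = sprintf("AQ%04d", q),
        trait = traits[(q - 1L) %% length(traits) + 1L],
        chrom = first$chrom, start = start, end = end,
        n_genes_true = k,
        genes_true = paste(cg$gene_id[i0:(i0 + k - 1L)], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate qPCR Ct tables from planted expression ratios
#'
#' Builds target and reference Ct values for P1, P2 and F1 of one tissue
#' context such that the Livak 2^-ddCt quantity recovers the planted
#' F1/parent expression ratios (exactly when `ct_sd = 0`).
#'
#' @param truth Truth table from [simulate_trio_counts()].
#' @param tissue Tissue context to draw genes from (default: first present).
#' @param genes Gene ids to assay; default: up to 8 genes with a planted
#'   effect in `tissue`.
#' @param n_replicates Technical replicates per reaction (default 3).
#' @param ct_sd Gaussian cycle noise added to every Ct (default 0).
#' @param ref_ct Reference-gene Ct level.
#' @param seed Integer seed.
#' @return Long `data.frame`: `sample` (P1/P2/F1), `gene_id`, `ct_target`,
#'   `ct_reference`, `replicate`.
#' @export
simulate_qpcr <- function(truth, tissue = NULL, genes = NULL,
                          n_replicates = 3L, ct_sd = 0, ref_ct = 20,
                          seed = 1L) {
  if (is.null(truth) || !nrow(truth)) stop_fmt("empty truth table")
  tissue <- tissue %||% truth$tissue[1]
  tt <- truth[truth$tissue == tissue, ]
  if (!nrow(tt)) stop_fmt("tissue %s not present in truth table", tissue)
  if (is.null(genes)) {
    cand <- tt$gene_id[tt$class != "null"]
    if (!length(cand)) cand <- tt$gene_id
    genes <- utils::head(cand, 8L)
  }
  tt <- tt[match(genes, tt$gene_id), ]
  if (anyNA(tt$gene_id)) stop_fmt("requested genes missing from truth table")
  # relative genotype means implied by the planted effects (baseline = 1)
  p1 <- 2^(tt$log2_p1_vs_p2 / 2)
  p2 <- 2^(-tt$log2_p1_vs_p2 / 2)
  f1 <- (p1 + p2) / 2 * 2^tt$log2_f1_vs_mp
  rel <- cbind(P1 = p1, P2 = p2, F1 = f1)
  withr::with_seed(seed + 41L, {
    base_dct <- stats::runif(length(genes), 2, 10)
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        sample = c("P1", "P2", "F1"),
                        gene = seq_along(genes), stringsAsFactors = FALSE)
    dct <- base_dct[grid$gene] -
      log2(rel[cbind(grid$gene, match(grid$sample, colnames(rel)))])
    out <- data.frame(
      sample = grid$sample,
      gene_id = genes[grid$gene],
      ct_target = ref_ct + dct + stats::rnorm(nrow(grid), 0, ct_sd),
      ct_reference = ref_ct + stats::rnorm(nrow(grid), 0, ct_sd),
      replicate = grid$replicate, stringsAsFactors = FALSE)
  })
  rownames(out) <- NULL
  out
}

#' Write the text outputs of a simulated trio experiment
#'
#' Writes counts, sample sheet, gene catalogue (TSV and BED), and truth table
#' as tab-delimited UTF-8 text with '#'-prefixed headers.
#'
#' @param sim A `trio_sim` object.
#' @param catalog Gene catalogue used to simulate it.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_sim_data <- function(sim, catalog, dir) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             catalog = file.path(dir, "genes.tsv"),
             bed = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, sim$samples, paths["counts"], paths["samples"])
  write_gene_catalog(catalog, paths["catalog"], format = "tsv")
  write_gene_catalog(catalog, paths["bed"], format = "bed")
  write_tsv_hash(sim$truth, paths["truth"])
  invisible(paths)
}
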