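# small shared fixtures, built in code

tiny_config <- function(seed = 7, tissues = c("0-L", "0-S"), n_genes = 300,
                        ...) {
  sim_config(n_genes = n_genes, n_chromosomes = 3, tissues = tissues,
             seed = seed, ...)
}

tiny_sim <- function(seed = 7, tissues = c("0-L", "0-S"), n_genes = 300,
                     hybrid = "HYB1", ...) {
  cfg <- tiny_config(seed = seed, tissues = tissues, n_genes = n_genes, ...)
  catalog <- simulate_annotation(cfg)
  sim <- simulate_trio_counts(catalog, cfg, hybrid = hybrid)
  list(cfg = cfg, catalog = catalog, sim = sim)
}

# deterministic trio count matrix with explicit genotype means, one tissue
manual_trio_counts <- function(means, n_rep = 3, tissue = "0-L",
                               hybrid = "H", jitter = NULL, seed = 1) {
  # means: matrix genes x 3 (P1, P2, F1)
  genotypes <- c("P1", "P2", "F1")
  samples <- expand.grid(replicate = seq_len(n_rep), genotype = genotypes,
                         stringsAsFactors = FALSE)
  samples$tissue <- tissue
  samples$hybrid <- hybrid
  samples$sample_id <- sprintf("%s.%s.%s.r%d", hybrid, samples$genotype,
                               tissue, samples$replicate)
  samples <- samples[, c("sample_id", "hybrid", "genotype", "tissue",
                         "replicate")]
  counts <- matrix(0L, nrow(means), nrow(samples),
                   dimnames = list(rownames(means), samples$sample_id))
  withr::with_seed(seed, {
    for (j in seq_len(nrow(samples))) {
      m <- means[, match(samples$genotype[j], genotypes)]
      x <- if (is.null(jitter)) m else stats::rnorm(length(m), m, jitter * m)
      counts[, j] <- as.integer(pmax(0, round(x)))
    }
  })
  list(counts = counts, samples = samples)
}

# brute-force enumeration oracle for the conditional NB split test:
# plain scalar loop over every split, probabilities via dnbinom products
oracle_nb_pvalue <- function(ka, kb, n_a, n_b, alpha) {
  s <- ka + kb
  if (s == 0) return(1)
  mu0 <- s / (n_a + n_b)
  prob <- numeric(s + 1)
  for (k in 0:s) {
    prob[k + 1] <- if (alpha <= 0) {
      stats::dbinom(k, s, n_a / (n_a + n_b))
    } else {
      stats::dnbinom(k, mu = n_a * mu0, size = n_a / alpha) *
        stats::dnbinom(s - k, mu = n_b * mu0, size = n_b / alpha)
    }
  }
  prob <- prob / sum(prob)
  p_obs <- prob[ka + 1]
  total <- 0
  for (k in 0:s) if (prob[k + 1] <= p_obs * (1 + 1e-7))
    total <- total + prob[k + 1]
  min(1, total)
}

# brute-force all-pairs interval overlap scan (1-based inclusive)
oracle_overlap <- function(genes, qtls, contained = FALSE) {
  hits <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(qtls))) {
    same <- sub("^chr", "", tolower(genes$chrom[i])) ==
      sub("^chr", "", tolower(qtls$chrom[j]))
    ok <- if (contained)
      same && genes$start[i] >= qtls$start[j] && genes$end[i] <= qtls$end[j]
    else
      same && genes$start[i] <= qtls$end[j] && genes$end[i] >= qtls$start[j]
    if (ok) hits[[length(hits) + 1]] <-
        data.frame(gene_id = genes$gene_id[i], qtl_id = qtls$qtl_id[j],
                   stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(gene_id = character(),
                                       qtl_id = character()))
  do.call(rbind, hits)
}
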