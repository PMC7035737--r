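test_that("fixed seed gives byte-identical catalogue and counts", {
  cfg <- tiny_config(seed = 1)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  catalog <- simulate_annotation(cfg)
  s1 <- simulate_trio_counts(catalog, cfg)
  s2 <- simulate_trio_counts(catalog, cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$samples, s2$samples)
})

test_that("catalogue respects construction invariants", {
  cfg <- sim_config(n_genes = 100, n_chromosomes = 2, seed = 3)
  catalog <- simulate_annotation(cfg)
  expect_equal(nrow(catalog), 100)
  expect_false(anyDuplicated(catalog$gene_id) > 0)
  expect_true(all(catalog$end >= catalog$start))
  expect_true(all(catalog$length >= 200))
  for (ch in split(catalog, catalog$chrom)) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1)
      expect_true(all(ch$start[-1] > ch$end[-nrow(ch)]))
  }
})

test_that("overfull chromosomes raise a sizing error", {
  cfg <- sim_config(n_genes = 1000, n_chromosomes = 1, chrom_length = 5e4,
                    seed = 1)
  expect_error(simulate_annotation(cfg), "sizing error")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(sim_config(class_fractions = c(null = 0.5, parent_diff = 0.2,
                                              f1_unique = 0.1,
                                              nonadd_up = 0.1,
                                              nonadd_down = 0.05,
                                              additive = 0.10)),
               "sum to 1")
  expect_error(sim_config(class_fractions = c(foo = 1)), "named")
})

test_that("class labels are allocated exactly by largest remainder", {
  cfg <- sim_config(n_genes = 1000, tissues = c("0-L", "0-S"),
                    class_fractions = c(null = 0.5, parent_diff = 0.1,
                                        f1_unique = 0.1, nonadd_up = 0.2,
                                        nonadd_down = 0.05, additive = 0.05),
                    seed = 2)
  catalog <- simulate_annotation(cfg)
  sim <- simulate_trio_counts(catalog, cfg)
  tab <- table(sim$truth$class, sim$truth$tissue)
  expect_equal(unname(tab["nonadd_up", ]), c(200, 200))
  expect_equal(unname(tab["null", ]), c(500, 500))
  # one truth row per (gene, tissue)
  expect_equal(nrow(sim$truth), 2000)
  expect_false(anyDuplicated(paste(sim$truth$gene_id, sim$truth$tissue)) > 0)
})

test_that("simulated counts match NB moments within 5%", {
  # one expression level, many replicates = many draws per cell
  cfg <- sim_config(n_genes = 5, n_chromosomes = 1, tissues = "0-L",
                    n_replicates = 10000, nb_mean_log_range = c(2, 2),
                    nb_dispersion = 0.1,
                    class_fractions = c(null = 1, parent_diff = 0,
                                        f1_unique = 0, nonadd_up = 0,
                                        nonadd_down = 0, additive = 0),
                    size_factor_range = c(1, 1), seed = 11)
  catalog <- simulate_annotation(cfg)
  sim <- simulate_trio_counts(catalog, cfg)
  p1 <- sim$counts[, sim$samples$genotype == "P1"]
  mu <- 100
  v_expect <- mu + 0.1 * mu^2
  for (g in seq_len(nrow(p1))) {
    expect_lt(abs(mean(p1[g, ]) - mu) / mu, 0.05)
    expect_lt(abs(stats::var(p1[g, ]) - v_expect) / v_expect, 0.05)
  }
})

test_that("trait simulator plants heterosis exactly in the zero-noise limit", {
  eff <- data.frame(cross = "C1", trait = "yield", p1_mean = 8, p2_mean = 12,
                    mph = 50, cv = 0)
  obs <- simulate_traits(eff, n_plants = 5, seed = 1)
  h <- heterosis_table(obs)
  expect_equal(h$mph, 50, tolerance = 1e-12)
  expect_equal(h$f1_mean, 15, tolerance = 1e-12)
  expect_equal(h$hph, (15 - 12) / 12 * 100, tolerance = 1e-12)
})

test_that("planted MPH of zero is recovered as n grows", {
  eff <- data.frame(cross = "C1", trait = "yield", p1_mean = 10,
                    p2_mean = 10, mph = 0, cv = 0.05)
  obs <- simulate_traits(eff, n_plants = 2000, seed = 4)
  h <- heterosis_table(obs)
  expect_lt(abs(h$mph), 0.5)
  # determinism
  expect_identical(obs, simulate_traits(eff, n_plants = 2000, seed = 4))
})

test_that("trait simulator rejects non-positive means", {
  eff <- data.frame(cross = "C1", trait = "yield", p1_mean = 1, p2_mean = 1,
                    mph = -150)
  expect_error(simulate_traits(eff), "config error")
})

test_that("simulated QTL membership is exact under overlap mapping", {
  x <- tiny_sim(seed = 5)
  qtls <- simulate_qtl_catalog(x$catalog, n_qtl = 30,
                               traits = c("GRNB", "TGRWT"), seed = 5)
  expect_identical(qtls, simulate_qtl_catalog(x$catalog, n_qtl = 30,
                                              traits = c("GRNB", "TGRWT"),
                                              seed = 5))
  index <- build_qtl_index(qtls)
  hits <- map_genes_to_qtl(x$catalog, index)
  expect_setequal(hits$qtl_id, qtls$qtl_id)
  m <- match(hits$qtl_id, qtls$qtl_id)
  expect_equal(hits$n_genes, qtls$n_genes_true[m])
  expect_equal(hits$genes,
               vapply(strsplit(qtls$genes_true[m], ";"),
                      function(g) paste(sort(g), collapse = ";"), ""))
  expect_error(simulate_qtl_catalog(x$catalog[0, ], 5, "GRNB"), "empty")
  expect_error(simulate_qtl_catalog(x$catalog, 5, character()), "non-empty")
})

test_that("simulated Ct tables invert to the planted expression ratios", {
  x <- tiny_sim(seed = 9)
  ct <- simulate_qpcr(x$sim$truth, tissue = "0-L", ct_sd = 0, seed = 2)
  expect_identical(ct, simulate_qpcr(x$sim$truth, tissue = "0-L", ct_sd = 0,
                                     seed = 2))
  rq <- ddct(ct, calibrator = "P1")
  tr <- x$sim$truth[x$sim$truth$tissue == "0-L", ]
  tr <- tr[match(unique(ct$gene_id), tr$gene_id), ]
  p1 <- 2^(tr$log2_p1_vs_p2 / 2)
  p2 <- 2^(-tr$log2_p1_vs_p2 / 2)
  f1 <- (p1 + p2) / 2 * 2^tr$log2_f1_vs_mp
  f1_rq <- rq$rq[rq$sample == "F1"][match(tr$gene_id,
                                          rq$gene_id[rq$sample == "F1"])]
  expect_equal(f1_rq, f1 / p1, tolerance = 1e-9)
  # a gene with planted F1/P1 ratio 4 shows a -2 cycle ddCt
  up <- which(abs(f1 / p1 - 4) < 1e-9)
  if (length(up)) {
    dd <- rq$delta_delta_ct[rq$sample == "F1" &
                              rq$gene_id %in% tr$gene_id[up]]
    expect_equal(dd, rep(-2, length(dd)), tolerance = 1e-9)
  }
})
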