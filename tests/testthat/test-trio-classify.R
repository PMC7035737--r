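test_that("trio sets are stored verbatim and deduplicated", {
  b <- build_trio_sets(list(P1_vs_P2 = c("a", "b"), F1_vs_P1 = c("b", "c"),
                            F1_vs_P2 = "c"), "H", "0-L")
  expect_setequal(b$DEG2P, c("a", "b"))
  expect_setequal(b$DEGP1, c("b", "c"))
  expect_setequal(b$DEGP2, "c")
  expect_warning(
    b2 <- build_trio_sets(list(P1_vs_P2 = c("a", "a"), F1_vs_P1 = "b",
                               F1_vs_P2 = "c"), "H", "0-L"),
    "duplicated")
  expect_equal(b2$DEG2P, "a")
  expect_error(build_trio_sets(list(P1_vs_P2 = "a", F1_vs_P1 = "b"),
                               "H", "0-S"),
               "missing contrast.*F1_vs_P2")
  b3 <- build_trio_sets(list(P1_vs_P2 = character(),
                             F1_vs_P1 = character(),
                             F1_vs_P2 = character()), "H", "0-L")
  expect_length(b3$DEG2P, 0)
})

test_that("DEGFu follows the set rule and stays disjoint from DEG2P", {
  b <- build_trio_sets(list(P1_vs_P2 = "c", F1_vs_P1 = c("a", "b"),
                            F1_vs_P2 = c("b", "c")), "H", "0-L")
  both <- derive_degfu(b, "both_parents")
  expect_equal(both$DEGFu, "b")
  either <- derive_degfu(b, "either_parent")
  expect_setequal(either$DEGFu, c("a", "b"))
  # DEG2P swallowing everything leaves nothing F1-unique
  b2 <- build_trio_sets(list(P1_vs_P2 = c("a", "b", "c"),
                             F1_vs_P1 = c("a", "b"), F1_vs_P2 = c("b", "c")),
                        "H", "0-L")
  expect_length(derive_degfu(b2, "both_parents")$DEGFu, 0)
  # property: both_parents DEGFu never intersects DEG2P
  set.seed(1)
  for (i in 1:20) {
    pool <- letters[1:10]
    b3 <- build_trio_sets(list(P1_vs_P2 = sample(pool, 4),
                               F1_vs_P1 = sample(pool, 5),
                               F1_vs_P2 = sample(pool, 5)), "H", "0-L")
    b3 <- derive_degfu(b3)
    expect_length(intersect(b3$DEGFu, b3$DEG2P), 0)
  }
})

test_that("tissue specificity keeps genes F1-unique in exactly one tissue", {
  mk <- function(tissue, fu) {
    b <- build_trio_sets(list(P1_vs_P2 = character(), F1_vs_P1 = fu,
                              F1_vs_P2 = fu), "H", tissue)
    derive_degfu(b)
  }
  bundles <- list(`0-L` = mk("0-L", c("a", "b")),
                  `5-L` = mk("5-L", c("b", "c")))
  out <- derive_degfu_sp(bundles)
  expect_equal(out$`0-L`$DEGFu_sp, "a")   # b shared across tissues: dropped
  expect_equal(out$`5-L`$DEGFu_sp, "c")
  # single tissue: identity
  single <- derive_degfu_sp(bundles["0-L"])
  expect_setequal(single$`0-L`$DEGFu_sp, c("a", "b"))
  # shared-allowed switch disables the filter
  off <- derive_degfu_sp(bundles, allow_shared = TRUE)
  expect_setequal(off$`0-L`$DEGFu_sp, c("a", "b"))
  # mixing hybrids is an error
  b2 <- mk("0-L", "a"); b2$hybrid <- "OTHER"
  expect_error(derive_degfu_sp(list(bundles$`0-L`, b2)), "mix")
})

test_that("exact mid-parent expression is classified additive", {
  means <- cbind(P1 = c(400, 100), P2 = c(200, 100), F1 = c(300, 100))
  rownames(means) <- c("g1", "g2")
  d <- manual_trio_counts(means)
  out <- additivity_test(d$counts, d$samples, c("g1", "g2"), "H", "0-L",
                         size_factors = stats::setNames(
                           rep(1, nrow(d$samples)), d$samples$sample_id),
                         method = "welch")
  expect_equal(out$class, c("additive", "additive"))
  expect_equal(out$log2_f1_vs_mp, c(0, 0), tolerance = 1e-9)
})

test_that("a four-fold mid-parent deviation is called non-additive", {
  set.seed(3)
  n <- 40
  means <- cbind(P1 = rep(200, n), P2 = rep(200, n),
                 F1 = rep(c(800, 50), each = n / 2))
  rownames(means) <- sprintf("g%02d", seq_len(n))
  d <- manual_trio_counts(means, jitter = 0.05)
  out <- additivity_test(d$counts, d$samples, rownames(means), "H", "0-L",
                         size_factors = stats::setNames(
                           rep(1, nrow(d$samples)), d$samples$sample_id))
  expect_true(all(out$class[1:(n / 2)] == "nonadditive_up"))
  expect_true(all(out$class[(n / 2 + 1):n] == "nonadditive_down"))
  # partition property: every tested gene lands in exactly one class
  expect_true(all(out$class %in% c("additive", "nonadditive_up",
                                   "nonadditive_down")))
  # sign coherence
  expect_true(all(out$log2_f1_vs_mp[out$class == "nonadditive_up"] > 0))
  expect_true(all(out$log2_f1_vs_mp[out$class == "nonadditive_down"] < 0))
})

test_that("all-zero genes are uninformative additives", {
  means <- cbind(P1 = c(0, 300), P2 = c(0, 100), F1 = c(0, 600))
  rownames(means) <- c("gz", "gx")
  d <- manual_trio_counts(means)
  out <- additivity_test(d$counts, d$samples, c("gz", "gx"), "H", "0-L",
                         size_factors = stats::setNames(
                           rep(1, nrow(d$samples)), d$samples$sample_id),
                         method = "welch")
  expect_identical(out$class[1], "additive")
  expect_true(out$uninformative[1])
  expect_false(out$uninformative[2])
})

test_that("summary tables keep their internal arithmetic coherent", {
  x <- tiny_sim(seed = 13, n_genes = 500)
  cls <- classify_trio(x$sim$counts, x$sim$samples)
  s <- summarize_classification(cls$bundles, cls$additivity)
  expect_equal(s$ndeg_counts$total, s$ndeg_counts$up + s$ndeg_counts$down)
  expect_equal(s$totals$ndeg_total, sum(s$ndeg_counts$total))
  expect_equal(s$totals$degfu_sp_grand_total, sum(s$deg_counts$degfu_sp))
  expect_equal(sum(s$totals$degfu_sp_by_hybrid$degfu_sp_total),
               s$totals$degfu_sp_grand_total)
  ok <- !is.na(s$tissue_percent$percent)
  expect_true(all(s$tissue_percent$percent[ok] >= 0 &
                    s$tissue_percent$percent[ok] <= 100))
  # additivity is confined to DEGFu-sp and partitions it per tissue
  for (ts in names(cls$bundles$HYB1)) {
    b <- cls$bundles$HYB1[[ts]]
    a <- cls$additivity[cls$additivity$tissue == ts, ]
    expect_setequal(a$gene_id, b$DEGFu_sp)
  }
  # DEGFu-sp sets of different tissues are pairwise disjoint
  expect_length(intersect(cls$bundles$HYB1$`0-L`$DEGFu_sp,
                          cls$bundles$HYB1$`0-S`$DEGFu_sp), 0)
})

test_that("planted classes are recovered on a small simulation", {
  x <- tiny_sim(seed = 17, n_genes = 600)
  cls <- classify_trio(x$sim$counts, x$sim$samples)
  rm <- recovery_metrics(x$sim$truth, cls, "HYB1")
  expect_true(all(rm$precision > 0.85))
  expect_true(all(rm$recall > 0.8))
})

test_that("cross-tissue sharing lowers tissue-specific recall by design", {
  x <- tiny_sim(seed = 19, n_genes = 600, shared_across_tissues = 0.5)
  cls <- classify_trio(x$sim$counts, x$sim$samples)
  rm <- recovery_metrics(x$sim$truth, cls, "HYB1")
  # shared F1-unique genes are planted in two tissues and must be dropped
  # by the exactly-one-tissue rule, so recall drops well below 0.9
  expect_lt(rm$recall[rm$class == "f1_unique"], 0.85)
  expect_true(all(rm$precision > 0.85, na.rm = TRUE))
})
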