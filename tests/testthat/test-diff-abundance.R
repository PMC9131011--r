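test_that("Dirichlet instances are proportion matrices with the right moments", {
  tab <- toy_table()
  tab$counts["ASV_2", ] <- tab$counts["ASV_2", ] + 1  # avoid zero-only row
  inst <- dirichlet_instances(tab, n_mc = 5, seed = 1)
  expect_length(inst, 5)
  for (m in inst) expect_equal(colSums(m), rep(1, 4), ignore_attr = TRUE,
                               tolerance = 1e-12)
  # single feature -> every draw is exactly 1
  one <- feature_table(matrix(c(3, 8), 1, 2,
                              dimnames = list("f", c("S1", "S2"))))
  expect_true(all(unlist(dirichlet_instances(one, n_mc = 3, seed = 1)) == 1))
  # prior-only draws have Dirichlet mean alpha_i / sum(alpha)
  zero <- feature_table(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                        c("S1", "S2"))))
  draws <- dirichlet_instances(zero, n_mc = 5000, prior = 0.5, seed = 2)
  m1 <- mean(vapply(draws, function(m) m[1, 1], numeric(1)))
  expect_lt(abs(m1 - 0.5), 0.02)
  # fixed seed reproduces the instance sequence
  expect_identical(dirichlet_instances(tab, n_mc = 3, seed = 9),
                   dirichlet_instances(tab, n_mc = 3, seed = 9))
  expect_error(dirichlet_instances(tab, prior = 0), "positive")
})

test_that("CLR matches hand computation and is permutation-equivariant", {
  p <- matrix(c(0.5, 0.25, 0.25), 3, 1,
              dimnames = list(c("a", "b", "c"), "S1"))
  expect_equal(unname(clr(p)[, 1]), c(2 / 3, -1 / 3, -1 / 3))
  u <- matrix(1 / 4, 4, 2, dimnames = list(letters[1:4], c("S1", "S2")))
  expect_true(all(clr(u) == 0))
  q <- matrix(c(.1, .2, .3, .4), 4, 1, dimnames = list(letters[1:4], "S1"))
  perm <- c(3, 1, 4, 2)
  expect_equal(clr(q[perm, , drop = FALSE]), clr(q)[perm, , drop = FALSE])
  expect_equal(sum(clr(q)), 0, tolerance = 1e-9)
  expect_error(clr(q * 0), "positive")
})

test_that("planted effects give the smallest expected p-values", {
  co <- generate_cohort(cohort_config(n_group_a = 50, n_group_b = 50,
                                      n_asv = 80, n_differential = 4,
                                      effect_log2 = 2, seed = 77))
  res <- test_features(co$counts, co$metadata, n_mc = 32, seed = 8)
  top4 <- res$feature[order(res$p)][1:4]
  expect_setequal(top4, co$truth$differential$all)
  # planted direction: PD-enriched, so positive log2fc
  expect_true(all(res$log2fc[res$feature %in% top4] > 0))
})

test_that("identical groups yield no significant features", {
  m <- small_cohort()$counts$counts[1:30, 1:10]
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("S%02d", 1:20)
  # each PD sample has an identical HC twin
  meta <- data.frame(sample_id = colnames(dup),
                     group = rep(c("PD", "HC"), each = 10))
  res <- test_features(feature_table(dup), meta, n_mc = 16, seed = 4)
  expect_gt(median(res$p), 0.5)
  expect_false(any(res$significant))
})

test_that("expected BH-adjusted p dominates expected raw p", {
  co <- small_cohort()
  res <- test_features(co$counts, co$metadata, n_mc = 16, seed = 5)
  expect_true(all(res$p_bh >= res$p - 1e-12))
  expect_true(all(res$p >= 0 & res$p_bh <= 1))
})

test_that("scaling one sample's depth perturbs CLR statistics only through
           the prior, and the perturbation shrinks with depth", {
  scale_shift <- function(depth) {
    co <- generate_cohort(cohort_config(n_group_a = 10, n_group_b = 10,
                                        n_asv = 60, n_differential = 4,
                                        sequencing_depth_mean = depth,
                                        seed = 55))
    tab <- co$counts
    scaled <- tab$counts
    scaled[, 1] <- scaled[, 1] * 10
    r1 <- test_features(tab, co$metadata, n_mc = 64, seed = 6)
    r2 <- test_features(feature_table(scaled), co$metadata, n_mc = 64,
                        seed = 6)
    median(abs(r1$log2fc - r2$log2fc))
  }
  shallow <- scale_shift(3000)
  deep <- scale_shift(60000)
  # residual sensitivity comes from the Dirichlet prior on zero counts; it
  # must fade as counts grow, and stay far below a genuine scale artefact
  # (which would move log2fc by about log2(10) for the scaled sample)
  expect_lt(deep, shallow)
  expect_lt(deep, 0.15)
})

test_that("doubling the Monte-Carlo depth barely moves expected p", {
  co <- small_cohort()
  cols <- c(1:12, 26:37)
  tab <- feature_table(co$counts$counts[, cols])
  meta <- co$metadata[cols, ]
  r64 <- test_features(tab, meta, n_mc = 64, seed = 7)
  r128 <- test_features(tab, meta, n_mc = 128, seed = 7)
  expect_lt(median(abs(r64$p - r128$p)), 0.01)
})

test_that("volcano flags follow the -log10 p and fold-change thresholds", {
  res <- data.frame(p = c(1e-4, 1e-4, 0.01, 1e-5),
                    p_bh = c(2e-4, 2e-4, 0.02, 2e-5),
                    fold_change = c(2.7, 1.0, 3.0, -1.5))
  expect_identical(flag_significant(res), c(TRUE, FALSE, FALSE, TRUE))
  # -log p = 2 <= 3 for p = 0.01 even with large fold change
  expect_false(flag_significant(res)[3])
  # adjusted-p variant and configurable base
  expect_identical(flag_significant(res, use_adjusted = TRUE),
                   c(TRUE, FALSE, FALSE, TRUE))
})
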