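test_that("the same config and seed give bit-identical cohorts", {
  cfg <- cohort_config(n_group_a = 10, n_group_b = 10, n_asv = 30, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("a degenerate group gives a single-label cohort", {
  co <- generate_cohort(cohort_config(n_group_a = 0, n_group_b = 10,
                                      n_asv = 20, n_differential = 3, seed = 2))
  expect_equal(ncol(co$counts$counts), 10)
  expect_true(all(co$metadata$group == "HC"))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sequencing_depth_mean = 0), "positive")
  expect_error(cohort_config(n_differential = 50, n_asv = 20), "exceeds")
  expect_error(cohort_config(n_asv = 20, n_differential = 15,
                             stratum_effect = TRUE), "disjoint")
  expect_error(cohort_config(depth_dispersion = -1), "positive")
})

test_that("cohort internals are mutually consistent", {
  co <- small_cohort()
  ids <- rownames(co$counts$counts)
  expect_setequal(co$taxonomy$asv_id, ids)
  expect_setequal(co$tree$tip.label, ids)
  expect_true(all(unlist(co$truth$differential) %in% ids))
  # taxonomy is hierarchical: fewer groups at each higher rank
  tx <- co$taxonomy
  expect_lte(length(unique(tx$phylum)), length(unique(tx$order)))
  expect_lte(length(unique(tx$order)), length(unique(tx$family)))
  expect_lte(length(unique(tx$family)), length(unique(tx$genus)))
  # macronutrient and %-energy columns present
  expect_true(all(c("protein_g", "fat_g", "sugar_g", "fiber_g",
                    "carbohydrate_g", "energy_kj", "pct_protein", "pct_fat",
                    "pct_carbohydrate") %in% names(co$metadata)))
  expect_true(all(co$metadata$pct_carbohydrate > 0 &
                  co$metadata$pct_carbohydrate < 100))
})

test_that("sequencing depths scatter around the configured mean", {
  co <- generate_cohort(cohort_config(n_group_a = 40, n_group_b = 40,
                                      n_asv = 50, sequencing_depth_mean = 20000,
                                      depth_dispersion = 0.3, seed = 5))
  depths <- colSums(co$counts$counts)
  expect_gt(mean(depths), 20000 * exp(-2 * 0.3))
  expect_lt(mean(depths), 20000 * exp(2 * 0.3))
})

test_that("planted taxa carry the configured CLR effect on average", {
  # oracle: direct CLR group-mean difference on the generated truth taxa,
  # averaged over replicate cohorts
  reps <- 20
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(cohort_config(
      n_group_a = 200, n_group_b = 200, n_asv = 200,
      sequencing_depth_mean = 50000, n_differential = 5, effect_log2 = 2,
      seed = 1000 + r))
    m <- co$counts$counts + 0.5
    lg <- log2(m)
    cl <- sweep(lg, 2, colMeans(lg), "-")
    pd <- co$metadata$group == "PD"
    planted <- co$truth$differential$all
    est[r] <- mean(rowMeans(cl[planted, pd, drop = FALSE]) -
                   rowMeans(cl[planted, !pd, drop = FALSE]))
  }
  expect_lt(abs(mean(est) - 2), 0.5)
})

test_that("random trees are binary, rooted, and round-trip through Newick", {
  tr <- generate_tree(c("A", "B"), seed = 3)
  expect_equal(ape::Ntip(tr), 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, c("A", "B"))
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-8)

  tr2 <- generate_tree(sprintf("t%02d", 1:17), seed = 9)
  expect_true(ape::is.binary(tr2))
  expect_true(ape::is.rooted(tr2))
  expect_equal(tr2$Nnode, 17 - 1)  # n - 1 internal nodes for binary rooted
  expect_true(all(tr2$edge.length > 0))
  expect_error(generate_tree("one"), ">= 2 leaves")
})

test_that("written cohorts read back identically", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_counts(file.path(dir, "counts.tsv"))
  expect_identical(back$counts, co$counts$counts)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tax$genus, co$taxonomy$genus)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$carbohydrate_g, co$metadata$carbohydrate_g)
})
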