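test_that("alpha diversity matches closed forms", {
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(simpson(rep(3, 4)), 0.75)
  expect_equal(shannon(c(0, 9, 0)), 0)
  expect_equal(simpson(c(0, 9, 0)), 0)
  expect_equal(richness(c(0, 9, 0)), 1)
  # oracle: direct summation
  p <- (1:4) / 10
  expect_equal(shannon(1:4), -sum(p * log(p)))
  expect_equal(simpson(1:4), 1 - sum(p^2))
  expect_equal(simpson(1:4, inverse = TRUE), 1 / sum(p^2))
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("alpha diversity agrees with vegan", {
  co <- small_cohort()
  m <- co$counts$counts[, 1:10]
  expect_equal(apply(m, 2, shannon),
               vegan::diversity(t(m), index = "shannon"))
  expect_equal(apply(m, 2, simpson),
               vegan::diversity(t(m), index = "simpson"))
})

test_that("Bray-Curtis matches hand computation and limit cases", {
  m <- cbind(S1 = c(1, 2, 0), S2 = c(0, 2, 4), S3 = c(1, 2, 0))
  rownames(m) <- paste0("f", 1:3)
  d <- bray_curtis(feature_table(m))
  expect_equal(d["S1", "S2"], 1 - 2 * 2 / 9)   # = 5/9
  expect_equal(d["S1", "S3"], 0)               # identical samples
  disj <- cbind(S1 = c(3, 1, 0, 0), S2 = c(0, 0, 2, 5))
  rownames(disj) <- paste0("f", 1:4)
  expect_equal(bray_curtis(feature_table(disj))["S1", "S2"], 1)
})

test_that("distance matrices are symmetric, zero-diagonal, in range", {
  co <- small_cohort()
  tab <- feature_table(co$counts$counts[, 1:12])
  for (d in list(bray_curtis(tab), unifrac(tab, co$tree),
                 unifrac(tab, co$tree, weighted = TRUE))) {
    expect_equal(d, t(d))
    expect_equal(diag(d), rep(0, 12), ignore_attr = TRUE)
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
})

test_that("UniFrac matches a branch-by-branch hand computation", {
  # ((A:1,B:2):1,(C:3,D:1):2); two samples with known per-branch sums
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  m <- cbind(S1 = c(A = 4, B = 0, C = 4, D = 0),
             S2 = c(A = 0, B = 2, C = 6, D = 0))
  tab <- feature_table(m)
  # unweighted: unique branches = A(1) + B(2); shared/union excludes D(1)
  un <- unifrac(tab, tree)
  expect_equal(un["S1", "S2"], (1 + 2) / (1 + 2 + 1 + 3 + 2))
  # weighted: proportions S1 = (.5,0,.5,0), S2 = (0,.25,.75,0)
  # per-branch |dA - dB| * length, internal branches carry subtree sums
  num <- 1 * abs(.5 - 0) + 2 * abs(0 - .25) + 1 * abs(.5 - .25) +
         3 * abs(.5 - .75) + 1 * 0 + 2 * abs(.5 - .75)
  den <- 1 * (.5 + 0) + 2 * (0 + .25) + 1 * (.5 + .25) +
         3 * (.5 + .75) + 1 * 0 + 2 * (.5 + .75)
  w <- unifrac(tab, tree, weighted = TRUE)
  expect_equal(w["S1", "S2"], num / den)
  expect_equal(unifrac(tab, tree, weighted = TRUE, normalized = FALSE)["S1", "S2"],
               num)
})

test_that("UniFrac limit cases: identical samples and complete turnover", {
  tree <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):2);")
  same <- cbind(S1 = c(A = 2, B = 1, C = 0, D = 3),
                S2 = c(A = 4, B = 2, C = 0, D = 6))
  tab <- feature_table(same)
  expect_equal(unifrac(tab, tree)["S1", "S2"], 0)
  expect_equal(unifrac(tab, tree, weighted = TRUE)["S1", "S2"], 0)
  # disjoint subtrees joined at the root -> unweighted = 1
  disj <- cbind(S1 = c(A = 3, B = 1, C = 0, D = 0),
                S2 = c(A = 0, B = 0, C = 2, D = 2))
  expect_equal(unifrac(feature_table(disj), tree)["S1", "S2"], 1)
  expect_error(unifrac(feature_table(rbind(same, E = c(1, 1))), tree),
               "absent from tree")
})

test_that("unweighted UniFrac agrees with picante on a random cohort", {
  skip_if_not_installed("picante")
  co <- small_cohort()
  tab <- feature_table(co$counts$counts[, 1:8])
  ours <- unifrac(tab, co$tree)
  ref <- as.matrix(picante::unifrac(t(tab$counts), co$tree))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("PCoA reproduces closed-form eigenstructure", {
  # equilateral triangle, side 1: two equal positive eigenvalues, third ~ 0
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(paste0("S", 1:3), paste0("S", 1:3))
  pc <- pcoa(d, n_axes = 2)
  eig <- pc$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  expect_equal(eig[1] + eig[2], 1, tolerance = 1e-10)
  expect_lt(abs(eig[3]), 1e-10)
  # embedded coordinates reproduce the distances
  expect_equal(as.matrix(dist(pc$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)

  # collinear points: one positive eigenvalue carries ~100% of the variance
  x <- c(0, 1, 3, 6)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("S", 1:4), paste0("S", 1:4))
  pl <- pcoa(dl, n_axes = 2)
  expect_equal(pl$proportion_explained[1], 1, tolerance = 1e-10)

  # duplicated sample -> coincident coordinates
  dd <- as.matrix(dist(c(0, 0, 2, 5)))
  dimnames(dd) <- list(paste0("S", 1:4), paste0("S", 1:4))
  pd_ <- pcoa(dd, n_axes = 2)
  expect_lt(sqrt(sum((pd_$coordinates["S1", ] - pd_$coordinates["S2", ])^2)),
            1e-6)
  expect_error(pcoa(dd, n_axes = 4), "n_samples - 1")
})

test_that("PCoA eigenvalue sum equals the trace of the centred matrix", {
  co <- small_cohort()
  d <- bray_curtis(feature_table(co$counts$counts[, 1:15]))
  pc <- pcoa(d, n_axes = 3)
  a <- -0.5 * d^2
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  expect_equal(sum(pc$eigenvalues), sum(diag(J %*% a %*% J)), tolerance = 1e-8)
})
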