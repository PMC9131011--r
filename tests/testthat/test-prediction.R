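# small feature matrix with a clean group signal for fast LOOCV tests
sep_data <- function(n_per = 10, p = 12, shift = 2.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[seq_len(n_per), 1:3] <- X[seq_len(n_per), 1:3] + shift
  rownames(X) <- sprintf("S%02d", seq_len(2 * n_per))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, labels = rep(c("PD", "HC"), each = n_per))
}

test_that("entropy and information gain match closed forms", {
  expect_equal(entropy(c(0, 0, 1, 1)), 1)
  expect_equal(entropy(rep("a", 5)), 0)
  expect_equal(information_gain(c(0, 0, 1, 1), c(1, 2, 3, 4), 2.5), 1)
  # constant variable: no admissible split
  expect_true(is.na(information_gain(c(0, 1), c(2, 2), 2)))
  # empty side is inadmissible
  expect_true(is.na(information_gain(c(0, 1, 1), c(1, 2, 3), 5)))
  # weighted-mean oracle on an impure split
  y <- c(0, 0, 1, 0, 1, 1); x <- 1:6
  g <- information_gain(y, x, 3.5)
  h <- function(k, m) { p <- k / m
    -ifelse(p > 0, p * log2(p), 0) - ifelse(p < 1, (1 - p) * log2(1 - p), 0) }
  expect_equal(g, h(3, 6) - 0.5 * h(1, 3) - 0.5 * h(2, 3))
})

test_that("the stump finds the maximum-gain midpoint", {
  st <- fit_stump(c(1, 2, 3, 4), c(0, 0, 1, 1), name = "x")
  expect_equal(st$threshold, 2.5)
  expect_equal(st$gain, 1)
  # perfectly separating clusters: gain = parent entropy, midpoint between
  st2 <- fit_stump(c(10, 11, 12, 30, 31), c("a", "a", "a", "b", "b"))
  expect_equal(st2$threshold, 21)
  expect_equal(st2$gain, entropy(c("a", "a", "a", "b", "b")))
  # ties broken by the lower threshold
  st3 <- fit_stump(c(1, 2, 3, 4), c(0, 1, 0, 1), name = "x")
  expect_equal(st3$threshold, 1.5)
  expect_error(fit_stump(rep(3, 4), c(0, 0, 1, 1)), "identical")
})

test_that("AUC is the Mann-Whitney statistic with half ties", {
  expect_equal(auc_mann_whitney(c(.9, .4, .8, .2), c("PD", "PD", "HC", "HC")), 0.75)
  expect_equal(auc_mann_whitney(c(.9, .8, .4, .2), c("PD", "PD", "HC", "HC")), 1)
  expect_equal(auc_mann_whitney(c(.5, .5, .5, .5), c("PD", "PD", "HC", "HC")), 0.5)
  # label swap maps AUC to 1 - AUC
  sc <- c(.9, .4, .8, .2, .7)
  lab <- c("PD", "PD", "HC", "HC", "PD")
  swap <- ifelse(lab == "PD", "HC", "PD")
  expect_equal(auc_mann_whitney(sc, lab, positive = "PD"),
               1 - auc_mann_whitney(sc, swap, positive = "PD"))
})

test_that("AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- round(runif(40), 2)   # rounding forces ties
  lab <- sample(c("PD", "HC"), 40, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("HC", "PD"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc_mann_whitney(sc, lab), ref)
})

test_that("LOOCV separates a clean signal and is reproducible", {
  d <- sep_data()
  r <- loocv_single(d$X, d$labels, seed = 3, num_trees = 150)
  expect_gt(r$auc, 0.9)
  expect_true(all(r$scores >= 0 & r$scores <= 1))
  expect_length(r$scores, nrow(d$X))
  r2 <- loocv_single(d$X, d$labels, seed = 3, num_trees = 150)
  expect_identical(r$scores, r2$scores)
  expect_error(loocv_single(d$X[1:8, ], d$labels[1:8], seed = 1), "n >= 10")
})

test_that("LOOCV scores do not depend on sample order", {
  d <- sep_data(n_per = 7, p = 8)
  r <- loocv_single(d$X, d$labels, seed = 5, num_trees = 100)
  perm <- sample(nrow(d$X))
  rp <- loocv_single(d$X[perm, ], d$labels[perm], seed = 5, num_trees = 100)
  expect_equal(rp$scores[names(r$scores)], r$scores)
})

test_that("shuffled labels give chance-level AUC", {
  aucs <- numeric(6)
  for (s in 1:6) {
    set.seed(100 + s)
    X <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("S%02d", 1:30), sprintf("f%d", 1:10)))
    lab <- sample(rep(c("PD", "HC"), each = 15))
    aucs[s] <- loocv_single(X, lab, seed = s, num_trees = 120)$auc
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a constant partition variable reduces two-stage to single-stage", {
  d <- sep_data()
  meta <- data.frame(sample_id = rownames(d$X), nutrient = rep(5, nrow(d$X)))
  r1 <- loocv_single(d$X, d$labels, seed = 7, num_trees = 120)
  r2 <- loocv_two_stage(d$X, meta, d$labels, "nutrient", seed = 7,
                        num_trees = 120)
  expect_identical(r2$scores, r1$scores)
  expect_equal(r2$auc, r1$auc)
})

test_that("tiny strata fall back to the whole-fold model and are counted", {
  d <- sep_data()
  meta <- data.frame(sample_id = rownames(d$X),
                     nutrient = c(100, rep(1, nrow(d$X) - 1)))
  r <- loocv_two_stage(d$X, meta, d$labels, "nutrient", seed = 9,
                       num_trees = 100)
  expect_gte(r$n_fallback, 1)
  expect_true(is.finite(r$auc))
})

test_that("the full-cohort split mode warns about leakage", {
  d <- sep_data()
  meta <- data.frame(sample_id = rownames(d$X),
                     nutrient = rnorm(nrow(d$X)))
  expect_warning(loocv_two_stage(d$X, meta, d$labels, "nutrient", seed = 2,
                                 refit_split_in_fold = FALSE, num_trees = 60),
                 "leak")
})

test_that("the SVM comparator runs through the identical harness", {
  skip_if_not_installed("e1071")
  d <- sep_data()
  r <- loocv_single(d$X, d$labels, seed = 4, model = "svm")
  expect_gt(r$auc, 0.85)
})

test_that("survey returns the baseline plus one row per candidate, ranked", {
  d <- sep_data(n_per = 8, p = 8)
  meta <- data.frame(sample_id = rownames(d$X), a = rnorm(16), b = rnorm(16))
  meta$b <- meta$a  # duplicated candidate -> identical rows
  sv <- survey_macronutrients(d$X, meta, d$labels, c("a", "b"), seed = 6,
                              num_trees = 80)
  expect_equal(nrow(sv), 3)
  expect_true("(single-stage)" %in% sv$variable)
  expect_equal(sv$auc, sort(sv$auc, decreasing = TRUE))
  expect_equal(sv$auc[sv$variable == "a"], sv$auc[sv$variable == "b"])
})
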