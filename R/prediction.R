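# Prediction of disease status from taxa profiles: single-stage random
# forest with leave-one-out cross-validated AUC, the macronutrient decision
# stump (maximum information gain), the two-stage nutrient-partitioned
# model with pooled LOOCV scores, and the macronutrient survey.

#' Shannon entropy of a label vector (bits)
#' @param labels Vector of class labels.
#' @return Entropy in bits.
#' @export
entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a threshold split
#'
#' `H(labels) - weighted mean of child entropies` for the partition
#' `variable <= threshold` vs `> threshold`, in bits. A threshold leaving
#' one side empty is inadmissible and returns `NA`.
#'
#' @param labels Binary label vector.
#' @param variable Numeric vector, no missing values.
#' @param threshold Split point.
#' @return Gain in bits, or `NA` for an inadmissible split.
#' @export
information_gain <- function(labels, variable, threshold) {
  if (anyNA(variable)) stop("variable has missing values")
  lo <- variable <= threshold
  if (!any(lo) || all(lo)) return(NA_real_)
  entropy(labels) -
    (mean(lo) * entropy(labels[lo]) + mean(!lo) * entropy(labels[!lo]))
}

#' Fit a decision stump on a macronutrient
#'
#' Exhaustive search over the midpoints between consecutive sorted distinct
#' values of the variable, returning the split with maximum information
#' gain on the labels (ties broken by the lower threshold).
#'
#' @param variable Numeric vector (the macronutrient), no missing values.
#' @param labels Binary label vector aligned with `variable`.
#' @param name Variable name recorded in the result.
#' @return List of class `stump_split`: `variable`, `threshold`, `gain`
#'   (bits).
#' @export
fit_stump <- function(variable, labels, name = deparse(substitute(variable))) {
  if (anyNA(variable)) stop("variable has missing values")
  ord <- order(variable)
  x <- variable[ord]
  y <- as.integer(as.factor(labels))[ord] - 1L
  ux <- unique(x)
  if (length(ux) < 2) stop("all values identical")
  n <- length(x)
  H <- entropy(y)
  # cumulative positives up to each boundary between distinct values
  cum_pos <- cumsum(y)
  last_idx <- cumsum(tabulate(match(x, ux)))  # index of last sample per distinct value
  n_lo <- last_idx[-length(ux)]
  pos_lo <- cum_pos[n_lo]
  ent2 <- function(k, m) {  # entropy of k positives among m
    p <- k / m; q <- 1 - p
    -ifelse(p > 0, p * log2(p), 0) - ifelse(q > 0, q * log2(q), 0)
  }
  pos_tot <- sum(y)
  gain <- H - (n_lo / n) * ent2(pos_lo, n_lo) -
    ((n - n_lo) / n) * ent2(pos_tot - pos_lo, n - n_lo)
  mids <- (ux[-length(ux)] + ux[-1]) / 2
  best <- which(gain >= max(gain) - 1e-12)[1]  # ties -> lower threshold
  structure(list(variable = name, threshold = mids[best], gain = gain[best]),
            class = "stump_split")
}

#' @export
print.stump_split <- function(x, ...) {
  cat(sprintf("stump: %s <= %.4g (information gain %.4f bits)\n",
              x$variable, x$threshold, x$gain))
  invisible(x)
}

#' AUC by the Mann-Whitney rank statistic
#'
#' Probability that a random positive scores above a random negative, ties
#' counted one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; `positive` names the positive level.
#' @param positive Positive class label (default `"PD"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels, positive = "PD") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and Youden-optimal operating point
#'
#' Threshold sweep over the unique scores; sensitivity and specificity are
#' reported at the point maximising Youden's J.
#'
#' @inheritParams auc_mann_whitney
#' @return List with `roc` (data frame threshold/sensitivity/specificity),
#'   `sensitivity`, `specificity`, `threshold` at the Youden point.
#' @export
roc_youden <- function(scores, labels, positive = "PD") {
  pos <- labels == positive
  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)
  list(roc = data.frame(threshold = thr, sensitivity = sens, specificity = spec),
       sensitivity = sens[best], specificity = spec[best],
       threshold = thr[best])
}

# deterministic per-sample fold seed from the master seed and the sample ID,
# so LOOCV scores do not depend on sample order
.fold_seed <- function(seed, id) {
  v <- utf8ToInt(id)
  h <- sum(v * (seq_along(v) * 131)) %% 104729
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483563)
}

# fit a probability forest and return P(positive) for newdata
.fit_score <- function(X, y, newX, seed, positive, model = "rf",
                       num_trees = 500) {
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  df <- data.frame(X, check.names = FALSE)
  df$.y <- factor(y)
  if (model == "rf") {
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = num_trees, mtry = max(1, floor(sqrt(ncol(X)))),
      seed = seed, num.threads = 1)
    pr <- stats::predict(fit, data.frame(newX, check.names = FALSE),
                         num.threads = 1)$predictions
    pr[, positive]
  } else if (model == "svm") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("the svm comparator needs the e1071 package")
    set.seed(seed)
    fit <- e1071::svm(x = X, y = factor(y), probability = TRUE)
    pr <- attr(stats::predict(fit, newX, probability = TRUE), "probabilities")
    pr[, positive]
  } else stop("unknown model: ", model)
}

#' Single-stage LOOCV classifier
#'
#' For each sample, a probability random forest (500 trees, sqrt(p)
#' variables per split) is trained on all other samples and scores the
#' held-out sample with its predicted probability of the positive class.
#' AUC is the Mann-Whitney statistic over the pooled held-out scores. The
#' per-fold seed is derived from the master seed and the held-out sample's
#' ID, so results do not depend on sample order.
#'
#' @param features Numeric matrix, samples x features, with sample IDs as
#'   rownames (e.g. `t(relative_abundance(table))`).
#' @param labels Binary labels aligned with the rows of `features`.
#' @param seed Master integer seed.
#' @param model `"rf"` (default) or `"svm"` comparator.
#' @param positive Positive class label (default `"PD"`).
#' @param num_trees Trees per forest (default 500).
#' @return List of class `loocv_result`: `scores` (named), `auc`, `roc`,
#'   `sensitivity`, `specificity`.
#' @export
loocv_single <- function(features, labels, seed = 1L, model = "rf",
                         positive = "PD", num_trees = 500) {
  n <- nrow(features)
  if (n < 10) stop("need n >= 10")
  if (length(unique(labels)) != 2) stop("both classes required")
  if (is.null(rownames(features))) stop("features must have sample ID rownames")
  scores <- stats::setNames(numeric(n), rownames(features))
  for (i in seq_len(n)) {
    ytr <- labels[-i]
    if (length(unique(ytr)) < 2) stop("training fold with one class only")
    scores[i] <- .fit_score(features[-i, , drop = FALSE], ytr,
                            features[i, , drop = FALSE],
                            seed = .fold_seed(seed, rownames(features)[i]),
                            positive = positive, model = model,
                            num_trees = num_trees)
  }
  ry <- roc_youden(scores, labels, positive)
  structure(list(scores = scores, auc = auc_mann_whitney(scores, labels, positive),
                 roc = ry$roc, sensitivity = ry$sensitivity,
                 specificity = ry$specificity, model = model),
            class = "loocv_result")
}

#' Two-stage nutrient-partitioned LOOCV classifier
#'
#' Stage one is a decision stump on a macronutrient; stage two fits a
#' separate random forest in each stratum. By default
#' (`refit_split_in_fold = TRUE`) the stump is refit inside every LOOCV
#' training fold, the held-out sample is assigned to a stratum by its own
#' nutrient value, and a forest trained on the fold's stratum members
#' scores it — all n held-out scores are pooled into one ROC/AUC.
#' `refit_split_in_fold = FALSE` reproduces the full-cohort stump (the
#' convention behind the printed splitting nodes) and warns that the split
#' then leaks information across folds. A stratum with fewer than
#' `min_stratum` training samples (or a single class) falls back to the
#' whole-fold model for that sample; the number of fallbacks is reported.
#'
#' @inheritParams loocv_single
#' @param metadata Data frame with `sample_id` and the nutrient column.
#' @param variable Metadata column used for the stage-one split.
#' @param refit_split_in_fold Refit the stump within each training fold
#'   (default) rather than once on the full cohort.
#' @param min_stratum Minimum training samples per stratum (default 5).
#' @return List of class `two_stage_result`: `stump` (full-data stump, for
#'   reporting), `scores`, `auc`, `roc`, `sensitivity`, `specificity`,
#'   `auc_by_stratum` (weighted-average alternative pooling), `n_fallback`.
#' @export
loocv_two_stage <- function(features, metadata, labels, variable, seed = 1L,
                            refit_split_in_fold = TRUE, min_stratum = 5,
                            model = "rf", positive = "PD", num_trees = 500) {
  n <- nrow(features)
  if (n < 10) stop("need n >= 10")
  meta <- metadata[match(rownames(features), metadata$sample_id), ]
  x <- meta[[variable]]
  if (is.null(x)) stop("metadata column not found: ", variable)
  if (anyNA(x)) stop("nutrient variable has missing values")

  if (length(unique(x)) < 2) {
    # degenerate partition: a single stratum is the whole cohort, so the
    # model reduces to the single-stage classifier with identical folds
    base <- loocv_single(features, labels, seed = seed, model = model,
                         positive = positive, num_trees = num_trees)
    return(structure(list(stump = NULL, scores = base$scores, auc = base$auc,
                          roc = base$roc, sensitivity = base$sensitivity,
                          specificity = base$specificity,
                          auc_by_stratum = base$auc,
                          stratum = stats::setNames(rep("all", n), rownames(features)),
                          n_fallback = 0L,
                          refit_split_in_fold = refit_split_in_fold),
                     class = "two_stage_result"))
  }
  full_stump <- fit_stump(x, labels, name = variable)
  if (!refit_split_in_fold)
    warning("full-cohort stump: the stage-one split is fit on all samples, ",
            "so held-out samples leak into the partition")

  scores <- stats::setNames(numeric(n), rownames(features))
  stratum_of <- character(n)
  n_fallback <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2) stop("training fold with one class only")
    st <- if (refit_split_in_fold && length(unique(x[tr])) >= 2)
      fit_stump(x[tr], ytr, name = variable) else full_stump
    side_tr <- x[tr] <= st$threshold
    side_i <- x[i] <= st$threshold
    stratum_of[i] <- if (side_i) "low" else "high"
    members <- tr[side_tr == side_i]
    fold_seed <- .fold_seed(seed, rownames(features)[i])
    if (length(members) < min_stratum || length(unique(labels[members])) < 2) {
      n_fallback <- n_fallback + 1L
      members <- tr
    }
    scores[i] <- .fit_score(features[members, , drop = FALSE], labels[members],
                            features[i, , drop = FALSE], seed = fold_seed,
                            positive = positive, model = model,
                            num_trees = num_trees)
  }
  ry <- roc_youden(scores, labels, positive)
  # alternative pooling: stratum-size-weighted average of per-stratum AUCs
  auc_strat <- vapply(unique(stratum_of), function(s) {
    idx <- stratum_of == s
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    auc_mann_whitney(scores[idx], labels[idx], positive)
  }, numeric(1))
  w <- table(stratum_of)[names(auc_strat)]
  ok <- !is.na(auc_strat)
  structure(list(stump = full_stump, scores = scores,
                 auc = auc_mann_whitney(scores, labels, positive),
                 roc = ry$roc, sensitivity = ry$sensitivity,
                 specificity = ry$specificity,
                 auc_by_stratum = if (any(ok))
                   sum(auc_strat[ok] * w[ok]) / sum(w[ok]) else NA_real_,
                 stratum = stats::setNames(stratum_of, rownames(features)),
                 n_fallback = n_fallback,
                 refit_split_in_fold = refit_split_in_fold),
            class = "two_stage_result")
}

#' Survey candidate macronutrients as stage-one partitions
#'
#' Runs the single-stage baseline plus one two-stage model per candidate
#' nutrient, and ranks them by LOOCV-AUC (descending).
#'
#' @inheritParams loocv_two_stage
#' @param candidates Character vector of numeric metadata columns.
#' @return Data frame `variable`, `threshold`, `gain`, `auc`,
#'   `sensitivity`, `specificity`, sorted by AUC; the baseline row has
#'   variable `"(single-stage)"`.
#' @export
survey_macronutrients <- function(features, metadata, labels, candidates,
                                  seed = 1L, refit_split_in_fold = TRUE,
                                  positive = "PD", num_trees = 500) {
  base <- loocv_single(features, labels, seed = seed, positive = positive,
                       num_trees = num_trees)
  rows <- list(data.frame(variable = "(single-stage)", threshold = NA_real_,
                          gain = NA_real_, auc = base$auc,
                          sensitivity = base$sensitivity,
                          specificity = base$specificity,
                          stringsAsFactors = FALSE))
  for (v in candidates) {
    ts <- loocv_two_stage(features, metadata, labels, v, seed = seed,
                          refit_split_in_fold = refit_split_in_fold,
                          positive = positive, num_trees = num_trees)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, threshold = ts$stump$threshold, gain = ts$stump$gain,
      auc = ts$auc, sensitivity = ts$sensitivity,
      specificity = ts$specificity, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$auc), , drop = FALSE]
}
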