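# Permutation PERMANOVA on a distance matrix: pseudo-F from the
# Gower-centred inner-product matrix with hat-matrix projections, p-values
# by permuting sample labels, marginal (each term against all others) or
# sequential term tests, and an exhaustive-enumeration mode for small
# two-group designs.

# Gower-centred inner-product matrix of a distance matrix
.gower_center <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% a %*% J
}

# hat matrix for a model matrix (intercept included by caller)
.hat <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) attr(X, "deficient") <- TRUE
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# build per-term model matrices (no intercept columns) from a design frame
.term_matrices <- function(design, terms) {
  lapply(terms, function(tm) {
    v <- design[[tm]]
    if (is.null(v)) stop("design column not found: ", tm)
    if (anyNA(v)) stop("design column has missing values: ", tm)
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      if (nlevels(droplevels(v)) < 2) stop("factor with < 2 levels: ", tm)
      stats::model.matrix(~v)[, -1, drop = FALSE]
    } else matrix(as.numeric(v), ncol = 1)
  })
}

#' Permutation PERMANOVA
#'
#' Partitions the distance matrix's Gower-centred sum of squares by the
#' design terms and tests each term by permuting raw sample labels.
#' `marginal = TRUE` (default, the `by = "margin"` convention) tests every
#' term against the model containing all other terms; `marginal = FALSE`
#' gives sequential tests in the order of `terms`. The permutation p-value
#' is `(1 + #{F* >= F}) / (1 + n_permutations)`.
#'
#' @param d Symmetric distance matrix with sample IDs as dimnames.
#' @param design Data frame of covariates (rows aligned with `d`; if it has
#'   a `sample_id` column it is aligned by ID).
#' @param terms Character vector of design columns to test.
#' @param n_permutations Number of label permutations (default 9999).
#' @param marginal Test terms marginally (default) or sequentially.
#' @param seed Integer seed for the permutation stream (mandatory for
#'   reproducibility).
#' @return List of class `permanova_result` with per-term `F`, `R2`, `df`,
#'   `p`, plus residual/total df and `n_permutations`.
#' @export
permanova <- function(d, design, terms, n_permutations = 9999, marginal = TRUE,
                      seed) {
  if (missing(seed)) stop("seed is required")
  d <- as.matrix(d)
  n <- nrow(d)
  if ("sample_id" %in% names(design) && !is.null(rownames(d)))
    design <- design[match(rownames(d), design$sample_id), , drop = FALSE]
  if (nrow(design) != n) stop("design rows do not match distance matrix")
  G <- .gower_center(d)
  ss_total <- sum(diag(G))
  Xs <- .term_matrices(design, terms)
  X_full <- do.call(cbind, Xs)
  X_full1 <- cbind(1, X_full)
  if (qr(X_full1)$rank < ncol(X_full1))
    stop("confounded design (singular projection) for terms: ",
         paste(terms, collapse = ", "))
  df_terms <- vapply(Xs, ncol, integer(1))
  df_res <- n - 1L - sum(df_terms)
  if (df_res < 1) stop("no residual degrees of freedom")

  # hat matrices are permutation-invariant (we permute G, not the design)
  H_full <- .hat(X_full1)
  H_hi <- H_lo <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    ones <- rep(1, n)
    if (marginal) {
      H_lo[[k]] <- .hat(cbind(ones, do.call(cbind, Xs[-k])))
      H_hi[[k]] <- H_full
    } else {
      X_prev <- if (k > 1) do.call(cbind, Xs[seq_len(k - 1)]) else NULL
      H_lo[[k]] <- .hat(cbind(ones, X_prev))
      H_hi[[k]] <- .hat(cbind(ones, X_prev, Xs[[k]]))
    }
  }
  stat_fun <- function(Gp) {
    ss_res <- sum(diag(Gp)) - sum(H_full * Gp)  # tr((I-H)G)
    ss_term <- vapply(seq_along(terms), function(k)
      sum(H_hi[[k]] * Gp) - sum(H_lo[[k]] * Gp), numeric(1))
    Fv <- (ss_term / df_terms) / (ss_res / df_res)
    list(F = Fv, ss_term = ss_term, ss_res = ss_res)
  }

  obs <- stat_fun(G)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  exceed <- numeric(length(terms))
  eps <- sqrt(.Machine$double.eps)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    st <- stat_fun(G[perm, perm])
    exceed <- exceed + (st$F >= obs$F - eps)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(terms = terms, F = obs$F,
                 R2 = obs$ss_term / ss_total,
                 df = df_terms, df_residual = df_res,
                 ss = obs$ss_term, ss_residual = obs$ss_res,
                 ss_total = ss_total,
                 p = p, n_permutations = n_permutations,
                 marginal = marginal),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n",
              if (x$marginal) "marginal" else "sequential", x$n_permutations))
  print(data.frame(term = x$terms, df = x$df, F = round(x$F, 4),
                   R2 = round(x$R2, 4), p = x$p))
  invisible(x)
}

#' Exact two-group PERMANOVA by exhaustive enumeration
#'
#' Enumerates every distinct assignment of the group sizes to samples and
#' reports the exact permutation p-value: the fraction of assignments
#' (including the observed one) whose pseudo-F is at least the observed
#' pseudo-F. Feasible for small n only.
#'
#' @param d Symmetric distance matrix.
#' @param labels Two-level grouping vector aligned with `d`.
#' @return List with observed `F`, exact `p` and the number of assignments.
#' @export
permanova_exact <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  n1 <- sum(labels == levels(labels)[1])
  if (choose(n, n1) > 20000) stop("too many label splits to enumerate")
  G <- .gower_center(d)
  ss_tot <- sum(diag(G))
  # G is double-centred, so the intercept projection contributes nothing and
  # tr(HG) is the between-group sum of squares directly.
  f_of <- function(idx1) {
    x <- as.numeric(seq_len(n) %in% idx1)
    H <- .hat(cbind(1, x))
    ss_between <- sum(H * G)
    ss_res <- ss_tot - ss_between
    ss_between / (ss_res / (n - 2))
  }
  combs <- utils::combn(n, n1)
  obs_idx <- which(labels == levels(labels)[1])
  f_obs <- f_of(obs_idx)
  eps <- sqrt(.Machine$double.eps)
  fs <- apply(combs, 2, f_of)
  p <- mean(fs >= f_obs - eps)
  list(F = f_obs, p = p, n_assignments = ncol(combs))
}
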