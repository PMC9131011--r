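# ALDEx-style compositional differential abundance: Monte-Carlo Dirichlet
# instances of the count table, centred log-ratio transform (base 2, geometric
# mean over all features), per-instance Welch t-tests with BH adjustment,
# expected p-values over instances, effect sizes, signed fold changes, and
# volcano-style significance flags.

#' Monte-Carlo Dirichlet instances of a count table
#'
#' For each sample, draws `n_mc` realisations of its underlying composition
#' from Dirichlet(counts + prior); each realisation is a proportion vector
#' summing to one.
#'
#' @param table A [feature_table()].
#' @param n_mc Number of Monte-Carlo instances (default 128).
#' @param prior Per-cell Dirichlet prior (default 0.5).
#' @param seed Integer seed.
#' @return List of `n_mc` proportion matrices (features x samples).
#' @export
dirichlet_instances <- function(table, n_mc = 128, prior = 0.5, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (prior <= 0) stop("prior must be positive")
  m <- table$counts
  if (nrow(m) < 1 || ncol(m) < 2) stop("need >= 1 feature and >= 2 samples")
  alpha <- m + prior
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_mc), function(b) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
                nrow(m), ncol(m), dimnames = dimnames(m))
    sweep(g, 2, colSums(g), "/")
  })
}

#' Centred log-ratio transform (base 2)
#'
#' Per sample (column): log2 p_i minus the mean over all features of log2 p
#' (the "denom = all" geometric-mean centring). Columns of the result sum
#' to zero.
#'
#' @param instance Strictly positive proportion matrix, features x samples.
#' @return CLR matrix of the same shape.
#' @export
clr <- function(instance) {
  if (any(instance <= 0)) stop("CLR requires strictly positive proportions")
  lg <- log2(instance)
  sweep(lg, 2, colMeans(lg), "-")
}

# vectorised Welch t-test across rows of x between two column sets
.welch_rows <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  xa <- x[, idx_a, drop = FALSE]; xb <- x[, idx_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- (rowSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(xb^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 1
  list(t = t, p = p, delta = ma - mb,
       disp = sqrt((va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)))
}

#' Differential abundance test between two groups
#'
#' For every Monte-Carlo Dirichlet instance: CLR transform, per-feature
#' Welch t-test between the groups, BH adjustment across features. Reports
#' per feature the expected (mean over instances) raw and BH-adjusted
#' p-value, the median between-group CLR difference (`log2fc`), a signed
#' fold change `sign(log2fc) * 2^|log2fc|`, and an effect size
#' (median CLR difference / median pooled within-group dispersion).
#'
#' @param table A [feature_table()] at any rank.
#' @param metadata Data frame with `sample_id` and a binary `group` column
#'   covering every sample of `table`.
#' @param n_mc,prior,seed Passed to [dirichlet_instances()].
#' @param group_col Name of the binary group column (default `"group"`).
#' @param positive_level Level treated as the test group (default `"PD"`,
#'   falling back to the first level); log2fc is positive when that group is
#'   enriched.
#' @return Data frame of class `diff_abundance_result` with one row per
#'   feature: `feature`, `p`, `p_bh`, `effect`, `log2fc`, `fold_change`,
#'   `significant`.
#' @export
test_features <- function(table, metadata, n_mc = 128, prior = 0.5, seed = 1L,
                          group_col = "group", positive_level = "PD") {
  stopifnot(inherits(table, "feature_table"))
  meta <- metadata[match(colnames(table$counts), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing sample(s)")
  grp <- as.character(meta[[group_col]])
  lev <- unique(grp)
  if (length(lev) != 2) stop("group must be binary")
  pos <- if (positive_level %in% lev) positive_level else lev[1]
  idx_a <- which(grp == pos); idx_b <- which(grp != pos)
  if (length(idx_a) < 2 || length(idx_b) < 2)
    stop("each group needs >= 2 samples")

  inst <- dirichlet_instances(table, n_mc = n_mc, prior = prior, seed = seed)
  nf <- nrow(table$counts)
  p_sum <- pbh_sum <- numeric(nf)
  delta_mat <- disp_mat <- matrix(0, nf, n_mc)
  for (b in seq_along(inst)) {
    x <- clr(inst[[b]])
    w <- .welch_rows(x, idx_a, idx_b)
    pbh <- stats::p.adjust(w$p, method = "BH")
    p_sum <- p_sum + w$p
    pbh_sum <- pbh_sum + pbh
    delta_mat[, b] <- w$delta
    disp_mat[, b] <- w$disp
  }
  lfc <- apply(delta_mat, 1, stats::median)
  disp <- apply(disp_mat, 1, stats::median)
  res <- data.frame(
    feature = rownames(table$counts),
    p = p_sum / n_mc,
    p_bh = pbh_sum / n_mc,
    effect = lfc / pmax(disp, .Machine$double.eps),
    log2fc = lfc,
    fold_change = sign(lfc) * 2^abs(lfc),
    stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- flag_significant(res)
  attr(res, "positive_level") <- pos
  attr(res, "n_mc") <- n_mc
  class(res) <- c("diff_abundance_result", "data.frame")
  res
}

#' Volcano-style significance flags
#'
#' A feature is flagged when `-log10(p) > p_threshold_neglog` and
#' `|fold_change| > fc_threshold` (fold change here is the signed
#' `2^|median CLR difference|`).
#'
#' @param result A [test_features()] result (needs columns `p` or `p_bh`,
#'   and `fold_change`).
#' @param p_threshold_neglog Threshold on `-log(p)` (default 3).
#' @param fc_threshold Threshold on `|fold change|` (default 1.2).
#' @param log_base Base of the log used for the p threshold (default 10).
#' @param use_adjusted Flag on BH-adjusted rather than raw expected p.
#' @return Logical vector, one flag per feature.
#' @export
flag_significant <- function(result, p_threshold_neglog = 3,
                             fc_threshold = 1.2, log_base = 10,
                             use_adjusted = FALSE) {
  p <- if (use_adjusted) result$p_bh else result$p
  neglog <- -log(pmax(p, .Machine$double.xmin), base = log_base)
  neglog > p_threshold_neglog & abs(result$fold_change) > fc_threshold
}
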