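# Spearman association screens between clinical covariates and taxa
# abundances, with a rank-residual partial correlation adjusting for age,
# sex and BMI, and the weak/moderate/strong strength bands.

# Spearman rho with average ranks and the t-approximation p (n - 2 df).
.spearman_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) return(list(rho = NA_real_, p = NA_real_, n = n,
                         reason = "fewer than 4 complete pairs"))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "constant vector"))
  rho <- stats::cor(rank(x), rank(y))
  p <- .t_p_from_r(rho, df = n - 2)
  list(rho = rho, p = p, n = n, reason = NA_character_)
}

.t_p_from_r <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Spearman correlation screen
#'
#' Pairwise Spearman correlations (average ranks for ties, p from the
#' t-approximation with n - 2 df) between each covariate column of the
#' metadata and each taxon row of the abundance matrix. Pairs with missing
#' values are dropped pairwise and the n actually used is reported.
#' Character/logical covariates are encoded 0/1 when binary.
#'
#' @param taxa Relative-abundance (or CLR) matrix, taxa x samples, or a
#'   [feature_table()] (converted with [relative_abundance()]).
#' @param metadata Data frame with `sample_id` and covariate columns.
#' @param covariates Covariate column names to screen.
#' @param adjust_for Optional covariate names to partial out (e.g.
#'   `c("age", "sex", "bmi")`); when given, [partial_spearman()] is used.
#' @return Long data frame: `covariate`, `taxon`, `rho`, `p`, `n`,
#'   `partial`, `bin`, `borderline`, `reason`.
#' @export
spearman_screen <- function(taxa, metadata, covariates, adjust_for = NULL) {
  if (inherits(taxa, "feature_table")) taxa <- relative_abundance(taxa)
  meta <- metadata[match(colnames(taxa), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing sample(s)")
  enc <- function(v) {
    if (is.numeric(v)) return(v)
    u <- sort(unique(stats::na.omit(as.character(v))))
    if (length(u) != 2) stop("non-numeric covariate with != 2 levels")
    as.numeric(as.character(v) == u[2])
  }
  adj <- if (length(adjust_for))
    as.data.frame(lapply(meta[adjust_for], enc)) else NULL
  out <- list()
  for (cv in covariates) {
    x <- enc(meta[[cv]])
    for (tx in rownames(taxa)) {
      y <- taxa[tx, ]
      r <- if (is.null(adj)) .spearman_t(x, y)
           else partial_spearman(x, y, adj)
      out[[length(out) + 1]] <- data.frame(
        covariate = cv, taxon = tx, rho = r$rho, p = r$p, n = r$n,
        partial = !is.null(adj),
        bin = bin_strength(r$rho),
        borderline = !is.na(r$rho) &&
          min(abs(abs(r$rho) - c(0.2, 0.4, 0.6))) <= 0.002,
        reason = r$reason, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the numeric covariates, residualises the
#' ranked `x` and `y` on the ranked covariates by least squares (with
#' intercept), and reports the Pearson correlation of the residuals with a
#' t-approximation p on n - 2 - k df. With zero covariates this equals the
#' plain Spearman correlation exactly.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame (possibly zero-column) of numeric
#'   covariates, e.g. age, sex (0/1), BMI.
#' @return List with `rho`, `p`, `n`, `reason`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  covariates <- if (is.null(covariates) || NCOL(covariates) == 0)
    data.frame(row.names = seq_along(x)) else as.data.frame(covariates)
  k <- ncol(covariates)
  ok <- if (k > 0) stats::complete.cases(x, y, covariates)
        else stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < k + 4) return(list(rho = NA_real_, p = NA_real_, n = n,
                             reason = "too few complete cases"))
  x <- rank(x[ok]); y <- rank(y[ok])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, reason = "constant vector"))
  if (k > 0) {
    Z <- cbind(1, as.matrix(as.data.frame(lapply(covariates[ok, , drop = FALSE], rank))))
    if (qr(Z)$rank < ncol(Z)) stop("singular covariate matrix")
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n,
                reason = "degenerate residuals"))
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = .t_p_from_r(rho, df = n - 2 - k), n = n,
       reason = NA_character_)
}

#' Correlation strength band
#'
#' `|rho| < 0.2` none, `[0.2, 0.4)` weak, `[0.4, 0.6)` moderate, `>= 0.6`
#' strong — the bands used to summarise the association screen.
#'
#' @param rho Correlation in `[-1, 1]` (vectorised; NA passes through).
#' @return Character vector of bins.
#' @export
bin_strength <- function(rho) {
  a <- abs(rho)
  out <- rep(NA_character_, length(rho))
  out[!is.na(a) & a < 0.2] <- "none"
  out[!is.na(a) & a >= 0.2 & a < 0.4] <- "weak"
  out[!is.na(a) & a >= 0.4 & a < 0.6] <- "moderate"
  out[!is.na(a) & a >= 0.6] <- "strong"
  out
}
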