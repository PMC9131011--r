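# Recomputation of two-sample statistics from printed summary data: the
# pooled-variance t from (mean, SD, n) pairs, Pearson chi-squared from
# (percentage, n) pairs, and a Welch diagnostic for rows the pooled form
# does not reproduce.

#' Pooled-variance two-sample t from summary statistics
#'
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`;
#' `t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2))`, df = n1 + n2 - 2. The sign
#' convention is group 1 minus group 2.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List with `t` and `df`.
#' @export
pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2))
    stop("zero pooled variance with unequal means")
  }
  list(t = (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2)), df = n1 + n2 - 2)
}

#' Welch two-sample t from summary statistics
#'
#' Unequal-variance statistic with Satterthwaite df; used to annotate
#' summary rows where the pooled form does not reproduce the printed value.
#'
#' @inheritParams pooled_t
#' @return List with `t` and `df`.
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 == 0) stop("zero variance in both groups")
  df <- se2^2 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
  list(t = (m1 - m2) / sqrt(se2), df = df)
}

#' Pearson chi-squared from printed percentages
#'
#' Reconstructs 2x2 counts by nearest-integer rounding of `pct/100 * n` per
#' group and computes the Pearson chi-squared statistic without continuity
#' correction (df = 1).
#'
#' @param pct1,n1 Percentage with the attribute and group size, group 1.
#' @param pct2,n2 Same for group 2.
#' @return List with `chi2`, `df` and the reconstructed `counts` matrix.
#' @export
chi2_from_pct <- function(pct1, n1, pct2, n2) {
  stopifnot(pct1 >= 0, pct1 <= 100, pct2 >= 0, pct2 <= 100, n1 >= 2, n2 >= 2)
  a <- round(pct1 / 100 * n1); c2 <- round(pct2 / 100 * n2)
  m <- matrix(c(a, n1 - a, c2, n2 - c2), nrow = 2,
              dimnames = list(c("yes", "no"), c("group1", "group2")))
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts == 0)) stop("expected cell count of zero")
  list(chi2 = sum((m - exp_counts)^2 / exp_counts), df = 1L, counts = m)
}

#' Read a printed summary table
#'
#' TSV with columns `label`, `type` (`t` or `chi2`), the summary fields
#' (`m1,sd1,n1,m2,sd2,n2` for `t` rows; `pct1,n1,pct2,n2` for `chi2` rows)
#' and the printed statistic `printed`.
#'
#' @param path Path to the TSV (defaults to the bundled cohort table).
#' @return Data frame of summary rows.
#' @export
read_summary_table <- function(path = system.file("extdata", "cohort_table_printed.tsv",
                                                  package = "pdbiome")) {
  read_strict_tsv(path, na = "")
}

#' Recompute summary-table statistics
#'
#' For `t` rows computes the pooled t (and, where the pooled value misses
#' the printed one by more than `tol`, the Welch diagnostic); for `chi2`
#' rows reconstructs counts and computes the Pearson statistic. Rows whose
#' printed value is not reproduced within `tol` by either form are flagged
#' `not_reproduced`, never force-fit.
#'
#' @param rows Data frame from [read_summary_table()].
#' @param tol Agreement tolerance on the statistic (default 0.05, i.e. the
#'   printed one-decimal precision).
#' @return The input with added `computed`, `computed_df`, `welch`,
#'   `match` columns.
#' @export
recompute_summary_stats <- function(rows = read_summary_table(), tol = 0.05) {
  rows$computed <- NA_real_
  rows$computed_df <- NA_real_
  rows$welch <- NA_real_
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$type == "t") {
      pt_ <- pooled_t(r$m1, r$sd1, r$n1, r$m2, r$sd2, r$n2)
      rows$computed[i] <- pt_$t; rows$computed_df[i] <- pt_$df
      if (is.finite(r$printed) && abs(pt_$t - r$printed) > tol)
        rows$welch[i] <- welch_t(r$m1, r$sd1, r$n1, r$m2, r$sd2, r$n2)$t
    } else if (r$type == "chi2") {
      cs <- chi2_from_pct(r$pct1, r$n1, r$pct2, r$n2)
      rows$computed[i] <- cs$chi2; rows$computed_df[i] <- cs$df
    } else stop("unknown row type: ", r$type)
  }
  rows$match <- ifelse(
    abs(rows$computed - rows$printed) <= tol, "reproduced",
    ifelse(!is.na(rows$welch) & abs(rows$welch - rows$printed) <= tol,
           "welch_only", "not_reproduced"))
  rows
}
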