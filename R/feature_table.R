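# Feature tables: ASV/taxon count matrices (features x samples), their TSV
# readers/writers, the prevalence filter, rank aggregation and proportions.

#' Construct a feature table
#'
#' A feature table holds a non-negative integer count matrix with features
#' (ASVs or aggregated taxa) as rows and samples as columns, plus the
#' taxonomic rank the rows live at.
#'
#' @param counts Numeric matrix, features x samples, non-negative integers,
#'   with unique rownames (feature IDs) and colnames (sample IDs).
#' @param rank One of `"asv"`, `"genus"`, `"family"`, `"order"`, `"phylum"`.
#' @return An object of class `feature_table`: a list with elements `counts`
#'   and `rank`.
#' @export
feature_table <- function(counts, rank = "asv") {
  rank <- match.arg(rank, c("asv", "genus", "family", "order", "phylum"))
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts contain negative entries")
  if (any(counts != round(counts))) {
    bad <- rownames(counts)[rowSums(counts != round(counts)) > 0]
    stop("non-integer counts in feature(s): ", paste(bad, collapse = ", "))
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, rank = rank), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features (%s) x %d samples, total reads %s\n",
              nrow(x$counts), x$rank, ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Read an ASV/taxon count table from TSV
#'
#' Expects a tab-separated file with a header row; the first column
#' (`asv_id`) gives feature IDs and remaining columns are samples.
#' Malformed input (duplicate IDs, negative or non-integer counts, ragged
#' rows) is rejected with an error naming the offender, never coerced.
#'
#' @param path Path to the TSV file.
#' @param rank Rank of the rows (default `"asv"`).
#' @return A [feature_table()].
#' @export
read_counts <- function(path, rank = "asv") {
  df <- read_strict_tsv(path)
  if (ncol(df) < 2) stop("count table needs an ID column and >= 1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated feature IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
  if (anyNA(num)) {
    bad <- ids[rowSums(is.na(num)) > 0]
    stop("non-numeric counts in row(s): ", paste(bad, collapse = ", "))
  }
  rownames(num) <- ids
  feature_table(num, rank = rank)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_counts()]: first column `asv_id`, then one column per
#' sample. `write_counts(read_counts(x))` round-trips losslessly.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(asv_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy assignment table
#'
#' Tab-separated with columns `asv_id`, `phylum`, `order`, `family`, `genus`
#' (Silva-style labels; empty string = unassigned at that rank).
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `taxonomy_map`.
#' @export
read_taxonomy <- function(path) {
  df <- read_strict_tsv(path)
  need <- c("asv_id", "phylum", "order", "family", "genus")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$asv_id))
    stop("duplicated asv_id in taxonomy: ",
         paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "))
  df[is.na(df)] <- ""
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Write a taxonomy table to TSV
#' @param tax A taxonomy data frame (`asv_id`, `phylum`, `order`, `family`, `genus`).
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated with a `sample_id` column, a binary `group` column (PD/HC)
#' and arbitrary clinical/nutritional covariates. Empty cells are preserved
#' as missing values.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read_strict_tsv(path, na = "")
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("group" %in% names(df) && anyNA(df$group))
    stop("group label missing for sample(s): ",
         paste(df$sample_id[is.na(df$group)], collapse = ", "))
  df
}

#' Write sample metadata to TSV
#' @param meta Metadata data frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Strict TSV reader shared by the ingest functions: rejects ragged rows.
read_strict_tsv <- function(path, na = character(0)) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  # trailing empty fields are significant -> count separators instead
  nsep <- vapply(lines, function(l) sum(charToRaw(l) == charToRaw("\t")),
                 integer(1), USE.NAMES = FALSE)
  if (any(nsep != nsep[1]))
    stop("ragged row(s) in ", path, " at line(s): ",
         paste(which(nsep != nsep[1]), collapse = ", "))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicated column name(s) in ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", na.strings = na,
                    quote = "", comment.char = "") -> df
  # convert numeric-looking columns (all non-missing cells parse as numbers)
  for (j in seq_along(df)) {
    v <- df[[j]]
    ok <- !is.na(v)
    if (!any(ok)) next
    num <- suppressWarnings(as.numeric(v[ok]))
    if (!anyNA(num) && !all(v[ok] %in% c("TRUE", "FALSE"))) {
      out <- rep(NA_real_, length(v)); out[ok] <- num
      df[[j]] <- out
    }
  }
  df
}

#' Prevalence filter
#'
#' Keeps features detected (count >= 1) in at least `floor(fraction * n)`
#' samples, where `n` is the number of samples — with 184 samples and the
#' default 10% this is 18 samples, and ties at the threshold are kept.
#' Sample set and feature order are unchanged.
#'
#' @param table A [feature_table()].
#' @param fraction Minimum prevalence fraction in (0, 1]; default 0.10.
#' @return The filtered [feature_table()].
#' @export
filter_by_prevalence <- function(table, fraction = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (nrow(table$counts) == 0L || ncol(table$counts) == 0L)
    stop("empty feature table")
  threshold <- floor(fraction * ncol(table$counts))
  keep <- rowSums(table$counts >= 1) >= threshold
  feature_table(table$counts[keep, , drop = FALSE], rank = table$rank)
}

#' Aggregate ASV counts to a higher taxonomic rank
#'
#' Counts are summed over ASVs sharing the rank label; ASVs unassigned at
#' that rank are pooled into a reserved `__unassigned__` feature so that
#' per-sample totals are conserved exactly (diversity and CLR statistics
#' depend on them).
#'
#' @param table A [feature_table()] at ASV rank.
#' @param tax Taxonomy map covering every ASV in `table`.
#' @param rank Target rank: `"genus"`, `"family"`, `"order"` or `"phylum"`.
#' @return A [feature_table()] at the requested rank.
#' @export
aggregate_to_rank <- function(table, tax, rank) {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank, c("genus", "family", "order", "phylum"))
  if (table$rank != "asv") stop("aggregation starts from an ASV-rank table")
  ids <- rownames(table$counts)
  miss <- setdiff(ids, tax$asv_id)
  if (length(miss))
    stop("taxonomy missing ASV(s): ", paste(utils::head(miss, 5), collapse = ", "))
  lab <- tax[[rank]][match(ids, tax$asv_id)]
  lab[is.na(lab) | lab == ""] <- "__unassigned__"
  agg <- rowsum(table$counts, group = lab, reorder = FALSE)
  feature_table(agg, rank = rank)
}

#' Relative abundance matrix
#'
#' Divides each sample column by its total so columns sum to one.
#'
#' @param table A [feature_table()].
#' @return A numeric matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[tot == 0], collapse = ", "))
  sweep(table$counts, 2, tot, "/")
}
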