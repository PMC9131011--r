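# Community ecology: alpha diversity, beta-diversity distance matrices
# (Bray-Curtis via vegan, UniFrac by branch traversal), principal
# coordinates, and permutation PERMANOVA.

#' Shannon diversity (nats)
#'
#' H = -sum p_i log p_i over taxa with positive counts, natural log.
#'
#' @param x Non-negative count (or proportion) vector, at least one positive.
#' @return Shannon index in nats.
#' @export
shannon <- function(x) {
  p <- .check_alpha_input(x)
  -sum(p * log(p))
}

#' Simpson diversity
#'
#' The Gini-Simpson index 1 - sum p_i^2 by default; `inverse = TRUE` gives
#' the inverse Simpson index 1 / sum p_i^2.
#'
#' @param x Non-negative count vector, at least one positive.
#' @param inverse Report inverse Simpson instead of Gini-Simpson.
#' @return Simpson index.
#' @export
simpson <- function(x, inverse = FALSE) {
  p <- .check_alpha_input(x)
  D <- sum(p^2)
  if (inverse) 1 / D else 1 - D
}

#' Taxon richness
#'
#' Number of taxa with a positive count.
#'
#' @param x Non-negative count vector, at least one positive.
#' @return Integer richness.
#' @export
richness <- function(x) {
  .check_alpha_input(x)
  sum(x > 0)
}

.check_alpha_input <- function(x) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative and complete")
  if (sum(x) == 0) stop("all-zero sample")
  p <- x / sum(x)
  p[p > 0]
}

#' Alpha diversity table for every sample
#'
#' @param table A [feature_table()].
#' @return Data frame with columns `sample_id`, `shannon`, `simpson`,
#'   `richness`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$counts
  data.frame(sample_id = colnames(m),
             shannon = apply(m, 2, shannon),
             simpson = apply(m, 2, simpson),
             richness = apply(m, 2, richness),
             row.names = NULL)
}

.as_distance_matrix <- function(m, sample_ids) {
  dimnames(m) <- list(sample_ids, sample_ids)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(u, v) = 1 - 2 sum min(u_i, v_i) / (sum u + sum v), computed on raw
#' counts by default (the vegan convention); set `proportions = TRUE` to
#' compute on per-sample relative abundances.
#'
#' @param table A [feature_table()].
#' @param proportions Normalise samples to proportions first.
#' @return Symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal.
#' @export
bray_curtis <- function(table, proportions = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  m <- table$counts
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ", paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  x <- t(m)
  if (proportions) x <- x / rowSums(x)
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  .as_distance_matrix(d, colnames(m))
}

# Per-edge descendant abundance: matrix (edges x samples) of the proportion
# of each sample's reads descending each edge, plus edge lengths.
.edge_profiles <- function(table, tree) {
  m <- table$counts
  miss <- setdiff(rownames(m), tree$tip.label)
  if (length(miss))
    stop("feature(s) absent from tree: ", paste(utils::head(miss, 5), collapse = ", "))
  prop <- sweep(m, 2, colSums(m), "/")
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  node_val <- matrix(0, n_node, ncol(m))
  idx <- match(tr$tip.label, rownames(prop))
  has <- !is.na(idx)
  node_val[seq_len(n_tip)[has], ] <- prop[idx[has], , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
    node_val[par, ] <- node_val[par, ] + node_val[chi, ]
  }
  list(profile = node_val[tr$edge[, 2], , drop = FALSE],
       lengths = tr$edge.length, sample_ids = colnames(m))
}

#' UniFrac distance matrix
#'
#' Unweighted UniFrac is the branch length unique to one of the two samples
#' divided by the branch length leading to taxa present in either. Weighted
#' UniFrac accumulates abundance-weighted branch differences
#' sum b_e |A_e - B_e| and, when `normalized` (default), divides by
#' sum b_e (A_e + B_e).
#'
#' @param table A [feature_table()] whose features are tips of `tree`.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param weighted Weighted (abundance) variant instead of presence/absence.
#' @param normalized Normalise the weighted variant into `[0, 1]`.
#' @return Symmetric sample-by-sample distance matrix.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(inherits(table, "feature_table"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(colSums(table$counts) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[colSums(table$counts) == 0], collapse = ", "))
  ep <- .edge_profiles(table, tree)
  A <- ep$profile; b <- ep$lengths
  if (sum(b) <= 0) stop("zero total branch length")
  ns <- ncol(A)
  d <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    ai <- A[, i]; aj <- A[, j]
    if (weighted) {
      num <- sum(b * abs(ai - aj))
      d[i, j] <- if (normalized) num / sum(b * (ai + aj)) else num
    } else {
      pi <- ai > 0; pj <- aj > 0
      denom <- sum(b[pi | pj])
      if (denom == 0) stop("zero branch length union for samples ",
                           ep$sample_ids[i], ", ", ep$sample_ids[j])
      d[i, j] <- sum(b[xor(pi, pj)]) / denom
    }
  }
  .as_distance_matrix(d + t(d), ep$sample_ids)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of the double-centred squared-distance matrix.
#' Negative eigenvalues are reported as-is (no Lingoes correction);
#' `proportion_explained` is computed over the positive eigenvalues only.
#'
#' @param d Symmetric distance matrix with sample IDs as dimnames.
#' @param n_axes Number of axes to return (default `n - 1`).
#' @return List with `coordinates` (samples x axes), `eigenvalues` and
#'   `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(n_axes)) n_axes <- n - 1L
  if (n_axes > n - 1L) stop("n_axes must be <= n_samples - 1")
  # cmdscale warns when the distance is non-Euclidean (negative eigenvalues);
  # that case is expected here and the eigenvalues are reported as-is
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L,
                                         eig = TRUE))
  eig <- sc$eig
  pos <- eig[eig > sqrt(.Machine$double.eps)]
  prop <- ifelse(eig > 0, eig / sum(pos), 0)
  coords <- sc$points
  # cmdscale may return fewer columns than k when eigenvalues vanish
  if (ncol(coords) < n_axes)
    coords <- cbind(coords, matrix(0, n, n_axes - ncol(coords)))
  coords <- coords[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = prop[seq_len(min(n_axes, length(prop)))])
}
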