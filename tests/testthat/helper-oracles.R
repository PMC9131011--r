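# Independent one-way oracle: the direct sums-of-squared-distances
# decomposition SS_total = (1/n) sum_{i<j} d2, SS_within summed per group,
# avoiding the Gower/hat-matrix route used by the implementation.
oneway_f_oracle <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  a <- length(unique(labels))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

exhaustive_p_oracle <- function(d, labels) {
  n <- length(labels)
  lev <- unique(labels)
  n1 <- sum(labels == lev[1])
  f_obs <- oneway_f_oracle(d, labels)
  combs <- utils::combn(n, n1)
  fs <- apply(combs, 2, function(idx) {
    lab <- rep(lev[2], n); lab[idx] <- lev[1]
    oneway_f_oracle(d, lab)
  })
  mean(fs >= f_obs - sqrt(.Machine$double.eps))
}

make_two_clouds <- function(n1, n2, sep, seed) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 2), n1), matrix(rnorm(n2 * 2, mean = sep), n2))
  rownames(x) <- sprintf("S%02d", seq_len(n1 + n2))
  d <- as.matrix(dist(x))
  list(d = d, labels = rep(c("A", "B"), c(n1, n2)),
       design = data.frame(sample_id = rownames(x),
                           group = rep(c("A", "B"), c(n1, n2))))
}
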