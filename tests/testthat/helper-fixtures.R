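# Small deterministic fixtures shared across test files.

# tiny feature table built by hand
toy_table <- function() {
  m <- matrix(c(5, 0, 3, 2,
                0, 0, 1, 0,
                4, 4, 4, 4,
                1, 2, 3, 4,
                0, 7, 0, 0), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("ASV_", 1:5), paste0("S", 1:4)))
  feature_table(m)
}

toy_taxonomy <- function() {
  data.frame(asv_id = paste0("ASV_", 1:5),
             phylum = c("P1", "P1", "P1", "P2", "P2"),
             order  = c("O1", "O1", "O2", "O3", "O3"),
             family = c("F1", "F1", "F2", "F3", "F3"),
             genus  = c("g1", "g1", "g2", "g3", ""),
             stringsAsFactors = FALSE)
}

# small cohort cached per session so several test files can share it
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(
        n_group_a = 25, n_group_b = 25, n_asv = 60, n_differential = 5,
        effect_log2 = 2, seed = 42))
    cache
  }
})
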