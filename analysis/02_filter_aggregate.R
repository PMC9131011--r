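#!/usr/bin/env Rscript
# Prevalence-filter the ASV table (detected in >= 10% of samples, i.e. 18 of
# 184) and aggregate the survivors to the four taxonomic ranks used by all
# downstream comparisons.

suppressPackageStartupMessages(library(pdbiome))

counts <- read_counts("results/cohort/counts.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")

filtered <- filter_by_prevalence(counts, 0.10)
cat(sprintf("prevalence filter: %d of %d ASVs kept (threshold %d samples)\n",
            nrow(filtered$counts), nrow(counts$counts),
            floor(0.10 * ncol(counts$counts))))
write_counts(filtered, "results/asv_filtered.tsv")

for (rank in c("genus", "family", "order", "phylum")) {
  agg <- aggregate_to_rank(filtered, tax, rank)
  write_counts(agg, sprintf("results/table_%s.tsv", rank))
  cat(sprintf("  %s: %d taxa\n", rank, nrow(agg$counts)))
}
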