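#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 103 PD / 81 HC samples, 627 ASVs with
# log-normal baselines and Dirichlet-multinomial counts, taxonomy, a rooted
# phylogeny and nutritional metadata. Writes the four input tables that every
# later analysis step consumes.

suppressPackageStartupMessages(library(pdbiome))
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = 20260928L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat(sprintf("cohort: %d ASVs x %d samples (%d PD / %d HC), mean depth %.0f\n",
            nrow(cohort$counts$counts), ncol(cohort$counts$counts),
            sum(cohort$metadata$group == "PD"),
            sum(cohort$metadata$group == "HC"),
            mean(colSums(cohort$counts$counts))))
cat("written to results/cohort/{counts,taxonomy,metadata}.tsv, tree.nwk\n")
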