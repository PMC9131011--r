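#!/usr/bin/env Rscript
# Spearman association screen between clinical/nutritional covariates and
# genus-level relative abundances, with partial correlations adjusting for
# age, sex and BMI, binned into the weak/moderate/strong bands.

suppressPackageStartupMessages(library(pdbiome))

genus <- read_counts("results/table_genus.tsv", rank = "genus")
meta <- read_metadata("results/cohort/metadata.tsv")
covs <- c("age", "bmi", "protein_g", "fat_g", "sugar_g", "fiber_g",
          "carbohydrate_g", "pct_carbohydrate")

plain <- spearman_screen(genus, meta, covs)
adj <- spearman_screen(genus, meta, covs, adjust_for = c("age", "sex", "bmi"))
out <- rbind(plain, adj)
write.table(out, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- adj[!is.na(adj$p) & adj$p < 0.05, ]
cat(sprintf("partial screen: %d/%d pairs at p < 0.05; bins: %s\n",
            nrow(sig), nrow(adj),
            paste(names(table(sig$bin)), table(sig$bin), collapse = ", ",
                  sep = "=")))
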