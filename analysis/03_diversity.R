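#!/usr/bin/env Rscript
# Alpha diversity (Shannon, Gini-Simpson, richness), beta diversity
# (Bray-Curtis + weighted/unweighted UniFrac), PCoA ordination, and the
# PERMANOVA test of the PD/HC contrast (marginal terms, 9,999 permutations).

suppressPackageStartupMessages(library(pdbiome))

genus <- read_counts("results/table_genus.tsv", rank = "genus")
asv <- read_counts("results/asv_filtered.tsv")
meta <- read_metadata("results/cohort/metadata.tsv")
tree <- ape::read.tree("results/cohort/tree.nwk")

ad <- alpha_diversity(genus)
write.table(merge(ad, meta[, c("sample_id", "group")]), "results/alpha.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
wt <- wilcox.test(shannon ~ group, data = merge(ad, meta))
cat(sprintf("alpha: mean Shannon %.3f; PD vs HC Wilcoxon p = %.3g\n",
            mean(ad$shannon), wt$p.value))

bc <- bray_curtis(genus)
ufu <- unifrac(asv, tree, weighted = FALSE)
ufw <- unifrac(asv, tree, weighted = TRUE)
for (nm in c("bc", "ufu", "ufw")) {
  d <- get(nm)
  write.table(data.frame(sample_id = rownames(d), d, check.names = FALSE),
              sprintf("results/beta_%s.tsv", nm), sep = "\t", quote = FALSE,
              row.names = FALSE)
}

pc <- pcoa(bc, n_axes = 2)
write.table(data.frame(sample_id = rownames(pc$coordinates), pc$coordinates),
            "results/pcoa_bc.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA (Bray-Curtis): axes explain %.1f%% and %.1f%%\n",
            100 * pc$proportion_explained[1], 100 * pc$proportion_explained[2]))

res <- lapply(list(bc = bc, ufu = ufu, ufw = ufw), function(d)
  permanova(d, meta, "group", n_permutations = 9999, marginal = TRUE,
            seed = 20260928L))
tab <- data.frame(metric = names(res),
                  F = sapply(res, function(r) r$F),
                  R2 = sapply(res, function(r) r$R2),
                  p = sapply(res, function(r) r$p))
write.table(tab, "results/permanova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
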