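#!/usr/bin/env Rscript
# Sample clustering: PCA of the LD-pruned neutral marker set, with and
# without the outgroup (mirroring the two published clustering analyses).
suppressMessages(library(macawpop))
suppressMessages(library(ggplot2))

fix <- "results/fixtures/macaw_like"
vt <- read_vcf(paste0(fix, ".vcf.gz"))
pops <- read_pop_map(paste0(fix, ".pops.tsv"))

run_pca <- function(drop, tag) {
  res <- run_recipe(vt, "neutral_markers", drop_samples = drop)
  pca <- pca_genotypes(res$dosage, 2)
  df <- data.frame(sample = rownames(pca$scores), pca$scores,
                   population = pops$population[match(rownames(pca$scores),
                                                      pops$sample)])
  cat(sprintf("\n== PCA (%s): %d pruned markers ==\n", tag, pca$n_sites))
  cat(sprintf("PC1 %.2f%%, PC2 %.2f%% of variance\n",
              100 * pca$var_frac[1], 100 * pca$var_frac[2]))
  print(df, row.names = FALSE)
  write.table(df, sprintf("results/pca_%s.tsv", tag), sep = "\t",
              quote = FALSE, row.names = FALSE)
  p <- ggplot(df, aes(PC1, PC2, colour = population)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.2f%%)", 100 * pca$var_frac[1]),
         y = sprintf("PC2 (%.2f%%)", 100 * pca$var_frac[2])) +
    theme_minimal()
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  ggsave(sprintf("results/figures/pca_%s.pdf", tag), p, width = 5, height = 4)
}

run_pca(NULL, "all_samples")
run_pca(c("out_1", "out_2"), "ingroup_only")
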