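#!/usr/bin/env Rscript
# Population structure from the filtered SNP genotype matrix: variance-
# standardized PCA and a neighbor-joining tree on allele-sharing distances
# with bootstrap supports (variants resampled with replacement).

source("analysis/00_config.R")

d <- load_filtered()
pops <- pops_of()
out <- file.path(RESULTS, "structure")

M <- t(d$snps$geno)
pca <- genotype_pca(M, k = 2)
write_tsv(data.frame(sample = rownames(M), pop = pops[rownames(M)],
                     pca$coordinates),
          file.path(out, "pca.tsv"))
dir.create(out, showWarnings = FALSE, recursive = TRUE)
writeLines(format(pca$eigenvalues, digits = 10),
           file.path(out, "eigenval.txt"))
message(sprintf("PC1 explains %.1f%%, PC2 %.1f%% of kinship variance",
                100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))

tree <- bootstrap_tree(M, n_reps = 200L, seed = ANALYSIS_SEED + 2L)
write_newick(tree, file.path(out, "tree.nwk"))
message("wrote ", file.path(out, "tree.nwk"))

## which population pair clusters together?
for (p in unique(pops)) {
  tips <- names(pops)[pops == p]
  mono <- ape::is.monophyletic(tree, tips)
  message(sprintf("population %s monophyletic in NJ tree: %s", p, mono))
}
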