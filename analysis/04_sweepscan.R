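#!/usr/bin/env Rscript
# Windowed selective-sweep scan: theta-pi per population and pairwise Hudson
# Fst in 100 kb windows sliding by 10 kb, selection of windows with
# Fst > 0.25 and pi ratio > 2 or < 0.5, merging into maximal regions, gene
# assignment by interval overlap, and the Venn partition of the selected
# gene sets across the three comparisons. Recovery of the injected sweeps
# is reported against truth.json.

source("analysis/00_config.R")

d <- load_filtered()
ann <- load_annotation(d$paths[["gff3"]], d$paths[["fasta"]])
pops <- pops_of()
out <- file.path(RESULTS, "sweeps")
cfg <- sweep_config()

chrom_lengths <- setNames(Biostrings::width(ann$seq), names(ann$seq))
stats <- sweep_scan(d$snps, pops, chrom_lengths, cfg)
write_tsv(stats, file.path(out, "windows.tsv"))

truth <- jsonlite::read_json(file.path(simdata_dir, "truth.json"),
                             simplifyVector = TRUE)
gene_sets <- list()
all_regions <- list()
for (key in unique(paste(stats$pop_a, stats$pop_b, sep = "_vs_"))) {
  sub <- stats[paste(stats$pop_a, stats$pop_b, sep = "_vs_") == key, ]
  reg <- call_selected_regions(sub, cfg)
  gene_sets[[key]] <- intersect_genes(reg, ann)$genes
  message(sprintf("%s: %d selected region(s), %d gene(s)", key, nrow(reg),
                  length(gene_sets[[key]])))
  if (nrow(reg)) {
    for (r in seq_len(nrow(reg))) {
      hit <- truth$true_sweeps$chrom == reg$chrom[r] &
        truth$true_sweeps$start < reg$end[r] &
        truth$true_sweeps$end > reg$start[r] &
        truth$true_sweeps$pop == reg$direction[r]
      message(sprintf("  %s:%d-%d toward %s (%d windows)%s", reg$chrom[r],
                      reg$start[r], reg$end[r], reg$direction[r],
                      reg$n_windows[r],
                      if (any(hit)) " -- matches an injected sweep" else ""))
    }
    all_regions[[key]] <- cbind(comparison = key, reg)
  }
}
write_tsv(do.call(rbind, all_regions), file.path(out, "regions.bed"))
write_tsv(data.frame(comparison = rep(names(gene_sets), lengths(gene_sets)),
                     gene = unlist(gene_sets, use.names = FALSE)),
          file.path(out, "region_genes.tsv"))
vc <- venn_counts(gene_sets)
write_tsv(vc, file.path(out, "venn_counts.tsv"))
message(sprintf("deduplicated selected genes: %d",
                length(unique(unlist(gene_sets)))))
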