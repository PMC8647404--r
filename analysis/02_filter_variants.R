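#!/usr/bin/env Rscript
# Hard-filter the call set with the standard thresholds (SNP-near-InDel 5 bp,
# adjacent InDels 10 bp, clusters of >2 in 5 bp, QUAL >= 30, QD >= 2,
# MQ >= 40, FS <= 60) and produce the SNP/InDel summary statistics:
# Ti/Tv, Het-ratio, insertion/deletion balance and length spectra.

source("analysis/00_config.R")

d <- load_filtered()
out <- file.path(RESULTS, "variants")

message(sprintf("filtering removed %d of %d records:", nrow(d$removals),
                nrow(d$removals) + nrow(d$all$sites)))
print(table(d$removals$reason))
write_tsv(d$removals, file.path(out, "removals.tsv"))

ss <- summarize_snps(d$snps)
message(sprintf("SNPs: %d Ti / %d Tv, Ti/Tv = %.2f; het ratio = %.2f%%",
                ss$n_transitions, ss$n_transversions, ss$ti_tv, ss$het_ratio))
write_tsv(data.frame(metric = c("n_transitions", "n_transversions", "ti_tv",
                                "n_het", "n_hom", "het_ratio"),
                     value = c(ss$n_transitions, ss$n_transversions, ss$ti_tv,
                               ss$n_het, ss$n_hom, ss$het_ratio)),
          file.path(out, "snp_summary.tsv"))

ann <- load_annotation(d$paths[["gff3"]], d$paths[["fasta"]])
ig <- summarize_indels(d$indels, scope = "genome")
ic <- summarize_indels(d$indels, ann, scope = "CDS")
message(sprintf("InDels: %d genome-wide (%d ins / %d del), %d overlapping CDS",
                ig$total, ig$n_insertions, ig$n_deletions, ic$total))
write_tsv(data.frame(scope = c("genome", "CDS"),
                     n_insertions = c(ig$n_insertions, ic$n_insertions),
                     n_deletions = c(ig$n_deletions, ic$n_deletions),
                     n_hom = c(ig$n_hom, ic$n_hom),
                     n_het = c(ig$n_het, ic$n_het)),
          file.path(out, "indel_summary.tsv"))
spec <- as.data.frame(ig$length_spectrum)
names(spec) <- c("signed_length", "count")
write_tsv(spec, file.path(out, "indel_length_spectrum.tsv"))
write_tsv(per_chromosome_counts(d$all), file.path(out, "per_chromosome.tsv"))
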