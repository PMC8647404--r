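#!/usr/bin/env Rscript
# Assign every passing variant a genomic region (intergenic, flank, intron,
# splice site, CDS ...) and, inside CDS, a coding effect (synonymous /
# non-synonymous / stop gain or loss / frameshift / codon indels), then
# tabulate the SNP and InDel annotation tables.

source("analysis/00_config.R")

d <- load_filtered()
ann <- load_annotation(d$paths[["gff3"]], d$paths[["fasta"]])
out <- file.path(RESULTS, "annotation")

calls <- annotate_variants(d$all, ann)
write_tsv(calls, file.path(out, "effects.tsv"))

snp_tab <- effect_table(calls[calls$class == "SNP", ])
indel_tab <- effect_table(calls[calls$class == "InDel", ])
write_tsv(snp_tab, file.path(out, "effect_table_snp.tsv"))
write_tsv(indel_tab, file.path(out, "effect_table_indel.tsv"))

message("SNP annotation (non-zero rows):")
print(snp_tab[snp_tab$count > 0, ], row.names = FALSE)
message("InDel annotation (non-zero rows):")
print(indel_tab[indel_tab$count > 0, ], row.names = FALSE)
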