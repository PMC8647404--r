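#!/usr/bin/env Rscript
# Simulate the three-population dataset: Balding-Nichols drift around a
# shared ancestral frequency pool (AP and SP close, LP diverged), SNPs and
# short InDels with per-site QUAL/QD/MQ/FS metrics, a toy annotated genome
# with valid ORFs, and two injected sweeps (one in AP, one in LP) whose
# coordinates are recorded in truth.json for later recovery checks.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
ds <- simulate_populations(cfg)
paths <- write_dataset(ds, simdata_dir)

message(sprintf("chromosome: %d bp, %d genes planted",
                cfg$chrom_length, sum(ds$features$type == "gene")))
message(sprintf("variants: %d (%d SNP, %d InDel) across %d samples",
                nrow(ds$sites), sum(ds$sites$class == "SNP"),
                sum(ds$sites$class == "InDel"), length(ds$samples)))
message(sprintf("injected sweeps: %s",
                paste(sprintf("%s:%d-%d (%s)", ds$true_sweeps$chrom,
                              ds$true_sweeps$start, ds$true_sweeps$end,
                              ds$true_sweeps$pop), collapse = ", ")))
message("files: ", paste(basename(paths), collapse = ", "))
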