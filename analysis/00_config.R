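# Shared configuration for the analysis scripts: one 500 kb chromosome,
# three populations of 10 diploids (AP and SP close, LP diverged), two
# injected sweeps, and the qPCR design used in 06_expression.R.

library(popsweep)

ANALYSIS_SEED <- 7L
RESULTS <- "results"

analysis_sim_config <- function(seed = ANALYSIS_SEED) {
  sim_config(
    n_chromosomes = 1L,
    chrom_length = 500000L,
    samples_per_pop = 10L,
    drift_F = c(AP = 0.02, LP = 0.25, SP = 0.03),
    snp_density = 0.002,
    indel_fraction = 0.37,
    n_genes = 15L,
    sweep_intervals = data.frame(
      chrom = c("chr1", "chr1"),
      start = c(200000L, 60000L),
      end = c(300000L, 120000L),
      pop = c("AP", "LP")),
    seed = seed)
}

simdata_dir <- file.path(RESULTS, "simdata")

ensure_simdata <- function() {
  vcf <- file.path(simdata_dir, "variants.vcf")
  if (!file.exists(vcf)) {
    message("simulated dataset not found; generating it first")
    write_dataset(simulate_populations(analysis_sim_config()), simdata_dir)
  }
  c(vcf = vcf,
    fasta = file.path(simdata_dir, "ref.fa"),
    gff3 = file.path(simdata_dir, "genes.gff3"),
    truth = file.path(simdata_dir, "truth.json"))
}

load_filtered <- function() {
  paths <- ensure_simdata()
  vs <- read_vcf(paths[["vcf"]])
  filt <- apply_hard_filters(vs)
  keep <- filt$passing$sites$class == "SNP"
  list(all = filt$passing,
       snps = popsweep:::.new_variant_set(
         filt$passing$sites[keep, , drop = FALSE],
         filt$passing$geno[keep, , drop = FALSE],
         filt$passing$samples),
       indels = popsweep:::.new_variant_set(
         filt$passing$sites[!keep, , drop = FALSE],
         filt$passing$geno[!keep, , drop = FALSE],
         filt$passing$samples),
       removals = filt$removals,
       paths = paths)
}

pops_of <- function() {
  truth <- jsonlite::read_json(file.path(simdata_dir, "truth.json"))
  unlist(truth$pops)
}

write_tsv <- function(d, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
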