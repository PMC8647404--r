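#' Simulation settings for a multi-population resequencing dataset
#'
#' Defines the stated world of the simulator: three diploid populations
#' (two genetically close, one diverged) drifted from a common ancestral
#' allele-frequency pool under the Balding-Nichols model, genotyped at
#' SNP and short-InDel sites along one or more chromosomes carrying a toy
#' set of protein-coding genes with valid ORFs.
#'
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chrom_length length of each chromosome in bp.
#' @param samples_per_pop diploid individuals per population (cohorts of 10
#'   per population are typical for this design).
#' @param drift_F per-population Balding-Nichols drift parameter, each in
#'   (0, 1); the expected pairwise Fst between two populations is close to
#'   the mean of their F values. The default `c(0.02, 0.25, 0.03)` gives two
#'   close populations (AP, SP) and one diverged population (LP).
#' @param pop_names population labels, one per entry of `drift_F`.
#' @param snp_density expected variant sites per bp.
#' @param indel_fraction fraction of variant sites that are InDels rather
#'   than SNPs (genome-wide InDel/variant ratios near 0.37 are typical for
#'   fish resequencing call sets).
#' @param ti_prob probability that a SNP is a transition; the default 0.56
#'   gives Ti/Tv near 1.27, the level reported for fish resequencing call
#'   sets (a uniform alternate choice would give 0.5).
#' @param sweep_intervals optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `pop`: regions where the named population
#'   is pushed toward fixation, emulating a selective sweep.
#' @param n_genes protein-coding genes to plant per chromosome.
#' @param metric_fail_rate fraction of sites whose QUAL/QD/MQ/FS metrics are
#'   drawn from the failing side of the hard-filter thresholds (independently
#'   per metric), so filtering has both classes to act on.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; together with the configuration it fully
#'   determines the dataset.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 500000L,
                       samples_per_pop = 10L,
                       drift_F = c(AP = 0.02, LP = 0.25, SP = 0.03),
                       pop_names = NULL,
                       snp_density = 0.002,
                       indel_fraction = 0.37,
                       ti_prob = 0.56,
                       sweep_intervals = NULL,
                       n_genes = 15L,
                       metric_fail_rate = 0.05,
                       missing_rate = 0.01,
                       seed = 1L) {
  if (is.null(pop_names)) {
    pop_names <- names(drift_F)
    if (is.null(pop_names)) pop_names <- paste0("pop", seq_along(drift_F))
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_pops = length(drift_F),
    samples_per_pop = as.integer(samples_per_pop),
    drift_F = stats::setNames(as.numeric(drift_F), pop_names),
    pop_names = pop_names,
    snp_density = snp_density,
    indel_fraction = indel_fraction,
    ti_prob = ti_prob,
    sweep_intervals = sweep_intervals,
    n_genes = as.integer(n_genes),
    metric_fail_rate = metric_fail_rate,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_chromosomes < 1L || cfg$chrom_length < 1L)
    stop("configuration error: chromosome number and length must be positive")
  if (any(cfg$drift_F <= 0) || any(cfg$drift_F >= 1))
    stop("configuration error: every drift_F must lie strictly in (0, 1)")
  if (cfg$samples_per_pop < 1L || cfg$n_pops < 1L)
    stop("configuration error: need at least one sample and one population")
  if (cfg$snp_density <= 0 || cfg$indel_fraction < 0 || cfg$indel_fraction > 1 ||
      cfg$ti_prob <= 0 || cfg$ti_prob >= 1)
    stop("configuration error: invalid variant density settings")
  if (!is.null(cfg$sweep_intervals)) {
    sw <- cfg$sweep_intervals
    stopifnot(all(c("chrom", "start", "end", "pop") %in% names(sw)))
    if (any(sw$start < 0) || any(sw$end > cfg$chrom_length) ||
        any(sw$start > sw$end))
      stop("configuration error: sweep intervals must lie within chromosome bounds")
    if (!all(sw$pop %in% pop_names))
      stop("configuration error: unknown sweep target population")
  }
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

## random ORF: ATG + n_codons sense codons + stop; returns character string
.rand_orf <- function(n_codons) {
  codons <- apply(matrix(sample(.BASES, 3L * n_codons, replace = TRUE), nrow = 3L),
                  2L, paste, collapse = "")
  bad <- codons %in% .STOPS
  while (any(bad)) {  # resample internal stops
    codons[bad] <- apply(matrix(sample(.BASES, 3L * sum(bad), replace = TRUE),
                                nrow = 3L), 2L, paste, collapse = "")
    bad <- codons %in% .STOPS
  }
  paste0("ATG", paste(codons, collapse = ""), sample(.STOPS, 1L))
}

## Plant non-overlapping multi-exon genes into a chromosome sequence.
## Returns list(seq = modified char string, features = GFF-shaped data.frame).
.plant_genes <- function(chrom, seq, n_genes) {
  len <- nchar(seq)
  feats <- list()
  if (n_genes < 1L) return(list(seq = seq, features = NULL))
  ## one slot per gene so genes spread over the whole chromosome
  slot <- (len - 12000L) %/% n_genes
  for (i in seq_len(n_genes)) {
    n_exons <- sample(1:4, 1L)
    orf_len <- 3L * (sample(50:200, 1L) + 2L)
    if (n_exons == 1L) {
      exon_len <- orf_len
    } else {
      repeat {
        cuts <- sort(sample(seq(21L, orf_len - 21L), n_exons - 1L))
        exon_len <- diff(c(0L, cuts, orf_len))
        if (all(exon_len >= 21L)) break
      }
    }
    intron_len <- if (n_exons > 1L) sample(60:400, n_exons - 1L, replace = TRUE) else integer(0)
    span <- sum(exon_len) + sum(intron_len)
    slot_start <- 6001L + (i - 1L) * slot
    if (span + 200L > slot) next
    cursor <- slot_start + sample.int(slot - span - 100L, 1L)
    strand <- sample(c("+", "-"), 1L)
    orf <- .rand_orf((orf_len - 6L) %/% 3L)
    genomic_seq <- if (strand == "+") orf else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
    ## genomic exon intervals left to right
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- cursor
    off <- 0L
    for (e in seq_len(n_exons)) {
      starts[e] <- pos
      ends[e] <- pos + exon_len[e] - 1L
      substr(seq, starts[e], ends[e]) <- substr(genomic_seq, off + 1L, off + exon_len[e])
      off <- off + exon_len[e]
      pos <- ends[e] + 1L + if (e < n_exons) intron_len[e] else 0L
    }
    ## CDS phase in transcript order (left->right for +, right->left for -)
    tx_order <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
    phase <- integer(n_exons)
    cum <- 0L
    for (e in tx_order) {
      phase[e] <- (3L - (cum %% 3L)) %% 3L
      cum <- cum + exon_len[e]
    }
    gid <- sprintf("gene_%s_%03d", chrom, i)
    tid <- sprintf("tx_%s_%03d", chrom, i)
    feats[[length(feats) + 1L]] <- rbind(
      data.frame(chrom = chrom, type = "gene", start = cursor, end = cursor + span - 1L,
                 strand = strand, phase = NA_integer_, ID = gid, Parent = NA_character_),
      data.frame(chrom = chrom, type = "mRNA", start = cursor, end = cursor + span - 1L,
                 strand = strand, phase = NA_integer_, ID = tid, Parent = gid),
      data.frame(chrom = chrom, type = "exon", start = starts, end = ends,
                 strand = strand, phase = NA_integer_,
                 ID = sprintf("%s.exon%d", tid, seq_len(n_exons)), Parent = tid),
      data.frame(chrom = chrom, type = "CDS", start = starts, end = ends,
                 strand = strand, phase = phase,
                 ID = sprintf("%s.cds", tid), Parent = tid)
    )
  }
  list(seq = seq, features = do.call(rbind, feats))
}

#' Simulate a multi-population variant dataset under Balding-Nichols drift
#'
#' Ancestral alternate-allele frequencies are drawn per site from
#' Uniform(0.05, 0.95); each population's frequency is drawn from the
#' Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F) distribution, and diploid
#' genotypes are Binomial(2, p_pop) under Hardy-Weinberg equilibrium.
#' Sweep intervals listed in the configuration are injected afterwards via
#' [inject_sweep()]. Per-site QUAL/QD/MQ/FS filter metrics are drawn from
#' their passing ranges, with a configurable fraction of violating sites.
#'
#' @param config a [sim_config()] object.
#' @return a `sim_dataset`: list with elements `sites` (data.frame: chrom,
#'   pos, ref, alt, class, qual, qd, mq, fs), `geno` (sites x samples dosage
#'   matrix in 0/1/2 with NA for missing), `samples`, `pops` (sample ->
#'   population), `true_freqs` (sites x populations), `true_sweeps`,
#'   `ref` (DNAStringSet), `features` (gene models), `config`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pops <- config$n_pops
  spp <- config$samples_per_pop
  n_samples <- n_pops * spp
  pops <- rep(config$pop_names, each = spp)
  samples <- sprintf("%s_%02d", pops, rep(seq_len(spp), times = n_pops))
  names(pops) <- samples

  ref <- character(config$n_chromosomes)
  feats <- list()
  sites <- list()
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  for (ci in seq_len(config$n_chromosomes)) {
    seq <- .rand_dna(config$chrom_length)
    planted <- .plant_genes(chroms[ci], seq, config$n_genes)
    seq <- planted$seq
    ref[ci] <- seq
    feats[[ci]] <- planted$features
    n_sites <- stats::rpois(1L, config$snp_density * config$chrom_length)
    pos <- sort(sample(seq(10L, config$chrom_length - 20L), n_sites))
    is_indel <- stats::runif(n_sites) < config$indel_fraction
    ref_al <- substring(seq, pos, pos)
    alt_al <- character(n_sites)
    transition_of <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in seq_len(n_sites)) {
      if (!is_indel[i]) {
        alt_al[i] <- if (stats::runif(1) < config$ti_prob)
          transition_of[[ref_al[i]]] else
          sample(setdiff(.BASES, c(ref_al[i], transition_of[[ref_al[i]]])), 1L)
      } else {
        l <- sample(1:10, 1L, prob = stats::dgeom(0:9, 0.5))
        if (stats::runif(1) < 0.5) {  # insertion
          alt_al[i] <- paste0(ref_al[i], .rand_dna(l))
        } else {                      # deletion
          ref_al[i] <- substring(seq, pos[i], pos[i] + l)
          alt_al[i] <- substring(seq, pos[i], pos[i])
        }
      }
    }
    sites[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                              ref = ref_al, alt = alt_al,
                              class = ifelse(is_indel, "InDel", "SNP"))
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL
  n_sites <- nrow(sites)

  ## filter metrics: passing ranges with a violating fraction per metric
  fr <- config$metric_fail_rate
  draw <- function(n, pass_lo, pass_hi, fail_lo, fail_hi) {
    bad <- stats::runif(n) < fr
    ifelse(bad, stats::runif(n, fail_lo, fail_hi), stats::runif(n, pass_lo, pass_hi))
  }
  sites$qual <- round(draw(n_sites, 30, 1500, 2, 30), 2)
  sites$qd   <- round(draw(n_sites, 2, 35, 0, 2), 2)
  sites$mq   <- round(draw(n_sites, 40, 60, 20, 40), 2)
  sites$fs   <- round(draw(n_sites, 0, 60, 60, 180), 3)

  ## Balding-Nichols population frequencies and HWE genotypes
  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  true_freqs <- matrix(NA_real_, n_sites, n_pops,
                       dimnames = list(NULL, config$pop_names))
  geno <- matrix(NA_integer_, n_sites, n_samples,
                 dimnames = list(NULL, samples))
  for (k in seq_len(n_pops)) {
    f <- config$drift_F[k]
    pk <- stats::rbeta(n_sites, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    true_freqs[, k] <- pk
    cols <- (k - 1L) * spp + seq_len(spp)
    geno[, cols] <- matrix(stats::rbinom(n_sites * spp, 2L, pk), nrow = n_sites)
  }
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }

  ds <- structure(list(
    config = config, sites = sites, geno = geno, samples = samples,
    pops = pops, true_freqs = true_freqs,
    true_sweeps = data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), pop = character(0)),
    ref = stats::setNames(ref, chroms), features = do.call(rbind, feats),
    seed = config$seed), class = "sim_dataset")

  if (!is.null(config$sweep_intervals)) {
    sw <- config$sweep_intervals
    for (i in seq_len(nrow(sw))) {
      ds <- inject_sweep(ds, sw$chrom[i], sw$start[i], sw$end[i], sw$pop[i])
    }
  }
  ds
}

#' Inject a selective sweep into a simulated dataset
#'
#' Inside the interval, the target population's minor-allele frequencies are
#' resampled from Beta(0.02 K, 0.98 K) with K = 50 and mapped onto the major
#' allele, so the population is pushed toward fixation: heterozygosity drops
#' and differentiation from the other populations rises, which is the signal
#' a windowed Fst / pi-ratio scan is designed to detect. Genotypes of the
#' target population are re-drawn under HWE at the new frequencies; other
#' populations are untouched.
#'
#' @param dataset a `sim_dataset`.
#' @param chrom,start,end sweep interval, 0-based half-open on `chrom`.
#' @param target_pop population label to sweep.
#' @param strength Beta concentration K (larger = closer to fixation).
#' @return the modified `sim_dataset`, with the interval appended to
#'   `true_sweeps`. An empty interval (start == end) returns the dataset
#'   unchanged.
#' @export
inject_sweep <- function(dataset, chrom, start, end, target_pop, strength = 50) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!target_pop %in% dataset$config$pop_names)
    stop("unknown population label: ", target_pop)
  if (start == end) return(dataset)
  if (start < 0 || end > dataset$config$chrom_length || start > end)
    stop("sweep interval out of chromosome bounds")
  idx <- which(dataset$sites$chrom == chrom &
               dataset$sites$pos >= start + 1L & dataset$sites$pos <= end)
  cols <- which(dataset$pops == target_pop)
  if (length(idx)) {
    p_old <- dataset$true_freqs[idx, target_pop]
    d <- stats::rbeta(length(idx), 0.02 * strength, 0.98 * strength)
    p_new <- ifelse(p_old >= 0.5, 1 - d, d)
    dataset$true_freqs[idx, target_pop] <- p_new
    miss <- is.na(dataset$geno[idx, cols, drop = FALSE])
    g <- matrix(stats::rbinom(length(idx) * length(cols), 2L, p_new),
                nrow = length(idx))
    g[miss] <- NA_integer_
    dataset$geno[idx, cols] <- g
  }
  dataset$true_sweeps <- rbind(
    dataset$true_sweeps,
    data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
               pop = target_pop))
  dataset
}

.dosage_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Write a simulated dataset to standard files
#'
#' Emits a multi-sample VCF v4.2 (GT format field; INFO QD/MQ/FS; site QUAL),
#' the reference FASTA, GFF3 gene models (every CDS starts with ATG, ends
#' with a stop codon and has length divisible by 3), and a `truth.json`
#' holding the ground-truth sweep intervals, per-population allele
#' frequencies and sample-to-population map. The VCF round-trips losslessly
#' through [read_vcf()].
#'
#' @param dataset a `sim_dataset`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths (vcf, fasta, gff3, truth).
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "variants.vcf"),
             fasta = file.path(out_dir, "ref.fa"),
             gff3 = file.path(out_dir, "genes.gff3"),
             truth = file.path(out_dir, "truth.json"))

  dna <- Biostrings::DNAStringSet(dataset$ref)
  Biostrings::writeXStringSet(dna, paths["fasta"])

  f <- dataset$features
  if (is.null(f)) {
    writeLines("##gff-version 3", paths["gff3"])
  } else {
    gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                                 strand = f$strand)
    S4Vectors::mcols(gr)$source <- "popsweep"
    S4Vectors::mcols(gr)$type <- f$type
    S4Vectors::mcols(gr)$phase <- f$phase
    S4Vectors::mcols(gr)$ID <- f$ID
    S4Vectors::mcols(gr)$Parent <- ifelse(is.na(f$Parent), "", f$Parent)
    rtracklayer::export(gr, paths["gff3"], format = "gff3")
  }

  con <- file(paths["vcf"], "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(dataset$ref),
            dataset$config$chrom_length),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled strand-bias Fisher p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")), con)
  s <- dataset$sites
  gt <- apply(dataset$geno, 1L, function(g) paste(.dosage_to_gt(g), collapse = "\t"))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\tQD=%.2f;MQ=%.2f;FS=%.3f\tGT\t%s",
                     s$chrom, s$pos, s$ref, s$alt, s$qual, s$qd, s$mq, s$fs, gt),
             con)

  jsonlite::write_json(list(
    seed = dataset$seed,
    pops = as.list(dataset$pops),
    true_sweeps = dataset$true_sweeps,
    sites = dataset$sites[, c("chrom", "pos", "ref", "alt", "class")],
    true_freqs = dataset$true_freqs,
    n_missing_genotypes = sum(is.na(dataset$geno))
  ), paths["truth"], auto_unbox = TRUE, digits = 10)

  paths
}

#' Simulate a qPCR Ct table with known group effects
#'
#' Ct values follow the exponential-amplification model
#' `Ct = baseline - log2(relative expression) + noise`, with three
#' housekeeping genes whose expectation is group-independent and technical
#' triplicates per (sample, gene). Recovering `effect_sizes` through
#' [ddct()] validates the whole 2^-ddCt chain.
#'
#' @param groups character vector of group labels (>= 2); the first is the
#'   natural calibrator.
#' @param effect_sizes numeric matrix of true relative expression,
#'   target genes in rows (rownames = gene ids), groups in columns.
#' @param seed integer seed.
#' @param housekeeping ids of the (>= 3) reference genes.
#' @param n_biological biological replicates (individuals) per group.
#' @param n_technical technical replicates per (sample, gene).
#' @param noise_sd Gaussian Ct noise standard deviation (cycles); 0 makes
#'   recovery exact.
#' @return long-format data.frame: sample, group, gene, rep, ct.
#' @export
simulate_qpcr <- function(groups, effect_sizes, seed = 1L,
                          housekeeping = c("actb", "rn18s", "gapdh"),
                          n_biological = 5L, n_technical = 3L,
                          noise_sd = 0.15) {
  if (length(housekeeping) < 3L)
    stop("at least 3 housekeeping genes are required")
  if (length(groups) < 2L) stop("need at least 2 groups")
  stopifnot(is.matrix(effect_sizes), !is.null(rownames(effect_sizes)))
  if (is.null(colnames(effect_sizes))) colnames(effect_sizes) <- groups
  stopifnot(all(groups %in% colnames(effect_sizes)))
  set.seed(seed)
  genes <- c(rownames(effect_sizes), housekeeping)
  baseline <- stats::setNames(stats::runif(length(genes), 20, 26), genes)
  rows <- list()
  for (g in groups) {
    for (b in seq_len(n_biological)) {
      sample_id <- sprintf("%s_%d", g, b)
      for (gene in genes) {
        rel <- if (gene %in% housekeeping) 1 else effect_sizes[gene, g]
        mu <- baseline[gene] - log2(rel)
        ct <- mu + stats::rnorm(n_technical, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, group = g, gene = gene,
          rep = seq_len(n_technical), ct = ct)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
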