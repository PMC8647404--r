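#' Hard-filter thresholds for SNP/InDel call sets
#'
#' Mirrors the GATK-style hard-filtering recipe used for resequencing call
#' sets: proximity of SNPs to InDels, InDel-InDel adjacency, variant
#' clusters, and the QUAL/QD/MQ/FS site metrics.
#'
#' @param snp_near_indel_bp remove a SNP within this many bp of an InDel.
#' @param adjacent_indel_bp remove an InDel within this many bp of another.
#' @param cluster_size,cluster_window_bp remove all members of any window of
#'   `cluster_window_bp` bp containing more than `cluster_size` variants.
#' @param min_qual minimum Phred site quality (QUAL).
#' @param min_qd minimum quality-by-depth (QD).
#' @param min_mq minimum RMS mapping quality (MQ).
#' @param max_fs maximum Phred-scaled strand-bias Fisher p (FS).
#' @return a `filter_config` object.
#' @export
filter_config <- function(snp_near_indel_bp = 5L, adjacent_indel_bp = 10L,
                          cluster_size = 2L, cluster_window_bp = 5L,
                          min_qual = 30, min_qd = 2.0, min_mq = 40,
                          max_fs = 60.0) {
  cfg <- list(snp_near_indel_bp = as.integer(snp_near_indel_bp),
              adjacent_indel_bp = as.integer(adjacent_indel_bp),
              cluster_size = as.integer(cluster_size),
              cluster_window_bp = as.integer(cluster_window_bp),
              min_qual = min_qual, min_qd = min_qd, min_mq = min_mq,
              max_fs = max_fs)
  if (any(unlist(cfg) <= 0)) stop("all filter thresholds must be positive")
  class(cfg) <- "filter_config"
  cfg
}

.variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel")
}

.new_variant_set <- function(sites, geno, samples) {
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites (%d SNP, %d InDel), %d samples\n",
              nrow(x$sites), sum(x$sites$class == "SNP"),
              sum(x$sites$class == "InDel"), length(x$samples)))
  invisible(x)
}

#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.x with GT genotypes through `VariantAnnotation`, splits
#' multi-allelic sites into one biallelic record per alternate allele (the
#' dosage of each split record counts only that allele; other alternate
#' alleles at the site count as reference), and preserves missing genotypes
#' as `NA`. Site metrics QD/MQ/FS are taken from INFO when present and
#' reported as `NA` otherwise.
#'
#' @param path VCF file path.
#' @return a `variant_set`: list with `sites` (data.frame: chrom, pos, ref,
#'   alt, qual, qd, mq, fs, class), `geno` (sites x samples dosage matrix),
#'   and `samples`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- tryCatch(VariantAnnotation::readVcf(path),
                  error = function(e) stop("VCF parse error in ", path, ": ",
                                           conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)  # DNAStringSetList
  n_alt <- S4Vectors::elementNROWS(alts)
  qual <- VariantAnnotation::qual(vcf)
  info <- VariantAnnotation::info(vcf)
  metric <- function(name) {
    if (name %in% colnames(info)) as.numeric(info[[name]]) else
      rep(NA_real_, length(rr))
  }
  qd <- metric("QD"); mq <- metric("MQ"); fs <- metric("FS")
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)

  ## expand multi-allelic sites: one row per (site, alt allele)
  site_idx <- rep(seq_along(n_alt), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt_chr <- unlist(lapply(alts, as.character), use.names = FALSE)
  sites <- data.frame(chrom = chrom[site_idx], pos = pos[site_idx],
                      ref = ref[site_idx], alt = alt_chr,
                      qual = qual[site_idx], qd = qd[site_idx],
                      mq = mq[site_idx], fs = fs[site_idx])
  sites$class <- .variant_class(sites$ref, sites$alt)

  ## dosage of allele k from GT strings like "0/1", "1|2", "./."
  al1 <- sub("[/|].*", "", gt)
  al2 <- sub(".*[/|]", "", gt)
  uncalled <- al1 == "." | al2 == "."
  geno <- matrix(NA_integer_, nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  for (k in unique(alt_idx)) {
    d <- (al1 == as.character(k)) + (al2 == as.character(k))
    d[uncalled] <- NA_integer_
    rows <- which(alt_idx == k)
    geno[rows, ] <- d[site_idx[rows], , drop = FALSE]
  }
  .new_variant_set(sites, geno, samples)
}

#' Classify a single-base substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) substitutions are
#' transitions; all purine-pyrimidine pairs are transversions.
#'
#' @param ref,alt single bases in A/C/G/T (vectorized).
#' @return character vector of "transition" / "transversion".
#' @export
classify_substitution <- function(ref, alt) {
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES) || any(ref == alt))
    stop("classify_substitution expects single-base SNP alleles")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(ref) == purine(alt), "transition", "transversion")
}

## cluster rule: mark every variant belonging to any `window_bp` span holding
## more than `max_in_window` variants (i.e. any run of max_in_window + 1
## consecutive sorted positions spanning <= window_bp - 1)
.cluster_members <- function(pos, max_in_window, window_bp) {
  n <- length(pos)
  k <- max_in_window + 1L
  bad <- logical(n)
  if (n >= k) {
    o <- order(pos)
    ps <- pos[o]
    for (i in seq_len(n - k + 1L)) {
      if (ps[i + k - 1L] - ps[i] <= window_bp - 1L) bad[o[i:(i + k - 1L)]] <- TRUE
    }
  }
  bad
}

#' Apply hard filters to a variant set
#'
#' Removal reasons are evaluated independently on the full input and applied
#' in a fixed order, each removed record reporting the first reason that
#' fires: (1) SNP near an InDel / InDel near another InDel; (2) variant
#' cluster; (3) low QUAL; (4) low QD; (5) low MQ; (6) high FS. A record
#' whose metric is absent skips that metric's rule (logged). Input must be
#' sorted by (chrom, pos); original order is preserved and
#' passing + removed = input.
#'
#' @param vs a `variant_set`.
#' @param config a [filter_config()].
#' @return list with `passing` (a `variant_set`), `removals` (data.frame:
#'   chrom, pos, ref, alt, reason) and `log` (character notes).
#' @export
apply_hard_filters <- function(vs, config = filter_config()) {
  stopifnot(inherits(vs, "variant_set"), inherits(config, "filter_config"))
  s <- vs$sites
  n <- nrow(s)
  ord <- order(match(s$chrom, unique(s$chrom)), s$pos)
  if (!identical(ord, seq_len(n)))
    stop("apply_hard_filters requires input sorted by (chrom, pos)")
  reason <- rep(NA_character_, n)
  log <- character(0)

  for (ch in unique(s$chrom)) {
    i <- which(s$chrom == ch)
    snp <- i[s$class[i] == "SNP"]
    ind <- i[s$class[i] == "InDel"]
    ## (1) proximity rules
    if (length(ind)) {
      if (length(snp)) {
        near <- vapply(s$pos[snp], function(p)
          any(abs(s$pos[ind] - p) <= config$snp_near_indel_bp), logical(1))
        reason[snp[near]] <- "snp_near_indel"
      }
      if (length(ind) > 1L) {
        near <- vapply(seq_along(ind), function(j)
          any(abs(s$pos[ind[-j]] - s$pos[ind[j]]) <= config$adjacent_indel_bp),
          logical(1))
        reason[ind[near]] <- "adjacent_indel"
      }
    }
    ## (2) cluster rule over all variants on the chromosome
    bad <- .cluster_members(s$pos[i], config$cluster_size,
                            config$cluster_window_bp)
    hit <- i[bad]
    reason[hit[is.na(reason[hit])]] <- "cluster"
  }
  ## (3)-(6) site metrics; absent metric skips its rule
  rule <- function(vals, fails, tag) {
    skipped <- is.na(vals)
    if (any(skipped))
      log <<- c(log, sprintf("%s rule skipped for %d record(s) with absent metric",
                             tag, sum(skipped)))
    hit <- which(!skipped & fails & is.na(reason))
    reason[hit] <<- tag
  }
  rule(s$qual, s$qual < config$min_qual, "low_qual")
  rule(s$qd, s$qd < config$min_qd, "low_qd")
  rule(s$mq, s$mq < config$min_mq, "low_mq")
  rule(s$fs, s$fs > config$max_fs, "high_fs")

  keep <- is.na(reason)
  removals <- data.frame(chrom = s$chrom[!keep], pos = s$pos[!keep],
                         ref = s$ref[!keep], alt = s$alt[!keep],
                         reason = reason[!keep])
  list(passing = .new_variant_set(s[keep, , drop = FALSE],
                                  vs$geno[keep, , drop = FALSE], vs$samples),
       removals = removals, log = log)
}

.trunc2 <- function(x) floor(x * 100) / 100

#' SNP summary from pre-tabulated counts
#'
#' Builds the transition/transversion and zygosity summary directly from
#' counts. Both ratios are truncated (not rounded) to two decimals, the
#' convention under which published count pairs and their printed ratios are
#' mutually consistent. `ti_tv` is `NA` when there are no transversions.
#'
#' @param n_transitions,n_transversions,n_het,n_hom non-negative counts.
#' @return a `snp_summary` list: counts plus `ti_tv` and `het_ratio`
#'   (percentage of heterozygous among all SNP genotype calls).
#' @export
snp_summary_counts <- function(n_transitions, n_transversions, n_het, n_hom) {
  stopifnot(n_transitions >= 0, n_transversions >= 0, n_het >= 0, n_hom >= 0)
  structure(list(
    n_transitions = n_transitions, n_transversions = n_transversions,
    ti_tv = if (n_transversions > 0) .trunc2(n_transitions / n_transversions)
            else NA_real_,
    n_het = n_het, n_hom = n_hom,
    het_ratio = if (n_het + n_hom > 0) .trunc2(100 * n_het / (n_het + n_hom))
                else NA_real_), class = "snp_summary")
}

#' Summarize SNPs: Ti/Tv and zygosity
#'
#' Transitions and transversions are counted over sites; zygosity is counted
#' over per-sample genotype calls carrying the alternate allele (dosage 1 =
#' heterozygous, dosage 2 = homozygous; reference-homozygous and missing
#' calls do not constitute a SNP call for that sample).
#'
#' @param vs a `variant_set` containing only SNP records.
#' @param per_sample if TRUE, return a per-sample data.frame of zygosity
#'   counts and Het-ratio instead of the pooled summary.
#' @return a `snp_summary` (see [snp_summary_counts()]) or a data.frame.
#' @export
summarize_snps <- function(vs, per_sample = FALSE) {
  stopifnot(inherits(vs, "variant_set"))
  if (any(vs$sites$class != "SNP"))
    stop("summarize_snps expects SNP records only; filter InDels first")
  cls <- classify_substitution(vs$sites$ref, vs$sites$alt)
  het_by_sample <- colSums(vs$geno == 1L, na.rm = TRUE)
  hom_by_sample <- colSums(vs$geno == 2L, na.rm = TRUE)
  if (per_sample) {
    return(data.frame(sample = vs$samples, n_het = het_by_sample,
                      n_hom = hom_by_sample,
                      het_ratio = .trunc2(100 * het_by_sample /
                                          (het_by_sample + hom_by_sample)),
                      row.names = NULL))
  }
  snp_summary_counts(sum(cls == "transition"), sum(cls == "transversion"),
                     sum(het_by_sample), sum(hom_by_sample))
}

#' InDel summary from pre-tabulated counts
#'
#' @param n_insertions,n_deletions,n_hom,n_het non-negative counts.
#' @param scope "genome" or "CDS".
#' @return an `indel_summary` list with the total added.
#' @export
indel_summary_counts <- function(n_insertions, n_deletions, n_hom, n_het,
                                 scope = "genome") {
  structure(list(n_insertions = n_insertions, n_deletions = n_deletions,
                 total = n_insertions + n_deletions,
                 n_hom = n_hom, n_het = n_het, scope = scope),
            class = "indel_summary")
}

#' Summarize InDels: direction, zygosity and length spectrum
#'
#' Insertion/deletion is decided by the sign of `nchar(alt) - nchar(ref)`;
#' the spectrum is keyed by that signed length. With `scope = "CDS"` only
#' InDels whose reference footprint overlaps an annotated CDS interval are
#' kept.
#'
#' @param vs a `variant_set` containing only InDel records.
#' @param annotation a `genome_annotation` (required for CDS scope).
#' @param scope "genome" or "CDS".
#' @return an `indel_summary` with a `length_spectrum` table (signed length
#'   -> count).
#' @export
summarize_indels <- function(vs, annotation = NULL,
                             scope = c("genome", "CDS")) {
  scope <- match.arg(scope)
  stopifnot(inherits(vs, "variant_set"))
  if (any(vs$sites$class != "InDel"))
    stop("summarize_indels expects InDel records only")
  s <- vs$sites
  geno <- vs$geno
  if (scope == "CDS") {
    if (is.null(annotation)) stop("CDS scope requires an annotation")
    gr <- GenomicRanges::GRanges(s$chrom,
      IRanges::IRanges(s$pos, s$pos + nchar(s$ref) - 1L))
    keep <- IRanges::overlapsAny(gr, annotation$cds)
    s <- s[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  signed_len <- nchar(s$alt) - nchar(s$ref)
  out <- indel_summary_counts(sum(signed_len > 0), sum(signed_len < 0),
                              sum(colSums(geno == 2L, na.rm = TRUE)),
                              sum(colSums(geno == 1L, na.rm = TRUE)),
                              scope)
  out$length_spectrum <- table(signed_len)
  out
}

#' Per-chromosome SNP and InDel counts
#'
#' @param vs a `variant_set`.
#' @return data.frame: chrom, n_snp, n_indel. Counts partition the input.
#' @export
per_chromosome_counts <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  s <- vs$sites
  if (nrow(s) == 0L)
    return(data.frame(chrom = character(0), n_snp = integer(0),
                      n_indel = integer(0)))
  chroms <- unique(s$chrom)
  data.frame(chrom = chroms,
             n_snp = vapply(chroms, function(ch)
               sum(s$chrom == ch & s$class == "SNP"), integer(1)),
             n_indel = vapply(chroms, function(ch)
               sum(s$chrom == ch & s$class == "InDel"), integer(1)),
             row.names = NULL)
}
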