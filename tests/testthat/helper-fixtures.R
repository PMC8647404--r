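# Shared fixture builders and independent oracles. Oracles deliberately use
# brute-force enumeration / full re-translation so they do not share code
# paths with the package implementation they check.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
SAFE_CODONS <- c("GCT", "GGA", "TGG", "CTG", "AAA", "TTC", "GAT", "CGT")

make_variant_set <- function(sites, geno = NULL, samples = NULL) {
  if (is.null(geno)) {
    samples <- c("s1", "s2")
    geno <- matrix(1L, nrow(sites), 2L, dimnames = list(NULL, samples))
  }
  if (is.null(samples)) samples <- colnames(geno)
  popsweep:::.new_variant_set(sites, geno, samples)
}

rand_sites <- function(n, chrom = "chr1", max_pos = 100000L,
                       indel_frac = 0.3) {
  pos <- sort(sample.int(max_pos, n))
  is_indel <- runif(n) < indel_frac
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (!is_indel[i]) sample(setdiff(BASES, ref[i]), 1)
    else paste0(ref[i], paste(sample(BASES, sample(1:4, 1), TRUE), collapse = ""))
  }, character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             class = ifelse(is_indel, "InDel", "SNP"),
             qual = runif(n, 30, 1000), qd = runif(n, 2, 35),
             mq = runif(n, 40, 60), fs = runif(n, 0, 60))
}

# ---- independent hard-filter oracle: each rule checked by brute force ----
oracle_hard_filters <- function(sites, cfg) {
  n <- nrow(sites)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    same <- sites$chrom == sites$chrom[i]
    if (sites$class[i] == "SNP") {
      ind <- which(same & sites$class == "InDel")
      if (any(abs(sites$pos[ind] - sites$pos[i]) <= cfg$snp_near_indel_bp))
        reason[i] <- "snp_near_indel"
    } else {
      oth <- setdiff(which(same & sites$class == "InDel"), i)
      if (any(abs(sites$pos[oth] - sites$pos[i]) <= cfg$adjacent_indel_bp))
        reason[i] <- "adjacent_indel"
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(reason[i])) next
    p <- sites$pos[i]
    same <- sites$chrom == sites$chrom[i]
    for (w in (p - cfg$cluster_window_bp + 1L):p) {
      inw <- sum(same & sites$pos >= w & sites$pos <= w + cfg$cluster_window_bp - 1L)
      if (inw > cfg$cluster_size) { reason[i] <- "cluster"; break }
    }
  }
  metric_rules <- list(
    list("qual", function(x) x < cfg$min_qual, "low_qual"),
    list("qd", function(x) x < cfg$min_qd, "low_qd"),
    list("mq", function(x) x < cfg$min_mq, "low_mq"),
    list("fs", function(x) x > cfg$max_fs, "high_fs"))
  for (r in metric_rules) {
    v <- sites[[r[[1]]]]
    hit <- which(is.na(reason) & !is.na(v) & r[[2]](v))
    reason[hit] <- r[[3]]
  }
  reason
}

# ---- O(n^2) pairwise-difference pi oracle ----
oracle_pi <- function(g, window_bp) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  total <- 0
  for (s in seq_len(nrow(g))) {
    alleles <- unlist(lapply(g[s, ], function(x)
      if (is.na(x)) NULL else c(rep(1L, x), rep(0L, 2L - x))))
    n <- length(alleles)
    if (n < 2L) next
    diffs <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      diffs <- diffs + (alleles[i] != alleles[j])
    total <- total + diffs / choose(n, 2L)
  }
  total / window_bp
}

# ---- toy annotated genome built base by base, plus a per-variant oracle ----
# Three genes on a 10 kb chromosome "t1" (flank 500 bp so intergenic space
# exists): gene A (+, 2 exons, padded gene span => INTRAGENIC zones),
# gene B (-, single exon), gene C (+, 3 exons with a small middle exon).
make_orf <- function(n_codons, stop = "TAA") {
  paste0("ATG", paste(sample(SAFE_CODONS, n_codons, TRUE), collapse = ""), stop)
}

toy_genome <- function(seed = 42) {
  set.seed(seed)
  L <- 10000L
  seq <- paste(sample(BASES, L, TRUE), collapse = "")
  put <- function(s, at, piece) {
    substr(s, at, at + nchar(piece) - 1L) <- piece
    s
  }
  # gene A: + strand, exons [2001,2150] + [2251,2460], gene span padded
  orfA <- make_orf((360L - 6L) / 3L)
  seq <- put(seq, 2001L, substr(orfA, 1L, 150L))
  seq <- put(seq, 2251L, substr(orfA, 151L, 360L))
  # gene B: - strand, single exon [5001,5300]
  orfB <- make_orf((300L - 6L) / 3L, stop = "TGA")
  seq <- put(seq, 5001L, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(orfB))))
  # gene C: + strand, exons [7001,7100], [7201,7230], [7301,7500]
  orfC <- make_orf((330L - 6L) / 3L)
  seq <- put(seq, 7001L, substr(orfC, 1L, 100L))
  seq <- put(seq, 7201L, substr(orfC, 101L, 130L))
  seq <- put(seq, 7301L, substr(orfC, 131L, 330L))
  feat <- function(type, start, end, strand, phase, id, parent)
    data.frame(chrom = "t1", type = type, start = start, end = end,
               strand = strand, phase = phase, ID = id, Parent = parent)
  features <- rbind(
    feat("gene", 1951L, 2510L, "+", NA, "gA", NA),
    feat("mRNA", 2001L, 2460L, "+", NA, "tA", "gA"),
    feat("exon", 2001L, 2150L, "+", NA, "tA.e1", "tA"),
    feat("exon", 2251L, 2460L, "+", NA, "tA.e2", "tA"),
    feat("CDS", 2001L, 2150L, "+", 0L, "tA.c", "tA"),
    feat("CDS", 2251L, 2460L, "+", 0L, "tA.c", "tA"),
    feat("gene", 5001L, 5300L, "-", NA, "gB", NA),
    feat("mRNA", 5001L, 5300L, "-", NA, "tB", "gB"),
    feat("exon", 5001L, 5300L, "-", NA, "tB.e1", "tB"),
    feat("CDS", 5001L, 5300L, "-", 0L, "tB.c", "tB"),
    feat("gene", 7001L, 7500L, "+", NA, "gC", NA),
    feat("mRNA", 7001L, 7500L, "+", NA, "tC", "gC"),
    feat("exon", 7001L, 7100L, "+", NA, "tC.e1", "tC"),
    feat("exon", 7201L, 7230L, "+", NA, "tC.e2", "tC"),
    feat("exon", 7301L, 7500L, "+", NA, "tC.e3", "tC"),
    feat("CDS", 7001L, 7100L, "+", 0L, "tC.c", "tC"),
    feat("CDS", 7201L, 7230L, "+", 2L, "tC.c", "tC"),
    feat("CDS", 7301L, 7500L, "+", 2L, "tC.c", "tC"))
  list(seq = c(t1 = seq), features = features,
       orfs = list(tA = orfA, tB = orfB, tC = orfC),
       exons = list(tA = list(c(2001L, 2150L), c(2251L, 2460L)),
                    tB = list(c(5001L, 5300L)),
                    tC = list(c(7001L, 7100L), c(7201L, 7230L),
                              c(7301L, 7500L))),
       strands = c(tA = "+", tB = "-", tC = "+"),
       gene_of = c(tA = "gA", tB = "gB", tC = "gC"))
}

# per-base region map by independent enumeration (no interval machinery)
oracle_base_map <- function(tg, flank_bp = 500L) {
  L <- nchar(tg$seq[[1]])
  sets <- list(CDS = integer(0), DONOR = integer(0), ACCEPTOR = integer(0),
               REGION = integer(0), INTRON = integer(0), GENE = integer(0),
               UP = integer(0), DOWN = integer(0))
  genes <- tg$features[tg$features$type == "gene", ]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sets$GENE <- c(sets$GENE, g$start:g$end)
    if (g$strand == "+") {
      sets$UP <- c(sets$UP, max(1L, g$start - flank_bp):(g$start - 1L))
      sets$DOWN <- c(sets$DOWN, (g$end + 1L):min(L, g$end + flank_bp))
    } else {
      sets$UP <- c(sets$UP, (g$end + 1L):min(L, g$end + flank_bp))
      sets$DOWN <- c(sets$DOWN, max(1L, g$start - flank_bp):(g$start - 1L))
    }
  }
  for (tx in names(tg$exons)) {
    ex <- tg$exons[[tx]]
    strand <- tg$strands[[tx]]
    for (e in ex) sets$CDS <- c(sets$CDS, e[1]:e[2])
    if (length(ex) > 1L) {
      for (k in seq_len(length(ex) - 1L)) {
        intron <- (ex[[k]][2] + 1L):(ex[[k + 1L]][1] - 1L)
        sets$INTRON <- c(sets$INTRON, intron)
        m <- length(intron)
        if (strand == "+") {
          sets$DONOR <- c(sets$DONOR, intron[1:2])
          sets$ACCEPTOR <- c(sets$ACCEPTOR, intron[(m - 1L):m])
        } else {
          sets$DONOR <- c(sets$DONOR, intron[(m - 1L):m])
          sets$ACCEPTOR <- c(sets$ACCEPTOR, intron[1:2])
        }
        sets$REGION <- c(sets$REGION, intron[3:min(8L, m)],
                         intron[max(1L, m - 7L):(m - 2L)],
                         (ex[[k]][2] - 2L):ex[[k]][2],
                         ex[[k + 1L]][1]:(ex[[k + 1L]][1] + 2L))
      }
    }
  }
  sets
}

# transcript-order CDS genome positions for one toy transcript
oracle_cds_positions <- function(tg, tx) {
  p <- unlist(lapply(tg$exons[[tx]], function(e) e[1]:e[2]))
  if (tg$strands[[tx]] == "-") rev(p) else p
}

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3L
  paste(Biostrings::GENETIC_CODE[substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

# full per-variant oracle: region by the per-base map, CDS effects by
# editing the complete CDS string and comparing full translations
oracle_annotate <- function(tg, chrom, pos, ref, alt, flank_bp = 500L) {
  map <- oracle_base_map(tg, flank_bp)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  foot <- pos:(pos + nchar(ref) - 1L)
  is_indel <- nchar(ref) != nchar(alt)
  if (any(foot %in% map$CDS)) {
    effects <- character(0)
    for (tx in names(tg$exons)) {
      cdsp <- oracle_cds_positions(tg, tx)
      strand <- tg$strands[[tx]]
      old_cds <- tg$orfs[[tx]]
      if (!is_indel) {
        ci <- match(pos, cdsp)
        if (is.na(ci)) next
        new_cds <- old_cds
        substr(new_cds, ci, ci) <- if (strand == "+") alt else comp[alt]
        pa <- oracle_translate(old_cds); pb <- oracle_translate(new_cds)
        cod <- (ci - 1L) %/% 3L + 1L
        a_old <- substr(pa, cod, cod); a_new <- substr(pb, cod, cod)
        eff <- if (cod == 1L && a_new != "M") "START_LOST"
          else if (a_old == a_new && a_old == "*") "SYNONYMOUS_STOP"
          else if (a_old == a_new) "SYNONYMOUS_CODING"
          else if (a_new == "*") "STOP_GAINED"
          else if (a_old == "*") "STOP_LOST"
          else "NON_SYNONYMOUS_CODING"
      } else if (nchar(ref) > nchar(alt)) {
        del <- (pos + 1L):(pos + nchar(ref) - 1L)
        exon_gone <- any(vapply(tg$exons[[tx]], function(e)
          all(e[1]:e[2] %in% del), logical(1)))
        ci <- which(cdsp %in% del)
        if (!length(ci) && !exon_gone) next
        eff <- if (exon_gone) "EXON_DELETED"
          else if (length(ci) %% 3L != 0L) "FRAME_SHIFT"
          else {
            keep <- strsplit(old_cds, "")[[1]][-ci]
            new_cds <- paste(keep, collapse = "")
            base <- if ((min(ci) - 1L) %% 3L == 0L) "CODON_DELETION"
                    else "CODON_CHANGE_PLUS_CODON_DELETION"
            pa <- oracle_translate(old_cds); pb <- oracle_translate(new_cds)
            istop <- function(x) grepl("\\*", substr(x, 1, nchar(x) - 1L))
            if (istop(pb) && !istop(pa)) "STOP_GAINED"
            else if (grepl("\\*$", pa) && !grepl("\\*", pb)) "STOP_LOST"
            else base
          }
      } else {
        ci <- match(pos, cdsp)
        if (is.na(ci)) next
        ins <- substr(alt, 2L, nchar(alt))
        if (strand == "-") ins <- rc(ins)
        after <- if (strand == "+") ci else ci - 1L
        eff <- if (nchar(ins) %% 3L != 0L) "FRAME_SHIFT"
          else {
            new_cds <- paste0(substr(old_cds, 1, after), ins,
                              substr(old_cds, after + 1L, nchar(old_cds)))
            base <- if (after %% 3L == 0L) "CODON_INSERTION"
                    else "CODON_CHANGE_PLUS_CODON_INSERTION"
            pa <- oracle_translate(old_cds); pb <- oracle_translate(new_cds)
            istop <- function(x) grepl("\\*", substr(x, 1, nchar(x) - 1L))
            if (istop(pb) && !istop(pa)) "STOP_GAINED"
            else if (grepl("\\*$", pa) && !grepl("\\*", pb)) "STOP_LOST"
            else base
          }
      }
      effects <- c(effects, eff)
    }
    if (length(effects))
      return(effects[which.min(match(effects, popsweep:::.SEVERITY))])
  }
  for (s in list(c("DONOR", "SPLICE_SITE_DONOR"),
                 c("ACCEPTOR", "SPLICE_SITE_ACCEPTOR"),
                 c("REGION", "SPLICE_SITE_REGION"),
                 c("INTRON", "INTRON"), c("GENE", "INTRAGENIC"),
                 c("UP", "UPSTREAM"), c("DOWN", "DOWNSTREAM"))) {
    if (any(foot %in% map[[s[1]]])) return(s[2])
  }
  "INTERGENIC"
}

# small Balding-Nichols genotype simulator used where only genotypes (no
# files/genes) are needed; independent of the package's own generator
bn_genotypes <- function(n_sites, n_per_pop, F1, F2, seed) {
  set.seed(seed)
  p0 <- runif(n_sites, 0.05, 0.95)
  p1 <- rbeta(n_sites, p0 * (1 - F1) / F1, (1 - p0) * (1 - F1) / F1)
  p2 <- rbeta(n_sites, p0 * (1 - F2) / F2, (1 - p0) * (1 - F2) / F2)
  list(ga = matrix(rbinom(n_sites * n_per_pop, 2, p1), nrow = n_sites),
       gb = matrix(rbinom(n_sites * n_per_pop, 2, p2), nrow = n_sites))
}
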