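# toy genome: gene A (+, exons 2001-2150 / 2251-2460, padded gene span),
# gene B (-, single exon 5001-5300), gene C (+, exons 7001-7100 / 7201-7230 /
# 7301-7500); flank 500 bp so intergenic space exists on the 10 kb chromosome
tg <- toy_genome()
ann <- annotation_from_features(tg$features, tg$seq, flank_bp = 500L)

test_that("derived splice intervals follow their definitions", {
  ## gene A intron is 2151..2250 (100 bp), + strand
  don <- ann$splice_donor[S4Vectors::mcols(ann$splice_donor)$tx_id == "tA"]
  acc <- ann$splice_acceptor[S4Vectors::mcols(ann$splice_acceptor)$tx_id == "tA"]
  expect_equal(GenomicRanges::start(don), 2151L)  # intron bases 1-2
  expect_equal(GenomicRanges::end(don), 2152L)
  expect_equal(GenomicRanges::start(acc), 2249L)  # intron bases 99-100
  expect_equal(GenomicRanges::end(acc), 2250L)
  ## single-exon gene B: no introns, no splice intervals
  expect_false("tB" %in% S4Vectors::mcols(ann$introns)$tx_id)
  expect_false("tB" %in% S4Vectors::mcols(ann$splice_donor)$tx_id)
  ## minus-strand donor/acceptor are swapped relative to genome orientation
  ## (gene C is +, so check by reverse-complement symmetry below instead)
  expect_equal(length(ann$introns[S4Vectors::mcols(ann$introns)$tx_id == "tC"]), 2L)
})

test_that("single-variant region and effect calls match known cases", {
  seqA <- tg$seq[["t1"]]
  at <- function(p) substr(seqA, p, p)
  ## UPSTREAM within the 5 kb default flank: separate mini-annotation
  mini <- tg$features[tg$features$ID %in% c("gB", "tB", "tB.e1", "tB.c"), ]
  ann5k <- annotation_from_features(mini, tg$seq)
  ## gene B is - strand: upstream is to the right of 5300
  up <- annotate_variant("t1", 5300 + 3000, at(5300 + 3000),
                         setdiff(BASES, at(5300 + 3000))[1], ann5k)
  expect_equal(up$label, "UPSTREAM")
  ## intergenic far from everything (toy ann, 500 bp flank)
  expect_equal(annotate_variant("t1", 4000, at(4000),
                                setdiff(BASES, at(4000))[1], ann)$label,
               "INTERGENIC")
  ## intragenic: inside padded gene A span but outside its mRNA
  expect_equal(annotate_variant("t1", 1960, at(1960),
                                setdiff(BASES, at(1960))[1], ann)$label,
               "INTRAGENIC")
  ## intron interior of gene A (bases 9-90 of the intron)
  expect_equal(annotate_variant("t1", 2200, at(2200),
                                setdiff(BASES, at(2200))[1], ann)$label,
               "INTRON")
  ## 2 bp deletion inside CDS of gene A -> frame shift
  fs <- annotate_variant("t1", 2060, substr(seqA, 2060, 2062),
                         at(2060), ann)
  expect_equal(fs$label, "FRAME_SHIFT")
  expect_equal(fs$region, "CDS")
  ## deletion spanning the whole 30 bp middle exon of gene C
  ed <- annotate_variant("t1", 7195, substr(seqA, 7195, 7235),
                         at(7195), ann)
  expect_equal(ed$label, "EXON_DELETED")
})

test_that("codon-level SNP effects follow the genetic code", {
  ## build a dedicated + strand single-exon gene with known codons:
  ## ATG GGA TGG TAT TAA  at 101..115
  s <- paste(rep("C", 300), collapse = "")
  orf <- "ATGGGATGGTATTAA"
  substr(s, 101, 115) <- orf
  feats <- data.frame(
    chrom = "k1", type = c("gene", "mRNA", "exon", "CDS"),
    start = 101L, end = 115L, strand = "+",
    phase = c(NA, NA, NA, 0L), ID = c("g1", "t1", "t1.e", "t1.c"),
    Parent = c(NA, "g1", "t1", "t1"))
  a <- annotation_from_features(feats, c(k1 = s), flank_bp = 50L)
  lab <- function(pos, ref, alt) annotate_variant("k1", pos, ref, alt, a)$label
  expect_equal(lab(106, "A", "G"), "SYNONYMOUS_CODING")  # GGA->GGG, Gly->Gly
  expect_equal(lab(109, "G", "A"), "STOP_GAINED")        # TGG->TGA mid-CDS
  expect_equal(lab(103, "G", "T"), "START_LOST")         # ATG->ATT
  expect_equal(lab(114, "A", "G"), "SYNONYMOUS_STOP")    # TAA->TGA
  expect_equal(lab(113, "T", "C"), "STOP_LOST")          # TAA->CAA
  expect_equal(lab(111, "A", "T"), "NON_SYNONYMOUS_CODING")  # TAT->TTT
  ## in-frame, codon-aligned insertion after a codon boundary
  expect_equal(lab(106, "A", "AGGG"), "CODON_INSERTION")
  ## in-frame but not codon-aligned
  expect_equal(lab(105, "G", "GAAA"), "CODON_CHANGE_PLUS_CODON_INSERTION")
  ## codon-aligned in-frame deletion (removes codon 3: positions 107-109)
  expect_equal(lab(106, "ATGG", "A"), "CODON_DELETION")
  ## in-frame deletion across a codon boundary
  expect_equal(lab(105, "GATG", "G"), "CODON_CHANGE_PLUS_CODON_DELETION")
})

test_that("variants beyond bounds or off-chromosome error", {
  expect_error(annotate_variant("nope", 5, "A", "G", ann), "unannotated")
  expect_error(annotate_variant("t1", 10000, "AAA", "A", ann), "beyond")
})

test_that("annotation equals the per-base brute-force oracle on the toy genome", {
  set.seed(31)
  seqA <- tg$seq[["t1"]]
  n <- 200
  pos <- sort(sample(100:9900, n))
  sites <- lapply(pos, function(p) {
    r <- substr(seqA, p, p)
    if (runif(1) < 0.65) {
      data.frame(chrom = "t1", pos = p, ref = r,
                 alt = sample(setdiff(BASES, r), 1))
    } else if (runif(1) < 0.5) {
      l <- sample(1:4, 1)
      data.frame(chrom = "t1", pos = p, ref = substr(seqA, p, p + l), alt = r)
    } else {
      data.frame(chrom = "t1", pos = p, ref = r,
                 alt = paste0(r, paste(sample(BASES, sample(1:4, 1), TRUE),
                                       collapse = "")))
    }
  })
  sites <- do.call(rbind, sites)
  got <- vapply(seq_len(nrow(sites)), function(i)
    annotate_variant("t1", sites$pos[i], sites$ref[i], sites$alt[i], ann)$label,
    character(1))
  want <- vapply(seq_len(nrow(sites)), function(i) {
    nm <- popsweep:::.left_normalize(seqA, sites$pos[i], sites$ref[i], sites$alt[i])
    oracle_annotate(tg, "t1", nm$pos, nm$ref, nm$alt)
  }, character(1))
  expect_equal(got, want)
})

test_that("reverse-complementing genome and features preserves SNP categories", {
  L <- 10000L
  seqA <- tg$seq[["t1"]]
  rc_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqA)))
  f <- tg$features
  rc_f <- f
  rc_f$start <- L - f$end + 1L
  rc_f$end <- L - f$start + 1L
  rc_f$strand <- ifelse(f$strand == "+", "-", "+")
  ann_rc <- annotation_from_features(rc_f, c(t1 = rc_seq), flank_bp = 500L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(32)
  pos <- sample(100:9900, 120)
  for (p in pos) {
    r <- substr(seqA, p, p)
    a <- sample(setdiff(BASES, r), 1)
    fwd <- annotate_variant("t1", p, r, a, ann)$label
    rev <- annotate_variant("t1", L - p + 1L, comp[[r]], comp[[a]], ann_rc)$label
    expect_equal(fwd, rev, label = paste("pos", p))
  }
})

test_that("effect table partitions calls and keeps the canonical layout", {
  empty <- effect_table(data.frame(label = character(0)))
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 20L)
  one <- effect_table(data.frame(label = "SYNONYMOUS_CODING"))
  expect_equal(one$count[one$type == "SYNONYMOUS_CODING"], 1L)
  expect_equal(sum(one$count), 1L)
  ## fixture: row sums equal variant count
  cfg <- sim_config(chrom_length = 50000L, n_genes = 5, seed = 41)
  ds <- simulate_populations(cfg)
  vs <- make_variant_set(ds$sites, ds$geno, ds$samples)
  ann_sim <- annotation_from_features(ds$features, ds$ref)
  calls <- annotate_variants(vs, ann_sim)
  expect_equal(sum(effect_table(calls)$count), nrow(ds$sites))
  ## every variant gets exactly one region; cds_effect iff region == CDS
  expect_false(any(is.na(calls$region)))
  expect_equal(is.na(calls$cds_effect), calls$region != "CDS")
})
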