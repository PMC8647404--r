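test_that("transition/transversion classification covers all 12 ordered pairs", {
  pairs <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_error(classify_substitution("A", "A"), "SNP")
})

clean_site <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             class = popsweep:::.variant_class(ref, alt),
             qual = 100, qd = 20, mq = 55, fs = 1)
}

test_that("hard filters fire with the documented reasons", {
  ## SNP within 5 bp of an InDel
  s <- rbind(clean_site("c1", 100, "A", "G"), clean_site("c1", 103, "AT", "A"))
  f <- apply_hard_filters(make_variant_set(s))
  expect_equal(f$removals$reason[f$removals$pos == 100], "snp_near_indel")
  ## three clean SNPs within a 5 bp window are all removed as a cluster
  s <- rbind(clean_site("c1", 200, "A", "G"), clean_site("c1", 202, "C", "T"),
             clean_site("c1", 204, "G", "A"))
  f <- apply_hard_filters(make_variant_set(s))
  expect_equal(nrow(f$passing$sites), 0L)
  expect_equal(f$removals$reason, rep("cluster", 3L))
  ## single metric violations
  s <- clean_site("c1", 500, "A", "G"); s$qd <- 1.5
  expect_equal(apply_hard_filters(make_variant_set(s))$removals$reason, "low_qd")
  s <- clean_site("c1", 500, "A", "G"); s$qual <- 29
  expect_equal(apply_hard_filters(make_variant_set(s))$removals$reason, "low_qual")
  s <- clean_site("c1", 500, "A", "G"); s$mq <- 39
  expect_equal(apply_hard_filters(make_variant_set(s))$removals$reason, "low_mq")
  s <- clean_site("c1", 500, "A", "G"); s$fs <- 61
  expect_equal(apply_hard_filters(make_variant_set(s))$removals$reason, "high_fs")
  ## absent metric skips that rule and is logged
  s <- clean_site("c1", 500, "A", "G"); s$qd <- NA
  f <- apply_hard_filters(make_variant_set(s))
  expect_equal(nrow(f$passing$sites), 1L)
  expect_match(f$log, "low_qd", all = FALSE)
  ## unsorted input rejected
  s <- rbind(clean_site("c1", 500, "A", "G"), clean_site("c1", 100, "C", "T"))
  expect_error(apply_hard_filters(make_variant_set(s)), "sorted")
})

test_that("filters match the independent oracle and conserve records", {
  cfg <- filter_config()
  for (seed in 1:5) {
    set.seed(seed)
    s <- rand_sites(100, max_pos = 5000L)
    ## plant metric violations
    s$qual[sample.int(100, 5)] <- runif(5, 1, 29)
    s$qd[sample.int(100, 5)] <- runif(5, 0, 1.9)
    s$mq[sample.int(100, 5)] <- runif(5, 10, 39)
    s$fs[sample.int(100, 5)] <- runif(5, 61, 200)
    vs <- make_variant_set(s)
    f <- apply_hard_filters(vs, cfg)
    truth <- oracle_hard_filters(s, cfg)
    ## passing + removed = input, no duplicates
    expect_equal(nrow(f$passing$sites) + nrow(f$removals), nrow(s))
    expect_equal(sum(is.na(truth)), nrow(f$passing$sites))
    got <- merge(s[, c("chrom", "pos")], f$removals, all.x = TRUE)
    got <- got[order(match(paste(got$chrom, got$pos),
                           paste(s$chrom, s$pos))), ]
    expect_equal(got$reason, truth)
    ## idempotence: refiltering the passing set removes nothing
    f2 <- apply_hard_filters(f$passing, cfg)
    expect_equal(nrow(f2$removals), 0L)
    expect_equal(f2$passing$sites, f$passing$sites)
  }
})

test_that("SNP summaries match a brute-force recount and printed-count arithmetic", {
  set.seed(7)
  s <- rand_sites(60, indel_frac = 0)
  geno <- matrix(sample(c(0:2, NA), 60 * 8, TRUE), 60, 8,
                 dimnames = list(NULL, paste0("s", 1:8)))
  vs <- make_variant_set(s, geno)
  ss <- summarize_snps(vs)
  ## brute force per genotype call
  het <- 0; hom <- 0
  for (i in 1:60) for (j in 1:8) {
    g <- geno[i, j]
    if (!is.na(g) && g == 1) het <- het + 1
    if (!is.na(g) && g == 2) hom <- hom + 1
  }
  ti <- sum(mapply(function(r, a)
    paste(sort(c(r, a)), collapse = "") %in% c("AG", "CT"), s$ref, s$alt))
  expect_equal(ss$n_het, het)
  expect_equal(ss$n_hom, hom)
  expect_equal(ss$n_transitions, ti)
  expect_equal(ss$ti_tv, floor(100 * ti / (60 - ti)) / 100)
  expect_equal(ss$het_ratio, floor(10000 * het / (het + hom)) / 100)
  ## all-heterozygous input
  vs2 <- make_variant_set(s, matrix(1L, 60, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(summarize_snps(vs2)$het_ratio, 100)
  ## zero transversions -> undefined ratio
  expect_true(is.na(snp_summary_counts(5, 0, 1, 1)$ti_tv))
  ## rejects InDels
  expect_error(summarize_snps(make_variant_set(rand_sites(10, indel_frac = 1))),
               "SNP records only")
})

test_that("InDel summaries classify direction and length correctly", {
  s <- data.frame(chrom = "c1", pos = c(10L, 50L), ref = c("A", "ACGT"),
                  alt = c("AT", "A"), class = "InDel",
                  qual = 100, qd = 20, mq = 50, fs = 1)
  geno <- matrix(c(1L, 2L, 2L, 1L), 2, 2, dimnames = list(NULL, c("x", "y")))
  is <- summarize_indels(make_variant_set(s, geno))
  expect_equal(is$n_insertions, 1L)
  expect_equal(is$n_deletions, 1L)
  expect_equal(as.integer(names(is$length_spectrum)), c(-3L, 1L))
  expect_equal(unname(c(is$length_spectrum)), c(1L, 1L))
  expect_equal(is$n_het, 2L)
  expect_equal(is$n_hom, 2L)
  expect_error(summarize_indels(make_variant_set(rand_sites(5, indel_frac = 0))),
               "InDel records only")
})

test_that("CDS-scope InDel summary equals the generator truth", {
  cfg <- sim_config(chrom_length = 60000L, n_genes = 6, seed = 21)
  ds <- simulate_populations(cfg)
  paths <- write_dataset(ds, file.path(tempdir(), "cdsscope"))
  vs <- read_vcf(paths[["vcf"]])
  ann <- load_annotation(paths[["gff3"]], paths[["fasta"]])
  ind <- vs$sites$class == "InDel"
  ivs <- make_variant_set(vs$sites[ind, ], vs$geno[ind, , drop = FALSE])
  got <- summarize_indels(ivs, ann, scope = "CDS")
  ## independent overlap count from the truth table
  cds <- ann$cds
  s <- ds$sites[ds$sites$class == "InDel", ]
  inside <- vapply(seq_len(nrow(s)), function(i)
    any(as.character(GenomicRanges::seqnames(cds)) == s$chrom[i] &
          GenomicRanges::start(cds) <= s$pos[i] + nchar(s$ref[i]) - 1L &
          GenomicRanges::end(cds) >= s$pos[i]), logical(1))
  expect_equal(got$total, sum(inside))
})

test_that("multi-allelic sites are split and summaries are split-invariant", {
  v1 <- c("##fileformat=VCFv4.2",
          "##INFO=<ID=QD,Number=1,Type=Float,Description=\"d\">",
          "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
          "chr1\t10\t.\tA\tG,T\t50\t.\tQD=20\tGT\t1/2\t0/1",
          "chr1\t40\t.\tC\tT\t60\t.\tQD=25\tGT\t./.\t1/1")
  v2 <- c(v1[1:4],
          "chr1\t10\t.\tA\tG\t50\t.\tQD=20\tGT\t0/1\t0/1",
          "chr1\t10\t.\tA\tT\t50\t.\tQD=20\tGT\t0/1\t0/0",
          "chr1\t40\t.\tC\tT\t60\t.\tQD=25\tGT\t./.\t1/1")
  f1 <- tempfile(fileext = ".vcf"); writeLines(v1, f1)
  f2 <- tempfile(fileext = ".vcf"); writeLines(v2, f2)
  a <- read_vcf(f1); b <- read_vcf(f2)
  expect_equal(nrow(a$sites), 3L)
  expect_equal(a$sites$alt, c("G", "T", "T"))
  expect_identical(unname(a$geno), unname(b$geno))
  expect_true(is.na(a$geno[3, "a"]))
  sa <- summarize_snps(a); sb <- summarize_snps(b)
  expect_identical(sa, sb)
})

test_that("per-chromosome counts partition the input", {
  set.seed(3)
  s <- rbind(rand_sites(30, chrom = "c1"), rand_sites(20, chrom = "c2"),
             rand_sites(10, chrom = "c3"))
  vs <- make_variant_set(s)
  tab <- per_chromosome_counts(vs)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$n_snp) + sum(tab$n_indel), 60L)
  expect_equal(sum(tab$n_snp), sum(s$class == "SNP"))
  empty <- make_variant_set(s[0, ])
  expect_equal(nrow(per_chromosome_counts(empty)), 0L)
})
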