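test_that("window tiling matches the closed form", {
  cfg <- sweep_config()
  w <- make_windows(250000L, cfg)
  expect_equal(nrow(w), 16L)  # floor((250000-100000)/10000)+1
  expect_equal(w$start[1], 0L)
  expect_equal(w$end[1], 100000L)
  expect_equal(nrow(make_windows(100000L, cfg)), 1L)
  expect_warning(w0 <- make_windows(99999L, cfg), "shorter")
  expect_equal(nrow(w0), 0L)
  expect_error(sweep_config(step_bp = 2e5), "exceed")
})

test_that("windowed pi matches the closed form and the O(n^2) oracle", {
  ## one site, 4 called alleles, 2 alt: pi_site = 0.5 * 4/3 = 2/3
  g <- matrix(c(1L, 1L), nrow = 1)
  expect_equal(window_pi(g, 100), (2 / 3) / 100)
  ## monomorphic window
  expect_equal(window_pi(matrix(0L, 5, 6), 1000), 0)
  expect_equal(window_pi(matrix(2L, 5, 6), 1000), 0)
  ## random windows against brute-force pairwise differences
  for (seed in 1:4) {
    set.seed(seed)
    g <- matrix(sample(c(0:2, NA), 50 * 8, TRUE, prob = c(.3, .3, .3, .1)),
                50, 8)
    expect_equal(window_pi(g, 12345), oracle_pi(g, 12345), tolerance = 1e-12)
  }
  expect_error(window_pi(g, 0), "positive")
})

test_that("Hudson Fst matches hand-computed values", {
  ## fixed difference: p1 = 1, p2 = 0, n1 = n2 = 20 alleles
  expect_equal(window_fst(matrix(2L, 1, 10), matrix(0L, 1, 10)), 1.0)
  ## p1 = p2 = 0.5 with n = 10 alleles each:
  ## N = 0 - 0.25/9 - 0.25/9, D = 0.5 -> -0.1111
  ga <- matrix(c(2L, 2L, 1L, 0L, 0L), 1, 5)
  gb <- matrix(c(0L, 1L, 2L, 2L, 0L), 1, 5)
  expect_equal(window_fst(ga, gb), (0 - 2 * 0.25 / 9) / 0.5, tolerance = 1e-12)
  ## symmetric in the population order
  set.seed(5)
  ga <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  gb <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  expect_equal(window_fst(ga, gb), window_fst(gb, ga))
  expect_equal(window_fst(ga, gb, "weir_cockerham"),
               window_fst(gb, ga, "weir_cockerham"))
  ## no variation anywhere -> undefined
  expect_true(is.na(window_fst(matrix(0L, 3, 4), matrix(0L, 3, 4))))
})

test_that("both Fst estimators agree near the simulated truth", {
  g <- bn_genotypes(20000, 25, 0.1, 0.1, seed = 8)
  expect_lt(abs(window_fst(g$ga, g$gb) - 0.1), 0.02)
  expect_lt(abs(window_fst(g$ga, g$gb, "weir_cockerham") - 0.1), 0.02)
})

test_that("pooled identical populations give Fst near zero", {
  set.seed(9)
  p <- runif(20000, 0.05, 0.95)
  g <- matrix(rbinom(20000 * 20, 2, p), 20000, 20)
  expect_lt(abs(window_fst(g[, 1:10], g[, 11:20])), 0.02)
})

test_that("pi is invariant to sample order and ref/alt relabeling", {
  set.seed(10)
  g <- matrix(sample(c(0:2, NA), 30 * 10, TRUE), 30, 10)
  expect_equal(window_pi(g, 500), window_pi(g[, sample(10)], 500))
  flip <- sample(c(TRUE, FALSE), 30, TRUE)
  g2 <- g
  g2[flip, ] <- 2L - g2[flip, ]
  expect_equal(window_pi(g, 500), window_pi(g2, 500))
})

test_that("scan composes window_pi / window_fst and assigns sites to windows", {
  set.seed(12)
  n <- 60
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(50000L, n)),
                      ref = "A", alt = "G", class = "SNP",
                      qual = 100, qd = 20, mq = 50, fs = 1)
  geno <- matrix(sample(0:2, n * 10, TRUE), n, 10,
                 dimnames = list(NULL, sprintf("s%02d", 1:10)))
  vs <- make_variant_set(sites, geno)
  pops <- setNames(rep(c("A", "B"), each = 5), vs$samples)
  cfg <- sweep_config(window_bp = 20000L, step_bp = 5000L,
                      min_sites_per_window = 5L)
  st <- sweep_scan(vs, pops, c(chr1 = 50000L), cfg)
  expect_equal(nrow(st), 7L)  # floor((50000-20000)/5000)+1 windows, 1 pair
  ## membership: site contributes to windows whose [start,end) contains pos-1
  for (w in seq_len(nrow(st))) {
    inw <- sites$pos - 1L >= st$start[w] & sites$pos - 1L < st$end[w]
    expect_equal(st$n_sites[w], sum(inw))
    expect_equal(st$pi_a[w], window_pi(geno[inw, 1:5, drop = FALSE], 20000L))
    expect_equal(st$fst[w],
                 window_fst(geno[inw, 1:5, drop = FALSE],
                            geno[inw, 6:10, drop = FALSE]))
  }
  ## empty input: every window ineligible
  st0 <- sweep_scan(make_variant_set(sites[0, ], geno[0, , drop = FALSE]),
                    pops, c(chr1 = 50000L), cfg)
  expect_true(all(!st0$eligible))
  ## unassigned sample errors
  expect_error(sweep_scan(vs, pops[-1], c(chr1 = 50000L), cfg), "missing")
})

test_that("region calling applies strict thresholds and merges windows", {
  base <- data.frame(chrom = "chr1", pop_a = "A", pop_b = "B",
                     n_sites = 50L, pi_a = 1e-3, eligible = TRUE)
  row <- function(start, fst, ratio) cbind(
    base, start = start, end = start + 100000L, pi_b = 1e-3 / ratio,
    fst = fst, pi_ratio = ratio)
  cfg <- sweep_config()
  expect_equal(nrow(call_selected_regions(row(0L, 0.30, 2.5), cfg)), 1L)
  expect_equal(nrow(call_selected_regions(row(0L, 0.30, 1.0), cfg)), 0L)
  expect_equal(nrow(call_selected_regions(row(0L, 0.20, 3.0), cfg)), 0L)
  ## boundary values are NOT selected (strict inequalities)
  expect_equal(nrow(call_selected_regions(row(0L, 0.25, 3.0), cfg)), 0L)
  expect_equal(nrow(call_selected_regions(row(0L, 0.30, 2.0), cfg)), 0L)
  ## direction: ratio > high blames pop_b; ratio < low blames pop_a
  expect_equal(call_selected_regions(row(0L, 0.3, 4), cfg)$direction, "B")
  expect_equal(call_selected_regions(row(0L, 0.3, 0.2), cfg)$direction, "A")
  ## overlapping same-direction windows merge into one maximal region
  st <- rbind(row(0L, 0.3, 3), row(10000L, 0.4, 4), row(20000L, 0.35, 5))
  reg <- call_selected_regions(st, cfg)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, 120000L)
  expect_equal(reg$n_windows, 3L)
  ## monotone in fst_min: raising the threshold never adds a region
  for (f in c(0.26, 0.31, 0.36)) {
    cf <- sweep_config(fst_min = f)
    expect_lte(nrow(call_selected_regions(st, cf)), nrow(reg))
  }
})

test_that("gene intersection uses half-open >= 1 bp overlap and matches the oracle", {
  feats <- do.call(rbind, lapply(1:20, function(i) {
    start <- (i - 1L) * 500L + 100L
    data.frame(chrom = "c1", type = c("gene", "mRNA", "exon", "CDS"),
               start = start, end = start + 299L, strand = "+",
               phase = c(NA, NA, NA, 0L),
               ID = paste0(c("g", "t", "e", "cd"), i),
               Parent = c(NA, paste0("g", i), paste0("t", i), paste0("t", i)))
  }))
  seq <- c(c1 = paste(rep("A", 11000), collapse = ""))
  ann <- suppressWarnings(annotation_from_features(feats, seq))
  ## gene [100,200) vs region [150,300): package is 1-based closed internally,
  ## so express the spec cases directly in 0-based half-open coordinates
  reg <- data.frame(chrom = "c1", start = c(99L, 399L), end = c(149L, 2000L))
  got <- intersect_genes(reg, ann)
  expect_true("g1" %in% got$per_region[[1]])   # overlaps gene 1 by >= 1 bp
  expect_false("g1" %in% got$per_region[[2]])  # [399,...) starts at gene 1's end
  ## adjacency does not count: region ending where a gene starts
  reg2 <- data.frame(chrom = "c1", start = 0L, end = 99L)  # gene 1 starts at 99 (0-based)
  expect_equal(intersect_genes(reg2, ann)$genes, character(0))
  ## quadratic all-pairs oracle on random regions
  set.seed(14)
  reg3 <- data.frame(chrom = "c1", start = sort(sample.int(9000L, 5)))
  reg3$end <- reg3$start + sample(200:1500, 5)
  got3 <- intersect_genes(reg3, ann)
  genes <- feats[feats$type == "gene", ]
  for (i in 1:5) {
    want <- sort(genes$ID[(genes$start - 1L) < reg3$end[i] &
                            genes$end > reg3$start[i]])
    expect_equal(got3$per_region[[i]], want)
  }
})

test_that("venn counts enumerate the full partition", {
  v <- venn_counts(list(X = c("a", "b"), Y = c("b", "c")))
  expect_equal(v$count[v$members == "X"], 1L)
  expect_equal(v$count[v$members == "Y"], 1L)
  expect_equal(v$count[v$members == "X&Y"], 1L)
  same <- venn_counts(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(same$count[same$members == "X&Y"], 2L)
  expect_equal(sum(same$count[same$members != "X&Y"]), 0L)
  ## three random sets against brute-force membership enumeration
  set.seed(15)
  sets <- list(P = sample(letters, 10), Q = sample(letters, 12),
               R = sample(letters, 8))
  v3 <- venn_counts(sets)
  for (i in seq_len(nrow(v3))) {
    members <- strsplit(v3$members[i], "&")[[1]]
    others <- setdiff(names(sets), members)
    want <- sum(vapply(unique(unlist(sets)), function(e)
      all(vapply(members, function(m) e %in% sets[[m]], logical(1))) &&
        !any(vapply(others, function(o) e %in% sets[[o]], logical(1))),
      logical(1)))
    expect_equal(v3$count[i], want)
  }
  expect_equal(sum(v3$count), length(unique(unlist(sets))))
})
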