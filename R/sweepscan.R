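#' Settings for the windowed selective-sweep scan
#'
#' Defaults follow the standard resequencing scan design: 100 kb windows
#' sliding in 10 kb steps, with a window called as selected when its
#' pairwise Fst exceeds 0.25 and its pi ratio is above 2 or below 0.5.
#'
#' @param window_bp window length in bp.
#' @param step_bp slide step in bp (must not exceed `window_bp`).
#' @param fst_min Fst threshold (strict inequality).
#' @param pi_ratio_high,pi_ratio_low pi-ratio thresholds (strict).
#' @param min_sites_per_window windows with fewer usable variant sites are
#'   flagged ineligible; guards against noise in sparse windows.
#' @param fst_estimator "hudson" (ratio-of-averages, default) or
#'   "weir_cockerham" (two-population variance components).
#' @return a `sweep_config` object.
#' @export
sweep_config <- function(window_bp = 100000L, step_bp = 10000L,
                         fst_min = 0.25, pi_ratio_high = 2.0,
                         pi_ratio_low = 0.5, min_sites_per_window = 10L,
                         fst_estimator = c("hudson", "weir_cockerham")) {
  fst_estimator <- match.arg(fst_estimator)
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  if (!(pi_ratio_low < 1 && 1 < pi_ratio_high))
    stop("pi ratio thresholds must bracket 1")
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp), fst_min = fst_min,
                 pi_ratio_high = pi_ratio_high, pi_ratio_low = pi_ratio_low,
                 min_sites_per_window = as.integer(min_sites_per_window),
                 fst_estimator = fst_estimator), class = "sweep_config")
}

#' Sliding windows over one chromosome
#'
#' Windows are 0-based half-open, start at 0 and advance by the step; only
#' full-length windows are emitted.
#'
#' @param chrom_length chromosome length in bp.
#' @param config a [sweep_config()].
#' @return data.frame with `start`, `end`; empty (with a warning) when the
#'   chromosome is shorter than one window.
#' @export
make_windows <- function(chrom_length, config = sweep_config()) {
  if (chrom_length < config$window_bp) {
    warning("chromosome shorter than one window; no windows emitted")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- seq(0L, chrom_length - config$window_bp, by = config$step_bp)
  data.frame(start = starts, end = starts + config$window_bp)
}

## Per-site pi: 2*(k/n)*(1-k/n)*n/(n-1) for k alt alleles among n called;
## identical to the fraction of differing pairs among all allele pairs.
.site_pi <- function(k, n) 2 * (k / n) * (1 - k / n) * n / (n - 1)

#' Windowed nucleotide diversity (theta-pi)
#'
#' Sums per-site pairwise-difference fractions over the variant sites of a
#' window and divides by the full window length (monomorphic bases
#' contribute zero). Sites with fewer than two called alleles are skipped.
#'
#' @param g dosage matrix (sites x samples of one population, 0/1/2, NA
#'   missing) for the sites inside the window.
#' @param window_bp window length in bp (the denominator).
#' @return per-bp pi (>= 0).
#' @export
window_pi <- function(g, window_bp) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  n <- 2L * rowSums(!is.na(g))
  k <- rowSums(g, na.rm = TRUE)
  use <- n >= 2L
  sum(.site_pi(k[use], n[use])) / window_bp
}

#' Windowed pairwise Fst between two populations
#'
#' The default Hudson estimator accumulates, per site, the numerator
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)` and reports the window value as the ratio of their
#' sums (ratio of averages), which is robust to rare variants. The
#' Weir-Cockerham option implements the two-population variance-components
#' estimator (sum of a over sum of a+b+c) using genotypic heterozygote
#' counts. Values are reported raw and may be negative.
#'
#' @param ga,gb dosage matrices (sites x samples) for the two populations
#'   over the same sites.
#' @param estimator "hudson" or "weir_cockerham".
#' @return the window Fst, or NA when no site is informative (no variation
#'   in either population); such windows are excluded from region calling.
#' @export
window_fst <- function(ga, gb, estimator = c("hudson", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  if (is.null(dim(ga))) ga <- matrix(ga, nrow = 1L)
  if (is.null(dim(gb))) gb <- matrix(gb, nrow = 1L)
  n1 <- 2L * rowSums(!is.na(ga)); n2 <- 2L * rowSums(!is.na(gb))
  k1 <- rowSums(ga, na.rm = TRUE); k2 <- rowSums(gb, na.rm = TRUE)
  use <- n1 >= 2L & n2 >= 2L
  if (!any(use)) return(NA_real_)
  n1 <- n1[use]; n2 <- n2[use]
  p1 <- k1[use] / n1; p2 <- k2[use] / n2
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (sum(den) == 0) return(NA_real_)
    sum(num) / sum(den)
  } else {
    ## Weir & Cockerham (1984), r = 2 populations, per-site a, b, c
    h1 <- rowSums(ga[use, , drop = FALSE] == 1L, na.rm = TRUE)
    h2 <- rowSums(gb[use, , drop = FALSE] == 1L, na.rm = TRUE)
    nn1 <- n1 / 2; nn2 <- n2 / 2              # individuals
    nbar <- (nn1 + nn2) / 2
    nc <- (2 * nbar - (nn1^2 + nn2^2) / (2 * nbar))
    pbar <- (nn1 * p1 + nn2 * p2) / (2 * nbar)
    s2 <- (nn1 * (p1 - pbar)^2 + nn2 * (p2 - pbar)^2) / nbar
    hbar <- (h1 + h2) / (2 * nbar)
    r <- 2
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    tot <- sum(a + b + cc)
    if (tot == 0) return(NA_real_)
    sum(a) / tot
  }
}

#' Sliding-window pi/Fst scan over all population pairs
#'
#' For every ordered population pair and every full window, computes both
#' populations' windowed pi, their pairwise Fst, and the pi ratio
#' (first-named population over second). A variant at position p (1-based)
#' contributes to exactly the windows whose 0-based half-open span contains
#' p - 1. Windows with fewer usable sites than the configured minimum, or
#' with undefined Fst or pi ratio, are flagged ineligible.
#'
#' @param vs a `variant_set` (biallelic SNPs recommended).
#' @param pops named character vector mapping sample -> population; must
#'   cover every sample of `vs`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param config a [sweep_config()].
#' @return data.frame of window statistics: chrom, start, end, pop_a, pop_b,
#'   n_sites, pi_a, pi_b, fst, pi_ratio, eligible.
#' @export
sweep_scan <- function(vs, pops, chrom_lengths, config = sweep_config()) {
  stopifnot(inherits(vs, "variant_set"))
  if (!all(vs$samples %in% names(pops)))
    stop("samples missing from population assignment: ",
         paste(setdiff(vs$samples, names(pops)), collapse = ", "))
  pop_of <- pops[vs$samples]
  pop_levels <- unique(pop_of)
  pairs <- utils::combn(pop_levels, 2L, simplify = FALSE)
  out <- list()
  for (ch in names(chrom_lengths)) {
    win <- suppressWarnings(make_windows(chrom_lengths[[ch]], config))
    if (!nrow(win)) next
    on_ch <- vs$sites$chrom == ch
    pos0 <- vs$sites$pos[on_ch] - 1L
    g <- vs$geno[on_ch, , drop = FALSE]
    for (pr in pairs) {
      ga_all <- g[, pop_of == pr[1], drop = FALSE]
      gb_all <- g[, pop_of == pr[2], drop = FALSE]
      for (w in seq_len(nrow(win))) {
        inw <- pos0 >= win$start[w] & pos0 < win$end[w]
        ga <- ga_all[inw, , drop = FALSE]
        gb <- gb_all[inw, , drop = FALSE]
        pi_a <- window_pi(ga, config$window_bp)
        pi_b <- window_pi(gb, config$window_bp)
        fst <- window_fst(ga, gb, config$fst_estimator)
        ratio <- if (pi_b > 0) pi_a / pi_b else if (pi_a > 0) Inf else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = win$start[w], end = win$end[w],
          pop_a = pr[1], pop_b = pr[2], n_sites = sum(inw),
          pi_a = pi_a, pi_b = pi_b, fst = fst, pi_ratio = ratio,
          eligible = sum(inw) >= config$min_sites_per_window &&
            !is.na(fst) && !is.na(ratio))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), pop_a = character(0),
                      pop_b = character(0), n_sites = integer(0),
                      pi_a = numeric(0), pi_b = numeric(0), fst = numeric(0),
                      pi_ratio = numeric(0), eligible = logical(0)))
  do.call(rbind, out)
}

#' Call selected regions from window statistics
#'
#' A window is selected when it is eligible, its Fst strictly exceeds the
#' threshold and its pi ratio lies strictly outside \[low, high\].
#' Overlapping or adjacent selected windows pointing at the same
#' low-diversity population are merged into maximal regions: a ratio above
#' the high threshold implicates the denominator population (pop_b), a
#' ratio below the low threshold the numerator (pop_a).
#'
#' @param stats window statistics of one population comparison
#'   (one `(pop_a, pop_b)` pair from [sweep_scan()]).
#' @param config a [sweep_config()].
#' @return data.frame of regions: chrom, start, end (0-based half-open),
#'   direction (population with reduced diversity), n_windows.
#' @export
call_selected_regions <- function(stats, config = sweep_config()) {
  if (length(unique(paste(stats$pop_a, stats$pop_b))) > 1L)
    stop("call_selected_regions expects windows of a single comparison")
  sel <- stats$eligible & !is.na(stats$fst) & stats$fst > config$fst_min &
    (stats$pi_ratio > config$pi_ratio_high | stats$pi_ratio < config$pi_ratio_low)
  s <- stats[sel, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_windows = integer(0)))
  s$direction <- ifelse(s$pi_ratio > config$pi_ratio_high, s$pop_b, s$pop_a)
  out <- list()
  for (key in unique(paste(s$chrom, s$direction))) {
    ss <- s[paste(s$chrom, s$direction) == key, , drop = FALSE]
    ir <- IRanges::IRanges(ss$start + 1L, ss$end)  # to 1-based closed
    red <- IRanges::reduce(ir)
    hits <- IRanges::countOverlaps(red, ir)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ss$chrom[1], start = IRanges::start(red) - 1L,
      end = IRanges::end(red), direction = ss$direction[1], n_windows = hits)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Genes overlapping selected regions
#'
#' A gene is assigned to a region when its span overlaps the region by at
#' least 1 bp (half-open interval intersection; mere adjacency does not
#' count). The global gene set is deduplicated across regions.
#'
#' @param regions data.frame from [call_selected_regions()] (0-based
#'   half-open `start`/`end` plus `chrom`).
#' @param ann a `genome_annotation`.
#' @return list with `per_region` (list of gene-id vectors, one per region)
#'   and `genes` (deduplicated, sorted gene ids).
#' @export
intersect_genes <- function(regions, ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (!nrow(regions)) return(list(per_region = list(), genes = character(0)))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(rg, ann$genes, ignore.strand = TRUE)
  ids <- S4Vectors::mcols(ann$genes)$gene_id
  per_region <- lapply(seq_len(nrow(regions)), function(i)
    sort(unique(ids[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]])))
  list(per_region = per_region, genes = sort(unique(unlist(per_region))))
}

#' Venn partition counts over named gene sets
#'
#' Counts every exclusive region of the Venn partition of two or more named
#' sets (e.g. the selected-gene sets of the three population comparisons).
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.frame: `members` (set names joined by "&"), `count`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop("venn_counts needs >= 2 named sets")
  elements <- unique(unlist(sets))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  data.frame(members = combos,
             count = vapply(combos, function(cb) sum(pattern == cb), integer(1)),
             row.names = NULL)
}
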