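#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene); each sample's
#' reference value is the arithmetic mean of its three (or more)
#' housekeeping-gene Cts, which under 100% amplification efficiency equals
#' normalizing by the geometric mean of the housekeeping expression levels.
#' Then `dCt = Ct_target - Ct_ref`, `ddCt = dCt - mean(dCt)` over the
#' calibrator group, and the relative quantity is `RQ = 2^-ddCt`, so the
#' calibrator group's geometric-mean RQ is 1 by construction.
#'
#' @param ct data.frame with columns sample, group, gene, rep, ct
#'   (long-format Ct table; `Ct > 0`).
#' @param housekeeping ids of >= 3 reference genes, present for every
#'   sample.
#' @param calibrator_group group whose mean dCt defines ddCt = 0; defaults
#'   to the alphabetically first group.
#' @return an `expression_result` data.frame: sample, group, gene, dct,
#'   ddct, rq (target genes only), with the calibrator recorded as an
#'   attribute.
#' @export
ddct <- function(ct, housekeeping = c("actb", "rn18s", "gapdh"),
                 calibrator_group = NULL) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  if (length(housekeeping) < 3L)
    stop("at least 3 housekeeping genes are required")
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (is.null(calibrator_group)) calibrator_group <- sort(unique(ct$group))[1]
  if (!calibrator_group %in% ct$group) stop("empty calibrator group")

  ## technical replicates -> one Ct per (sample, gene)
  m <- stats::aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  for (s in unique(m$sample)) {
    miss <- setdiff(housekeeping, m$gene[m$sample == s])
    if (length(miss))
      stop("sample ", s, " is missing housekeeping gene(s): ",
           paste(miss, collapse = ", "))
  }
  hk <- m[m$gene %in% housekeeping, , drop = FALSE]
  ref <- stats::aggregate(ct ~ sample, data = hk, FUN = mean)
  names(ref)[2] <- "ct_ref"
  tg <- m[!m$gene %in% housekeeping, , drop = FALSE]
  tg <- merge(tg, ref, by = "sample")
  tg$dct <- tg$ct - tg$ct_ref
  cal <- stats::aggregate(dct ~ gene, data = tg[tg$group == calibrator_group, ],
                          FUN = mean)
  names(cal)[2] <- "dct_cal"
  tg <- merge(tg, cal, by = "gene")
  tg$ddct <- tg$dct - tg$dct_cal
  tg$rq <- 2^(-tg$ddct)
  out <- tg[order(tg$gene, tg$group, tg$sample),
            c("sample", "group", "gene", "dct", "ddct", "rq")]
  rownames(out) <- NULL
  attr(out, "calibrator_group") <- calibrator_group
  attr(out, "housekeeping") <- housekeeping
  class(out) <- c("expression_result", "data.frame")
  out
}

## compact-letter display from a logical "differs" matrix: groups sharing at
## least one letter are not significantly different
.significance_letters <- function(group_names, differs) {
  k <- length(group_names)
  sets <- list(seq_len(k))  # candidate letter groups, refined by splitting
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!differs[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
        } else new_sets <- c(new_sets, list(s))
      }
      ## drop sets contained in another
      keep <- vapply(seq_along(new_sets), function(a)
        !any(vapply(seq_along(new_sets), function(b)
          a != b && all(new_sets[[a]] %in% new_sets[[b]]), logical(1))),
        logical(1))
      sets <- unique(new_sets[keep])
    }
  }
  letters_out <- rep("", k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  stats::setNames(letters_out, group_names)
}

#' Group summaries, ANOVA and pairwise Welch tests for expression results
#'
#' Reports mean +/- SD of the relative quantity per group and gene, a
#' one-way ANOVA F test across groups, unadjusted pairwise Welch t-tests,
#' and compact significance letters at alpha = 0.05 (groups sharing a
#' letter are not significantly different). Groups with a single sample are
#' dropped from the tests with a warning.
#'
#' @param result an `expression_result` from [ddct()].
#' @param alpha significance level for the letters.
#' @return list with `summary` (gene, group, n, mean, sd, letter),
#'   `anova` (gene, f, p) and `pairwise` (gene, group1, group2, p).
#' @export
group_summary <- function(result, alpha = 0.05) {
  out_sum <- list(); out_aov <- list(); out_pw <- list()
  for (gene in unique(result$gene)) {
    d <- result[result$gene == gene, , drop = FALSE]
    sizes <- table(d$group)
    if (any(sizes < 2L)) {
      warning("dropping single-sample group(s) for ", gene, ": ",
              paste(names(sizes)[sizes < 2L], collapse = ", "))
      d <- d[d$group %in% names(sizes)[sizes >= 2L], , drop = FALSE]
    }
    groups <- sort(unique(d$group))
    if (length(groups) < 2L) next
    fit <- stats::anova(stats::lm(rq ~ group, data = d))
    out_aov[[gene]] <- data.frame(gene = gene, f = fit$`F value`[1],
                                  p = fit$`Pr(>F)`[1])
    differs <- matrix(FALSE, length(groups), length(groups))
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in (i + 1L):length(groups)) {
        x <- d$rq[d$group == groups[i]]; y <- d$rq[d$group == groups[j]]
        p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
        } else stats::t.test(x, y)$p.value
        out_pw[[length(out_pw) + 1L]] <- data.frame(
          gene = gene, group1 = groups[i], group2 = groups[j], p = p)
        differs[i, j] <- differs[j, i] <- p < alpha
      }
    }
    lts <- .significance_letters(groups, differs)
    out_sum[[gene]] <- data.frame(
      gene = gene, group = groups,
      n = as.integer(table(d$group)[groups]),
      mean = vapply(groups, function(g) mean(d$rq[d$group == g]), numeric(1)),
      sd = vapply(groups, function(g) stats::sd(d$rq[d$group == g]), numeric(1)),
      letter = lts[groups], row.names = NULL)
  }
  list(summary = do.call(rbind, c(out_sum, list(make.row.names = FALSE))),
       anova = do.call(rbind, c(out_aov, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(out_pw, list(make.row.names = FALSE))))
}
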