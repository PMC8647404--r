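#' Principal component analysis of a genotype matrix
#'
#' Standard variance-standardized genotype PCA: monomorphic variants are
#' dropped, missing entries are imputed to the variant mean dosage, each
#' variant is centered by `2*p` and scaled by `sqrt(2*p*(1-p))` (`p` the
#' alternate-allele frequency from non-missing calls), the sample kinship
#' matrix is the scaled matrix times its transpose over the variant count,
#' and coordinates are the top-k eigenvectors scaled by the square root of
#' their eigenvalues. The sign of each PC is fixed by forcing its
#' largest-magnitude loading positive, for reproducible output.
#'
#' @param M samples x variants dosage matrix (0/1/2, NA missing).
#' @param k number of components (must be < number of samples).
#' @return a `pca_result`: list with `coordinates` (samples x k),
#'   `eigenvalues` (all, non-increasing), `variance_fraction`, and
#'   `kinship_trace`.
#' @export
genotype_pca <- function(M, k = 2L) {
  if (k >= nrow(M)) stop("k must be smaller than the sample count")
  p <- colMeans(M, na.rm = TRUE) / 2
  v <- colMeans(M * M, na.rm = TRUE) - colMeans(M, na.rm = TRUE)^2
  poly <- !is.na(p) & p > 0 & p < 1 & v > 0
  if (sum(poly) < 2L) stop("need at least 2 polymorphic variants")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(M, 2L, 2 * p)
  X[is.na(X)] <- 0  # mean imputation after centering
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(X) / ncol(X)
  e <- eigen(K, symmetric = TRUE)
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  coords <- sweep(vecs, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  rownames(coords) <- rownames(M)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 variance_fraction = pmax(e$values, 0) / sum(pmax(e$values, 0)),
                 kinship_trace = sum(diag(K))), class = "pca_result")
}

#' Allele-sharing distance matrix
#'
#' `d(i, j)` is the mean of `|g_i - g_j| / 2` over the sites where both
#' samples are called: 0 for identical genotypes everywhere, 1 for opposite
#' homozygotes everywhere. Symmetric with a zero diagonal.
#'
#' @param M samples x variants dosage matrix (0/1/2, NA missing).
#' @return symmetric numeric matrix with sample dimnames.
#' @export
distance_matrix <- function(M) {
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 samples")
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !is.na(M[i, ]) & !is.na(M[j, ])
      if (!any(shared))
        stop("samples ", rownames(M)[i], " and ", rownames(M)[j],
             " share no called sites")
      D[i, j] <- D[j, i] <- mean(abs(M[i, shared] - M[j, shared])) / 2
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via the standard implementation in \pkg{ape});
#' for an additive distance matrix the tree's path lengths reproduce the
#' input exactly. Negative branch-length estimates, which NJ can produce on
#' noisy matrices, are clamped to zero with the deficit transferred to the
#' sibling edge so path lengths through the parent node are preserved; the
#' affected edge count is attached as attribute `n_clamped`.
#'
#' @param D symmetric zero-diagonal distance matrix over >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(D)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
  }
  attr(tr, "n_clamped") <- length(neg)
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples variants (columns) with replacement, rebuilds the
#' allele-sharing distance and the NJ tree for each replicate, and reports
#' for every internal edge of the full-data tree the percentage of
#' replicates containing the same bipartition (stored as `node.label`).
#'
#' @param M samples x variants dosage matrix.
#' @param n_reps bootstrap replicates (0 returns the full-data tree with no
#'   supports).
#' @param seed integer seed making the resampling deterministic.
#' @return a `phylo` tree; with `n_reps > 0`, internal node labels hold
#'   bootstrap percentages in \[0, 100\].
#' @export
bootstrap_tree <- function(M, n_reps = 1000L, seed = 1L) {
  full <- neighbor_joining(distance_matrix(M))
  if (n_reps == 0L) return(full)
  set.seed(seed)
  counts <- ape::boot.phylo(full, M,
                            function(x) neighbor_joining(distance_matrix(x)),
                            B = n_reps, quiet = TRUE, rooted = FALSE)
  full$node.label <- round(100 * counts / n_reps, 1)
  full
}

#' Write / read a tree in Newick format
#'
#' Serialization keeps branch lengths and bootstrap supports (as internal
#' node labels); `read_newick(write_newick(t))` preserves topology, lengths
#' and supports.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns a
#'   `phylo` and raises a parse error on malformed input.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("write_newick expects a phylo tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}
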