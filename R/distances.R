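#' Observed (P) distance matrix
#'
#' Entry (i, j) is the fraction of sites at which both taxa are non-missing
#' and differ (pairwise deletion of missing cells).
#'
#' @param aln an [alignment()] with >= 2 taxa.
#' @return Symmetric matrix with zero diagonal and taxa dimnames.
#' @export
p_distance_matrix <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least two taxa")
  alph <- aln_alphabet(aln)
  mat <- unclass(aln)
  obs <- !(matrix(mat %in% alph$missing, nrow = nrow(mat)))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- obs[i, ] & obs[j, ]
    if (!any(comp)) stop("no comparable sites between ", rownames(mat)[i],
                         " and ", rownames(mat)[j])
    D[i, j] <- D[j, i] <- sum(mat[i, comp] != mat[j, comp]) / sum(comp)
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion (via `ape::nj`);
#' deterministic given the matrix (ape resolves ties by the first minimal
#' pair in scan order).
#'
#' @param dist symmetric matrix with zero diagonal, >= 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!isSymmetric(unname(as.matrix(dist)), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (nrow(as.matrix(dist)) < 3L) stop("need at least three taxa")
  ape::nj(as.matrix(dist))
}

#' Patristic (tip-to-tip path) distances of a tree
#'
#' @param tree `phylo` tree with branch lengths.
#' @return Symmetric matrix of tip-to-tip path lengths.
#' @export
patristic <- function(tree) {
  stats::cophenetic(validate_tree(tree))
}

#' Saturation index from matched distance matrices
#'
#' Through-origin regression of observed-tree distances on model-tree
#' distances over all unordered taxon pairs: slope
#' `M = sum(x * y) / sum(x^2)` with `x` the model-tree patristic distances
#' and `y` the observed (NJ) distances; saturation is `Sat = 1 - M`.
#'
#' @param model_tree_dists,nj_dists symmetric matrices over the same taxa
#'   (`x` and `y` respectively).
#' @return List of class `"saturation_result"`: `M`, `sat`, `n_pairs`.
#' @export
saturation_index <- function(model_tree_dists, nj_dists) {
  x <- as.matrix(model_tree_dists); y <- as.matrix(nj_dists)
  if (!setequal(rownames(x), rownames(y)))
    stop("matrices must cover the same taxa")
  y <- y[rownames(x), rownames(x)]
  ut <- upper.tri(x)
  xv <- x[ut]; yv <- y[ut]
  if (all(xv == 0)) stop("model-tree distances are all zero")
  M <- sum(xv * yv) / sum(xv * xv)
  structure(list(M = M, sat = 1 - M, n_pairs = length(xv)),
            class = "saturation_result")
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf("Saturation: M = %.4f, Sat = %.4f over %d pairs\n",
              x$M, x$sat, x$n_pairs))
  invisible(x)
}

#' Saturation of an alignment against a reference tree
#'
#' Convenience wrapper reproducing the full procedure: NJ tree from P
#' distances, patristic distances from both trees, then [saturation_index()].
#'
#' @param aln an [alignment()].
#' @param model_tree reference (model-based) tree over the same taxa.
#' @return A `saturation_result`.
#' @export
alignment_saturation <- function(aln, model_tree) {
  nj <- nj_tree(p_distance_matrix(aln))
  nj$edge.length[nj$edge.length < 0] <- 0  # NJ can emit tiny negatives
  saturation_index(patristic(model_tree), patristic(nj))
}
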