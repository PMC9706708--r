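# ---- Fitch parsimony --------------------------------------------------------

# integer state-set masks per taxon per pattern; missing = full set
.fitch_masks <- function(aln) {
  alph <- aln_alphabet(aln)
  k <- length(alph$symbols)
  full <- bitwShiftL(1L, k) - 1L
  mat <- unclass(aln)
  code <- matrix(match(mat, alph$symbols), nrow = nrow(mat))
  masks <- matrix(full, nrow(mat), ncol(mat))
  obs <- !is.na(code)
  masks[obs] <- bitwShiftL(1L, code[obs] - 1L)
  rownames(masks) <- rownames(mat)
  masks
}

#' Fitch parsimony tree length
#'
#' Minimum number of state changes of the alignment on the tree, summed over
#' sites, by Fitch's post-order union/intersection rule for unordered states.
#' Missing symbols are treated as the full state set. Internal nodes with more
#' than two children are combined pairwise in child order.
#'
#' @param aln an [alignment()].
#' @param tree `phylo` tree whose leaves match the alignment taxa.
#' @return Integer number of parsimony steps.
#' @export
fitch_length <- function(aln, tree) {
  prep <- .prep_tree(tree, rownames(aln))
  masks <- .fitch_masks(aln)
  # compress patterns for speed
  key <- apply(masks, 2L, paste, collapse = ",")
  fac <- factor(key, levels = unique(key))
  w <- tabulate(as.integer(fac), nbins = nlevels(fac))
  masks <- masks[, match(levels(fac), key), drop = FALSE]

  node_mask <- matrix(NA_integer_, prep$n_nodes, ncol(masks))
  node_mask[seq_len(prep$ntip), ] <- masks
  cost <- numeric(ncol(masks))
  for (e in seq_along(prep$edge_child)) {
    child <- prep$edge_child[e] + 1L
    parent <- prep$edge_parent[e] + 1L
    cm <- node_mask[child, ]
    pm <- node_mask[parent, ]
    if (anyNA(pm)) {
      node_mask[parent, ] <- cm
    } else {
      inter <- bitwAnd(pm, cm)
      zero <- inter == 0L
      inter[zero] <- bitwOr(pm[zero], cm[zero])
      cost <- cost + zero
      node_mask[parent, ] <- inter
    }
  }
  as.integer(sum(cost * w))
}

#' Heuristic parsimony search
#'
#' Best tree length over random stepwise-addition starts, each refined by
#' nearest-neighbour-interchange to a local optimum; a single best tree is
#' retained. Reproducible given the RNG state.
#'
#' @param aln an [alignment()] with >= 4 taxa.
#' @param n_random_additions number of random-addition starts.
#' @return List with `tree`, `length` (parsimony steps) and
#'   `n_random_additions`.
#' @export
parsimony_search <- function(aln, n_random_additions = 10L) {
  taxa <- rownames(aln)
  if (length(taxa) < 4L) stop("need at least four taxa")
  best_tree <- NULL; best_len <- Inf
  for (s in seq_len(n_random_additions)) {
    ord <- sample(taxa)
    tr <- .stepwise_addition(aln, ord)
    res <- .nni_refine(aln, tr)
    if (res$length < best_len) { best_len <- res$length; best_tree <- res$tree }
  }
  list(tree = best_tree, length = as.integer(best_len),
       n_random_additions = n_random_additions)
}

.stepwise_addition <- function(aln, ord) {
  nwk <- sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3])
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  for (i in seq_along(ord)[-(1:3)]) {
    taxon <- ord[i]
    sub <- alignment(unclass(aln)[c(tr$tip.label, taxon), , drop = FALSE],
                     aln_alphabet(aln))
    best <- Inf; best_tr <- NULL
    for (e in seq_len(nrow(tr$edge))) {
      cand <- ape::bind.tree(tr, .single_tip(taxon), where = tr$edge[e, 2],
                             position = 0.5)
      cand$edge.length <- rep(1, nrow(cand$edge))
      len <- fitch_length(sub, cand)
      if (len < best) { best <- len; best_tr <- cand }
    }
    tr <- best_tr
  }
  tr
}

.single_tip <- function(label) {
  ape::read.tree(text = sprintf("(%s:1);", label))
}

.nni_refine <- function(aln, tree) {
  len <- fitch_length(aln, tree)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (nb in .nni_neighbours(tree)) {
      l2 <- fitch_length(aln, nb)
      if (l2 < len) { len <- l2; tree <- nb; improved <- TRUE; break }
    }
  }
  list(tree = tree, length = len)
}

# all NNI rearrangements around internal edges of an unrooted binary tree
.nni_neighbours <- function(tree) {
  if (length(tree$tip.label) < 4L) return(list())
  nb <- phangorn::nni(ape::unroot(tree))
  if (inherits(nb, "phylo")) list(nb)
  else lapply(seq_along(nb), function(i) nb[[i]])  # expands shared tip labels
}

#' Percent information loss between two parsimony tree lengths
#'
#' `100 * (len_source - len_recoded) / len_source`: the share of inferred
#' substitutions masked by the recoding.
#'
#' @param len_source parsimony steps of the source (amino-acid) data (> 0).
#' @param len_recoded parsimony steps of the recoded data.
#' @return Percent.
#' @export
information_loss <- function(len_source, len_recoded) {
  if (len_source <= 0) stop("source tree length must be positive")
  100 * (len_source - len_recoded) / len_source
}

#' Parsimony steps per site
#'
#' Best heuristic parsimony tree length divided by the number of sites,
#' approximating the number of substitutions per site.
#'
#' @inheritParams parsimony_search
#' @return Numeric steps per site.
#' @export
persite_substitutions <- function(aln, n_random_additions = 5L) {
  if (nrow(aln) == 2L) {
    # forced two-taxon case: the single branch carries all differences
    alph <- aln_alphabet(aln)
    m <- unclass(aln)
    ok <- !(m[1, ] %in% alph$missing) & !(m[2, ] %in% alph$missing)
    return(sum(m[1, ok] != m[2, ok]) / ncol(aln))
  }
  res <- parsimony_search(aln, n_random_additions)
  res$length / ncol(aln)
}

#' Per-branch parsimony step counts and loss map
#'
#' Counts state changes per branch from a single deterministic minimal-change
#' reconstruction (Fitch traceback: the root takes the lowest-index state in
#' its down-pass set; every other node takes its parent's state when that
#' state is in its own down-pass set, and the lowest-index member otherwise).
#' The per-branch loss map is `100 * (steps_source - steps_recoded) /
#' steps_source`, with zero-step source branches flagged as `NA`.
#'
#' @param aln_source,aln_recoded alignments over the source and recoded
#'   alphabets, sharing taxa.
#' @param topology fixed `phylo` tree.
#' @return Data frame with one row per branch: `edge`, `steps_source`,
#'   `steps_recoded`, `loss_percent`.
#' @export
branch_loss_map <- function(aln_source, aln_recoded, topology) {
  if (!setequal(rownames(aln_source), rownames(aln_recoded)))
    stop("alignments do not share taxa")
  s1 <- .branch_steps(aln_source, topology)
  s2 <- .branch_steps(aln_recoded, topology)
  loss <- ifelse(s1 > 0, 100 * (s1 - s2) / s1, NA_real_)
  data.frame(edge = seq_along(s1), steps_source = s1, steps_recoded = s2,
             loss_percent = loss)
}

# per-branch changes of the deterministic Fitch reconstruction; branch order
# follows the postorder prep of the (unrooted) topology
.branch_steps <- function(aln, tree) {
  prep <- .prep_tree(tree, rownames(aln))
  masks <- .fitch_masks(aln)
  n_pat <- ncol(masks)
  node_mask <- matrix(NA_integer_, prep$n_nodes, n_pat)
  node_mask[seq_len(prep$ntip), ] <- masks
  for (e in seq_along(prep$edge_child)) {
    child <- prep$edge_child[e] + 1L
    parent <- prep$edge_parent[e] + 1L
    cm <- node_mask[child, ]; pm <- node_mask[parent, ]
    if (anyNA(pm)) node_mask[parent, ] <- cm
    else {
      inter <- bitwAnd(pm, cm)
      zero <- inter == 0L
      inter[zero] <- bitwOr(pm[zero], cm[zero])
      node_mask[parent, ] <- inter
    }
  }
  lowest_bit <- function(m) {
    out <- integer(length(m))
    for (b in 0:30) {
      sel <- out == 0L & bitwAnd(m, bitwShiftL(1L, b)) != 0L
      out[sel] <- bitwShiftL(1L, b)
    }
    out
  }
  root <- prep$root + 1L
  state <- matrix(0L, prep$n_nodes, n_pat)
  # root state: the state present in the most root-children down-pass sets
  # (exact at the basal trifurcation), lowest index on ties
  root_children <- prep$edge_child[prep$edge_parent + 1L == root] + 1L
  k <- length(aln_alphabet(aln)$symbols)
  best_cnt <- rep(-1L, n_pat); best_state <- integer(n_pat)
  for (b in seq_len(k) - 1L) {
    bit <- bitwShiftL(1L, b)
    cnt <- integer(n_pat)
    for (ch in root_children)
      cnt <- cnt + (bitwAnd(node_mask[ch, ], bit) != 0L)
    better <- cnt > best_cnt
    best_cnt[better] <- cnt[better]
    best_state[better] <- bit
  }
  state[root, ] <- best_state
  steps <- numeric(length(prep$edge_child))
  for (e in rev(seq_along(prep$edge_child))) {  # preorder
    child <- prep$edge_child[e] + 1L
    parent <- prep$edge_parent[e] + 1L
    ps <- state[parent, ]
    cm <- node_mask[child, ]
    keep <- bitwAnd(cm, ps) != 0L
    cs <- integer(n_pat)
    cs[keep] <- ps[keep]
    cs[!keep] <- lowest_bit(cm[!keep])
    state[child, ] <- cs
    steps[e] <- sum(cs != ps)
  }
  steps
}
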