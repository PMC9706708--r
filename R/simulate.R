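#' Simulate an alignment under a profile-mixture model
#'
#' Per site: a mixture category is drawn from the category weights, a rate
#' from the discrete Gamma categories (or the continuous Gamma when
#' `continuous_gamma = TRUE`), the root state from the category's stationary
#' profile, and states are then evolved along every branch with transition
#' probabilities `expm(Q_c * r * t)`. The process is reversible, so root
#' placement does not affect the distribution; the tree is rooted at its
#' first internal node for the traversal.
#'
#' @param tree `phylo` tree with branch lengths in expected substitutions per
#'   site.
#' @param model a [mixture_model()].
#' @param n_sites number of sites to simulate.
#' @param alph alphabet used to label states (defaults to amino acids for
#'   k = 20, bin labels for other k).
#' @param continuous_gamma draw site rates from the continuous Gamma instead
#'   of the discrete categories.
#' @return An [alignment()] with the tree's leaf labels as taxa.
#' @export
simulate_alignment <- function(tree, model, n_sites,
                               alph = NULL, continuous_gamma = FALSE) {
  if (n_sites < 1L) stop("n_sites must be positive")
  k <- model$k
  if (is.null(alph))
    alph <- if (k == 20L) aa_alphabet() else recoded_alphabet(k)
  if (length(alph$symbols) != k) stop("alphabet size does not match model k")
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least two leaves")

  C <- nrow(model$profiles)
  cat_of_site <- sample.int(C, n_sites, replace = TRUE, prob = model$weights)
  rate_of_site <- if (continuous_gamma) {
    stats::rgamma(n_sites, shape = model$alpha, rate = model$alpha)
  } else {
    r <- gamma_rates(model$alpha, model$n_rate_cats)
    r[sample.int(length(r), n_sites, replace = TRUE)]
  }

  edge <- tree$edge
  elen <- tree$edge.length
  n_nodes <- max(edge)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  # preorder: parents before children
  ord <- order(.preorder_rank(edge, root))

  states <- matrix(0L, n_nodes, n_sites)
  eig <- lapply(seq_len(C), function(c) eigen_q(q_matrix(model, c)))
  for (c in seq_len(C)) {
    idx <- which(cat_of_site == c)
    if (!length(idx)) next
    states[root, idx] <- sample.int(k, length(idx), replace = TRUE,
                                    prob = model$profiles[c, ])
  }
  rate_groups <- split(seq_len(n_sites), cat_of_site)
  for (e in ord) {
    par <- edge[e, 1]; child <- edge[e, 2]; t_e <- elen[e]
    for (c in seq_len(C)) {
      idx <- rate_groups[[as.character(c)]]
      if (is.null(idx) || !length(idx)) next
      # group sites of this category by (discrete) rate for shared P matrices
      rr <- rate_of_site[idx]
      for (r in unique(rr)) {
        ii <- idx[rr == r]
        P <- p_matrix(eig[[c]], r * t_e)
        prev <- states[par, ii]
        nxt <- integer(length(ii))
        for (s in unique(prev)) {
          sel <- prev == s
          nxt[sel] <- sample.int(k, sum(sel), replace = TRUE, prob = P[s, ])
        }
        states[child, ii] <- nxt
      }
    }
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  mat <- matrix(alph$symbols[tips], nrow = ntip)
  rownames(mat) <- tree$tip.label
  alignment(mat, alph)
}

.preorder_rank <- function(edge, root) {
  # rank edges so that an edge is visited after the edge leading to its parent
  parent_edge <- match(edge[, 1], edge[, 2])  # NA for root's children
  rank <- rep(NA_integer_, nrow(edge))
  depth <- function(e) {
    if (!is.na(rank[e])) return(rank[e])
    pe <- parent_edge[e]
    r <- if (is.na(pe)) 0L else depth(pe) + 1L
    rank[e] <<- r
    r
  }
  for (e in seq_len(nrow(edge))) depth(e)
  rank
}

#' Eigen machinery for reversible rate matrices
#'
#' Decomposes a reversible `Q` (with stationary distribution `pi`) through the
#' symmetric similarity transform, giving real eigenvalues and stable
#' transition probabilities `p_matrix(eig, t)`.
#'
#' @param Q rate matrix with rows summing to zero.
#' @return List with eigenvalues and transform matrices.
#' @keywords internal
#' @export
eigen_q <- function(Q) {
  k <- nrow(Q)
  # stationary distribution: for Q = rho diag(pi) with symmetric rho, pi is
  # recoverable from the off-diagonal ratios; solve generally via null space
  pi_st <- .stationary(Q)
  s <- sqrt(pi_st)
  S <- diag(s) %*% Q %*% diag(1 / s)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(values = es$values,
       right = diag(1 / s) %*% es$vectors,
       left = t(es$vectors) %*% diag(s),
       pi = pi_st)
}

.stationary <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_st <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi_st <- pmax(pi_st, 1e-12)
  pi_st / sum(pi_st)
}

#' @rdname eigen_q
#' @param eig result of [eigen_q()].
#' @param t branch length (rate x time).
#' @export
p_matrix <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Generate a suite of simulated fixtures
#'
#' Simulates replicate alignments for each condition (hypothesis x number of
#' sites x number of taxa) under a shared generating model, writing files and
#' a manifest when `dir` is given, or returning the objects in memory.
#'
#' @param conditions data frame with columns `hypothesis`, `n_sites`,
#'   `n_taxa`; one row per condition.
#' @param n_replicates replicates per condition.
#' @param model generating [mixture_model()]; default [default_study_model()].
#' @param tree_params named list passed to [zone_tree()] (branch lengths).
#' @param dir optional output directory; alignments are written as FASTA and
#'   a `manifest.csv` records hypothesis, sizes, file and the RNG seed used
#'   for each replicate.
#' @param seed master seed; per-replicate seeds are derived from it so every
#'   alignment is independently reproducible.
#' @return Invisibly, a list with `manifest` (data frame) and, when `dir` is
#'   `NULL`, `alignments` and `trees` lists keyed by dataset id.
#' @export
make_fixture_suite <- function(conditions, n_replicates = 2L,
                               model = NULL, tree_params = list(),
                               dir = NULL, seed = 1L) {
  if (is.null(model)) {
    set.seed(seed)
    model <- default_study_model()
  }
  rows <- list(); alns <- list(); trees <- list()
  id <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    tr <- do.call(zone_tree, c(list(hypothesis = cond$hypothesis,
                                    n_taxa = cond$n_taxa), tree_params))
    for (rep in seq_len(n_replicates)) {
      id <- id + 1L
      rep_seed <- (seed * 10000L + id) %% .Machine$integer.max
      set.seed(rep_seed)
      aln <- simulate_alignment(tr, model, cond$n_sites)
      ds <- sprintf("%s_s%d_t%d_r%02d", substr(cond$hypothesis, 1, 4),
                    cond$n_sites, cond$n_taxa, rep)
      rows[[id]] <- data.frame(dataset = ds, hypothesis = cond$hypothesis,
                               n_sites = cond$n_sites, n_taxa = cond$n_taxa,
                               replicate = rep, seed = rep_seed,
                               stringsAsFactors = FALSE)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        f <- file.path(dir, paste0(ds, ".fasta"))
        write_alignment(aln, f)
        rows[[id]]$file <- basename(f)
      } else {
        alns[[ds]] <- aln; trees[[ds]] <- tr
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  invisible(list(manifest = manifest, alignments = alns, trees = trees))
}

#' Subsample alignment sites without replacement
#'
#' Draws `n_sites` distinct columns (each site used at most once per
#' subsampled dataset) in increasing positional order.
#'
#' @param aln an [alignment()].
#' @param n_sites number of sites to keep.
#' @return A smaller [alignment()].
#' @export
subsample_sites <- function(aln, n_sites) {
  if (n_sites > ncol(aln)) stop("cannot subsample more sites than available")
  keep <- sort(sample.int(ncol(aln), n_sites))
  alignment(unclass(aln)[, keep, drop = FALSE], aln_alphabet(aln))
}
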