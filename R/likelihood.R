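# ---- internal machinery -----------------------------------------------------

# site-pattern compression: integer tip states 0..k-1, k = missing
.encode_patterns <- function(aln) {
  alph <- aln_alphabet(aln)
  k <- length(alph$symbols)
  mat <- unclass(aln)
  code <- matrix(match(mat, alph$symbols) - 1L, nrow = nrow(mat))
  code[is.na(code)] <- k
  key <- apply(code, 2L, paste, collapse = ",")
  fac <- factor(key, levels = unique(key))
  idx <- as.integer(fac)
  first <- match(levels(fac), key)
  tips <- code[, first, drop = FALSE]
  rownames(tips) <- rownames(mat)
  list(tips = tips, weights = as.numeric(tabulate(idx, nbins = length(first))),
       pattern_of_site = idx, k = k)
}

# postorder traversal structures for a tree, matched to alignment taxa order
.prep_tree <- function(tree, taxa) {
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  if (!setequal(tree$tip.label, taxa))
    stop("tree leaves do not match alignment taxa")
  ntip <- length(tree$tip.label)
  # tip node i corresponds to row of `taxa`; remap tip indices so that node
  # j-1 (0-based) is taxa[j]
  tip_map <- match(tree$tip.label, taxa)  # node i -> taxa row
  edge <- tree$edge
  relab <- function(v) ifelse(v <= ntip, tip_map[v], v)
  edge <- cbind(relab(edge[, 1]), relab(edge[, 2]))
  root <- setdiff(edge[, 1], edge[, 2])[1]
  list(tree = tree, ntip = ntip,
       edge_child = as.integer(edge[, 2] - 1L),
       edge_parent = as.integer(edge[, 1] - 1L),
       n_nodes = max(edge), root = as.integer(root - 1L))
}

# per-pattern log-likelihoods given traversal prep, branch lengths in the
# prep's postorder edge order, and a mixture model
.loglik_patterns <- function(pat, prep, blen, model) {
  G <- model$n_rate_cats
  rates <- gamma_rates(model$alpha, G)
  lw <- log(model$weights)
  if (model$poisson) {
    plik_f81(pat$tips, prep$edge_child, prep$edge_parent, prep$n_nodes,
             prep$root, blen, model$profiles, lw, rates)
  } else {
    C <- nrow(model$profiles)
    eig <- lapply(seq_len(C), function(c) eigen_q(q_matrix(model, c)))
    P_by_combo <- vector("list", C * G)
    for (c in seq_len(C)) for (g in seq_len(G)) {
      P_by_combo[[(c - 1L) * G + g]] <-
        lapply(blen, function(t) p_matrix(eig[[c]], rates[g] * t))
    }
    plik_pmat(pat$tips, prep$edge_child, prep$edge_parent, prep$n_nodes,
              prep$root, P_by_combo, model$profiles, lw, G)
  }
}

# ---- public surface ---------------------------------------------------------

#' Mixture-model site likelihoods by pruning
#'
#' Computes per-site log-likelihoods of an alignment on a tree under a
#' [mixture_model()]: each site's likelihood is the weighted sum over profile
#' categories and discrete Gamma rates of the pruning likelihood, with missing
#' symbols contributing a vector of ones at the leaf. Site patterns are
#' compressed before computation.
#'
#' @param aln an [alignment()].
#' @param tree `phylo` tree whose leaves match the alignment taxa.
#' @param model a [mixture_model()] with `k` equal to the alphabet size.
#' @return List with `log_likelihood` (sum of per-site values) and
#'   `per_site` (vector of per-site log-likelihoods in site order).
#' @export
site_likelihoods <- function(aln, tree, model) {
  pat <- .encode_patterns(aln)
  if (pat$k != model$k) stop("alphabet size does not match model k")
  prep <- .prep_tree(tree, rownames(aln))
  blen <- prep$tree$edge.length
  pl <- .loglik_patterns(pat, prep, blen, model)
  per_site <- pl[pat$pattern_of_site]
  list(log_likelihood = sum(pl * pat$weights), per_site = per_site)
}

#' Closed-form two-state-space helpers for the equal-rates (Poisson) chain
#'
#' For a k-state process with equal exchangeabilities and uniform frequencies,
#' the probability that two sequences at distance `t` differ at a site is
#' `(k-1)/k * (1 - exp(-k t/(k-1)))`, and the maximum-likelihood distance for
#' an observed difference fraction `p` is `-(k-1)/k * log(1 - k p/(k-1))`.
#'
#' @param t branch length (expected substitutions per site).
#' @param p observed fraction of differing sites.
#' @param k number of states.
#' @export
poisson_expected_diff <- function(t, k) (k - 1) / k * (1 - exp(-k * t / (k - 1)))

#' @rdname poisson_expected_diff
#' @export
poisson_ml_distance <- function(p, k) {
  if (any(p >= (k - 1) / k)) stop("difference fraction at or beyond saturation")
  -(k - 1) / k * log(1 - k * p / (k - 1))
}

#' Maximum-likelihood fitting on a fixed topology
#'
#' Coordinate ascent over branch lengths (one-dimensional optimisation per
#' branch), the Gamma shape, and family-specific free parameters:
#' * `poisson_g` - F81-type process with a single empirical frequency profile;
#' * `lg_g` - LG exchangeabilities with empirical frequencies;
#' * `gtr_g` - free symmetric exchangeabilities (optimised on log scale);
#' * `mix_n_g` - an `n_categories`-profile Poisson mixture; profiles are
#'   initialised by k-means on site frequency vectors and updated by a
#'   guarded expectation-maximisation step (weights in closed form from
#'   category responsibilities, profile moves accepted only when the observed
#'   log-likelihood does not decrease).
#'
#' Convergence is declared when a sweep improves the log-likelihood by less
#' than `tol`; non-convergence after `max_sweeps` is flagged, not an error.
#'
#' @param aln an [alignment()].
#' @param topology fixed `phylo` topology (branch lengths used as start
#'   values when positive).
#' @param model_family one of `"poisson_g"`, `"gtr_g"`, `"lg_g"`, `"mix_n_g"`.
#' @param n_categories mixture size for `mix_n_g`.
#' @param gamma fit discrete-Gamma rate variation (4 categories) when `TRUE`;
#'   a single rate otherwise.
#' @param n_rate_cats number of discrete Gamma categories.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum coordinate-ascent sweeps.
#' @return List with `log_likelihood`, `per_site`, fitted `model`, `tree`
#'   (fitted branch lengths), `alpha`, `converged`, `sweeps`.
#' @export
ml_fit <- function(aln, topology,
                   model_family = c("poisson_g", "gtr_g", "lg_g", "mix_n_g"),
                   n_categories = 2L, gamma = TRUE, n_rate_cats = 4L,
                   tol = 1e-4, max_sweeps = 25L) {
  model_family <- match.arg(model_family)
  pat <- .encode_patterns(aln)
  prep <- .prep_tree(topology, rownames(aln))
  k <- pat$k
  n_edge <- length(prep$edge_child)
  blen <- prep$tree$edge.length
  blen[!is.finite(blen) | blen <= 0] <- 0.05
  alpha <- 1
  G <- if (gamma) as.integer(n_rate_cats) else 1L

  emp <- .empirical_freqs(pat)
  rho <- switch(model_family,
    poisson_g = "poisson", mix_n_g = "poisson",
    lg_g = "lg", gtr_g = matrix(1, k, k))
  profiles <- switch(model_family,
    poisson_g = rbind(emp), lg_g = rbind(emp), gtr_g = rbind(emp),
    mix_n_g = .init_profiles(aln, pat, n_categories))
  weights <- rep(1 / nrow(profiles), nrow(profiles))
  build <- function(profiles, weights, alpha, rho)
    mixture_model(k, rho = rho, profiles = profiles, weights = weights,
                  alpha = alpha, n_rate_cats = G)
  model <- build(profiles, weights, alpha, rho)
  ll_fun <- function(blen, model) {
    sum(.loglik_patterns(pat, prep, blen, model) * pat$weights)
  }
  ll <- ll_fun(blen, model)
  converged <- FALSE; sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    ll_prev <- ll
    # branch lengths, optimised on the log scale so that the probe points
    # span magnitudes instead of sitting in the saturation plateau
    for (e in seq_len(n_edge)) {
      opt <- stats::optimize(function(x) {
        b <- blen; b[e] <- exp(x); ll_fun(b, model)
      }, interval = log(c(1e-8, 20)), maximum = TRUE, tol = 1e-6)
      if (opt$objective > ll) { blen[e] <- exp(opt$maximum)
                                ll <- opt$objective }
    }
    # Gamma shape
    if (gamma) {
      opt <- stats::optimize(function(a) {
        ll_fun(blen, build(model$profiles, model$weights, a, model$rho))
      }, interval = c(0.05, 50), maximum = TRUE, tol = 1e-4)
      if (opt$objective > ll) {
        alpha <- opt$maximum
        model <- build(model$profiles, model$weights, alpha, model$rho)
        ll <- opt$objective
      }
    }
    # family-specific free parameters
    if (model_family == "gtr_g" && sweep >= 2L) {
      up <- .update_gtr(pat, prep, blen, model, ll, build)
      model <- up$model; ll <- up$ll
    }
    if (model_family == "mix_n_g") {
      up <- .em_step(pat, prep, blen, model, ll, build)
      model <- up$model; ll <- up$ll
    }
    if (ll - ll_prev < tol) { converged <- TRUE; break }
  }
  tree_out <- prep$tree
  tree_out$edge.length <- blen
  pl <- .loglik_patterns(pat, prep, blen, model)
  list(log_likelihood = sum(pl * pat$weights),
       per_site = pl[pat$pattern_of_site],
       model = model, tree = tree_out, alpha = alpha,
       converged = converged, sweeps = sweep, family = model_family)
}

.empirical_freqs <- function(pat) {
  k <- pat$k
  counts <- numeric(k)
  for (i in seq_len(k))
    counts[i] <- sum((pat$tips == (i - 1L)) %*% pat$weights)
  counts <- counts + 0.5  # regularise: every state strictly positive
  counts / sum(counts)
}

.init_profiles <- function(aln, pat, n_categories) {
  k <- pat$k
  # per-site empirical frequency vectors over non-missing cells
  freqs <- t(apply(pat$tips, 2L, function(col) {
    tab <- tabulate(col[col < k] + 1L, nbins = k)
    if (sum(tab) == 0) rep(1 / k, k) else tab / sum(tab)
  }))
  freqs_full <- freqs[pat$pattern_of_site, , drop = FALSE]
  n_categories <- min(n_categories, nrow(unique(freqs_full)))
  km <- stats::kmeans(freqs_full, centers = n_categories, nstart = 1L)
  centers <- km$centers[order(km$centers[, 1], decreasing = TRUE), , drop = FALSE]
  centers <- centers + 1e-3
  centers / rowSums(centers)
}

# per-category, per-pattern log-likelihood matrix (C x n_patterns)
.percat_loglik <- function(pat, prep, blen, model) {
  C <- nrow(model$profiles)
  out <- matrix(0, C, length(pat$weights))
  for (c in seq_len(C)) {
    m1 <- mixture_model(model$k, rho = if (model$poisson) "poisson" else model$rho,
                        profiles = model$profiles[c, , drop = FALSE],
                        weights = 1, alpha = model$alpha,
                        n_rate_cats = model$n_rate_cats)
    out[c, ] <- .loglik_patterns(pat, prep, blen, m1)
  }
  out
}

.em_step <- function(pat, prep, blen, model, ll, build) {
  C <- nrow(model$profiles)
  lc <- .percat_loglik(pat, prep, blen, model)         # C x P
  lw <- lc + log(model$weights)
  mx <- apply(lw, 2L, max)
  resp <- exp(sweep(lw, 2L, mx))
  resp <- sweep(resp, 2L, colSums(resp), "/")          # responsibilities
  # weights: closed-form M-step
  w_new <- as.numeric(resp %*% pat$weights)
  w_new <- w_new / sum(w_new)
  model2 <- build(model$profiles, w_new, model$alpha, model$rho)
  ll2 <- sum(.loglik_patterns(pat, prep, blen, model2) * pat$weights)
  if (ll2 >= ll) { model <- model2; ll <- ll2 }
  # profiles: guarded moment update per category
  k <- model$k
  state_count <- matrix(0, k, length(pat$weights))
  for (i in seq_len(k))
    state_count[i, ] <- colSums(pat$tips == (i - 1L))
  for (c in seq_len(C)) {
    wsite <- resp[c, ] * pat$weights
    prof <- as.numeric(state_count %*% wsite)
    prof <- prof + 1e-2
    prof <- prof / sum(prof)
    newp <- model$profiles
    newp[c, ] <- prof
    model2 <- build(newp, model$weights, model$alpha, model$rho)
    ll2 <- sum(.loglik_patterns(pat, prep, blen, model2) * pat$weights)
    if (ll2 >= ll) { model <- model2; ll <- ll2 }
  }
  list(model = model, ll = ll)
}

.update_gtr <- function(pat, prep, blen, model, ll, build) {
  k <- model$k
  ut <- upper.tri(matrix(0, k, k))
  x0 <- log(model$rho[ut] + 1e-9)
  f <- function(x) {
    rho <- matrix(0, k, k)
    rho[ut] <- exp(x - mean(x))  # scale-free
    rho <- rho + t(rho)
    m <- build(model$profiles, model$weights, model$alpha, rho)
    -sum(.loglik_patterns(pat, prep, blen, m) * pat$weights)
  }
  opt <- stats::optim(x0, f, method = "L-BFGS-B",
                      control = list(maxit = 20L))
  if (-opt$value > ll) {
    rho <- matrix(0, k, k)
    rho[ut] <- exp(opt$par - mean(opt$par))
    rho <- rho + t(rho)
    model <- build(model$profiles, model$weights, model$alpha, rho)
    ll <- -opt$value
  }
  list(model = model, ll = ll)
}

#' Per-topology maximum-likelihood scores and bootstrap support
#'
#' Fits every candidate topology independently with [ml_fit()], then measures
#' support by the nonparametric bootstrap: site columns are resampled with
#' replacement, each candidate is refitted (warm-started from its full-data
#' fit), and a candidate's support is the proportion of replicates in which it
#' attains the best refitted score (exact ties broken uniformly at random).
#'
#' @param aln an [alignment()].
#' @param candidates list of >= 2 candidate `phylo` topologies.
#' @param model_family,n_categories,gamma passed to [ml_fit()].
#' @param n_bootstrap number of bootstrap replicates.
#' @param refit_sweeps coordinate-ascent sweeps per bootstrap refit.
#' @return List with `log_likelihoods`, `support` (sums to 1 over
#'   candidates), `fits` (full-data fits).
#' @export
topology_scan <- function(aln, candidates, model_family = "poisson_g",
                          n_categories = 2L, gamma = TRUE,
                          n_bootstrap = 100L, refit_sweeps = 2L) {
  if (length(candidates) < 2L) stop("need at least two candidate topologies")
  fits <- lapply(candidates, function(tr)
    ml_fit(aln, tr, model_family, n_categories = n_categories, gamma = gamma))
  n_sites <- ncol(aln)
  pat <- .encode_patterns(aln)
  preps <- lapply(fits, function(f) .prep_tree(f$tree, rownames(aln)))
  wins <- numeric(length(candidates))
  for (b in seq_len(n_bootstrap)) {
    draw <- sample.int(n_sites, n_sites, replace = TRUE)
    pcount <- tabulate(pat$pattern_of_site[draw], nbins = length(pat$weights))
    scores <- vapply(seq_along(fits), function(i) {
      .boot_refit(pat, preps[[i]], fits[[i]], pcount, refit_sweeps)
    }, numeric(1))
    best <- which(scores > max(scores) - 1e-9)
    w <- best[sample.int(length(best), 1L)]
    wins[w] <- wins[w] + 1
  }
  support <- wins / sum(wins)
  names(support) <- names(candidates)
  list(log_likelihoods = vapply(fits, `[[`, numeric(1), "log_likelihood"),
       support = support, fits = fits)
}

.boot_refit <- function(pat, prep, fit, pcount, sweeps) {
  pat2 <- pat; pat2$weights <- as.numeric(pcount)
  blen <- fit$tree$edge.length
  model <- fit$model
  ll_fun <- function(b) sum(.loglik_patterns(pat2, prep, b, model) * pat2$weights)
  ll <- ll_fun(blen)
  for (s in seq_len(sweeps)) {
    for (e in seq_along(blen)) {
      opt <- stats::optimize(function(x) { b <- blen; b[e] <- exp(x)
                                           ll_fun(b) },
                             interval = log(c(1e-8, 20)), maximum = TRUE,
                             tol = 1e-5)
      if (opt$objective > ll) { blen[e] <- exp(opt$maximum)
                                ll <- opt$objective }
    }
  }
  ll
}
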