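#' Chain settings for the Metropolis-Hastings sampler
#'
#' @param n_cycles total cycles; one cycle is a sweep of every move class.
#' @param burnin_cycles cycles discarded before recording.
#' @param subsample_every record every this-many post-burnin cycles.
#' @param branch_lambda,alpha_lambda multiplier-move window widths.
#' @param profile_conc,weight_conc Dirichlet proposal concentrations.
#' @param branch_moves_per_cycle number of branch-length moves per cycle
#'   (random subset of branches); `NULL` sweeps every branch.
#' @return A `chain_settings` list.
#' @export
chain_settings <- function(n_cycles = 500L, burnin_cycles = 200L,
                           subsample_every = 5L, branch_lambda = 1.2,
                           alpha_lambda = 0.6, profile_conc = 300,
                           weight_conc = 300, branch_moves_per_cycle = NULL) {
  if (burnin_cycles >= n_cycles) stop("burnin must be smaller than n_cycles")
  if (subsample_every < 1L) stop("subsample_every must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 burnin_cycles = as.integer(burnin_cycles),
                 subsample_every = as.integer(subsample_every),
                 branch_lambda = branch_lambda, alpha_lambda = alpha_lambda,
                 profile_conc = profile_conc, weight_conc = weight_conc,
                 branch_moves_per_cycle = branch_moves_per_cycle),
            class = "chain_settings")
}

# bipartition keys of the postorder edges of a prep (sorted tip labels below,
# canonicalised to the smaller side)
.edge_keys <- function(prep, taxa) {
  nt <- prep$ntip
  below <- vector("list", prep$n_nodes)
  for (i in seq_len(nt)) below[[i]] <- taxa[i]
  keys <- character(length(prep$edge_child))
  for (e in seq_along(prep$edge_child)) {
    child <- prep$edge_child[e] + 1L
    parent <- prep$edge_parent[e] + 1L
    below[[parent]] <- c(below[[parent]], below[[child]])
    side <- sort(below[[child]])
    other <- sort(setdiff(taxa, side))
    keys[e] <- if (length(side) < length(other) ||
                   (length(side) == length(other) && side[1] < other[1]))
      paste(side, collapse = "|") else paste(other, collapse = "|")
  }
  keys
}

# carry branch lengths from topology a to topology b: shared bipartitions map
# directly; leftover keys are paired in sorted order (deterministic)
.carry_blen <- function(blen, keys_from, keys_to) {
  out <- numeric(length(keys_to))
  m <- match(keys_to, keys_from)
  out[!is.na(m)] <- blen[m[!is.na(m)]]
  left_from <- setdiff(keys_from, keys_to)
  left_to <- setdiff(keys_to, keys_from)
  lf <- sort(left_from); lt <- sort(left_to)
  for (i in seq_along(lt))
    out[keys_to == lt[i]] <- blen[keys_from == lf[min(i, length(lf))]]
  out
}

#' Posterior sampling over candidate topologies
#'
#' Metropolis-Hastings sampler over an explicit candidate-topology list,
#' branch lengths, the Gamma shape, and mixture parameters. One cycle sweeps
#' every move class: a multiplier move on each branch length, a multiplier
#' move on alpha, Dirichlet proposals on the mixture weights and on one
#' frequency profile (for mixture families), and a uniform topology proposal
#' that carries branch lengths across topologies by matching bipartitions.
#' Mixture categories are marginalised analytically in the likelihood.
#'
#' Priors: exponential (mean 0.1) on branch lengths, exponential (mean 1) on
#' alpha, symmetric Dirichlet(1) on profiles and weights.
#'
#' @param aln an [alignment()].
#' @param candidates named list of candidate `phylo` topologies sharing the
#'   alignment's taxa.
#' @param model_family `"poisson_g"` or `"mix_n_g"`.
#' @param n_categories mixture size for `mix_n_g`.
#' @param settings a [chain_settings()].
#' @param n_rate_cats discrete Gamma categories.
#' @param init_blen initial branch length for every branch.
#' @param warm_start start the chain near a local optimum (one branch-length
#'   sweep, plus guarded expectation-maximisation steps on mixture profiles
#'   and weights); recommended for short chains.
#' @return List with `pp` (posterior probability per candidate), `samples`
#'   (list of posterior draws: `topology`, `tree`, `model`, `log_likelihood`),
#'   `trace` (data frame: cycle, log-likelihood, alpha, topology, seconds),
#'   `acceptance` (per move class), `settings`.
#' @export
sample_posterior <- function(aln, candidates, model_family = c("poisson_g", "mix_n_g"),
                             n_categories = 2L, settings = chain_settings(),
                             n_rate_cats = 4L, init_blen = 0.1,
                             warm_start = TRUE) {
  model_family <- match.arg(model_family)
  if (length(candidates) < 1L) stop("need at least one candidate")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("topology", seq_along(candidates))
  t0 <- proc.time()[["elapsed"]]
  pat <- .encode_patterns(aln)
  taxa <- rownames(aln)
  preps <- lapply(candidates, .prep_tree, taxa = taxa)
  keys <- lapply(preps, .edge_keys, taxa = taxa)
  k <- pat$k
  n_topo <- length(candidates)

  # state
  topo <- 1L
  blen <- rep(init_blen, length(preps[[1]]$edge_child))
  alpha <- 1
  C <- if (model_family == "poisson_g") 1L else as.integer(n_categories)
  profiles <- if (C == 1L) rbind(.empirical_freqs(pat))
              else .init_profiles(aln, pat, C)
  C <- nrow(profiles)
  weights <- rep(1 / C, C)
  build <- function(profiles, weights, alpha)
    mixture_model(k, rho = "poisson", profiles = profiles, weights = weights,
                  alpha = alpha, n_rate_cats = n_rate_cats)
  loglik <- function(topo, blen, model)
    sum(.loglik_patterns(pat, preps[[topo]], blen, model) * pat$weights)
  log_prior_b <- function(b) sum(stats::dexp(b, rate = 10, log = TRUE))

  model <- build(profiles, weights, alpha)
  ll <- loglik(topo, blen, model)
  if (!is.finite(ll)) stop("initial likelihood not finite")
  if (warm_start) {
    # branch-length sweep under a cheap single-profile surrogate, then
    # guarded EM steps, so mixture chains start near a local optimum
    # instead of at the raw k-means profiles
    cheap <- build(rbind(.empirical_freqs(pat)), 1, alpha)
    ll_cheap <- loglik(topo, blen, cheap)
    for (e in seq_along(blen)) {
      opt <- stats::optimize(function(x) { b <- blen; b[e] <- exp(x)
                                           loglik(topo, b, cheap) },
                             interval = log(c(1e-8, 20)), maximum = TRUE,
                             tol = 1e-4)
      if (opt$objective > ll_cheap) { blen[e] <- exp(opt$maximum)
                                      ll_cheap <- opt$objective }
    }
    ll <- loglik(topo, blen, model)
    if (C > 1L) {
      build4 <- function(p, w, a, rho) build(p, w, a)
      for (i in 1:2) {
        up <- .em_step(pat, preps[[topo]], blen, model, ll, build4)
        model <- up$model; ll <- up$ll
      }
      profiles <- model$profiles; weights <- model$weights
    }
  }
  lp_b <- log_prior_b(blen)

  acc <- c(branch = 0, alpha = 0, weights = 0, profile = 0, topology = 0)
  try_n <- c(branch = 0, alpha = 0, weights = 0, profile = 0, topology = 0)
  samples <- list()
  trace <- vector("list", settings$n_cycles)

  for (cyc in seq_len(settings$n_cycles)) {
    # branch-length multiplier moves (all branches, or a random subset when
    # branch_moves_per_cycle caps the sweep)
    bmax <- settings$branch_moves_per_cycle %||% length(blen)
    edges_now <- if (bmax >= length(blen)) seq_along(blen)
                 else sample.int(length(blen), bmax)
    for (e in edges_now) {
      try_n["branch"] <- try_n["branch"] + 1
      mult <- exp(settings$branch_lambda * (stats::runif(1) - 0.5))
      b2 <- blen; b2[e] <- blen[e] * mult
      ll2 <- loglik(topo, b2, model)
      lp2 <- log_prior_b(b2)
      if (log(stats::runif(1)) < ll2 - ll + lp2 - lp_b + log(mult)) {
        blen <- b2; ll <- ll2; lp_b <- lp2
        acc["branch"] <- acc["branch"] + 1
      }
    }
    # alpha multiplier
    try_n["alpha"] <- try_n["alpha"] + 1
    mult <- exp(settings$alpha_lambda * (stats::runif(1) - 0.5))
    a2 <- alpha * mult
    m2 <- build(profiles, weights, a2)
    ll2 <- loglik(topo, blen, m2)
    if (log(stats::runif(1)) < ll2 - ll +
        stats::dexp(a2, 1, log = TRUE) - stats::dexp(alpha, 1, log = TRUE) +
        log(mult)) {
      alpha <- a2; model <- m2; ll <- ll2
      acc["alpha"] <- acc["alpha"] + 1
    }
    # mixture weights
    if (C > 1L) {
      try_n["weights"] <- try_n["weights"] + 1
      conc <- settings$weight_conc
      w2 <- as.numeric(rdirichlet(1, conc * weights + 0.1))
      q_fwd <- ddirichlet_log(w2, conc * weights + 0.1)
      q_rev <- ddirichlet_log(weights, conc * w2 + 0.1)
      m2 <- build(profiles, w2, alpha)
      ll2 <- loglik(topo, blen, m2)
      if (log(stats::runif(1)) < ll2 - ll + q_rev - q_fwd) {
        weights <- w2; model <- m2; ll <- ll2
        acc["weights"] <- acc["weights"] + 1
      }
    }
    # one profile
    {
      try_n["profile"] <- try_n["profile"] + 1
      ci <- sample.int(C, 1L)
      conc <- settings$profile_conc
      p_cur <- profiles[ci, ]
      p2 <- as.numeric(rdirichlet(1, conc * p_cur + 0.1))
      q_fwd <- ddirichlet_log(p2, conc * p_cur + 0.1)
      q_rev <- ddirichlet_log(p_cur, conc * p2 + 0.1)
      prof2 <- profiles; prof2[ci, ] <- p2
      m2 <- build(prof2, weights, alpha)
      ll2 <- loglik(topo, blen, m2)
      if (log(stats::runif(1)) < ll2 - ll + q_rev - q_fwd) {
        profiles <- prof2; model <- m2; ll <- ll2
        acc["profile"] <- acc["profile"] + 1
      }
    }
    # topology
    if (n_topo > 1L) {
      try_n["topology"] <- try_n["topology"] + 1
      t2 <- sample(setdiff(seq_len(n_topo), topo), 1L)
      b2 <- .carry_blen(blen, keys[[topo]], keys[[t2]])
      ll2 <- loglik(t2, b2, model)
      lp2 <- log_prior_b(b2)
      if (log(stats::runif(1)) < ll2 - ll + lp2 - lp_b) {
        topo <- t2; blen <- b2; ll <- ll2; lp_b <- lp2
        acc["topology"] <- acc["topology"] + 1
      }
    }
    if (!is.finite(ll)) stop("chain diverged: non-finite log-likelihood")
    trace[[cyc]] <- data.frame(cycle = cyc, log_likelihood = ll,
                               alpha = alpha, topology = topo,
                               seconds = proc.time()[["elapsed"]] - t0)
    if (cyc > settings$burnin_cycles &&
        (cyc - settings$burnin_cycles) %% settings$subsample_every == 0L) {
      tr <- preps[[topo]]$tree
      tr$edge.length <- blen
      samples[[length(samples) + 1L]] <-
        list(topology = topo, tree = tr, model = model,
             log_likelihood = ll)
    }
  }
  topos <- vapply(samples, `[[`, integer(1), "topology")
  pp <- tabulate(topos, nbins = n_topo) / length(topos)
  names(pp) <- names(candidates)
  list(pp = pp, samples = samples, trace = do.call(rbind, trace),
       acceptance = ifelse(try_n > 0, acc / pmax(try_n, 1), NA),
       settings = settings)
}

#' Compare two independent chains
#'
#' Reports the absolute difference in topology posterior probabilities and in
#' the posterior-mean Gamma shape between two chains run with identical
#' settings but different seeds, flagging runs whose largest PP difference
#' exceeds `pp_tol`.
#'
#' @param chain1,chain2 results of [sample_posterior()].
#' @param pp_tol flag threshold on the per-topology PP difference.
#' @return List with `pp_diff`, `alpha_diff`, `flagged`.
#' @export
convergence_check <- function(chain1, chain2, pp_tol = 0.1) {
  if (!identical(names(chain1$pp), names(chain2$pp)))
    stop("chains have different candidate sets")
  pp_diff <- abs(chain1$pp - chain2$pp)
  a1 <- mean(vapply(chain1$samples, function(s) s$model$alpha, numeric(1)))
  a2 <- mean(vapply(chain2$samples, function(s) s$model$alpha, numeric(1)))
  list(pp_diff = pp_diff, alpha_diff = abs(a1 - a2),
       flagged = any(pp_diff > pp_tol))
}
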