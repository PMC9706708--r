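test_that("chain settings are validated", {
  expect_error(chain_settings(n_cycles = 100, burnin_cycles = 100), "burnin")
  expect_error(chain_settings(subsample_every = 0), "subsample")
})

test_that("constant data give near-uniform topology posterior", {
  set.seed(71)
  cands <- candidate_topologies(4)
  const <- alignment(matrix("A", 4, 40,
                            dimnames = list(cands[[1]]$tip.label, NULL)),
                     aa_alphabet())
  res <- sample_posterior(const, cands, "poisson_g",
                          settings = chain_settings(n_cycles = 400,
                                                    burnin_cycles = 100,
                                                    subsample_every = 1))
  expect_equal(sum(res$pp), 1)
  expect_true(all(res$pp > 0.1))
})

test_that("chains are exactly reproducible given the seed", {
  cands <- candidate_topologies(4)
  set.seed(72)
  m <- default_study_model(4)
  aln <- simulate_alignment(zone_tree("porifera_sister", 4), m, 120)
  st <- chain_settings(n_cycles = 60, burnin_cycles = 20)
  set.seed(5); r1 <- sample_posterior(aln, cands, "poisson_g", settings = st)
  set.seed(5); r2 <- sample_posterior(aln, cands, "poisson_g", settings = st)
  expect_identical(r1$pp, r2$pp)
  expect_identical(r1$trace$log_likelihood, r2$trace$log_likelihood)
})

test_that("strong signal concentrates the posterior on the true topology", {
  set.seed(73)
  cands <- candidate_topologies(4, long_branch = 0.3, short_branch = 0.1,
                                internal_branch = 0.2)
  tr <- zone_tree("porifera_sister", 4, long_branch = 0.3,
                  short_branch = 0.1, internal_branch = 0.2)
  m <- default_study_model(5)
  aln <- simulate_alignment(tr, m, 800)
  res <- sample_posterior(aln, cands, "poisson_g",
                          settings = chain_settings(n_cycles = 120,
                                                    burnin_cycles = 50))
  expect_gte(res$pp[["porifera_sister"]], 0.95)
  # posterior samples respect model constraints
  s <- res$samples[[length(res$samples)]]
  expect_equal(rowSums(s$model$profiles), rep(1, nrow(s$model$profiles)),
               tolerance = 1e-9)
  expect_true(all(s$tree$edge.length >= 0))
  expect_gt(s$model$alpha, 0)
})

test_that("convergence check flags disagreement and passes agreement", {
  set.seed(74)
  cands <- candidate_topologies(4, long_branch = 0.3, short_branch = 0.1,
                                internal_branch = 0.2)
  tr <- zone_tree("porifera_sister", 4, long_branch = 0.3,
                  short_branch = 0.1, internal_branch = 0.2)
  m <- default_study_model(5)
  aln <- simulate_alignment(tr, m, 800)
  st <- chain_settings(n_cycles = 120, burnin_cycles = 50)
  set.seed(1); c1 <- sample_posterior(aln, cands, "poisson_g", settings = st)
  set.seed(1); c1b <- sample_posterior(aln, cands, "poisson_g", settings = st)
  same <- convergence_check(c1, c1b)
  expect_equal(unname(same$pp_diff), rep(0, 3))
  expect_false(same$flagged)
  set.seed(2); c2 <- sample_posterior(aln, cands, "poisson_g", settings = st)
  two <- convergence_check(c1, c2)
  expect_false(two$flagged)  # strong signal: chains agree
  # deliberately truncated chains on weak data disagree
  weak <- alignment(unclass(aln)[, 1:40], aln_alphabet(aln))
  stw <- chain_settings(n_cycles = 8, burnin_cycles = 2, subsample_every = 1)
  set.seed(3); w1 <- sample_posterior(weak, cands, "poisson_g", settings = stw,
                                      warm_start = FALSE)
  set.seed(8); w2 <- sample_posterior(weak, cands, "poisson_g", settings = stw,
                                      warm_start = FALSE)
  expect_true(convergence_check(w1, w2)$flagged ||
                max(abs(w1$pp - w2$pp)) > 0)
})

test_that("posterior probabilities sum to one and trace is complete", {
  set.seed(75)
  cands <- candidate_topologies(4)
  m <- default_study_model(4)
  aln <- simulate_alignment(zone_tree("ctenophora_sister", 4), m, 150)
  st <- chain_settings(n_cycles = 50, burnin_cycles = 10,
                       subsample_every = 2)
  res <- sample_posterior(aln, cands, "poisson_g", settings = st)
  expect_equal(sum(res$pp), 1)
  expect_equal(nrow(res$trace), 50L)
  expect_equal(length(res$samples), 20L)
  expect_true(all(is.finite(res$trace$log_likelihood)))
  expect_true(all(diff(res$trace$seconds) >= 0))
})
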