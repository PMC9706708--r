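test_that("single-leaf and two-leaf likelihoods match stationary closed forms", {
  k <- 20
  m <- mixture_model(k, "poisson", matrix(1 / k, 1, k), alpha = 1,
                     n_rate_cats = 1)
  # two identical states at distance t
  t_tot <- 0.2
  aln <- alignment(c(a = "A", b = "A"), aa_alphabet())
  tr <- parse_tree(sprintf("(a:%g,b:%g);", t_tot / 2, t_tot / 2))
  got <- site_likelihoods(aln, tr, m)$log_likelihood
  want <- log((1 / k) * (1 / k + (1 - 1 / k) * exp(-k * t_tot / (k - 1))))
  expect_equal(got, want, tolerance = 1e-10)
  # differing states
  aln2 <- alignment(c(a = "A", b = "C"), aa_alphabet())
  got2 <- site_likelihoods(aln2, tr, m)$log_likelihood
  p_same <- 1 / k + (1 - 1 / k) * exp(-k * t_tot / (k - 1))
  want2 <- log((1 / k) * (1 - p_same) / (k - 1))
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on mixture instances", {
  set.seed(41)
  for (rep in 1:3) {
    k <- 4
    profs <- rdirichlet(2, rep(0.8, k))
    m <- mixture_model(k, "poisson", profs, weights = c(0.3, 0.7),
                       alpha = 0.6, n_rate_cats = 2)
    tr <- parse_tree(sprintf("((t1:%.3f,t2:%.3f):%.3f,t3:%.3f,t4:%.3f);",
                             runif(1, .05, .5), runif(1, .05, .5),
                             runif(1, .05, .3), runif(1, .05, .5),
                             runif(1, .05, .5)))
    mat <- matrix(sample(LETTERS[1:k], 8, TRUE), 4, 2,
                  dimnames = list(paste0("t", 1:4), NULL))
    mat[1, 1] <- "-"  # missing handled identically in both routes
    aln <- alignment(mat, recoded_alphabet(k))
    expect_equal(site_likelihoods(aln, tr, m)$log_likelihood,
                 brute_force_loglik(aln, tr, m), tolerance = 1e-10)
  }
})

test_that("pruning with LG exchangeabilities matches the enumeration oracle", {
  set.seed(42)
  k <- 4
  rho <- matrix(runif(16, 0.2, 2), k, k)
  rho <- (rho + t(rho)) / 2
  m <- mixture_model(k, rho, rdirichlet(2, rep(1, k)), alpha = 1,
                     n_rate_cats = 2)
  tr <- parse_tree("((t1:0.2,t2:0.35):0.1,t3:0.15,t4:0.4);")
  mat <- matrix(sample(LETTERS[1:k], 12, TRUE), 4, 3,
                dimnames = list(paste0("t", 1:4), NULL))
  aln <- alignment(mat, recoded_alphabet(k))
  expect_equal(site_likelihoods(aln, tr, m)$log_likelihood,
               brute_force_loglik(aln, tr, m), tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting and column order", {
  set.seed(43)
  m <- default_study_model(3)
  tr <- zone_tree("porifera_sister", 4)
  aln <- simulate_alignment(tr, m, 40)
  l1 <- site_likelihoods(aln, tr, m)
  rerooted <- ape::root(tr, outgroup = "Porifera_1", resolve.root = TRUE)
  l2 <- site_likelihoods(aln, rerooted, m)
  expect_equal(l1$log_likelihood, l2$log_likelihood, tolerance = 1e-8)
  perm <- sample(ncol(aln))
  aln_p <- alignment(unclass(aln)[, perm], aln_alphabet(aln))
  l3 <- site_likelihoods(aln_p, tr, m)
  expect_equal(l3$per_site, l1$per_site[perm], tolerance = 1e-10)
  expect_equal(sum(l1$per_site), l1$log_likelihood, tolerance = 1e-8)
})

test_that("likelihood agrees with an independent implementation on LG+G", {
  skip_if_not_installed("phangorn")
  set.seed(44)
  tr <- parse_tree("((t1:0.2,t2:0.3):0.1,t3:0.15,t4:0.4);")
  m <- mixture_model(20, "lg", matrix(lg_frequencies(), 1, 20, byrow = TRUE),
                     alpha = 0.7, n_rate_cats = 4)
  aln <- simulate_alignment(tr, m, 150)
  mine <- site_likelihoods(aln, tr, m)$log_likelihood
  pd <- phangorn::phyDat(unclass(aln), type = "AA")
  ref <- phangorn::pml(tr, pd, model = "LG", bf = unname(lg_frequencies()),
                       k = 4, shape = 0.7)$logLik
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("ml_fit recovers the closed-form Poisson distance", {
  set.seed(45)
  k <- 20
  n <- 800
  m1 <- sample(aa_syms(), n, TRUE)
  m2 <- m1
  idx <- sample(n, 180)
  m2[idx] <- sample(aa_syms(), 180, TRUE)
  aln <- alignment(rbind(a = m1, b = m2), aa_alphabet())
  p <- mean(m1 != m2)
  fit <- ml_fit(aln, parse_tree("(a:0.1,b:0.1);"), "poisson_g", gamma = FALSE)
  # empirical-frequency F81 reduces to the uniform closed form approximately;
  # the distance itself is compared against the analytic Poisson estimate
  expect_equal(sum(fit$tree$edge.length), poisson_ml_distance(p, k),
               tolerance = 0.01)
  # identical sequences collapse to zero distance
  aln0 <- alignment(rbind(a = m1, b = m1), aa_alphabet())
  fit0 <- ml_fit(aln0, parse_tree("(a:0.1,b:0.1);"), "poisson_g",
                 gamma = FALSE)
  expect_lt(sum(fit0$tree$edge.length), 1e-4)
})

test_that("mixture EM never decreases the log-likelihood across sweeps", {
  set.seed(46)
  m <- default_study_model(6)
  tr <- zone_tree("porifera_sister", 4)
  aln <- simulate_alignment(tr, m, 400)
  rec <- apply_recoding(aln, builtin_scheme("dayhoff6"))
  lls <- c()
  for (sweeps in 1:4) {
    set.seed(460)  # identical k-means initialisation per run
    fit <- ml_fit(rec, tr, "mix_n_g", n_categories = 3, gamma = FALSE,
                  max_sweeps = sweeps, tol = 0)
    lls <- c(lls, fit$log_likelihood)
  }
  expect_true(all(diff(lls) > -1e-6))
})

test_that("lg and gtr families fit and order sensibly", {
  set.seed(48)
  # data generated with LG exchangeabilities: the LG family should beat the
  # Poisson family on the same topology
  tr <- parse_tree("((t1:0.3,t2:0.4):0.15,t3:0.2,t4:0.5);")
  m <- mixture_model(20, "lg", matrix(lg_frequencies(), 1, 20, byrow = TRUE),
                     alpha = 1, n_rate_cats = 1)
  aln <- simulate_alignment(tr, m, 400)
  f_pois <- ml_fit(aln, tr, "poisson_g", gamma = FALSE, max_sweeps = 4)
  f_lg <- ml_fit(aln, tr, "lg_g", gamma = FALSE, max_sweeps = 4)
  expect_true(is.finite(f_lg$log_likelihood))
  expect_gt(f_lg$log_likelihood, f_pois$log_likelihood)
  # free exchangeabilities on a small state space recover extra fit
  rec <- apply_recoding(aln, builtin_scheme("dayhoff6"))
  f6_pois <- ml_fit(rec, tr, "poisson_g", gamma = FALSE, max_sweeps = 3)
  f6_gtr <- ml_fit(rec, tr, "gtr_g", gamma = FALSE, max_sweeps = 4)
  expect_gte(f6_gtr$log_likelihood, f6_pois$log_likelihood)
  expect_equal(dim(f6_gtr$model$rho), c(6L, 6L))
})

test_that("topology_scan splits support under no signal and finds true trees", {
  set.seed(47)
  cands <- candidate_topologies(4)
  # constant alignment: no signal, support near uniform
  const <- alignment(matrix("A", 4, 30,
                            dimnames = list(cands[[1]]$tip.label, NULL)),
                     aa_alphabet())
  scan0 <- topology_scan(const, cands, "poisson_g", gamma = FALSE,
                         n_bootstrap = 60)
  expect_equal(sum(scan0$support), 1)
  expect_true(all(scan0$support > 0.1))
  expect_lt(diff(range(scan0$log_likelihoods)), 1e-6)
  # strong signal on an easy tree
  tr <- zone_tree("porifera_sister", 4, long_branch = 0.3,
                  short_branch = 0.1, internal_branch = 0.2)
  m <- default_study_model(5)
  aln <- simulate_alignment(tr, m, 600)
  scan <- topology_scan(aln, cands, "poisson_g", n_bootstrap = 30)
  expect_equal(unname(which.max(scan$support)), 2L)
  expect_gte(scan$support[["porifera_sister"]], 0.9)
})
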