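test_that("mixture models validate their parts", {
  expect_error(mixture_model(20, "poisson", profiles = matrix(0.05, 1, 19)),
               "columns")
  p <- matrix(1 / 20, 1, 20)
  expect_error(mixture_model(20, "poisson", p, alpha = -1), "alpha")
  expect_error(mixture_model(20, "poisson", p, weights = c(0.5, 0.5)),
               "simplex")
  m <- mixture_model(6, "poisson", matrix(1 / 6, 2, 6))
  expect_true(m$poisson)
})

test_that("every category rate matrix is normalised to rate one", {
  set.seed(31)
  m <- default_study_model(8)
  for (cc in 1:8) {
    Q <- q_matrix(m, cc)
    expect_lt(max(abs(rowSums(Q))), 1e-9)
    expect_equal(-sum(m$profiles[cc, ] * diag(Q)), 1, tolerance = 1e-9)
  }
})

test_that("discrete gamma rates have mean one and order with alpha", {
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(gamma_rates(0.5, 1), 1)
  # smaller alpha = more rate spread
  expect_gt(stats::var(gamma_rates(0.3, 4)), stats::var(gamma_rates(2, 4)))
})

test_that("zero-length branches give constant columns", {
  set.seed(32)
  tr <- parse_tree("((t1:0,t2:0):0,t3:0,t4:0);")
  m <- default_study_model(5)
  aln <- simulate_alignment(tr, m, 50)
  expect_true(all(apply(unclass(aln), 2, function(col)
    length(unique(col))) == 1L))
})

test_that("two-taxon difference fraction matches the equal-rates closed form", {
  set.seed(33)
  k <- 20; t_tot <- 0.5; n <- 60000
  m <- mixture_model(k, "poisson", matrix(1 / k, 1, k), alpha = 1,
                     n_rate_cats = 1)
  tr <- parse_tree(sprintf("(a:%g,b:%g);", t_tot / 2, t_tot / 2))
  aln <- simulate_alignment(tr, m, n)
  p_obs <- mean(unclass(aln)[1, ] != unclass(aln)[2, ])
  p_exp <- poisson_expected_diff(t_tot, k)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("pooled state frequencies match the mixture stationary mix", {
  set.seed(34)
  m <- default_study_model(10)
  tr <- parse_tree("(a:0.15,b:0.15);")
  n <- 50000
  aln <- simulate_alignment(tr, m, n)
  emp <- table(factor(unclass(aln), levels = aa_alphabet()$symbols)) /
    (2 * n)
  target <- colSums(m$profiles * m$weights)
  tv <- 0.5 * sum(abs(as.numeric(emp) - target))
  expect_lt(tv, 0.012)
})

test_that("zone trees express the two hypotheses", {
  far <- zone_tree("ctenophora_sister", 4)
  fel <- zone_tree("porifera_sister", 4)
  expect_true(has_target_split(far, c("Outgroup", "Ctenophora")))
  expect_false(has_target_split(far, c("Outgroup", "Porifera")))
  expect_true(has_target_split(fel, c("Outgroup", "Porifera")))
  for (n in c(10L, 20L)) {
    tr <- zone_tree("porifera_sister", n)
    expect_equal(length(tr$tip.label), n)
    expect_true(has_target_split(tr, c("Outgroup", "Porifera")))
  }
  expect_error(zone_tree("porifera_sister", 7), "4, 10 or 20")
  expect_error(zone_tree("porifera_sister", 4, long_branch = 0.1,
                         short_branch = 0.2), "long_branch")
  cands <- candidate_topologies(10)
  expect_equal(length(cands), 3L)
  rf <- ape::dist.topo(cands$ctenophora_sister, cands$porifera_sister)
  expect_gt(rf, 0)
})

test_that("default study model is seed-deterministic", {
  set.seed(35); m1 <- default_study_model(6)
  set.seed(35); m2 <- default_study_model(6)
  set.seed(36); m3 <- default_study_model(6)
  expect_identical(m1$profiles, m2$profiles)
  expect_false(identical(m1$profiles, m3$profiles))
  # diffusion keeps rows on the simplex
  expect_equal(rowSums(m1$profiles), rep(1, 6), tolerance = 1e-9)
})

test_that("fixture suite writes a complete manifest and unique subsampling", {
  set.seed(37)
  conds <- data.frame(hypothesis = c("ctenophora_sister", "porifera_sister"),
                      n_sites = c(60L, 60L), n_taxa = c(4L, 4L),
                      stringsAsFactors = FALSE)
  dir <- tempfile()
  suite <- make_fixture_suite(conds, n_replicates = 2L, dir = dir, seed = 5L)
  expect_equal(nrow(suite$manifest), 4L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (f in suite$manifest$file) {
    aln <- read_alignment(file.path(dir, f))
    expect_equal(ncol(aln), 60L)
  }
  aln <- read_alignment(file.path(dir, suite$manifest$file[1]))
  sub <- subsample_sites(aln, 30L)
  expect_equal(ncol(sub), 30L)
  expect_error(subsample_sites(aln, 100L), "more sites")
})
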