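test_that("diversity and compositional statistics match forced cases", {
  expect_equal(div_stat(alignment(c(a = "AC", b = "AC"), aa_alphabet())), 1)
  expect_equal(div_stat(alignment(c(a = "AC", b = "CA"), aa_alphabet())), 2)
  three <- alignment(c(a = "A", b = "-", c = "C"), aa_alphabet())
  expect_equal(div_stat(three), 2)

  expect_equal(mean_comp_stat(alignment(c(a = "AA", b = "AA"),
                                        aa_alphabet())), 0)
  expect_equal(mean_comp_stat(alignment(c(a = "AA", b = "CC"),
                                        aa_alphabet())), 1)
  set.seed(61)
  aln <- random_aa_alignment(6, 50)
  perm <- sample(rownames(aln))
  expect_equal(mean_comp_stat(alignment(unclass(aln)[perm, ],
                                        aln_alphabet(aln))),
               mean_comp_stat(aln))
  expect_gte(mean_comp_stat(aln), 0)
  allmiss <- alignment(rbind(a = c("A", "C"), b = c("-", "-")),
                       aa_alphabet())
  expect_error(mean_comp_stat(allmiss), "all-missing")
})

test_that("fit bands follow the published thresholds", {
  expect_equal(fit_band(-0.9), "adequate")
  expect_equal(fit_band(2.5), "acceptable")
  expect_equal(fit_band(4.69), "acceptable-to-fairly-poor")
  expect_equal(fit_band(-7), "poor")
  expect_equal(fit_band(43.6), "very poor")
  expect_error(fit_band(Inf), "finite")
})

test_that("ppa z-score follows its definition and keeps its sign", {
  set.seed(62)
  tr <- quartet_tree(0.15)
  m <- default_study_model(4)
  aln <- simulate_alignment(tr, m, 150)
  cands <- list(t1 = tr)
  res <- sample_posterior(aln, cands, "poisson_g",
                         settings = chain_settings(n_cycles = 60,
                                                   burnin_cycles = 20,
                                                   subsample_every = 2))
  pr <- ppa(aln, res$samples, "div", n_sims = 12)
  expect_equal(pr$z, (pr$observed - pr$predictive_mean) / pr$predictive_sd)
  expect_equal(pr$n_sims, 12L)
  expect_true(pr$band %in% c("adequate", "acceptable",
                             "acceptable-to-fairly-poor", "poor",
                             "very poor"))
  expect_error(ppa(aln, res$samples[1], "div"), "two posterior samples")
})

test_that("ppa masks observed missing cells in predictive replicates", {
  set.seed(63)
  tr <- quartet_tree(0.15)
  m <- default_study_model(4)
  aln <- simulate_alignment(tr, m, 120)
  mm <- unclass(aln)
  mm[1, 1:60] <- "-"   # heavy asymmetric missingness
  aln_m <- alignment(mm, aln_alphabet(aln))
  res <- sample_posterior(aln_m, list(t = tr), "poisson_g",
                          settings = chain_settings(n_cycles = 60,
                                                    burnin_cycles = 20,
                                                    subsample_every = 2))
  pr <- ppa(aln_m, res$samples, "div", n_sims = 15)
  # with masking, the predictive mean must sit near the observed value for
  # data generated by a matching process, not offset by the missing cells
  expect_lt(abs(pr$z), 6)
})

test_that("ppa detects planted across-lineage compositional heterogeneity", {
  set.seed(65)
  tr <- quartet_tree(0.15)
  m <- default_study_model(4)
  aln <- simulate_alignment(tr, m, 300)
  res <- sample_posterior(aln, list(t = tr), "poisson_g",
                          settings = chain_settings(n_cycles = 60,
                                                    burnin_cycles = 20,
                                                    subsample_every = 2))
  # matching data: the compositional statistic should look adequate
  z_ok <- ppa(aln, res$samples, "mean_comp", n_sims = 15)$z
  expect_lt(abs(z_ok), 5)
  # plant strong lineage-specific composition in one taxon
  mm <- unclass(aln)
  mm[1, ] <- "A"
  z_bad <- ppa(alignment(mm, attr(aln, "alphabet")), res$samples,
               "mean_comp", n_sims = 15)$z
  expect_gt(z_bad, 5)
})

test_that("ppa is reproducible under a fixed seed", {
  set.seed(64)
  tr <- quartet_tree(0.15)
  m <- default_study_model(4)
  aln <- simulate_alignment(tr, m, 100)
  res <- sample_posterior(aln, list(t = tr), "poisson_g",
                          settings = chain_settings(n_cycles = 50,
                                                    burnin_cycles = 20,
                                                    subsample_every = 2))
  set.seed(99); z1 <- ppa(aln, res$samples, "div", n_sims = 10)$z
  set.seed(99); z2 <- ppa(aln, res$samples, "div", n_sims = 10)$z
  expect_identical(z1, z2)
})
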