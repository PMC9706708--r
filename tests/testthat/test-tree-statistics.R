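test_that("fitch length matches forced cases and the quartet split", {
  a2 <- alignment(c(x = "A", y = "C"), aa_alphabet())
  expect_equal(fitch_length(a2, parse_tree("(x:1,y:1);")), 1L)
  a <- alignment(c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"), aa_alphabet())
  expect_equal(fitch_length(a, parse_tree("((t1:1,t2:1):1,(t3:1,t4:1):1);")),
               1L)
  expect_equal(fitch_length(a, parse_tree("((t1:1,t3:1):1,(t2:1,t4:1):1);")),
               2L)
  const <- alignment(matrix("A", 4, 7, dimnames =
                              list(paste0("t", 1:4), NULL)), aa_alphabet())
  expect_equal(fitch_length(const, quartet_tree()), 0L)
})

test_that("fitch length agrees with phangorn on random data", {
  skip_if_not_installed("phangorn")
  set.seed(51)
  for (i in 1:5) {
    aln <- random_aa_alignment(7, 50, missing_frac = 0.06)
    tr <- ape::rtree(7, tip.label = rownames(aln))
    pd <- phangorn::phyDat(unclass(aln), type = "AA")
    expect_equal(fitch_length(aln, tr),
                 phangorn::fitch(ape::unroot(tr), pd))
  }
})

test_that("heuristic parsimony finds the exhaustive optimum on 6 taxa", {
  set.seed(52)
  m <- default_study_model(5)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  aln <- simulate_alignment(tr, m, 80)
  all_topos <- phangorn::allTrees(6, rooted = FALSE,
                                  tip.label = rownames(aln))
  best_exhaustive <- min(vapply(all_topos, function(tt) {
    tt$edge.length <- rep(1, nrow(tt$edge))
    fitch_length(aln, tt)
  }, numeric(1)))
  res <- parsimony_search(aln, n_random_additions = 5)
  expect_equal(res$length, as.integer(best_exhaustive))
  # returned length is never above the score of any fixed topology
  expect_lte(res$length, fitch_length(aln, tr))
})

test_that("information loss arithmetic and bounds", {
  expect_equal(information_loss(100, 51), 49)
  expect_equal(information_loss(100, 100), 0)
  expect_error(information_loss(0, 0), "positive")
  set.seed(53)
  m <- default_study_model(5)
  tr <- zone_tree("porifera_sister", 4)
  for (i in 1:3) {
    aln <- simulate_alignment(tr, m, 150)
    rec <- apply_recoding(aln, random_scheme())
    il <- information_loss(fitch_length(aln, tr), fitch_length(rec, tr))
    expect_gte(il, 0)
    expect_lte(il, 100)
  }
})

test_that("branch step attribution conserves the fitch total", {
  set.seed(54)
  m <- default_study_model(5)
  for (n_taxa in c(4L, 10L)) {
    tr <- zone_tree("porifera_sister", n_taxa)
    aln <- simulate_alignment(tr, m, 120)
    rec <- apply_recoding(aln, builtin_scheme("dayhoff6"))
    map <- branch_loss_map(aln, rec, tr)
    expect_equal(sum(map$steps_source), fitch_length(aln, tr))
    expect_equal(sum(map$steps_recoded), fitch_length(rec, tr))
  }
  # identical alignments give an all-zero loss map
  tr <- zone_tree("porifera_sister", 4)
  aln <- simulate_alignment(tr, m, 60)
  map0 <- branch_loss_map(aln, aln, tr)
  expect_true(all(map0$loss_percent[is.finite(map0$loss_percent)] == 0))
})

test_that("persite substitutions behaves on forced cases", {
  const <- alignment(matrix("A", 4, 10,
                            dimnames = list(paste0("t", 1:4), NULL)),
                     aa_alphabet())
  expect_equal(persite_substitutions(const, 2), 0)
  two <- alignment(c(a = "AAAC", b = "ACCC"), aa_alphabet())
  expect_equal(persite_substitutions(two), 0.5)
})

test_that("p-distances use pairwise deletion", {
  aln <- alignment(c(a = "AAAA", b = "AAAC"), aa_alphabet())
  expect_equal(p_distance_matrix(aln)["a", "b"], 0.25)
  aln2 <- alignment(c(a = "A-AA", b = "ACAC"), aa_alphabet())
  expect_equal(p_distance_matrix(aln2)["a", "b"], 1 / 3)
  same <- alignment(c(a = "ACD", b = "ACD"), aa_alphabet())
  expect_equal(p_distance_matrix(same)["a", "b"], 0)
})

test_that("nj recovers additive trees exactly and ignores taxon order", {
  tr <- parse_tree("((A:0.1,B:0.2):0.05,(C:0.1,D:0.3):0.02);")
  D <- patristic(tr)
  nj <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  expect_equal(patristic(nj)[rownames(D), rownames(D)], D, tolerance = 1e-10)
  perm <- c("C", "A", "D", "B")
  nj2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(nj2)), 0,
               ignore_attr = TRUE)
  # three taxa: closed-form star resolution
  tr3 <- parse_tree("(A:0.1,B:0.2,C:0.4);")
  nj3 <- nj_tree(patristic(tr3))
  expect_equal(sort(nj3$edge.length), c(0.1, 0.2, 0.4))
})

test_that("saturation slope arithmetic and monotonicity under divergence", {
  x <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  y <- x
  s <- saturation_index(x, y)
  expect_equal(s$M, 1)
  expect_equal(s$sat, 0)
  y2 <- y * 0.5
  s2 <- saturation_index(x, y2)
  expect_equal(s2$M, 0.5)
  expect_equal(s2$sat, 0.5)
  expect_equal(s2$n_pairs, 1L)

  set.seed(55)
  m <- default_study_model(10)
  sats <- vapply(c(0.3, 1.0), function(scale) {
    tr <- zone_tree("porifera_sister", 10,
                    long_branch = scale, short_branch = scale / 5,
                    internal_branch = scale / 8)
    aln <- simulate_alignment(tr, m, 1500)
    alignment_saturation(aln, tr)$sat
  }, numeric(1))
  expect_gt(sats[1], 0)
  expect_gt(sats[2], sats[1])
})
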