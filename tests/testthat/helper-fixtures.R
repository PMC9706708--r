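# shared fixtures built in code; everything deterministic given set.seed in
# the tests that use them

aa_syms <- function() aa_alphabet()$symbols

random_aa_alignment <- function(n_taxa, n_sites, missing_frac = 0) {
  mat <- matrix(sample(aa_syms(), n_taxa * n_sites, replace = TRUE),
                nrow = n_taxa)
  if (missing_frac > 0) {
    idx <- sample(length(mat), round(missing_frac * length(mat)))
    mat[idx] <- "-"
  }
  rownames(mat) <- paste0("t", seq_len(n_taxa))
  alignment(mat, aa_alphabet())
}

quartet_tree <- function(b = 0.2) {
  parse_tree(sprintf("((t1:%g,t2:%g):%g,t3:%g,t4:%g);", b, b, b, b, b))
}

# brute-force mixture likelihood: sum over all interior-node state
# assignments, categories and rates; independent of the pruning code path
brute_force_loglik <- function(aln, tree, model) {
  alph <- aln_alphabet(aln)
  k <- model$k
  tree <- ape::reorder.phylo(if (length(tree$tip.label) > 2L)
    ape::unroot(tree) else tree, "postorder")
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  n_nodes <- max(edge)
  interior <- setdiff(seq_len(n_nodes), seq_len(ntip))
  root <- setdiff(edge[, 1], edge[, 2])[1]
  rates <- gamma_rates(model$alpha, model$n_rate_cats)
  mat <- unclass(aln)[tree$tip.label, , drop = FALSE]
  total <- 0
  for (s in seq_len(ncol(mat))) {
    site_lik <- 0
    for (cc in seq_len(nrow(model$profiles))) {
      Q <- q_matrix(model, cc)
      eig <- eigen_q(Q)
      pi_c <- model$profiles[cc, ]
      for (g in seq_along(rates)) {
        P_edges <- lapply(seq_len(nrow(edge)), function(e)
          p_matrix(eig, rates[g] * tree$edge.length[e]))
        lik_g <- 0
        grid <- do.call(expand.grid, rep(list(seq_len(k)), length(interior)))
        for (a in seq_len(nrow(grid))) {
          assign_state <- integer(n_nodes)
          assign_state[interior] <- as.integer(grid[a, ])
          prod_a <- pi_c[assign_state[root]]
          for (e in seq_len(nrow(edge))) {
            par <- edge[e, 1]; child <- edge[e, 2]
            P <- P_edges[[e]]
            if (child <= ntip) {
              x <- match(mat[child, s], alph$symbols)
              prod_a <- prod_a *
                (if (is.na(x)) 1 else P[assign_state[par], x])
            } else {
              prod_a <- prod_a * P[assign_state[par], assign_state[child]]
            }
          }
          lik_g <- lik_g + prod_a
        }
        site_lik <- site_lik + model$weights[cc] * lik_g / length(rates)
      }
    }
    total <- total + log(site_lik)
  }
  total
}

# similarity oracle: maximise total intersection over every size-respecting
# complete pairing of bins, enumerated directly over permutations of b's bins
brute_force_similarity <- function(a, b) {
  sa <- vapply(a$bins, length, 1L)
  perms <- aarecode:::.permutations(length(b$bins))
  best <- 0L
  for (p in seq_len(nrow(perms))) {
    perm <- perms[p, ]
    sb <- vapply(b$bins[perm], length, 1L)
    if (!all(sa == sb)) next
    tot <- sum(vapply(seq_along(sa), function(i)
      length(intersect(a$bins[[i]], b$bins[[perm[i]]])), 1L))
    best <- max(best, tot)
  }
  100 * best / 20
}
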