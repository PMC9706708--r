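#' Farris-zone and Felsenstein-zone target trees
#'
#' Builds the four-clade target topologies used throughout the experiments.
#' The four subtree slots are the outgroup (long stem), Ctenophora (long
#' stem), Porifera (short stem) and the remaining animals (short stem).
#' Under the Ctenophora-sister hypothesis the two long stems are adjacent
#' across the internal target branch (the Farris zone); under Porifera-sister
#' a long and a short stem sit on each side (the Felsenstein zone).
#'
#' For `n_taxa = 4` each slot is a single leaf named after its clade. For
#' `n_taxa = 10` or `20` each slot is expanded into a pectinate clade whose
#' stem carries the long/short length and whose internal branches have length
#' `within_clade_length`.
#'
#' @param hypothesis `"ctenophora_sister"` (Farris zone) or
#'   `"porifera_sister"` (Felsenstein zone).
#' @param n_taxa total number of leaves: 4, 10 or 20.
#' @param long_branch,short_branch,internal_branch branch lengths in expected
#'   substitutions per site; `long_branch > short_branch > 0`,
#'   `internal_branch > 0`.
#' @param within_clade_length branch length inside expanded clades.
#' @return Unrooted `ape::phylo` tree. Leaf labels encode clade membership
#'   (`Outgroup*`, `Ctenophora*`, `Porifera*`, `OtherAnimals*`).
#' @export
zone_tree <- function(hypothesis = c("ctenophora_sister", "porifera_sister"),
                      n_taxa = 4L,
                      long_branch = 1.0, short_branch = 0.1,
                      internal_branch = 0.05,
                      within_clade_length = 0.05) {
  hypothesis <- match.arg(hypothesis)
  if (!n_taxa %in% c(4L, 10L, 20L)) stop("n_taxa must be 4, 10 or 20")
  if (!(long_branch > short_branch && short_branch > 0))
    stop("need long_branch > short_branch > 0")
  if (internal_branch <= 0) stop("internal branch must be positive")
  sizes <- switch(as.character(n_taxa),
                  "4" = c(1L, 1L, 1L, 1L),
                  "10" = c(2L, 3L, 3L, 2L),
                  "20" = c(5L, 5L, 5L, 5L))
  clades <- c("Outgroup", "Ctenophora", "Porifera", "OtherAnimals")
  stems <- c(Outgroup = long_branch, Ctenophora = long_branch,
             Porifera = short_branch, OtherAnimals = short_branch)
  sub <- function(clade, n) {
    if (n == 1L) return(sprintf("%s_1:%g", clade, stems[[clade]]))
    tip <- function(i) sprintf("%s_%d:%g", clade, i, within_clade_length)
    nwk <- tip(1)
    if (n > 1L) for (i in 2:n) {
      closing <- if (i == n) stems[[clade]] else within_clade_length
      nwk <- sprintf("(%s,%s):%g", nwk, tip(i), closing)
    }
    nwk
  }
  parts <- Map(sub, clades, sizes)
  names(parts) <- clades
  partner <- if (hypothesis == "ctenophora_sister") "Ctenophora" else "Porifera"
  .four_clade_newick(parts, partner, internal_branch)
}

# unrooted quartet-of-clades: Outgroup pairs with `partner` across the
# internal branch, the remaining two clades sit on the other side
.four_clade_newick <- function(parts, partner, internal_branch) {
  others <- setdiff(names(parts), c("Outgroup", partner))
  nwk <- sprintf("((%s,%s):%g,%s,%s);",
                 parts$Outgroup, parts[[partner]], internal_branch,
                 parts[[others[1]]], parts[[others[2]]])
  parse_tree(nwk)
}

#' The three candidate resolutions of the four-clade problem
#'
#' Returns the Ctenophora-sister tree, the Porifera-sister tree and the third
#' resolution (Outgroup with OtherAnimals), all with the same leaves and
#' branch-length conventions, for use as the candidate set in inference.
#'
#' @inheritParams zone_tree
#' @return Named list of three `phylo` trees.
#' @export
candidate_topologies <- function(n_taxa = 4L, long_branch = 1.0,
                                 short_branch = 0.1, internal_branch = 0.05,
                                 within_clade_length = 0.05) {
  cs <- zone_tree("ctenophora_sister", n_taxa, long_branch, short_branch,
                  internal_branch, within_clade_length)
  ps <- zone_tree("porifera_sister", n_taxa, long_branch, short_branch,
                  internal_branch, within_clade_length)
  # rebuild the clade parts exactly as zone_tree does, then form the third
  # resolution: Outgroup pairs with OtherAnimals
  sizes <- switch(as.character(n_taxa),
                  "4" = c(1L, 1L, 1L, 1L),
                  "10" = c(2L, 3L, 3L, 2L),
                  "20" = c(5L, 5L, 5L, 5L))
  clades <- c("Outgroup", "Ctenophora", "Porifera", "OtherAnimals")
  stems <- c(Outgroup = long_branch, Ctenophora = long_branch,
             Porifera = short_branch, OtherAnimals = short_branch)
  sub <- function(clade, n) {
    if (n == 1L) return(sprintf("%s_1:%g", clade, stems[[clade]]))
    tip <- function(i) sprintf("%s_%d:%g", clade, i, within_clade_length)
    nwk <- tip(1)
    for (i in 2:n) {
      closing <- if (i == n) stems[[clade]] else within_clade_length
      nwk <- sprintf("(%s,%s):%g", nwk, tip(i), closing)
    }
    nwk
  }
  parts <- Map(sub, clades, sizes)
  names(parts) <- clades
  third <- .four_clade_newick(parts, "OtherAnimals", internal_branch)
  list(ctenophora_sister = cs, porifera_sister = ps, other = third)
}

#' Does a tree display the target clade split?
#'
#' Tests whether `tree` contains the unrooted bipartition that separates the
#' two clades named in `pair` from the rest (the "target branch" of the
#' four-clade problem).
#'
#' @param tree a `phylo` tree with clade-encoded leaf names.
#' @param pair character vector of two clade prefixes expected on one side.
#' @return Logical.
#' @export
has_target_split <- function(tree, pair = c("Outgroup", "Ctenophora")) {
  side <- tree$tip.label[grepl(paste0("^(", paste(pair, collapse = "|"), ")_"),
                               tree$tip.label)]
  bp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(bp, "labels")
  target <- sort(match(side, labs))
  n <- length(labs)
  for (p in bp) {
    p <- sort(p)
    if (identical(p, target) || identical(sort(setdiff(seq_len(n), p)), target))
      return(TRUE)
  }
  FALSE
}
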