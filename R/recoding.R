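#' Recoding schemes
#'
#' A recoding scheme is a labelled partition of the 20 amino acids into bins;
#' applying it to an alignment replaces every amino acid by its bin label,
#' masking within-bin substitutions. Bin labels are `A`, `B`, ... in bin
#' order so that recoded alignments remain FASTA-compatible.
#'
#' @param bins list of character vectors of amino-acid codes; the bins must be
#'   pairwise disjoint and union to the full 20-letter amino-acid alphabet.
#' @param name scheme name.
#' @return An object of class `"recoding_scheme"` with elements `name`,
#'   `bins` (list of sorted member vectors, named by bin label) and `map`
#'   (named character vector amino acid -> bin label).
#' @export
#' @examples
#' dayhoff6 <- builtin_scheme("dayhoff6")
#' dayhoff6
recoding_scheme <- function(bins, name = "custom") {
  bins <- lapply(bins, function(b) sort(toupper(as.character(b))))
  all_members <- unlist(bins)
  aa <- sort(aa_alphabet()$symbols)
  if (anyDuplicated(all_members))
    stop("bins overlap: ", paste(all_members[duplicated(all_members)], collapse = " "))
  if (!identical(sort(all_members), aa))
    stop("bins must partition the 20 amino acids; missing: ",
         paste(setdiff(aa, all_members), collapse = " "))
  labels <- LETTERS[seq_along(bins)]
  names(bins) <- labels
  map <- character(0)
  for (l in labels) map[bins[[l]]] <- l
  structure(list(name = name, bins = bins, map = map),
            class = "recoding_scheme")
}

#' @export
print.recoding_scheme <- function(x, ...) {
  cat("Recoding scheme '", x$name, "' (", length(x$bins), " bins)\n", sep = "")
  for (l in names(x$bins))
    cat(" ", l, ": ", paste(x$bins[[l]], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Built-in six-state recoding schemes
#'
#' `dayhoff6` groups amino acids by exchangeability into the classic six bins
#' \{AGPST\}, \{DENQ\}, \{HKR\}, \{ILMV\}, \{FWY\}, \{C\}. `sr6` is the
#' six-bin scheme of Susko and Roger; `kgb6` the six-bin scheme of Kosiol,
#' Goldman and Buttimore.
#'
#' @param name one of `"dayhoff6"`, `"sr6"`, `"kgb6"`.
#' @return A [recoding_scheme()].
#' @export
builtin_scheme <- function(name = c("dayhoff6", "sr6", "kgb6")) {
  name <- match.arg(name)
  bins <- switch(name,
    dayhoff6 = list(c("A","G","P","S","T"), c("D","E","N","Q"),
                    c("H","K","R"), c("I","L","M","V"),
                    c("F","W","Y"), "C"),
    sr6      = list(c("A","P","S","T"), c("D","E","N","G"),
                    c("Q","K","R"), c("M","I","V","L"),
                    c("W","C"), c("F","Y","H")),
    kgb6     = list(c("A","G","P","S"), c("D","E","N","Q","H","K","R","T"),
                    c("M","I","L"), "W", c("F","Y"), c("C","V")))
  recoding_scheme(bins, name = name)
}

#' Apply a recoding scheme to an alignment
#'
#' Every amino acid is replaced by its bin label; missing symbols are left
#' unchanged. The result is an alignment over the reduced alphabet with the
#' same taxa and number of sites.
#'
#' @param aln a 20-state [alignment()].
#' @param scheme a [recoding_scheme()].
#' @return A recoded [alignment()] over [recoded_alphabet()].
#' @export
apply_recoding <- function(aln, scheme) {
  if (!inherits(aln, "alignment")) stop("not an alignment")
  alph <- aln_alphabet(aln)
  if (!identical(alph$symbols, aa_alphabet()$symbols))
    stop("apply_recoding expects an amino-acid alignment")
  mat <- unclass(aln)
  out <- mat
  is_state <- mat %in% alph$symbols
  out[is_state] <- scheme$map[mat[is_state]]
  attr(out, "alphabet") <- NULL
  alignment(out, recoded_alphabet(length(scheme$bins)))
}

#' Random recoding schemes of a fixed bin-size template
#'
#' Draws a uniformly random partition of the 20 amino acids into bins of the
#' given sizes (a uniform permutation filled into the size template). The
#' default template is the Dayhoff-6 one: one 5-, two 4-, two 3- and one
#' 1-amino-acid bin.
#'
#' @param bin_sizes integer vector of bin sizes summing to 20.
#' @return A [recoding_scheme()].
#' @export
random_scheme <- function(bin_sizes = c(5L, 4L, 4L, 3L, 3L, 1L)) {
  bin_sizes <- as.integer(bin_sizes)
  if (sum(bin_sizes) != 20L) stop("bin sizes must sum to 20")
  perm <- sample(aa_alphabet()$symbols)
  ends <- cumsum(bin_sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  bins <- Map(function(s, e) perm[s:e], starts, ends)
  recoding_scheme(bins, name = "random")
}

#' Percent similarity between two recoding schemes
#'
#' Size-constrained optimal bin matching: bins may only be paired with bins of
#' equal size; over all such pairings the total intersection cardinality is
#' maximised, and the similarity is that count expressed as a percentage of
#' the 20 amino acids. Values are multiples of 5; identical partitions (up to
#' bin relabelling) score 100, and 0 is attainable because equal-size bins of
#' two partitions can be pairwise disjoint.
#'
#' @param a,b two [recoding_scheme()]s with identical bin-size multisets.
#' @return Percent similarity in `{0, 5, ..., 100}`.
#' @export
scheme_similarity <- function(a, b) {
  sa <- unname(vapply(a$bins, length, 1L))
  sb <- unname(vapply(b$bins, length, 1L))
  if (!identical(sort(sa), sort(sb)))
    stop("schemes have different bin-size multisets")
  total <- 0L
  for (sz in unique(sa)) {
    A <- a$bins[sa == sz]
    B <- b$bins[sb == sz]
    m <- length(A)
    inter <- matrix(0L, m, m)
    for (i in seq_len(m)) for (j in seq_len(m))
      inter[i, j] <- length(intersect(A[[i]], B[[j]]))
    total <- total + .best_assignment(inter)
  }
  100 * total / 20
}

# maximum-weight perfect assignment by enumeration (bin classes are tiny)
.best_assignment <- function(w) {
  m <- nrow(w)
  if (m == 1L) return(w[1, 1])
  perms <- .permutations(m)
  best <- 0L
  for (p in seq_len(nrow(perms))) {
    s <- sum(w[cbind(seq_len(m), perms[p, ])])
    if (s > best) best <- s
  }
  best
}

.permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(m - 1L)
  out <- matrix(0L, 0, m)
  for (k in seq_len(m)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Search for random schemes at a target similarity to a reference
#'
#' Rejection sampling: random schemes from the reference's bin-size template
#' are drawn and kept when their [scheme_similarity()] to the reference equals
#' `target_percent`. For a 90% target a constructive shortcut is available
#' (displace exactly two amino acids between two bins), verified by
#' re-scoring; it is used when `shortcut = TRUE` because 90%-similar schemes
#' are rare under uniform draws.
#'
#' @param target_percent a multiple of 5 in `[0, 100]`.
#' @param reference reference [recoding_scheme()].
#' @param n_wanted number of schemes to return.
#' @param max_draws rejection-sampling budget.
#' @param shortcut use the constructive two-swap generator for a 90% target.
#' @return List of [recoding_scheme()]s (fewer than `n_wanted` if the draw
#'   budget is exhausted, with a warning).
#' @export
find_schemes_at_similarity <- function(target_percent, reference,
                                       n_wanted = 10L, max_draws = 200000L,
                                       shortcut = TRUE) {
  if (target_percent %% 5 != 0 || target_percent < 0 || target_percent > 100)
    stop("target must be a multiple of 5 in [0, 100]")
  if (target_percent == 100 && n_wanted > 1L)
    stop("only the reference itself has 100% similarity (up to relabelling)")
  sizes <- vapply(reference$bins, length, 1L)
  out <- list()
  if (target_percent == 90 && shortcut) {
    draws <- 0L
    while (length(out) < n_wanted && draws < max_draws) {
      draws <- draws + 1L
      cand <- .two_swap(reference)
      if (scheme_similarity(cand, reference) == 90)
        out[[length(out) + 1L]] <- cand
    }
  } else {
    for (d in seq_len(max_draws)) {
      cand <- random_scheme(sizes)
      if (scheme_similarity(cand, reference) == target_percent) {
        out[[length(out) + 1L]] <- cand
        if (length(out) >= n_wanted) break
      }
    }
  }
  if (length(out) < n_wanted)
    warning("draw budget exhausted: found ", length(out), " of ", n_wanted)
  out
}

# displace two amino acids between two distinct bins of the reference
.two_swap <- function(reference) {
  bins <- reference$bins
  repeat {
    ij <- sample(length(bins), 2L)
    a <- sample(bins[[ij[1]]], 1L)
    b <- sample(bins[[ij[2]]], 1L)
    bins2 <- bins
    bins2[[ij[1]]] <- sort(c(setdiff(bins2[[ij[1]]], a), b))
    bins2[[ij[2]]] <- sort(c(setdiff(bins2[[ij[2]]], b), a))
    return(recoding_scheme(unname(bins2), name = "two_swap"))
  }
}

#' Read and write recoding-scheme files
#'
#' Plain-text format, one line per bin: `label: MEMBERS`, e.g. `F: C` for the
#' singleton cysteine bin. Round-trips through [read_scheme()].
#'
#' @param path file path.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  bins <- lapply(lines, function(l) {
    parts <- strsplit(l, ":")[[1]]
    if (length(parts) != 2L) stop("malformed scheme line: ", l)
    strsplit(gsub("[[:space:]]", "", parts[2]), "")[[1]]
  })
  nm <- sub("\\..*$", "", basename(path))
  recoding_scheme(bins, name = nm)
}

#' @rdname read_scheme
#' @param scheme a [recoding_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  lines <- vapply(names(scheme$bins), function(l)
    paste0(l, ": ", paste(scheme$bins[[l]], collapse = "")), character(1))
  writeLines(lines, path)
  invisible(path)
}
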