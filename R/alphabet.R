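#' Character-state alphabets
#'
#' An alphabet is an ordered set of single-character state codes plus a set of
#' codes treated as missing/unobserved. The amino-acid alphabet has 20 states
#' (PAML/phangorn order `ARNDCQEGHILKMFPSTWYV`); recoded alphabets have 6.
#'
#' @param symbols character vector of unique single-character state codes.
#' @param missing character vector of codes treated as unobserved. Must be
#'   disjoint from `symbols`.
#' @return An object of class `"aa_alphabet"` with elements `symbols` and
#'   `missing`.
#' @export
#' @examples
#' alphabet(c("A", "C", "G", "T"))
alphabet <- function(symbols, missing = c("-", "?", "X")) {
  symbols <- as.character(symbols)
  missing <- as.character(missing)
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  if (any(nchar(symbols) != 1L) || any(nchar(missing) != 1L))
    stop("alphabet codes must be single characters")
  if (length(intersect(symbols, missing)))
    stop("missing codes must be disjoint from state symbols")
  structure(list(symbols = symbols, missing = missing), class = "aa_alphabet")
}

#' @rdname alphabet
#' @details `aa_alphabet()` returns the canonical 20-state amino-acid alphabet.
#'   The ambiguity codes B, Z, J, U, O are not part of the state space; readers
#'   convert them to missing with a warning.
#' @export
aa_alphabet <- function() {
  alphabet(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
           missing = c("-", "?", "X"))
}

#' @rdname alphabet
#' @param n_states number of reduced states (bins).
#' @details `recoded_alphabet()` returns the reduced alphabet used for recoded
#'   data: bin labels `A`, `B`, ... in bin order, FASTA-compatible.
#' @export
recoded_alphabet <- function(n_states = 6L) {
  alphabet(LETTERS[seq_len(n_states)], missing = c("-", "?", "X"))
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("Alphabet:", length(x$symbols), "states [",
      paste(x$symbols, collapse = ""), "] missing {",
      paste(x$missing, collapse = " "), "}\n")
  invisible(x)
}

n_states <- function(a) length(a$symbols)

# residues silently convertible to missing in amino-acid data
.aa_soft_missing <- c("B", "Z", "J", "U", "O")
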