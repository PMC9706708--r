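#' Alignment container
#'
#' A multiple sequence alignment is stored as a taxa x sites character matrix
#' over a declared alphabet. Row names are the (unique) taxon labels. All cells
#' must belong to the alphabet's state symbols or its missing codes.
#'
#' @param mat character matrix (taxa x sites) with row names, or a named
#'   character vector of equal-length sequences.
#' @param alph an [alphabet()] describing the state space.
#' @return An object of class `"alignment"`: the character matrix with an
#'   `alphabet` attribute.
#' @export
#' @examples
#' alignment(c(t1 = "ACD", t2 = "A-D"), aa_alphabet())
alignment <- function(mat, alph = aa_alphabet()) {
  if (is.character(mat) && is.null(dim(mat))) {
    if (is.null(names(mat))) stop("sequences must be named by taxon")
    lens <- nchar(mat)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: taxon '", names(mat)[which(lens != lens[1])[1]],
           "' has a different length")
    mat <- do.call(rbind, strsplit(mat, ""))
    rownames(mat) <- names(lens)
  }
  if (!is.matrix(mat) || !is.character(mat)) stop("need a character matrix")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("taxa labels must be present and unique")
  if (ncol(mat) < 1L) stop("alignment must have at least one site")
  ok <- mat %in% c(alph$symbols, alph$missing)
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    stop("symbols outside alphabet: ", paste(bad, collapse = " "))
  }
  structure(mat, alphabet = alph, class = c("alignment", "matrix"))
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", nrow(x), "taxa x", ncol(x), "sites,",
      length(attr(x, "alphabet")$symbols), "states\n")
  invisible(x)
}

#' @rdname alignment
#' @param aln an alignment.
#' @export
taxa_names <- function(aln) rownames(aln)

aln_alphabet <- function(aln) attr(aln, "alphabet")

# Map soft ambiguity codes of amino-acid data to missing, with one warning.
.sanitize_aa <- function(mat, alph) {
  soft <- mat %in% .aa_soft_missing
  if (any(soft)) {
    warning(sum(soft), " ambiguous residues (",
            paste(sort(unique(mat[soft])), collapse = ","),
            ") converted to missing")
    mat[soft] <- alph$missing[1]
  }
  mat
}

#' Read an alignment
#'
#' Reads FASTA, relaxed PHYLIP (sequential or interleaved, whitespace-delimited
#' names) or a NEXUS DATA/CHARACTERS block. Lower-case residues are upcased.
#' For the amino-acid alphabet the ambiguity codes B, Z, J, U, O are converted
#' to missing with a warning.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip"`, `"nexus"`. Default guesses from
#'   the file extension and content.
#' @param alph target [alphabet()].
#' @return An [alignment()].
#' @export
read_alignment <- function(path, format = c("guess", "fasta", "phylip", "nexus"),
                           alph = aa_alphabet()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "guess") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (grepl("^>", first)) "fasta"
      else if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
      else "phylip"
  }
  seqs <- switch(format,
    fasta  = .parse_fasta(lines),
    phylip = .parse_phylip(lines),
    nexus  = .parse_nexus(lines))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: taxon '", names(seqs)[which(lens != lens[1])[1]],
         "' has length ", lens[which(lens != lens[1])[1]], " not ", lens[1])
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  if (identical(alph$symbols, aa_alphabet()$symbols))
    mat <- .sanitize_aa(mat, alph)
  alignment(mat, alph)
}

.parse_fasta <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA headers found")
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  to <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, to[i])]
    gsub("[[:space:]]", "", paste(body, collapse = ""))
  }, character(1))
  names(seqs) <- nm
  seqs
}

.parse_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(head) < 2L || anyNA(suppressWarnings(as.integer(head[1:2]))))
    stop("malformed PHYLIP header")
  ntax <- as.integer(head[1]); nsites <- as.integer(head[2])
  body <- lines[-1]
  if (length(body) < ntax) stop("PHYLIP file truncated")
  nm <- character(ntax); seqs <- character(ntax)
  # first block carries the names
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    nm[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  rest <- body[-seq_len(ntax)]
  # interleaved continuation blocks: bare sequence chunks, cycling over taxa
  i <- 0L
  for (ln in rest) {
    chunk <- gsub("[[:space:]]", "", ln)
    if (!nzchar(chunk)) next
    seqs[i %% ntax + 1L] <- paste0(seqs[i %% ntax + 1L], chunk)
    i <- i + 1L
  }
  if (any(nchar(seqs) != nsites))
    stop("PHYLIP sequences do not match stated length ", nsites,
         " (taxon '", nm[which(nchar(seqs) != nsites)[1]], "')")
  names(seqs) <- nm
  seqs
}

.parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  m <- regexpr("(?is)matrix(.*?);", txt, perl = TRUE)
  if (m == -1L) stop("no MATRIX statement in NEXUS file")
  block <- regmatches(txt, m)
  block <- sub("(?is)^matrix", "", block, perl = TRUE)
  block <- sub(";$", "", block)
  rows <- strsplit(block, "\n")[[1]]
  rows <- rows[nzchar(trimws(rows))]
  rows <- rows[!grepl("^\\s*\\[", rows)]  # comments
  seqs <- list()
  for (r in rows) {
    parts <- strsplit(trimws(r), "[[:space:]]+")[[1]]
    if (length(parts) < 2L) next
    nm <- gsub("^'|'$", "", parts[1])
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]],
                         paste(parts[-1], collapse = ""))
  }
  unlist(seqs)
}

#' Write an alignment
#'
#' Writes FASTA or relaxed sequential PHYLIP. Output is byte-stable for
#' identical inputs and round-trips through [read_alignment()].
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!inherits(aln, "alignment")) stop("not an alignment")
  if (nrow(aln) == 0L) stop("alignment has no taxa")
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", names(seqs), "\n", seqs), con)
  } else {
    writeLines(paste(length(seqs), nchar(seqs[1])), con)
    writeLines(paste(names(seqs), seqs), con)
  }
  invisible(path)
}
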