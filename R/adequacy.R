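#' Compositional-heterogeneity adequacy statistics
#'
#' `div_stat` is the mean number of distinct non-missing states per alignment
#' column (the diversity statistic; recoding can only decrease it, because
#' state merging is monotone). `mean_comp_stat` is the mean over taxa of the
#' summed absolute differences between taxon-specific and global empirical
#' state frequencies, computed over non-missing cells.
#'
#' @param aln an [alignment()].
#' @return A single numeric value.
#' @export
#' @examples
#' a <- alignment(c(t1 = "AC", t2 = "CA"), aa_alphabet())
#' div_stat(a)  # 2
div_stat <- function(aln) {
  alph <- aln_alphabet(aln)
  mat <- unclass(aln)
  miss <- matrix(mat %in% alph$missing, nrow = nrow(mat))
  mean(vapply(seq_len(ncol(mat)), function(j) {
    length(unique(mat[!miss[, j], j]))
  }, numeric(1)))
}

#' @rdname div_stat
#' @export
mean_comp_stat <- function(aln) {
  alph <- aln_alphabet(aln)
  mat <- unclass(aln)
  k <- length(alph$symbols)
  counts <- t(apply(mat, 1L, function(row) {
    tabulate(match(row, alph$symbols), nbins = k)
  }))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("taxon with all-missing data: ",
                          rownames(mat)[which(tot == 0)[1]])
  f_taxon <- counts / tot
  f_global <- colSums(counts) / sum(counts)
  mean(rowSums(abs(sweep(f_taxon, 2L, f_global))))
}

#' Posterior predictive analysis of an adequacy statistic
#'
#' For each of `n_sims` draws (with replacement) from the posterior samples,
#' an alignment of the observed dimensions is simulated under the sampled
#' tree and model, the statistic is computed, and the observed value is
#' summarised against the predictive distribution as a signed Z-score
#' `(observed - predictive mean) / predictive sd`. Observed missing cells are
#' masked at the same positions in every predictive replicate so both sides
#' of the comparison use identical cell sets.
#'
#' @param observed the observed [alignment()].
#' @param samples posterior draws from [sample_posterior()] (each with `tree`
#'   and `model`).
#' @param statistic `"div"` or `"mean_comp"`.
#' @param n_sims number of predictive simulations (default one per retained
#'   posterior sample).
#' @return List of class `"ppa_result"`: `statistic`, `observed`,
#'   `predictive_mean`, `predictive_sd`, `z`, `n_sims`, `band`.
#' @export
ppa <- function(observed, samples, statistic = c("div", "mean_comp"),
                n_sims = NULL) {
  statistic <- match.arg(statistic)
  if (length(samples) < 2L) stop("need at least two posterior samples")
  if (is.null(n_sims)) n_sims <- length(samples)
  if (n_sims < 2L) stop("need at least two predictive simulations")
  stat_fun <- if (statistic == "div") div_stat else mean_comp_stat
  alph <- aln_alphabet(observed)
  miss_mask <- matrix(unclass(observed) %in% alph$missing, nrow = nrow(observed))
  draw_idx <- sample.int(length(samples), n_sims, replace = TRUE)
  preds <- vapply(draw_idx, function(i) {
    s <- samples[[i]]
    sim <- simulate_alignment(s$tree, s$model, ncol(observed), alph = alph)
    sim <- sim[rownames(observed), , drop = FALSE]  # align taxon order
    m <- unclass(sim)
    m[miss_mask] <- alph$missing[1]
    stat_fun(alignment(m, alph))
  }, numeric(1))
  obs <- stat_fun(observed)
  pm <- mean(preds); psd <- stats::sd(preds)
  z <- if (psd > 0) (obs - pm) / psd else NA_real_
  if (is.na(z)) warning("predictive standard deviation is zero; Z undefined")
  structure(list(statistic = statistic, observed = obs, predictive_mean = pm,
                 predictive_sd = psd, z = z, n_sims = n_sims,
                 band = if (is.finite(z)) fit_band(z) else NA_character_),
            class = "ppa_result")
}

#' @export
print.ppa_result <- function(x, ...) {
  cat(sprintf("PPA-%s: observed %.4f, predictive %.4f +/- %.4f, Z = %.2f (%s)\n",
              x$statistic, x$observed, x$predictive_mean, x$predictive_sd,
              x$z, x$band))
  invisible(x)
}

#' Interpretation band for a PPA Z-score
#'
#' `|z| <= 2` adequate; `2 < |z| <= 3` acceptable; `3 < |z| <= 5`
#' acceptable-to-fairly-poor; `5 < |z| <= 10` poor; `|z| > 10` very poor.
#'
#' @param z finite Z-score (signed).
#' @return Band label.
#' @export
fit_band <- function(z) {
  if (!is.finite(z)) stop("z must be finite")
  a <- abs(z)
  if (a <= 2) "adequate"
  else if (a <= 3) "acceptable"
  else if (a <= 5) "acceptable-to-fairly-poor"
  else if (a <= 10) "poor"
  else "very poor"
}
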