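# Entropy-based saturation statistics.
#
# Under full substitution saturation, the nucleotides observed at a site are
# modelled as one draw from a multinomial distribution whose probabilities are
# the overall base frequencies of the alignment. The test compares per-site
# information content against the exact entropy of that multinomial.

LOG2 <- log(2)

#' Expected entropy of a multinomial sample (full saturation)
#'
#' Exact entropy, in bits, of a multinomial draw with `n` observations over the
#' four nucleotides with probabilities `p`:
#' \deqn{H(X) = -\log_2 n! - n \sum_i p_i \log_2 p_i +
#'       \sum_i \sum_{x=0}^{n} \binom{n}{x} p_i^x (1-p_i)^{n-x} \log_2 x!}
#' This is the reference value an alignment's mean per-site information is
#' compared against: at full saturation site patterns are independent
#' multinomial draws and their expected information equals this entropy.
#' Categories with \eqn{p_i = 0} contribute nothing; factorials are evaluated
#' through `lgamma`, and the binomial expectation of \eqn{\log x!} is a finite
#' exact sum.
#'
#' @param n Number of observations (taxa with a non-missing state), `>= 1`.
#' @param p Probability 4-vector (overall base frequencies), summing to 1.
#' @return Entropy in bits (a non-negative scalar).
#' @examples
#' expected_full_entropy(1, rep(0.25, 4)) # = 2 bits
#' @export
expected_full_entropy <- function(n, p) {
  if (length(n) != 1L || n < 1 || n != round(n)) stop("n must be an integer >= 1")
  check_simplex(p)
  p <- p[p > 0]
  H <- -lgamma(n + 1) / LOG2 - n * sum(p * log2(p))
  x <- 0:n
  lx <- lgamma(x + 1) / LOG2
  for (pi in p) H <- H + sum(dbinom(x, n, pi) * lx)
  H
}

check_simplex <- function(p) {
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a non-negative 4-vector summing to 1")
  invisible(p)
}

#' Information content of an observed site
#'
#' \eqn{I(x) = -\log_2 P(X = x)} where \eqn{P} is the multinomial density with
#' `n_obs` trials and probabilities `p`. High values flag site patterns that
#' are surprising under the saturation model.
#'
#' @param counts A `site_counts()` result, or a bare integer 4-vector of
#'   A,C,G,T counts.
#' @param p Probability 4-vector (overall base frequencies).
#' @return Information in bits.
#' @examples
#' site_information(c(8, 0, 0, 0), rep(0.25, 4)) # 16 bits
#' @export
site_information <- function(counts, p) {
  if (is.list(counts)) counts <- counts$counts
  if (length(counts) != 4L || any(counts < 0)) stop("counts must be 4 non-negative integers")
  check_simplex(p)
  if (sum(counts) < 1L) stop("n_obs must be >= 1")
  if (any(counts > 0 & p == 0))
    entsat_stop("entsat_infinite_information",
                "observed state has zero probability under the supplied composition")
  drop(site_information_cols(matrix(counts, 4L, 1L), p))
}

# vectorised information content over the columns of a 4 x S count matrix
site_information_cols <- function(cm, p) {
  nobs <- colSums(cm)
  lp <- ifelse(p > 0, log(p), 0)
  -(lgamma(nobs + 1) - colSums(lgamma(cm + 1)) + colSums(cm * lp)) / LOG2
}

#' One-sample t-statistic of information against full-saturation entropy
#'
#' \deqn{t = \frac{\bar I - H_{\mathrm{full}}}{s_I / \sqrt{S}}}
#' with \eqn{\bar I, s_I} the sample mean and standard deviation (S-1
#' denominator) of the per-site information over the S sites used. Site
#' patterns carrying historical signal (conserved or clade-structured columns)
#' are improbable under the saturation multinomial, so their information
#' content exceeds the full-saturation entropy: alignments far from saturation
#' have large positive t, while values near zero are consistent with full
#' saturation. A locus is flagged saturated when the statistic falls below a
#' calibrated critical value (see [predict_tcrit()]).
#'
#' @param informations Numeric vector of per-site information, length >= 2.
#' @param H_full Full-saturation entropy in the same units (bits).
#' @return The t statistic (scalar).
#' @export
entropy_t_statistic <- function(informations, H_full) {
  S <- length(informations)
  if (S < 2L)
    entsat_stop("entsat_insufficient_sites", "need at least 2 sites for the t statistic")
  m <- mean(informations)
  s <- stats::sd(informations)
  if (s == 0) {
    if (isTRUE(all.equal(m, H_full))) return(0)
    entsat_stop("entsat_degenerate_variance",
                "zero variance in site information with mean != full entropy")
  }
  (m - H_full) / (s / sqrt(S))
}

#' Run the entropy saturation test on an alignment
#'
#' Computes the test in one of two modes. `"all_sites"` uses every alignment
#' column; `"informative_sites"` restricts both the base composition and the
#' tested columns to parsimony-informative sites, which removes the influence
#' of slowly evolving sites on the composition estimate and is the recommended
#' mode for screening. Columns with missing data contribute their own number
#' of observed states to the information term; the reference entropy is
#' evaluated at the modal per-column count of observed states (the full taxon
#' count for complete columns).
#'
#' If a calibrated critical-value model is supplied, the observed statistic is
#' compared against the value predicted for this alignment's taxon count and
#' number of tested sites, and a saturation decision is reported together with
#' the expected false/true-positive rates of the calibration cell.
#'
#' @param aln An [alignment()] object with at least 2 taxa.
#' @param mode `"informative_sites"` (default) or `"all_sites"`.
#' @param crit Optional critical-value model from [fit_crit_model()],
#'   [read_crit_model()] or [default_crit_model()].
#' @return An object of class `"entsat_test"`: list with `t_obs`, `mode`,
#'   `H_full`, `mean_I`, `sd_I`, `S`, `n_used`, `p_used`, and, when `crit` is
#'   given, `t_crit`, `decision` (`"saturated"` or `"unsaturated"`),
#'   `expected_fpr`, `expected_tpr`, `extrapolated`.
#' @examples
#' set.seed(1)
#' aln <- alignment(matrix(sample(c("A", "C", "G", "T"), 8 * 200, TRUE), 8, 200))
#' run_saturation_test(aln, mode = "all_sites")
#' @export
run_saturation_test <- function(aln, mode = c("informative_sites", "all_sites"),
                                crit = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "entsat_aln"))
  if (aln$n_taxa < 2L) stop("need at least 2 taxa")
  sites <- if (mode == "informative_sites") which(informative_mask(aln)) else
    seq_len(aln$n_sites)
  if (length(sites) < 2L)
    entsat_stop("entsat_insufficient_sites",
                sprintf("only %d usable site(s) in mode %s", length(sites), mode))
  comp <- base_frequencies(aln, sites, source = mode)
  cm <- site_count_matrix(aln, sites)
  nobs <- colSums(cm)
  keep <- nobs > 0L
  cm <- cm[, keep, drop = FALSE]
  if (any(cm > 0 & comp$p == 0))
    entsat_stop("entsat_infinite_information",
                "observed state with zero overall frequency")
  I <- site_information_cols(cm, comp$p)
  H_full <- expected_full_entropy(comp$n_effective, comp$p)
  t_obs <- entropy_t_statistic(I, H_full)
  res <- list(t_obs = t_obs, mode = mode, H_full = H_full,
              mean_I = mean(I), sd_I = stats::sd(I), S = length(I),
              n_used = comp$n_effective, p_used = comp,
              t_crit = NA_real_, decision = NA_character_,
              expected_fpr = NA_real_, expected_tpr = NA_real_,
              extrapolated = NA)
  if (!is.null(crit)) {
    pr <- predict_tcrit(crit, aln$n_taxa, length(I))
    res$t_crit <- pr$t_crit
    res$decision <- if (t_obs < pr$t_crit) "saturated" else "unsaturated"
    res$expected_fpr <- pr$expected_fpr
    res$expected_tpr <- pr$expected_tpr
    res$extrapolated <- pr$extrapolation
  }
  class(res) <- "entsat_test"
  res
}

#' @export
print.entsat_test <- function(x, ...) {
  cat("Entropy saturation test (", x$mode, ")\n", sep = "")
  cat(sprintf("  sites used (S):        %d\n", x$S))
  cat(sprintf("  full entropy (bits):   %.4f at n = %d\n", x$H_full, x$n_used))
  cat(sprintf("  mean/sd information:   %.4f / %.4f bits\n", x$mean_I, x$sd_I))
  cat(sprintf("  t_obs:                 %.4f\n", x$t_obs))
  if (!is.na(x$t_crit)) {
    cat(sprintf("  t_crit (calibrated):   %.4f%s\n", x$t_crit,
                if (isTRUE(x$extrapolated)) "  [extrapolated]" else ""))
    cat(sprintf("  decision:              %s\n", x$decision))
    cat(sprintf("  expected FPR / TPR:    %.3f / %.3f\n",
                x$expected_fpr, x$expected_tpr))
  }
  invisible(x)
}
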