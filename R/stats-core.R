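## Closed-form statistics used by both enrichment pipelines.
##
## All tail probabilities are evaluated through R's survival-function
## parameterisations (pbinom/pnbinom/pchisq), never by naive term-by-term
## summation, so that very small p-values retain full double precision.

#' Per-feature success probability
#'
#' Converts a per-nucleotide, per-sample background mutation rate `p` into
#' the probability that a feature of `L` testable nucleotides carries at
#' least one mutation in a sample: `p_n = 1 - (1 - p)^L`. This is the
#' binomial success probability used by the sample-count burden test.
#'
#' Evaluated as `-expm1(L * log1p(-p))` so that tiny rates over large
#' features do not underflow.
#'
#' @param per_nt_rate Background mutation probability per nucleotide per
#'   sample, in `[0, 1]`.
#' @param feature_length Total testable feature length in nucleotides
#'   (`>= 1`).
#' @return Probability `p_n` in `[0, 1]`. Vectorised over both arguments.
#' @examples
#' per_feature_success_prob(1e-6, 2000)
#' @export
per_feature_success_prob <- function(per_nt_rate, feature_length) {
  stopifnot(is.numeric(per_nt_rate), is.numeric(feature_length))
  if (any(per_nt_rate < 0 | per_nt_rate > 1)) {
    stop("per_nt_rate must lie in [0, 1]")
  }
  if (any(feature_length < 1)) {
    stop("feature_length must be >= 1")
  }
  -expm1(feature_length * log1p(-per_nt_rate))
}

#' Binomial burden p-value
#'
#' Upper-tail binomial probability of observing at least `n` mutated
#' samples out of a cohort of `N`, where each sample is mutated in the
#' feature with probability `p_n` (see [per_feature_success_prob()]):
#' `sum_{i=n}^{N} C(N, i) p_n^i (1 - p_n)^(N - i)`.
#'
#' `n = 0` returns exactly 1: absence of evidence is never significant.
#'
#' @param n_mutated_samples Number of samples with at least one foreground
#'   mutation in the feature.
#' @param cohort_size Total number of samples tested, `N >= n`.
#' @param p_n Per-sample probability of the feature being mutated.
#' @return Upper-tail p-value in `[0, 1]`.
#' @export
binomial_burden_pvalue <- function(n_mutated_samples, cohort_size, p_n) {
  stopifnot(length(n_mutated_samples) == 1, length(cohort_size) == 1,
            length(p_n) == 1)
  if (is.na(n_mutated_samples) || n_mutated_samples < 0 ||
      n_mutated_samples > cohort_size) {
    stop("require 0 <= n_mutated_samples <= cohort_size")
  }
  if (is.na(p_n) || p_n < 0 || p_n > 1) stop("p_n must lie in [0, 1]")
  if (n_mutated_samples == 0) return(1)
  stats::pbinom(n_mutated_samples - 1, cohort_size, p_n, lower.tail = FALSE)
}

#' Negative-binomial burden p-value
#'
#' Significance of observing `k` total mutations in a feature of length
#' `L` across `N` samples with per-nucleotide rate `p`. With
#' `x = L * N` nucleotide trials, the p-value is
#' `sum_{r=0}^{x-k} C(k + r - 1, r) p^k (1 - p)^r`, i.e. the probability
#' that the k-th mutation arrives within the first `x` trials. This counts
#' mutations rather than mutated samples, so recurrent mutation within a
#' single sample contributes evidence.
#'
#' `k = 0` returns exactly 1.
#'
#' @param total_mutations Total foreground mutation count `k` in the
#'   feature.
#' @param feature_length Feature length `L` in nucleotides.
#' @param cohort_size Number of samples `N`.
#' @param per_nt_rate Background mutation probability `p` per nucleotide
#'   per sample; must be positive when `k > 0`.
#' @return Lower-tail negative-binomial p-value in `[0, 1]`.
#' @export
negbin_pvalue <- function(total_mutations, feature_length, cohort_size,
                          per_nt_rate) {
  stopifnot(length(total_mutations) == 1, total_mutations >= 0,
            feature_length >= 1, cohort_size >= 1)
  x <- feature_length * cohort_size
  if (total_mutations > x) {
    stop("total_mutations exceeds the number of nucleotide trials L * N")
  }
  if (total_mutations == 0) return(1)
  if (per_nt_rate <= 0 || per_nt_rate > 1) {
    stop("per_nt_rate must lie in (0, 1] when total_mutations > 0")
  }
  if (per_nt_rate == 1) return(1)
  ## number of failures before the k-th success is at most x - k
  stats::pnbinom(x - total_mutations, size = total_mutations,
                 prob = per_nt_rate)
}

#' Combine p-values by Fisher's method
#'
#' Computes `X = -2 * sum(log(p))` and refers it to a chi-square
#' distribution with `2 m` degrees of freedom, `m` the number of
#' component p-values. A single component is returned unchanged (the
#' chi-square with 2 df is exactly the inverse of the log transform).
#'
#' Components of exactly zero are clamped to `floor` before taking logs;
#' negative components or components above 1 are an error.
#'
#' @param p_values Numeric vector of component p-values in `(0, 1]`
#'   (zeros tolerated via `floor`).
#' @param floor Smallest value substituted for a component of exactly 0.
#' @return The combined p-value.
#' @export
fisher_combine <- function(p_values, floor = 1e-300) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop("p_values must be non-empty")
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("all p_values must lie in [0, 1]")
  }
  p_values <- pmax(p_values, floor)
  x <- -2 * sum(log(p_values))
  stats::pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; a thin, range-checked wrapper
#' around `p.adjust(method = "BH")` that preserves input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order, each in `[p, 1]`.
#' @export
bh_fdr <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("all p_values must lie in [0, 1]")
  }
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}
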