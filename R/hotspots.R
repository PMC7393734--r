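## Hotspot detection and positional clustering statistics.
##
## Hotspots are built by progressively chaining sorted mutation positions
## whose consecutive gaps do not exceed `max_gap` (inclusive), then
## testing each surviving group directly on its own span. The weighted
## average proximity (WAP) statistic scores positional clustering of all
## mutations in a region with a Gaussian distance-decay kernel and gets
## its significance from uniform positional permutations.

#' Find candidate hotspots by gap chaining
#'
#' Single left-to-right pass over sorted positions: a new group starts
#' whenever the gap to the previous mutated position exceeds `max_gap`
#' (the boundary is inclusive: positions exactly `max_gap` apart chain).
#' Groups with fewer than `min_mutations` mutations or fewer than
#' `min_samples` distinct samples are dropped.
#'
#' @param positions Numeric vector of 1-based mutation positions within
#'   one feature (any order; duplicates allowed).
#' @param sample_ids Character vector parallel to `positions`.
#' @param max_gap Maximum chaining distance in nucleotides (default 50).
#' @param min_mutations Minimum mutations per reported hotspot
#'   (default 5).
#' @param min_samples Minimum distinct samples per reported hotspot
#'   (default 3).
#' @return Data frame with `start`, `end` (1-based inclusive), `span`,
#'   `n_mutations`, `n_samples`; zero rows when nothing survives.
#' @export
find_candidate_hotspots <- function(positions, sample_ids, max_gap = 50,
                                    min_mutations = 5, min_samples = 3) {
  stopifnot(max_gap >= 1, length(positions) == length(sample_ids))
  empty <- data.frame(start = numeric(0), end = numeric(0), span = numeric(0),
                      n_mutations = integer(0), n_samples = integer(0))
  if (length(positions) == 0) return(empty)
  ord <- order(positions)
  pos <- positions[ord]
  sam <- as.character(sample_ids)[ord]
  grp <- cumsum(c(0, diff(pos) > max_gap))
  out <- lapply(split(seq_along(pos), grp), function(ii) {
    data.frame(start = pos[ii[1]], end = pos[ii[length(ii)]],
               span = pos[ii[length(ii)]] - pos[ii[1]] + 1,
               n_mutations = length(ii),
               n_samples = length(unique(sam[ii])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[out$n_mutations >= min_mutations & out$n_samples >= min_samples,
             , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hotspot significance
#'
#' Tests a hotspot directly on its own span against the enclosing
#' feature's aggregate background rate. The default binomial test counts
#' samples: success probability `p_n = 1 - (1 - rate)^span` and `n` the
#' number of distinct mutated samples in the hotspot. The
#' negative-binomial alternative counts the hotspot's mutations over
#' `span * N` trials.
#'
#' @param hotspot One row of [find_candidate_hotspots()] output (list or
#'   single-row data frame with `span`, `n_samples`, `n_mutations`).
#' @param cohort_size Total number of samples `N`.
#' @param aggregate_rate The feature's aggregate per-nucleotide
#'   background rate.
#' @param test `"binomial"` (default) or `"negbinom"`.
#' @return The hotspot p-value.
#' @export
hotspot_pvalue <- function(hotspot, cohort_size, aggregate_rate,
                           test = c("binomial", "negbinom")) {
  test <- match.arg(test)
  if (test == "binomial") {
    p_n <- per_feature_success_prob(aggregate_rate, hotspot$span)
    binomial_burden_pvalue(hotspot$n_samples, cohort_size, p_n)
  } else {
    negbin_pvalue(hotspot$n_mutations, hotspot$span, cohort_size,
                  aggregate_rate)
  }
}

#' Weighted average proximity (WAP) statistic
#'
#' Mean over all unordered position pairs of a Gaussian proximity weight
#' `exp(-d^2 / (2 * scale^2))`, `d` the pairwise distance. Lies in
#' `(0, 1]`, equals 1 exactly when all positions coincide, and is
#' translation-invariant.
#'
#' @param positions Numeric vector of at least two 1-based positions.
#' @param scale Kernel length scale in nucleotides (default 30).
#' @return The WAP score.
#' @export
wap_statistic <- function(positions, scale = 30) {
  if (length(positions) < 2) {
    stop("WAP requires at least two positions")
  }
  stopifnot(scale > 0)
  d <- as.numeric(stats::dist(positions))
  mean(exp(-d^2 / (2 * scale^2)))
}

## WAP scores for a matrix of permuted position sets, one column per
## permutation; vectorised over permutations, looped over pairs.
wap_statistic_columns <- function(M, scale) {
  m <- nrow(M)
  acc <- numeric(ncol(M))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- M[i, ] - M[j, ]
      acc <- acc + exp(-d^2 / (2 * scale^2))
    }
  }
  acc / (m * (m - 1) / 2)
}

#' WAP permutation test
#'
#' Significance of the observed WAP score under a uniform positional
#' null: each permutation redraws the same number of positions
#' independently and uniformly within the feature's intervals
#' (mutations are treated as exchangeable across samples). The p-value
#' uses the add-one correction
#' `(1 + #\{permuted WAP >= observed\}) / (1 + n_permutations)`, so it is
#' bounded below by `1 / (1 + n_permutations)`.
#'
#' @param feature A `GRanges` of the feature's intervals (or a
#'   single-feature `feature_set`).
#' @param positions Numeric vector of observed 1-based positions
#'   (at least two).
#' @param n_permutations Number of permutations (default 10000).
#' @param scale WAP kernel scale (default 30 nt).
#' @param seed Integer seed; results are bit-for-bit reproducible for a
#'   fixed seed.
#' @return List with `observed_wap`, `n_permutations`, `p_value`.
#' @export
wap_permutation_pvalue <- function(feature, positions, n_permutations = 10000,
                                   scale = 30, seed = 1) {
  if (inherits(feature, "feature_set")) feature <- feature$grl[[1]]
  if (length(positions) < 2) stop("WAP requires at least two positions")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  L <- sum(width(feature))
  if (L < length(positions)) {
    stop("feature shorter than the number of positions")
  }
  obs <- wap_statistic(positions, scale)
  m <- length(positions)
  perm <- with_local_seed(seed, {
    off <- sample.int(L, m * n_permutations, replace = TRUE)
    M <- matrix(map_offsets(feature, off), nrow = m, ncol = n_permutations)
    wap_statistic_columns(M, scale)
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  list(observed_wap = obs, n_permutations = n_permutations, p_value = p)
}
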