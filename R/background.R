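## Background mutation-rate estimation.
##
## Four methods, mirroring the tool's configurable null models:
##   global          - one rate per sample: mutations in all features over
##                     total feature length.
##   local           - per feature and sample: maximal mutation density
##                     over megabase-scale windows slid across the feature.
##   clustered       - features grouped by genomic covariates (affinity
##                     propagation); rate pooled over cluster members.
##   local_clustered - local window scan per cluster member, pooled by
##                     length-weighted mean.
## The per-feature aggregate used in testing is the geometric mean of
## sample-wise rates over samples carrying at least one foreground
## mutation in the feature, floored to avoid annihilation by zeros.

#' Global background rate for one sample
#'
#' Sum of the sample's mutation counts within all features divided by the
#' total feature length; every feature of the sample shares this rate.
#'
#' @param feature_counts Numeric vector of the sample's mutation counts
#'   per feature.
#' @param feature_lengths Numeric vector of feature lengths (nucleotides).
#' @return Per-nucleotide mutation rate.
#' @export
global_rate <- function(feature_counts, feature_lengths) {
  stopifnot(length(feature_counts) == length(feature_lengths))
  total_len <- sum(feature_lengths)
  if (total_len <= 0) stop("total feature length is zero")
  sum(feature_counts) / total_len
}

#' Local (windowed maximal) background rate
#'
#' Scans windows of `window_length` nucleotides that cover the feature,
#' slid from the placement with the feature at the window's right edge to
#' the placement with the feature at its left edge in increments of
#' `step`, clipping at chromosome bounds. The rate is the maximal
#' mutations-per-nucleotide density over these placements. A feature
#' longer than the window falls back to a single window equal to the
#' feature span, with a warning.
#'
#' @param feature_start,feature_end 1-based inclusive bounds of the
#'   feature span.
#' @param positions Sorted numeric vector of the sample's mutation
#'   positions on the feature's chromosome (1-based).
#' @param window_length Window size in nucleotides (default 1 Mb;
#'   intended range 1-2 Mb).
#' @param step Slide increment (default `window_length / 4`).
#' @param chrom_length Chromosome length for clipping; `Inf` disables the
#'   right-hand clip.
#' @return Maximal per-nucleotide mutation density over the window
#'   placements.
#' @export
local_rate <- function(feature_start, feature_end, positions,
                       window_length = 1e6, step = window_length / 4,
                       chrom_length = Inf) {
  span <- feature_end - feature_start + 1
  if (span > window_length) {
    warning("feature span (", span, " nt) exceeds window_length; ",
            "falling back to a single feature-sized window")
    starts <- feature_start
    window_length <- span
  } else {
    ## feature at right edge ... feature at left edge
    starts <- seq(feature_end - window_length + 1, feature_start, by = step)
    if (starts[length(starts)] != feature_start) {
      starts <- c(starts, feature_start)
    }
  }
  best <- 0
  for (s in starts) {
    lo <- max(1, s)
    hi <- min(chrom_length, s + window_length - 1)
    len <- hi - lo + 1
    if (len <= 0) next
    r <- count_in_window(positions, lo, hi) / len
    if (r > best) best <- r
  }
  best
}

#' Prepare per-feature genomic covariates
#'
#' Computes each feature's GC fraction from a genome FASTA and, for each
#' supplied interval-value track (bedGraph-style: chrom, start, end,
#' value), the length-weighted mean of the track value over the feature's
#' intervals. Features with no overlapping track interval receive the
#' cohort median of that covariate; the substitution count is warned.
#'
#' @param features A `feature_set`.
#' @param genome Path to an indexed FASTA file (a `.fai` is created if
#'   absent).
#' @param tracks Named character vector or list of bedGraph file paths;
#'   names become covariate names.
#' @return Data frame with `feature_id` and one numeric column per
#'   covariate (`gc` first).
#' @export
prepare_covariates <- function(features, genome, tracks = NULL) {
  stopifnot(inherits(features, "feature_set"))
  fa <- FaFile(genome)
  if (!file.exists(paste0(genome, ".fai"))) indexFa(genome)
  iv <- unlist(features$grl)
  fid <- rep(names(features$grl), lengths(features$grl))
  fa_chroms <- as.character(GenomeInfoDb::seqnames(Rsamtools::seqinfo(fa)))
  absent <- setdiff(unique(as.character(seqnames(iv))), fa_chroms)
  if (length(absent) > 0) {
    stop("chromosome(s) absent from FASTA: ", paste(absent, collapse = ", "))
  }
  seqs <- scanFa(fa, iv)
  gc_counts <- Biostrings::letterFrequency(seqs, "GC")[, 1]
  out <- data.frame(
    feature_id = names(features$grl),
    gc = as.numeric(tapply(gc_counts, factor(fid, levels = names(features$grl)),
                           sum)) / features$table$length,
    stringsAsFactors = FALSE
  )
  if (!is.null(tracks) && length(tracks) > 0) {
    tnames <- names(tracks)
    if (is.null(tnames) || any(!nzchar(tnames))) {
      tnames <- paste0("track", seq_along(tracks))
    }
    for (ti in seq_along(tracks)) {
      tg <- rtracklayer::import(tracks[[ti]], format = "bedGraph")
      hits <- findOverlaps(iv, tg)
      ww <- width(pintersect(iv[queryHits(hits)], tg[subjectHits(hits)]))
      vv <- tg$score[subjectHits(hits)] * ww
      fi <- factor(fid[queryHits(hits)], levels = names(features$grl))
      wsum <- as.numeric(tapply(ww, fi, sum))
      vsum <- as.numeric(tapply(vv, fi, sum))
      val <- vsum / wsum
      n_missing <- sum(is.na(val) | is.nan(val))
      if (n_missing > 0) {
        warning(n_missing, " feature(s) missing covariate '", tnames[ti],
                "'; cohort median substituted")
        val[is.na(val) | is.nan(val)] <- stats::median(val, na.rm = TRUE)
      }
      out[[tnames[ti]]] <- val
    }
  }
  out
}

## ---------------------------------------------------------------------
## affinity propagation
##
## Frey-Dueck message passing on a similarity matrix. Written here
## directly (vectorised responsibility/availability updates) with the
## defaults used by the clustering background method: similarity =
## negative squared Euclidean distance on z-scored covariates, preference
## = median similarity, damping 0.9.

affinity_propagation <- function(S, damping = 0.9, max_iter = 1000,
                                 convergence_iter = 100) {
  n <- nrow(S)
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  last_exemplars <- NULL
  stable <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    ## availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsums <- colSums(Rp)
    Anew <- matrix(colsums, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(R) + diag(A) > 0)
    if (!is.null(last_exemplars) && length(exemplars) > 0 &&
        identical(exemplars, last_exemplars)) {
      stable <- stable + 1
      if (stable >= convergence_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0
    }
    last_exemplars <- exemplars
  }
  exemplars <- which(diag(R) + diag(A) > 0)
  if (!converged || length(exemplars) == 0) {
    return(NULL)
  }
  assign <- exemplars[max.col(S[, exemplars, drop = FALSE],
                              ties.method = "first")]
  assign[exemplars] <- exemplars
  list(exemplars = exemplars, assignment = assign)
}

#' Cluster features by covariate similarity
#'
#' Groups features with similar genomic covariates (GC content,
#' replication timing, ...) by affinity propagation so that background
#' rates can be pooled over covariate-matched features. Covariates are
#' z-scored per column; similarity is negative squared Euclidean
#' distance; the shared preference is the median similarity. Features
#' are processed in feature-id order, so the partition is deterministic
#' and invariant to input order. If message passing does not converge,
#' all features fall back to a single cluster with a warning.
#'
#' @param profiles Data frame from [prepare_covariates()]: `feature_id`
#'   plus numeric covariate columns.
#' @param damping Message damping factor in `[0.5, 1)`.
#' @param max_iter Maximum message-passing iterations.
#' @return Data frame with `feature_id`, `cluster` (integer label) and
#'   `exemplar` (feature id of the cluster exemplar); attribute
#'   `converged` records whether the fallback was taken.
#' @export
cluster_features <- function(profiles, damping = 0.9, max_iter = 1000) {
  stopifnot(is.data.frame(profiles), "feature_id" %in% names(profiles),
            nrow(profiles) >= 2)
  profiles <- profiles[order(profiles$feature_id), , drop = FALSE]
  X <- as.matrix(profiles[, setdiff(names(profiles), "feature_id"),
                          drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("covariate profiles contain missing values")
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  one_cluster <- function(converged) {
    out <- data.frame(feature_id = profiles$feature_id, cluster = 1L,
                      exemplar = profiles$feature_id[1],
                      stringsAsFactors = FALSE)
    attr(out, "converged") <- converged
    out
  }
  if (all(apply(Z, 1, function(r) identical(r, Z[1, ])))) {
    return(one_cluster(TRUE))
  }
  D2 <- as.matrix(stats::dist(Z))^2
  S <- -D2
  pref <- stats::median(S[upper.tri(S)])
  diag(S) <- pref
  fit <- affinity_propagation(S, damping = damping, max_iter = max_iter)
  if (is.null(fit)) {
    warning("affinity propagation did not converge; ",
            "all features placed in a single cluster")
    return(one_cluster(FALSE))
  }
  labels <- match(fit$assignment, sort(unique(fit$assignment)))
  out <- data.frame(feature_id = profiles$feature_id,
                    cluster = labels,
                    exemplar = profiles$feature_id[fit$assignment],
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- TRUE
  out
}

#' Covariate-clustered background rate
#'
#' For one sample and feature, pools mutation counts and lengths over the
#' feature's cluster members: `sum(counts) / sum(lengths)`.
#'
#' @param feature_id Feature whose rate is wanted.
#' @param clusters Data frame from [cluster_features()].
#' @param feature_counts Named numeric vector: the sample's per-feature
#'   mutation counts (names are feature ids).
#' @param feature_lengths Named numeric vector of feature lengths.
#' @return Per-nucleotide rate for the sample and feature.
#' @export
clustered_rate <- function(feature_id, clusters, feature_counts,
                           feature_lengths) {
  cl <- clusters$cluster[match(feature_id, clusters$feature_id)]
  if (is.na(cl)) stop("feature '", feature_id, "' is not in the clustering")
  members <- clusters$feature_id[clusters$cluster == cl]
  sum(feature_counts[members]) / sum(feature_lengths[members])
}

#' Local-clustered hybrid background rate
#'
#' For each member of the feature's covariate cluster, computes the local
#' (windowed maximal) rate around that member, then pools members by a
#' length-weighted mean.
#'
#' @inheritParams clustered_rate
#' @param member_spans Data frame with `feature_id`, `chrom`, `start`,
#'   `end` (1-based inclusive spans) for all features.
#' @param positions_by_chrom Named list of sorted mutation position
#'   vectors for the sample, one per chromosome.
#' @param window_length,step As in [local_rate()].
#' @param chrom_lengths Named numeric vector of chromosome lengths
#'   (missing chromosomes are unclipped).
#' @return Per-nucleotide rate.
#' @export
local_clustered_rate <- function(feature_id, clusters, member_spans,
                                 positions_by_chrom, window_length = 1e6,
                                 step = window_length / 4,
                                 chrom_lengths = numeric(0)) {
  cl <- clusters$cluster[match(feature_id, clusters$feature_id)]
  if (is.na(cl)) stop("feature '", feature_id, "' is not in the clustering")
  members <- clusters$feature_id[clusters$cluster == cl]
  sp <- member_spans[match(members, member_spans$feature_id), , drop = FALSE]
  rates <- vapply(seq_len(nrow(sp)), function(i) {
    cl_len <- chrom_lengths[sp$chrom[i]]
    local_rate(sp$start[i], sp$end[i],
               positions_by_chrom[[sp$chrom[i]]] %||% numeric(0),
               window_length = window_length, step = step,
               chrom_length = if (is.na(cl_len) || length(cl_len) == 0) Inf
                              else cl_len)
  }, numeric(1))
  lens <- sp$end - sp$start + 1
  stats::weighted.mean(rates, lens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-sample rates into the testing rate
#'
#' Geometric mean of sample-wise background rates over the foreground
#' samples (those carrying at least one foreground mutation in the
#' feature), after flooring each rate at `floor` so a single zero cannot
#' annihilate the mean. An empty foreground set marks the feature
#' untestable and returns `NA`.
#'
#' @param per_sample_rates Named numeric vector of rates per sample.
#' @param foreground_samples Character vector of sample ids with at least
#'   one foreground mutation in the feature.
#' @param floor Minimum rate substituted for smaller (or zero) rates
#'   (default 1e-8, roughly one mutation per 100 Mb).
#' @return The aggregate per-nucleotide rate `p`, or `NA_real_` when no
#'   sample is foreground.
#' @export
aggregate_rate <- function(per_sample_rates, foreground_samples,
                           floor = 1e-8) {
  if (length(foreground_samples) == 0) return(NA_real_)
  r <- per_sample_rates[foreground_samples]
  if (anyNA(r)) stop("missing rate for foreground sample(s): ",
                     paste(foreground_samples[is.na(r)], collapse = ", "))
  if (any(r < 0 | r > 1)) stop("rates must lie in [0, 1]")
  geo_mean(pmax(r, floor))
}
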