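## Enrichment pipelines: orchestration of ingestion, background
## estimation, burden/hotspot/WAP testing, Fisher combination and FDR
## control. The coding and noncoding entry points share one engine and
## differ in what they load (GTF genes vs BED regions), which mutations
## are foreground (non-silent vs all), and whether the WAP test runs.

## ---------------------------------------------------------------------
## engine

run_enrichment_engine <- function(features, mutations, cohort_size,
                                  foreground_class, bg_method,
                                  bg_count_class, covariates, window_size,
                                  step, stat_test, max_gap, min_hs_muts,
                                  min_hs_samples, wap_enabled, wap_scale,
                                  n_permutations, combine_wap, seed,
                                  n_workers, chrom_lengths, rate_floor) {
  nfeat <- length(features)
  fids <- names(features)
  lens <- stats::setNames(features$table$length, fids)
  samples <- names(mutations)
  stopifnot(length(samples) == cohort_size)

  fg_counts <- matrix(0, nfeat, cohort_size, dimnames = list(fids, samples))
  bg_counts <- fg_counts
  pos_rows <- vector("list", cohort_size)
  positions_by_chrom <- vector("list", cohort_size)
  names(positions_by_chrom) <- samples
  needs_local <- bg_method %in% c("local", "local_clustered")
  for (si in seq_along(samples)) {
    g <- mutations[[si]]
    cls <- if (length(g)) g$impact_class else character(0)
    bg_class_mask <- if (bg_count_class == "all") rep(TRUE, length(g))
                     else cls == foreground_class | foreground_class == "all"
    if (needs_local) {
      keep <- bg_class_mask
      positions_by_chrom[[si]] <- lapply(
        split(start(g)[keep], as.character(seqnames(g))[keep]), sort)
    }
    ## drop mutations on chromosomes with no features before the overlap
    keep_chr <- as.character(seqnames(g)) %in% unique(features$table$chrom)
    g <- g[keep_chr]
    cls <- cls[keep_chr]
    bg_class_mask <- bg_class_mask[keep_chr]
    if (length(g) == 0) next
    ov <- findOverlaps(g, features$grl)
    qi <- queryHits(ov); fi <- subjectHits(ov)
    is_fg <- if (foreground_class == "all") rep(TRUE, length(qi))
             else cls[qi] == foreground_class
    is_bg <- bg_class_mask[qi]
    fg_counts[, si] <- tabulate(fi[is_fg], nfeat)
    bg_counts[, si] <- tabulate(fi[is_bg], nfeat)
    if (any(is_fg)) {
      pos_rows[[si]] <- data.frame(feat = fi[is_fg],
                                   pos = start(g)[qi[is_fg]],
                                   sample = samples[si])
    }
  }
  pos_tab <- if (all(vapply(pos_rows, is.null, logical(1)))) {
    data.frame(feat = integer(0), pos = numeric(0), sample = character(0))
  } else {
    do.call(rbind, pos_rows[!vapply(pos_rows, is.null, logical(1))])
  }
  pos_by_feat <- split(pos_tab[, c("pos", "sample")], pos_tab$feat)

  ## background rate lookup: rate_fun(feature_index, sample_index)
  ap_fallback <- FALSE
  if (bg_method == "global") {
    total_len <- sum(lens)
    if (total_len <= 0) stop("total feature length is zero")
    sample_rates <- colSums(bg_counts) / total_len
    rate_fun <- function(fi, si) sample_rates[si]
  } else if (bg_method %in% c("clustered", "local_clustered")) {
    if (is.null(covariates)) {
      stop("background method '", bg_method, "' requires covariates")
    }
    clusters <- cluster_features(covariates)
    ap_fallback <- !attr(clusters, "converged")
    cluster_of <- clusters$cluster[match(fids, clusters$feature_id)]
    if (anyNA(cluster_of)) {
      stop("covariate profiles are missing for ", sum(is.na(cluster_of)),
           " feature(s)")
    }
    if (bg_method == "clustered") {
      nclust <- max(clusters$cluster)
      cl_rates <- matrix(0, nclust, cohort_size)
      for (cc in seq_len(nclust)) {
        members <- which(cluster_of == cc)
        cl_rates[cc, ] <- colSums(bg_counts[members, , drop = FALSE]) /
          sum(lens[members])
      }
      rate_fun <- function(fi, si) cl_rates[cluster_of[fi], si]
    } else {
      spans <- features$table[, c("feature_id", "chrom", "start", "end")]
      rate_fun <- function(fi, si) {
        local_clustered_rate(fids[fi], clusters, spans,
                             positions_by_chrom[[si]],
                             window_length = window_size, step = step,
                             chrom_lengths = chrom_lengths)
      }
    }
  } else if (bg_method == "local") {
    tab <- features$table
    rate_fun <- function(fi, si) {
      cl <- chrom_lengths[tab$chrom[fi]]
      local_rate(tab$start[fi], tab$end[fi],
                 positions_by_chrom[[si]][[tab$chrom[fi]]] %||% numeric(0),
                 window_length = window_size, step = step,
                 chrom_length = if (length(cl) == 0 || is.na(cl)) Inf else cl)
    }
  } else {
    stop("unknown background method: ", bg_method)
  }

  test_one <- function(fi) {
    fid <- fids[fi]
    L <- lens[[fi]]
    fg_si <- which(fg_counts[fi, ] > 0)
    n <- length(fg_si)
    k <- sum(fg_counts[fi, ])
    flags <- character(0)
    rate <- NA_real_
    burden_p <- 1
    hs <- NULL
    wap_p <- NA_real_
    if (n == 0) {
      flags <- c(flags, "untestable")
    } else {
      per_sample <- vapply(fg_si, function(si) rate_fun(fi, si), numeric(1))
      names(per_sample) <- samples[fg_si]
      rate <- aggregate_rate(per_sample, samples[fg_si], floor = rate_floor)
      burden_p <- if (stat_test == "binomial") {
        binomial_burden_pvalue(n, cohort_size,
                               per_feature_success_prob(rate, L))
      } else {
        negbin_pvalue(k, L, cohort_size, rate)
      }
      pd <- pos_by_feat[[as.character(fi)]]
      if (!is.null(pd)) {
        cand <- find_candidate_hotspots(pd$pos, pd$sample, max_gap = max_gap,
                                        min_mutations = min_hs_muts,
                                        min_samples = min_hs_samples)
        if (nrow(cand) > 0) {
          cand$p <- vapply(seq_len(nrow(cand)), function(hi)
            hotspot_pvalue(cand[hi, ], cohort_size, rate, test = stat_test),
            numeric(1))
          hs <- cbind(feature_id = fid, chrom = features$table$chrom[fi],
                      cand)
        }
        if (wap_enabled && nrow(pd) >= 2 && L >= nrow(pd)) {
          wap_p <- wap_permutation_pvalue(
            features$grl[[fi]], pd$pos, n_permutations = n_permutations,
            scale = wap_scale, seed = feature_seed(seed, fid))$p_value
        }
      }
    }
    if (is.null(hs)) flags <- c(flags, "no_hotspot")
    if (ap_fallback) flags <- c(flags, "ap_fallback")
    best_hs_p <- if (is.null(hs)) NA_real_ else min(hs$p)
    comps <- burden_p
    if (!is.na(best_hs_p)) comps <- c(comps, best_hs_p)
    if (combine_wap && !is.na(wap_p)) comps <- c(comps, wap_p)
    combined_p <- fisher_combine(comps)
    list(row = data.frame(
           feature_id = fid, chrom = features$table$chrom[fi],
           start = features$table$start[fi], end = features$table$end[fi],
           strand = features$table$strand[fi], length = L,
           n_samples = n, cohort_size = cohort_size, total_mutations = k,
           bg_rate = rate, burden_p = burden_p, n_hotspots =
             if (is.null(hs)) 0L else nrow(hs),
           best_hotspot_p = best_hs_p, wap_p = wap_p,
           combined_p = combined_p,
           flags = paste(flags, collapse = ","),
           stringsAsFactors = FALSE),
         hotspots = hs)
  }

  res <- if (n_workers > 1) {
    out <- parallel::mclapply(seq_len(nfeat), test_one,
                              mc.cores = n_workers, mc.preschedule = TRUE)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) stop("worker failure: ", attr(out[[which(bad)[1]]],
                                                "condition")$message)
    out
  } else {
    lapply(seq_len(nfeat), test_one)
  }

  feat_df <- do.call(rbind, lapply(res, `[[`, "row"))
  hs_list <- lapply(res, `[[`, "hotspots")
  hs_df <- do.call(rbind, hs_list[!vapply(hs_list, is.null, logical(1))])
  if (is.null(hs_df)) {
    hs_df <- data.frame(feature_id = character(0), chrom = character(0),
                        start = numeric(0), end = numeric(0),
                        span = numeric(0), n_mutations = integer(0),
                        n_samples = integer(0), p = numeric(0),
                        q = numeric(0))
  } else {
    rownames(hs_df) <- NULL
    hs_df$q <- bh_fdr(hs_df$p)
  }
  feat_df$burden_q <- bh_fdr(feat_df$burden_p)
  feat_df$combined_q <- bh_fdr(feat_df$combined_p)
  feat_df$wap_q <- NA_real_
  wap_ok <- !is.na(feat_df$wap_p)
  if (any(wap_ok)) feat_df$wap_q[wap_ok] <- bh_fdr(feat_df$wap_p[wap_ok])
  feat_df <- feat_df[, c("feature_id", "chrom", "start", "end", "strand",
                         "length", "n_samples", "cohort_size",
                         "total_mutations", "bg_rate", "burden_p",
                         "burden_q", "n_hotspots", "best_hotspot_p",
                         "wap_p", "wap_q", "combined_p", "combined_q",
                         "flags")]
  feat_df <- feat_df[order(feat_df$combined_q, feat_df$combined_p,
                           feat_df$feature_id), , drop = FALSE]
  rownames(feat_df) <- NULL
  list(features = feat_df, hotspots = hs_df)
}

## ---------------------------------------------------------------------
## shared wrapper plumbing

resolve_manifest <- function(vcf_list) {
  if (inherits(vcf_list, "cohort_manifest")) vcf_list else load_cohort(vcf_list)
}

resolve_covariates <- function(covariates) {
  if (is.null(covariates) || is.data.frame(covariates)) return(covariates)
  cov <- utils::read.table(covariates, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(cov)[1] <- "feature_id"
  cov
}

read_cohort_mutations <- function(manifest, anno_field) {
  muts <- lapply(seq_len(nrow(manifest)), function(i)
    read_sample_mutations(manifest$path[i], manifest$sample_id[i],
                          anno_field = anno_field))
  names(muts) <- manifest$sample_id
  muts
}

finish_run <- function(res, params, out_prefix) {
  out <- structure(list(features = res$features, hotspots = res$hotspots,
                        params = params), class = "burden_results")
  if (!is.null(out_prefix)) {
    write_results(out, out_prefix)
    write_run_log(params, out_prefix)
  }
  out
}

#' @export
print.burden_results <- function(x, ...) {
  nsig <- sum(x$features$combined_q < 0.05)
  cat(sprintf(paste0("<burden_results> %d feature(s), %d hotspot(s); ",
                     "%d feature(s) at combined q < 0.05\n"),
              nrow(x$features), nrow(x$hotspots), nsig))
  invisible(x)
}

## ---------------------------------------------------------------------
## public pipelines

#' Coding enrichment pipeline
#'
#' Tests every gene for enrichment of non-silent somatic mutations.
#' Per gene: `n` is the number of samples with at least one non-silent
#' mutation, `k` the total non-silent mutation count, `L` the merged
#' coding (or exonic) length. The burden test is binomial on `(n, N,
#' p_n)` by default or negative-binomial on `k` over `L * N` trials;
#' hotspots are chained from non-silent mutations and tested on their own
#' spans; the combined p-value is Fisher's method over the burden p-value
#' and the best hotspot p-value (when a hotspot exists). Benjamini-
#' Hochberg corrections are applied across genes for burden and combined
#' p-values and, separately, across the hotspot table.
#'
#' @param vcf_list Path to a cohort VCF list file, or a
#'   `cohort_manifest`; mutually exclusive with `maf`.
#' @param maf Path to a cohort MAF file, or a `maf_cohort`.
#' @param gtf Path to the GTF gene models.
#' @param anno_field INFO field carrying coding impact annotations
#'   (required with `vcf_list`).
#' @param feature_selector Gene sub-features to merge: `"auto"`, `"cds"`
#'   or `"exon"` (see [load_gene_models()]).
#' @param bg_method Background rate method: `"global"`, `"local"`,
#'   `"clustered"` or `"local_clustered"`.
#' @param bg_count_class Mutation classes counted in the background:
#'   `"all"` (default; silent and non-coding genic mutations contribute)
#'   or `"foreground"` (non-silent only).
#' @param covariates Covariate table (data frame or TSV path: first
#'   column feature id, remaining columns numeric); required for the
#'   clustered methods.
#' @param window_size Local background window length in nucleotides
#'   (default 1e6).
#' @param stat_test `"binomial"` (default) or `"negbinom"`; switches both
#'   the burden and hotspot tests.
#' @param max_gap Hotspot chaining distance (default 50).
#' @param min_hs_muts,min_hs_samples Hotspot reporting thresholds
#'   (defaults 5 mutations from 3 samples).
#' @param seed Master seed; per-feature permutation seeds are derived
#'   from it by hashing feature ids, so results do not depend on worker
#'   scheduling.
#' @param n_workers Number of parallel workers (forked; results are
#'   identical for any value).
#' @param chrom_lengths Named numeric vector of chromosome lengths for
#'   local-window clipping; taken from the first VCF header when `NULL`.
#' @param rate_floor Per-sample rate floor applied before the geometric
#'   mean (default 1e-8).
#' @param out_prefix If non-`NULL`, TSV reports and a run log are
#'   written under this prefix.
#' @return A `burden_results` object: `$features` (one row per gene) and
#'   `$hotspots` data frames, plus the resolved `$params`.
#' @export
run_coding <- function(vcf_list = NULL, maf = NULL, gtf,
                       anno_field = NULL,
                       feature_selector = "auto",
                       bg_method = c("global", "local", "clustered",
                                     "local_clustered"),
                       bg_count_class = c("all", "foreground"),
                       covariates = NULL, window_size = 1e6,
                       stat_test = c("binomial", "negbinom"),
                       max_gap = 50, min_hs_muts = 5, min_hs_samples = 3,
                       seed = 1, n_workers = 1, chrom_lengths = NULL,
                       rate_floor = 1e-8, out_prefix = NULL) {
  bg_method <- match.arg(bg_method)
  bg_count_class <- match.arg(bg_count_class)
  stat_test <- match.arg(stat_test)
  if (is.null(vcf_list) == is.null(maf)) {
    stop("provide exactly one of vcf_list or maf")
  }
  if (!is.null(vcf_list) && is.null(anno_field)) {
    stop("anno_field is required for VCF input to the coding pipeline")
  }
  covariates <- resolve_covariates(covariates)
  if (bg_method %in% c("clustered", "local_clustered") &&
      is.null(covariates)) {
    stop("background method '", bg_method, "' requires covariates")
  }
  features <- load_gene_models(gtf, feature_selector)
  if (!is.null(vcf_list)) {
    manifest <- resolve_manifest(vcf_list)
    mutations <- read_cohort_mutations(manifest, anno_field)
    cohort_size <- attr(manifest, "cohort_size")
    if (is.null(chrom_lengths)) {
      chrom_lengths <- vcf_contig_lengths(manifest$path[1])
    }
  } else {
    mc <- if (inherits(maf, "maf_cohort")) maf else load_maf(maf)
    mutations <- mc$mutations
    cohort_size <- mc$cohort_size
    if (is.null(chrom_lengths)) chrom_lengths <- numeric(0)
  }
  params <- list(module = "coding", bg_method = bg_method,
                 bg_count_class = bg_count_class, window_size = window_size,
                 stat_test = stat_test, max_gap = max_gap,
                 min_hs_muts = min_hs_muts, min_hs_samples = min_hs_samples,
                 seed = seed, n_workers = n_workers,
                 anno_field = anno_field,
                 feature_selector = feature_selector,
                 rate_floor = rate_floor,
                 n_features = length(features), cohort_size = cohort_size)
  res <- run_enrichment_engine(
    features, mutations, cohort_size,
    foreground_class = "nonsilent", bg_method = bg_method,
    bg_count_class = bg_count_class, covariates = covariates,
    window_size = window_size, step = window_size / 4,
    stat_test = stat_test, max_gap = max_gap, min_hs_muts = min_hs_muts,
    min_hs_samples = min_hs_samples, wap_enabled = FALSE, wap_scale = 30,
    n_permutations = 0, combine_wap = FALSE, seed = seed,
    n_workers = n_workers, chrom_lengths = chrom_lengths,
    rate_floor = rate_floor)
  finish_run(res, params, out_prefix)
}

#' Noncoding enrichment pipeline
#'
#' Tests every user-defined region (promoters, enhancers, ...) for
#' enrichment of somatic mutations of any class: `n` is the number of
#' samples with any mutation in the region and `k` the total mutation
#' count. In addition to the burden and hotspot tests shared with the
#' coding pipeline, regions holding at least two mutations get a
#' permutation-based weighted average proximity (WAP) clustering test.
#' By default the Fisher combination uses the burden and best-hotspot
#' p-values only; `combine_wap = TRUE` adds the WAP p-value.
#'
#' @inheritParams run_coding
#' @param bed Path to the BED region definitions.
#' @param wap Run the WAP permutation test (default `TRUE`).
#' @param wap_scale WAP Gaussian kernel scale in nucleotides
#'   (default 30).
#' @param n_permutations WAP permutations per region (default 10000).
#' @param combine_wap Include the WAP p-value in the Fisher combination
#'   (default `FALSE`; WAP is reported alongside).
#' @return A `burden_results` object (see [run_coding()]); `wap_p` and
#'   `wap_q` are populated for regions where the test applies.
#' @export
run_noncoding <- function(vcf_list, bed,
                          bg_method = c("global", "local", "clustered",
                                        "local_clustered"),
                          bg_count_class = "all",
                          covariates = NULL, window_size = 1e6,
                          stat_test = c("binomial", "negbinom"),
                          max_gap = 50, min_hs_muts = 5, min_hs_samples = 3,
                          wap = TRUE, wap_scale = 30, n_permutations = 10000,
                          combine_wap = FALSE, seed = 1, n_workers = 1,
                          chrom_lengths = NULL, rate_floor = 1e-8,
                          out_prefix = NULL) {
  bg_method <- match.arg(bg_method)
  stat_test <- match.arg(stat_test)
  covariates <- resolve_covariates(covariates)
  if (bg_method %in% c("clustered", "local_clustered") &&
      is.null(covariates)) {
    stop("background method '", bg_method, "' requires covariates")
  }
  features <- load_regions(bed)
  manifest <- resolve_manifest(vcf_list)
  mutations <- read_cohort_mutations(manifest, anno_field = NULL)
  cohort_size <- attr(manifest, "cohort_size")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vcf_contig_lengths(manifest$path[1])
  }
  params <- list(module = "noncoding", bg_method = bg_method,
                 bg_count_class = "all", window_size = window_size,
                 stat_test = stat_test, max_gap = max_gap,
                 min_hs_muts = min_hs_muts, min_hs_samples = min_hs_samples,
                 wap = wap, wap_scale = wap_scale,
                 n_permutations = n_permutations, combine_wap = combine_wap,
                 seed = seed, n_workers = n_workers,
                 rate_floor = rate_floor,
                 n_features = length(features), cohort_size = cohort_size)
  res <- run_enrichment_engine(
    features, mutations, cohort_size,
    foreground_class = "all", bg_method = bg_method,
    bg_count_class = "all", covariates = covariates,
    window_size = window_size, step = window_size / 4,
    stat_test = stat_test, max_gap = max_gap, min_hs_muts = min_hs_muts,
    min_hs_samples = min_hs_samples, wap_enabled = wap,
    wap_scale = wap_scale, n_permutations = n_permutations,
    combine_wap = combine_wap, seed = seed, n_workers = n_workers,
    chrom_lengths = chrom_lengths, rate_floor = rate_floor)
  finish_run(res, params, out_prefix)
}
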