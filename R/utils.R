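## Internal helpers shared across modules.

#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. Keeps pipeline seeding from
## stomping on the user's random stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Deterministic 31-bit hash of a character id, combined with a master
## seed. Used to derive per-feature permutation seeds that do not depend
## on worker scheduling or feature iteration order.
feature_seed <- function(master_seed, feature_id) {
  stopifnot(length(feature_id) == 1)
  m <- 2147483629  # largest prime below 2^31
  h <- 5381
  for (b in utf8ToInt(as.character(feature_id))) {
    h <- (h * 33 + b) %% m
  }
  as.integer((h + (as.numeric(master_seed) %% m) * 65599) %% m)
}

## Geometric mean.
geo_mean <- function(x) exp(mean(log(x)))

## Map 1-based offsets along a feature's concatenated intervals to
## genomic positions. `feature_gr`: GRanges of disjoint sorted intervals;
## `off` in 1..sum(width).
map_offsets <- function(feature_gr, off) {
  w <- width(feature_gr)
  cumlen <- cumsum(w)
  iv <- findInterval(off - 1, c(0, cumlen[-length(cumlen)]))
  start(feature_gr)[iv] + (off - 1 - c(0, cumlen)[iv])
}

## Count elements of sorted numeric vector `pos` lying in [lo, hi].
count_in_window <- function(pos, lo, hi) {
  if (length(pos) == 0) return(0L)
  findInterval(hi, pos) - findInterval(lo - 1, pos)
}

## Format numbers for TSV output: 6 significant digits, NA -> "NA".
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.6g", v)
  }, character(1))
  out
}
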