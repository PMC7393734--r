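test_that("global rate is the pooled density and is shared by all features", {
  expect_equal(global_rate(10, 1e6), 1e-5)
  expect_equal(global_rate(c(4, 6), c(5e5, 5e5)), 1e-5)
  expect_equal(global_rate(0, 1000), 0)
  ## linearity
  expect_equal(global_rate(c(8, 12), c(5e5, 5e5)),
               2 * global_rate(c(4, 6), c(5e5, 5e5)))
  expect_error(global_rate(numeric(0), numeric(0)), "zero")
})

test_that("local rate equals the brute-force window enumeration", {
  W <- 2000
  step <- W / 4
  clen <- 10000
  pos <- sort(c(3100, 3150, 4200, 4210, 6100))
  fstart <- 4000
  fend <- 4500
  got <- local_rate(fstart, fend, pos, window_length = W, step = step,
                    chrom_length = clen)
  ## oracle: independently enumerate the stated placements and count
  ## naively
  starts <- seq(fend - W + 1, fstart, by = step)
  if (tail(starts, 1) != fstart) starts <- c(starts, fstart)
  rates <- vapply(starts, function(s) {
    lo <- max(1, s); hi <- min(clen, s + W - 1)
    sum(pos >= lo & pos <= hi) / (hi - lo + 1)
  }, numeric(1))
  expect_equal(got, max(rates))
  ## the maximum picks the denser placement
  expect_equal(local_rate(100, 140, c(120, 130), window_length = 100,
                          step = 25, chrom_length = 1e4), 2 / 100)
  ## no mutations anywhere gives zero
  expect_equal(local_rate(4000, 4500, numeric(0), window_length = W), 0)
  ## over-long feature falls back to a feature-sized window with warning
  expect_warning(
    r <- local_rate(1000, 5000, c(1500, 2500), window_length = 2000),
    "falling back")
  expect_equal(r, 2 / 4001)
  ## local rate is never below the feature's own density when the
  ## fallback window applies
  expect_gte(r, 2 / 4001)
})

test_that("covariate preparation computes GC and length-weighted track means", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "g.fa")
  writeLines(c(">chr1", "GGCCATATACGTACGT"), fa)
  bed <- file.path(d, "r.bed")
  writeLines(c("chr1\t0\t4\tr1", "chr1\t4\t8\tr2", "chr1\t8\t16\tr3"), bed)
  fs <- load_regions(bed)
  track <- file.path(d, "t.bedGraph")
  ## r3 is covered by two equal-length intervals with values 1 and 3
  writeLines(c("chr1\t8\t12\t1", "chr1\t12\t16\t3"), track)
  expect_warning(
    cov <- prepare_covariates(fs, fa, tracks = c(rt = track)),
    "missing covariate")
  expect_equal(cov$gc[cov$feature_id == "r1"], 1.0)   # GGCC
  expect_equal(cov$gc[cov$feature_id == "r2"], 0.0)   # ATAT
  expect_equal(cov$rt[cov$feature_id == "r3"], 2)
  ## r1/r2 had no track coverage: cohort median substituted
  expect_equal(cov$rt[cov$feature_id == "r1"], 2)
  ## absent chromosome is fatal
  bed2 <- file.path(d, "r2.bed")
  writeLines("chrZ\t0\t4", bed2)
  expect_error(prepare_covariates(load_regions(bed2), fa), "absent")
})

test_that("affinity propagation separates well-separated covariate groups", {
  set.seed(99)
  n <- 10
  prof <- data.frame(
    feature_id = sprintf("f%02d", 1:(2 * n)),
    a = c(rnorm(n, 0, 0.01), rnorm(n, 10, 0.01)),
    b = c(rnorm(n, 0, 0.01), rnorm(n, 10, 0.01)))
  cl <- cluster_features(prof)
  expect_true(attr(cl, "converged"))
  ## purity: no cluster mixes the two groups
  grp <- rep(1:2, each = n)[match(cl$feature_id, prof$feature_id)]
  for (k in unique(cl$cluster)) {
    expect_equal(length(unique(grp[cl$cluster == k])), 1)
  }
  ## exemplars are members of their own cluster
  expect_true(all(mapply(function(e, k)
    k == cl$cluster[cl$feature_id == e], cl$exemplar, cl$cluster)))
  ## identical covariates collapse to one cluster
  same <- data.frame(feature_id = c("x", "y", "z"), a = 1, b = 2)
  cl1 <- cluster_features(same)
  expect_equal(unique(cl1$cluster), 1L)
  ## input order invariance
  perm <- sample(nrow(prof))
  cl2 <- cluster_features(prof[perm, ])
  m <- merge(cl, cl2, by = "feature_id")
  expect_equal(m$exemplar.x, m$exemplar.y)
})

test_that("clustered rates pool members and reduce to the global rate", {
  counts <- c(f1 = 2, f2 = 0, f3 = 5)
  lens <- c(f1 = 1000, f2 = 1000, f3 = 2500)
  two <- data.frame(feature_id = c("f1", "f2", "f3"),
                    cluster = c(1L, 1L, 2L), exemplar = c("f1", "f1", "f3"))
  expect_equal(clustered_rate("f1", two, counts, lens), 2 / 2000)
  expect_equal(clustered_rate("f2", two, counts, lens), 1e-3)
  ## singleton cluster equals the feature's own density
  expect_equal(clustered_rate("f3", two, counts, lens), 5 / 2500)
  ## all-in-one-cluster partition reproduces the global rate exactly
  one <- data.frame(feature_id = names(counts), cluster = 1L,
                    exemplar = "f1")
  for (f in names(counts)) {
    expect_identical(clustered_rate(f, one, counts, lens),
                     global_rate(counts, lens))
  }
})

test_that("local-clustered rate is the length-weighted mean of member local rates", {
  spans <- data.frame(feature_id = c("f1", "f2"), chrom = "chr1",
                      start = c(1000, 6000), end = c(1999, 6499))
  pos <- list(chr1 = sort(c(1100, 1200, 1300, 6100)))
  cl <- data.frame(feature_id = c("f1", "f2"), cluster = 1L, exemplar = "f1")
  W <- 2000
  r1 <- local_rate(1000, 1999, pos$chr1, window_length = W,
                   chrom_length = 10000)
  r2 <- local_rate(6000, 6499, pos$chr1, window_length = W,
                   chrom_length = 10000)
  got <- local_clustered_rate("f1", cl, spans, pos, window_length = W,
                              chrom_lengths = c(chr1 = 10000))
  expect_equal(got, weighted.mean(c(r1, r2), c(1000, 500)))
  ## singleton cluster equals the plain local rate
  cl2 <- data.frame(feature_id = c("f1", "f2"), cluster = c(1L, 2L),
                    exemplar = c("f1", "f2"))
  expect_equal(local_clustered_rate("f1", cl2, spans, pos, window_length = W,
                                    chrom_lengths = c(chr1 = 10000)), r1)
})

test_that("aggregation takes the floored geometric mean over foreground samples", {
  rates <- c(A = 1e-6, B = 4e-6, C = 0)
  expect_equal(aggregate_rate(rates, c("A", "B")), 2e-6)
  expect_equal(aggregate_rate(c(A = 3e-6, B = 3e-6), c("A", "B")), 3e-6)
  ## zero rates are floored, not annihilating
  expect_equal(aggregate_rate(rates, c("A", "C")),
               sqrt(1e-6 * 1e-8))
  ## empty foreground set marks the feature untestable
  expect_true(is.na(aggregate_rate(rates, character(0))))
  ## scale equivariance when the floor does not bind
  r <- c(A = 2e-6, B = 8e-6, C = 1e-5)
  expect_equal(aggregate_rate(3 * r, names(r)),
               3 * aggregate_rate(r, names(r)), tolerance = 1e-12)
})
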