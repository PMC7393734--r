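test_that("pipeline burden p-values compose exactly from the core statistics", {
  toy <- toy_small()
  coh <- toy_cohort()
  res <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 5,
                       wap = FALSE)
  ft <- res$features
  tested <- ft[ft$n_samples > 0, ]
  for (i in seq_len(nrow(tested))) {
    p_n <- per_feature_success_prob(tested$bg_rate[i], tested$length[i])
    expect_equal(tested$burden_p[i],
                 binomial_burden_pvalue(tested$n_samples[i],
                                        tested$cohort_size[i], p_n))
  }
  ## untestable features carry p = 1 and the flag
  unt <- ft[ft$n_samples == 0, ]
  expect_true(all(unt$burden_p == 1))
  expect_true(all(grepl("untestable", unt$flags)))
  ## combined with no hotspot equals the burden p-value
  nohs <- ft[ft$n_hotspots == 0 & ft$n_samples > 0, ]
  expect_equal(nohs$combined_p, nohs$burden_p)
  ## with a hotspot, combined follows Fisher on (burden, best hotspot)
  hs <- ft[ft$n_hotspots > 0, ]
  expect_gt(nrow(hs), 0)
  for (i in seq_len(nrow(hs))) {
    expect_equal(hs$combined_p[i],
                 fisher_combine(c(hs$burden_p[i], hs$best_hotspot_p[i])))
  }
  ## q-value columns are BH over the respective p-value columns
  expect_equal(ft$burden_q, bh_fdr(ft$burden_p))
  expect_equal(ft$combined_q, bh_fdr(ft$combined_p))
})

test_that("planted structure is recovered with the expected ranking", {
  toy <- toy_small()
  coh <- toy_cohort()
  res <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 5,
                       n_permutations = 500)
  ft <- res$features
  truth <- coh$truth_table
  top2 <- ft$feature_id[1:2]
  expect_setequal(top2,
                  truth$feature_id[truth$class != "null"])
  ## the planted hotspot is found and lies inside its feature's window
  expect_gte(nrow(res$hotspots), 1)
  hrow <- res$hotspots[which.min(res$hotspots$p), ]
  plant <- truth$feature_id[truth$class == "hotspot_only"]
  expect_equal(hrow$feature_id, plant)
  iv <- toy$regions$grl[[plant]]
  expect_gte(hrow$start, min(start(iv)))
  expect_lte(hrow$end, max(end(iv)))
  ## WAP flags the planted hotspot region as positionally clustered
  expect_lte(ft$wap_p[ft$feature_id == plant], 0.05)
})

test_that("a cohort with no non-silent mutations yields null coding results", {
  toy <- toy_small()
  d <- withr::local_tempdir()
  coh <- generate_cohort(toy$genes, d, n_samples = 10,
                         chrom_lengths = toy$chrom_lengths,
                         background_rate = 3e-5, silent_fraction = 1,
                         seed = 13)
  res <- run_coding(vcf_list = coh$vcf_list, gtf = toy$ann$gtf,
                    anno_field = "ANNO", seed = 2)
  expect_true(all(res$features$burden_p == 1))
  expect_equal(nrow(res$hotspots), 0)
  expect_true(all(res$features$n_samples == 0))
})

test_that("MAF and VCF ingestion of one cohort give identical coding results", {
  toy <- toy_small()
  d <- withr::local_tempdir()
  ## rate high enough that every sample is mutated: a MAF cannot encode
  ## mutation-free samples, so the equivalence only holds in that regime
  coh <- generate_cohort(toy$genes, d, n_samples = 12,
                         chrom_lengths = toy$chrom_lengths,
                         background_rate = 2e-4, silent_fraction = 0.3,
                         seed = 21, write_maf = TRUE)
  resv <- run_coding(vcf_list = coh$vcf_list, gtf = toy$ann$gtf,
                     anno_field = "ANNO", seed = 2)
  resm <- run_coding(maf = coh$maf, gtf = toy$ann$gtf, seed = 2)
  expect_equal(resv$features$cohort_size[1], 12)  # regime check
  expect_equal(resm$features, resv$features)
  expect_equal(resm$hotspots, resv$hotspots)
})

test_that("worker count and repeated runs do not change written outputs", {
  toy <- toy_small()
  coh <- toy_cohort()
  d <- withr::local_tempdir()
  r1 <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 9,
                      n_permutations = 300, n_workers = 1,
                      out_prefix = file.path(d, "w1"))
  r4 <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 9,
                      n_permutations = 300, n_workers = 4,
                      out_prefix = file.path(d, "w4"))
  expect_identical(readLines(file.path(d, "w1_feature_results.tsv")),
                   readLines(file.path(d, "w4_feature_results.tsv")))
  expect_identical(readLines(file.path(d, "w1_hotspots.tsv")),
                   readLines(file.path(d, "w4_hotspots.tsv")))
  ## same seed, same bytes on a rerun
  r1b <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 9,
                       n_permutations = 300,
                       out_prefix = file.path(d, "again"))
  expect_identical(readLines(file.path(d, "w1_feature_results.tsv")),
                   readLines(file.path(d, "again_feature_results.tsv")))
  ## more workers than features still works
  few <- toy$regions[1:2]
  bed2 <- file.path(d, "two.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", few$table$chrom,
                     few$table$start - 1, few$table$end,
                     few$table$feature_id), bed2)
  r8 <- run_noncoding(coh$vcf_list, bed2, seed = 9, wap = FALSE,
                      n_workers = 8)
  expect_equal(nrow(r8$features), 2)
})

test_that("injected enrichment strengthens monotonically with the multiplier", {
  toy <- toy_small()
  target <- names(toy$regions)[length(toy$regions)]  # last in draw order
  ps <- vapply(c(1, 10, 40), function(m) {
    d <- withr::local_tempdir()
    coh <- generate_cohort(
      toy$regions, d, n_samples = 30, chrom_lengths = toy$chrom_lengths,
      background_rate = 2e-5,
      enriched_features = stats::setNames(m, target), seed = 55)
    res <- run_noncoding(coh$vcf_list, toy$ann$bed_long, seed = 3,
                         wap = FALSE)
    res$features$burden_p[res$features$feature_id ==
                            paste0(target)]
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[3], ps[1])
})

test_that("binomial and negative-binomial paths diverge on recurrent mutation", {
  ## one sample carries many mutations in one region: the sample-count
  ## test sees n = 1 while the mutation-count test sees k = 12
  d <- withr::local_tempdir()
  contigs <- c(chr1 = 1000000)
  ## every sample carries 3 scattered backdrop mutations so the global
  ## rate is anchored by a long quiet region, not by the recurrence
  backdrop_pos <- function(i) 200000 + 30000 * (0:2) + 137 * i
  hot <- write_mini_vcf(file.path(d, "hot.vcf"), rep("chr1", 15),
                        c(seq(5010, 5980, length.out = 12),
                          backdrop_pos(0)), contig_lengths = contigs)
  quiet <- lapply(1:9, function(i)
    write_mini_vcf(file.path(d, sprintf("q%d.vcf", i)), rep("chr1", 3),
                   backdrop_pos(i), contig_lengths = contigs))
  lf <- write_cohort_list(d, c(hot, unlist(quiet)),
                          c("hot", sprintf("q%d", 1:9)))
  bed <- file.path(d, "r.bed")
  writeLines(c("chr1\t5000\t7000\ttarget", "chr1\t190000\t290000\tbackdrop"),
             bed)
  resb <- run_noncoding(lf, bed, stat_test = "binomial", wap = FALSE,
                        min_hs_muts = 100, seed = 1)
  resn <- run_noncoding(lf, bed, stat_test = "negbinom", wap = FALSE,
                        min_hs_muts = 100, seed = 1)
  pb <- resb$features$burden_p[resb$features$feature_id == "target"]
  pn <- resn$features$burden_p[resn$features$feature_id == "target"]
  expect_lt(pn, pb)        # NB rewards recurrence within one sample
  expect_gt(pb / pn, 10)   # and by a wide margin on this fixture
})

test_that("growing a region by unmutated flanks weakens burden but not the hotspot", {
  ## the same five-sample mutation cluster analysed as a short region
  ## containing it and as a long region padded with unmutated flanks:
  ## burden significance decays with the padding while the hotspot test,
  ## and hence the combined estimate, survives the boundary change
  d <- withr::local_tempdir()
  contigs <- c(chr1 = 100000)
  pos <- c(5110, 5115, 5120, 5125, 5130)
  vcfs <- vapply(seq_along(pos), function(i)
    write_mini_vcf(file.path(d, sprintf("c%d.vcf", i)), "chr1", pos[i],
                   contig_lengths = contigs), character(1))
  lf <- write_cohort_list(d, vcfs, sprintf("c%d", seq_along(pos)))
  bed <- file.path(d, "r.bed")
  writeLines(c("chr1\t5050\t5150\tshort", "chr1\t4000\t6000\tlong"), bed)
  res <- run_noncoding(lf, bed, wap = FALSE, seed = 1)
  ft <- res$features
  short_p <- ft$burden_p[ft$feature_id == "short"]
  long_row <- ft[ft$feature_id == "long", ]
  expect_lt(short_p, long_row$burden_p)
  ## hotspot chained from the cluster rescues the long definition
  expect_equal(long_row$n_hotspots, 1)
  expect_lt(long_row$combined_p, long_row$burden_p)
})

test_that("configuration errors fail before computation", {
  toy <- toy_small()
  coh <- toy_cohort()
  expect_error(run_coding(gtf = toy$ann$gtf), "exactly one")
  expect_error(run_coding(vcf_list = coh$vcf_list, gtf = toy$ann$gtf),
               "anno_field")
  expect_error(run_noncoding(coh$vcf_list, toy$ann$bed_long,
                             bg_method = "clustered"),
               "covariates")
})
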