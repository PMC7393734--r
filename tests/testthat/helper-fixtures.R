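## Shared fixture builders. Everything is generated in code at test time;
## expensive fixtures are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Small two-chromosome toy genome with 40 genes / promoters.
toy_small <- function() {
  cached("toy_small", function() {
    d <- file.path(tempdir(), "toy_small")
    chrom_lengths <- c(chr1 = 200000, chr2 = 200000)
    ann <- generate_toy_annotations(d, chrom_lengths, seed = 101)
    list(dir = d, chrom_lengths = chrom_lengths, ann = ann,
         regions = load_regions(ann$bed_long),
         regions_short = load_regions(ann$bed_short),
         genes = load_gene_models(ann$gtf))
  })
}

## A small noncoding cohort on the toy genome: 20 samples, one enriched
## region, one planted hotspot region.
toy_cohort <- function() {
  cached("toy_cohort", function() {
    toy <- toy_small()
    regions <- toy$regions
    plant_feat <- names(regions)[2]
    generate_cohort(
      regions, file.path(toy$dir, "cohort"), n_samples = 20,
      chrom_lengths = toy$chrom_lengths, background_rate = 2e-5,
      enriched_features = stats::setNames(10, names(regions)[1]),
      hotspot_plants = data.frame(
        feature_id = plant_feat,
        window_start = regions$table$start[2] + 100,
        window_length = 40, n_carriers = 6),
      genome = toy$ann$fasta, seed = 202)
  })
}

## WGS-scale validation layout: five 1 Mb chromosomes carrying 500 genes,
## whose 2 kb "long" promoters are the tested features (total 1 Mb of
## feature space).
toy_wgs <- function() {
  cached("toy_wgs", function() {
    d <- file.path(tempdir(), "toy_wgs")
    chrom_lengths <- stats::setNames(rep(1e6, 5), paste0("chr", 1:5))
    ann <- generate_toy_annotations(d, chrom_lengths,
                                    genes_per_chrom = 100, seed = 500)
    list(dir = d, chrom_lengths = chrom_lengths, ann = ann,
         regions = load_regions(ann$bed_long))
  })
}

## One null cohort on the WGS layout: 100 samples, 1e-6 /nt/sample.
wgs_null_cohort <- function(seed, extra = list()) {
  toy <- toy_wgs()
  d <- file.path(toy$dir, sprintf("cohort_s%d_%s", seed,
                                  if (length(extra)) "x" else "null"))
  do.call(generate_cohort, c(
    list(features = toy$regions, out_dir = d, n_samples = 100,
         chrom_lengths = toy$chrom_lengths, background_rate = 1e-6,
         seed = seed),
    extra))
}

## Write a hand-specified single-sample VCF (positions, alt strings with
## possible multi-allelic commas, INFO terms), bgzip + tabix it.
write_mini_vcf <- function(path, chrom, pos, ref = NULL, alt = NULL,
                           anno = NULL, contig_lengths = c(chr1 = 100000)) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  info <- if (is.null(anno)) rep(".", n) else paste0("ANNO=", anno)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                      as.integer(contig_lengths)),
              paste0('##INFO=<ID=ANNO,Number=1,Type=String,',
                     'Description="impact">'),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(match(chrom, names(contig_lengths)), pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", chrom[ord],
                  as.integer(pos[ord]), ref[ord], alt[ord], info[ord])
  writeLines(c(header, if (n > 0) body), path)
  bg <- Rsamtools::bgzip(path, overwrite = TRUE)
  Rsamtools::indexTabix(bg, format = "vcf")
  bg
}

## Cohort list file for a set of mini VCFs.
write_cohort_list <- function(dir, vcf_paths, sample_ids) {
  lf <- file.path(dir, "list.txt")
  writeLines(sprintf("%s\t%s", vcf_paths, sample_ids), lf)
  lf
}

## Naive term-by-term oracles for the closed-form statistics.
naive_binom_tail <- function(n, N, p) {
  if (n == 0) return(1)
  sum(vapply(n:N, function(i) choose(N, i) * p^i * (1 - p)^(N - i),
             numeric(1)))
}

naive_negbin <- function(k, x, p) {
  if (k == 0) return(1)
  sum(vapply(0:(x - k), function(r) choose(k + r - 1, r) * p^k * (1 - p)^r,
             numeric(1)))
}

naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(pmin(p[ord][js] * m / js, 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
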