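## Input ingestion (cohort VCF lists, MAF, GTF gene models, BED regions,
## covariate tables) and TSV report writing.
##
## Coordinate conventions: everything in memory is a GRanges (1-based,
## closed intervals, the Bioconductor convention). GTF input is 1-based
## inclusive and imports directly; BED input is 0-based half-open and is
## converted once at import by rtracklayer. All written reports are
## 1-based inclusive.

#' @importFrom Rsamtools TabixFile bgzip indexTabix FaFile scanFa indexFa
#' @importFrom VariantAnnotation scanVcf ScanVcfParam scanVcfHeader
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom utils write.table read.table
NULL

## ---------------------------------------------------------------------
## feature sets

new_feature_set <- function(grl, kind) {
  stopifnot(is(grl, "GRangesList"), kind %in% c("gene", "region"))
  if (anyDuplicated(names(grl))) stop("duplicate feature ids")
  rgl <- range(grl, ignore.strand = TRUE)
  if (any(lengths(rgl) != 1)) {
    stop("feature(s) span multiple chromosomes: ",
         paste(head(names(grl)[lengths(rgl) != 1], 5), collapse = ", "))
  }
  rg <- unlist(rgl, use.names = FALSE)
  sl <- S4Vectors::runValue(strand(grl))
  first <- as.character(unlist(sl, use.names = FALSE))[
    cumsum(lengths(sl)) - lengths(sl) + 1]
  tab <- data.frame(
    feature_id = names(grl),
    chrom = as.character(seqnames(rg)),
    start = start(rg),
    end = end(rg),
    strand = ifelse(lengths(sl) == 1, first, "*"),
    length = as.numeric(sum(width(grl))),
    stringsAsFactors = FALSE
  )
  structure(list(grl = grl, kind = kind, table = tab), class = "feature_set")
}

#' @export
length.feature_set <- function(x) length(x$grl)

#' @export
names.feature_set <- function(x) names(x$grl)

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d %s feature(s), total length %.0f nt\n",
              length(x), x$kind, sum(x$table$length)))
  invisible(x)
}

#' Subset a feature set
#' @param x A `feature_set`.
#' @param i Index or feature-id vector.
#' @param ... Unused.
#' @export
`[.feature_set` <- function(x, i, ...) {
  new_feature_set(x$grl[i], x$kind)
}

## ---------------------------------------------------------------------
## cohort manifest

#' Load a cohort manifest from a VCF list file
#'
#' The list file holds one bgzip-compressed, tabix-indexed VCF path per
#' line, with an optional tab-separated sample id in the second column.
#' Sample ids default to the file name stripped of `.vcf.gz`/`.vcf.bgz`.
#'
#' @param list_file Path to the plain-text list file.
#' @return A `cohort_manifest`: data frame of `sample_id`, `path` with the
#'   cohort size `N` attached.
#' @export
load_cohort <- function(list_file) {
  lines <- readLines(list_file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty cohort: no entries in ", list_file)
  parts <- strsplit(lines, "\t")
  path <- vapply(parts, `[[`, character(1), 1)
  sample_id <- vapply(parts, function(p) {
    if (length(p) >= 2 && nzchar(p[2])) p[2]
    else sub("\\.vcf(\\.b?gz)?$", "", basename(p[1]))
  }, character(1))
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  for (i in seq_along(path)) {
    if (!file.exists(path[i])) {
      stop("cohort entry '", sample_id[i], "': missing file ", path[i])
    }
    if (!file.exists(paste0(path[i], ".tbi")) &&
        !file.exists(paste0(path[i], ".csi"))) {
      stop("cohort entry '", sample_id[i], "': missing tabix index for ",
           path[i])
    }
  }
  structure(
    data.frame(sample_id = sample_id, path = path, stringsAsFactors = FALSE),
    cohort_size = length(sample_id),
    class = c("cohort_manifest", "data.frame")
  )
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d sample(s)\n", attr(x, "cohort_size")))
  invisible(as.data.frame(x))
}

## ---------------------------------------------------------------------
## gene models and regions

## Drop GTF lines that do not have 9 tab-separated fields, warning with a
## count, so that one malformed row does not abort a run.
filter_gtf_lines <- function(gtf) {
  lines <- readLines(gtf)
  keep <- startsWith(lines, "#") |
    vapply(strsplit(lines, "\t"), length, integer(1)) >= 9
  if (any(!keep)) {
    warning(sum(!keep), " unparseable GTF line(s) skipped")
    tmp <- tempfile(fileext = ".gtf")
    writeLines(lines[keep], tmp)
    tmp
  } else {
    gtf
  }
}

#' Load gene models from a GTF file
#'
#' Builds one feature per `gene_id`. Intervals are the union of the
#' selected sub-features across all transcripts of the gene, merged into
#' disjoint ranges; the feature length `L` is the merged total. By
#' default CDS rows are used where a gene has any, otherwise its exon
#' rows, so that coding length is tested for coding genes and exonic
#' length for non-coding ones.
#'
#' @param gtf Path to a GTF file (Ensembl/GENCODE dialect; `gene_id`
#'   attribute mandatory).
#' @param feature_selector One of `"auto"` (CDS if present, else exons),
#'   `"cds"`, or `"exon"`.
#' @return A `feature_set` of kind `"gene"`.
#' @export
load_gene_models <- function(gtf, feature_selector = c("auto", "cds", "exon")) {
  feature_selector <- match.arg(feature_selector)
  gr <- rtracklayer::import(filter_gtf_lines(gtf), format = "gtf")
  if (is.null(gr$gene_id)) stop("GTF lacks gene_id attributes")
  type <- tolower(as.character(gr$type))
  sub <- gr[type %in% c("cds", "exon")]
  if (length(sub) == 0) stop("no usable exon/CDS rows in GTF")
  subtype <- tolower(as.character(sub$type))
  keep <- switch(feature_selector,
    exon = subtype == "exon",
    cds = subtype == "cds",
    auto = {
      cds_genes <- unique(sub$gene_id[subtype == "cds"])
      (subtype == "cds") |
        (subtype == "exon" & !(sub$gene_id %in% cds_genes))
    })
  sub <- sub[keep]
  if (length(sub) == 0) stop("no usable genes after sub-feature selection")
  grl <- split(granges(sub), sub$gene_id)
  multi <- lengths(range(grl, ignore.strand = TRUE)) > 1
  if (any(multi)) {
    warning("dropping ", sum(multi), " gene(s) spanning multiple chromosomes: ",
            paste(head(names(grl)[multi], 5), collapse = ", "))
    grl <- grl[!multi]
  }
  grl <- reduce(grl)
  grl <- grl[sum(width(grl)) > 0]
  if (length(grl) == 0) stop("no usable genes in GTF")
  new_feature_set(sort(grl), "gene")
}

#' Load non-coding regions from a BED file
#'
#' One feature per BED line (no merging across lines); exact duplicate
#' lines are dropped. Unnamed lines get ids of the form
#' `chrom:start-end` in the BED's own 0-based half-open coordinates.
#' Lines with `end <= start` or non-numeric coordinates are skipped with
#' a warning.
#'
#' @param bed Path to a BED3+ file.
#' @return A `feature_set` of kind `"region"`.
#' @export
load_regions <- function(bed) {
  lines <- readLines(bed)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  lines <- unique(lines)
  parts <- strsplit(lines, "\t")
  ok <- vapply(parts, function(p) {
    length(p) >= 3 && !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[3]))) &&
      as.numeric(p[3]) > as.numeric(p[2])
  }, logical(1))
  if (any(!ok)) warning(sum(!ok), " malformed BED line(s) skipped")
  parts <- parts[ok]
  if (length(parts) == 0) stop("no usable regions in BED file")
  chrom <- vapply(parts, `[[`, character(1), 1)
  start0 <- as.numeric(vapply(parts, `[[`, character(1), 2))
  end0 <- as.numeric(vapply(parts, `[[`, character(1), 3))
  name <- vapply(parts, function(p) {
    if (length(p) >= 4 && nzchar(p[4]) && p[4] != ".") p[4] else NA_character_
  }, character(1))
  auto <- sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0))
  name[is.na(name)] <- auto[is.na(name)]
  if (anyDuplicated(name)) {
    name <- make.unique(name, sep = "_dup")
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  grl <- as(split(gr, factor(name, levels = name)), "GRangesList")
  new_feature_set(grl, "region")
}

## ---------------------------------------------------------------------
## impact classification

default_vcf_impact_scheme <- function() {
  list(
    nonsilent = c("nonsynonymous_snv", "stopgain", "stoploss", "startloss",
                  "frameshift_insertion", "frameshift_deletion",
                  "nonframeshift_insertion", "nonframeshift_deletion",
                  "splicing", "missense", "nonsense"),
    silent = c("synonymous_snv", "silent"),
    noncoding = c("intronic", "intergenic", "upstream", "downstream",
                  "utr3", "utr5", "ncrna_exonic", "ncrna_intronic")
  )
}

default_maf_impact_scheme <- function() {
  list(
    nonsilent = c("missense_mutation", "nonsense_mutation",
                  "nonstop_mutation", "translation_start_site",
                  "frame_shift_del", "frame_shift_ins", "in_frame_del",
                  "in_frame_ins", "splice_site"),
    silent = c("silent"),
    noncoding = c("igr", "intron", "3'utr", "5'utr", "3'flank", "5'flank",
                  "rna")
  )
}

#' Classify coding impact annotation terms
#'
#' Maps annotation strings (for example ANNOVAR exonic function terms
#' from a VCF INFO field, or MAF `Variant_Classification` values) to
#' `nonsilent` / `silent` / `noncoding`. Matching is case-insensitive
#' with spaces treated as underscores; unmatched terms map to `unknown`
#' and raise one warning carrying the count.
#'
#' @param annotation_value Character vector of annotation terms (`NA`
#'   allowed).
#' @param scheme Named list with character vectors `nonsilent`, `silent`
#'   and optionally `noncoding`.
#' @return Character vector of impact classes.
#' @export
classify_coding_impact <- function(annotation_value,
                                   scheme = default_vcf_impact_scheme()) {
  norm <- tolower(gsub("[ ]", "_", as.character(annotation_value)))
  out <- rep("unknown", length(norm))
  out[norm %in% tolower(scheme$nonsilent)] <- "nonsilent"
  out[norm %in% tolower(scheme$silent)] <- "silent"
  if (!is.null(scheme$noncoding)) {
    out[norm %in% tolower(scheme$noncoding)] <- "noncoding"
  }
  n_unmatched <- sum(out == "unknown" & !is.na(annotation_value))
  if (n_unmatched > 0) {
    warning(n_unmatched, " annotation term(s) did not match the impact ",
            "scheme and were classified 'unknown'")
  }
  out
}

## ---------------------------------------------------------------------
## VCF access

## Read mutation records from one sample's VCF via VariantAnnotation's
## scanVcf. `which = NULL` reads the whole file. Multi-allelic rows are
## split into one record per alternate allele; exact duplicate records
## (same pos/ref/alt) within the sample are dropped.
read_sample_mutations <- function(path, sample_id, anno_field = NULL,
                                  which = NULL) {
  tf <- TabixFile(path)
  info_sel <- if (is.null(anno_field)) NA_character_ else anno_field
  empty_gr <- GRanges(sample_id = character(0), ref = character(0),
                      alt = character(0), annotation = character(0),
                      impact_class = character(0))
  if (!is.null(which)) {
    ## a tabix index only knows chromosomes with data; querying others
    ## is an error downstream, but for us it just means zero records
    indexed <- Rsamtools::seqnamesTabix(tf)
    which <- which[as.character(seqnames(which)) %in% indexed]
    if (length(which) == 0) return(empty_gr)
  }
  param <- if (is.null(which)) {
    ScanVcfParam(fixed = "ALT", info = info_sel, geno = NA_character_)
  } else {
    ScanVcfParam(fixed = "ALT", info = info_sel, geno = NA_character_,
                 which = which)
  }
  chunks <- scanVcf(tf, param = param)
  recs <- lapply(chunks, function(ch) {
    rr <- ch$rowRanges
    if (length(rr) == 0) return(NULL)
    ref <- as.character(ch$REF)
    alt <- ch$ALT
    if (is(alt, "List")) alt <- as.list(alt)
    nalt <- pmax(lengths(alt), 1L)
    alt_flat <- unlist(lapply(alt, function(a) {
      a <- as.character(a)
      if (length(a) == 0) NA_character_ else a
    }), use.names = FALSE)
    idx <- rep(seq_along(rr), nalt)
    anno <- if (!is.null(anno_field)) {
      av <- ch$INFO[[anno_field]]
      if (is.null(av)) rep(NA_character_, length(rr)) else as.character(av)
    } else {
      rep(NA_character_, length(rr))
    }
    gr <- granges(rr)[idx]
    mcols(gr) <- S4Vectors::DataFrame(
      sample_id = sample_id,
      ref = ref[idx],
      alt = alt_flat,
      annotation = anno[idx]
    )
    gr
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  gr <- if (length(recs) == 0) {
    GRanges(sample_id = character(0), ref = character(0),
            alt = character(0), annotation = character(0))
  } else {
    do.call(c, unname(recs))
  }
  key <- paste(as.character(seqnames(gr)), start(gr), gr$ref, gr$alt)
  gr <- gr[!duplicated(key)]
  gr <- sort(gr)
  if (!is.null(anno_field)) {
    gr$impact_class <- suppressWarnings(classify_coding_impact(gr$annotation))
  } else {
    gr$impact_class <- rep("unknown", length(gr))
  }
  gr
}

#' Fetch cohort mutations overlapping a feature
#'
#' Tabix-queries every sample's VCF for variant rows whose position lies
#' inside any interval of the feature. A failed query on one sample is
#' downgraded to a warning and that sample contributes zero records.
#'
#' @param manifest A `cohort_manifest` from [load_cohort()].
#' @param feature A single-feature `feature_set` (or an element of one,
#'   i.e. a `GRanges` of its intervals).
#' @param anno_field Optional INFO field name carrying coding impact
#'   annotations.
#' @return A `GRanges` of mutation records with metadata columns
#'   `sample_id`, `ref`, `alt`, `annotation`, `impact_class`.
#' @export
fetch_mutations <- function(manifest, feature, anno_field = NULL) {
  which <- if (is(feature, "feature_set")) {
    if (length(feature) != 1) stop("feature must contain exactly one feature")
    feature$grl[[1]]
  } else {
    feature
  }
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    tryCatch(
      read_sample_mutations(manifest$path[i], manifest$sample_id[i],
                            anno_field = anno_field, which = which),
      error = function(e) {
        warning("query failed for sample '", manifest$sample_id[i],
                "' (treated as zero mutations): ", conditionMessage(e))
        NULL
      })
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  recs <- recs[vapply(recs, length, integer(1)) > 0]
  if (length(recs) == 0) {
    return(GRanges(sample_id = character(0), ref = character(0),
                   alt = character(0), annotation = character(0),
                   impact_class = character(0)))
  }
  do.call(c, unname(recs))
}

## Chromosome lengths as declared in a VCF header's contig lines, or an
## empty named numeric vector when none are declared.
vcf_contig_lengths <- function(path) {
  hd <- tryCatch(scanVcfHeader(path), error = function(e) NULL)
  if (is.null(hd)) return(numeric(0))
  sl <- seqlengths(hd)
  sl[!is.na(sl)]
}

## ---------------------------------------------------------------------
## MAF ingestion

maf_col <- function(cols, candidates) {
  hit <- which(tolower(cols) %in% tolower(candidates))
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Load a cohort MAF file
#'
#' Reads a tab-separated MAF and converts it to the in-memory cohort
#' representation used by the coding pipeline: one sample per distinct
#' `Tumor_Sample_Barcode`, mutations as `GRanges` with impact classes
#' mapped from `Variant_Classification` terms.
#'
#' @param maf Path to a MAF file.
#' @return A `maf_cohort`: list with `sample_ids`, `cohort_size`, and
#'   `mutations` (named list of per-sample `GRanges`).
#' @export
load_maf <- function(maf) {
  dt <- data.table::fread(maf, sep = "\t", data.table = FALSE,
                          showProgress = FALSE)
  cols <- names(dt)
  need <- list(
    chrom = c("Chromosome"),
    pos = c("Start_Position", "Start_position"),
    vc = c("Variant_Classification"),
    barcode = c("Tumor_Sample_Barcode")
  )
  idx <- lapply(need, function(cand) maf_col(cols, cand))
  missing <- names(idx)[vapply(idx, is.na, logical(1))]
  if (length(missing) > 0) {
    stop("MAF is missing required column(s): ",
         paste(vapply(need[missing], `[[`, character(1), 1), collapse = ", "))
  }
  ref_i <- maf_col(cols, "Reference_Allele")
  alt_i <- maf_col(cols, c("Tumor_Seq_Allele2", "Tumor_Seq_Allele1"))
  chrom <- as.character(dt[[idx$chrom]])
  pos <- as.numeric(dt[[idx$pos]])
  vc <- as.character(dt[[idx$vc]])
  barcode <- as.character(dt[[idx$barcode]])
  ref <- if (!is.na(ref_i)) as.character(dt[[ref_i]]) else rep("N", nrow(dt))
  alt <- if (!is.na(alt_i)) as.character(dt[[alt_i]]) else rep("N", nrow(dt))
  impact <- suppressWarnings(
    classify_coding_impact(vc, default_maf_impact_scheme()))
  sample_ids <- sort(unique(barcode))
  mutations <- lapply(sample_ids, function(s) {
    sel <- barcode == s
    gr <- GRanges(chrom[sel], IRanges(pos[sel], width = 1))
    mcols(gr) <- S4Vectors::DataFrame(
      sample_id = s, ref = ref[sel], alt = alt[sel],
      annotation = vc[sel], impact_class = impact[sel])
    key <- paste(as.character(seqnames(gr)), start(gr), gr$ref, gr$alt)
    sort(gr[!duplicated(key)])
  })
  names(mutations) <- sample_ids
  structure(list(sample_ids = sample_ids, cohort_size = length(sample_ids),
                 mutations = mutations),
            class = "maf_cohort")
}

#' @export
print.maf_cohort <- function(x, ...) {
  cat(sprintf("<maf_cohort> %d sample(s), %d mutation record(s)\n",
              x$cohort_size, sum(vapply(x$mutations, length, integer(1)))))
  invisible(x)
}

## ---------------------------------------------------------------------
## report writing

#' Write enrichment results to TSV files
#'
#' Writes `<prefix>_feature_results.tsv` (one row per feature, sorted by
#' combined q-value, then combined p-value, then feature id) and
#' `<prefix>_hotspots.tsv` (one row per candidate hotspot, sorted by
#' hotspot q, p, feature id, start). All coordinates are 1-based
#' inclusive; numeric columns carry 6 significant digits.
#'
#' @param results A `burden_results` object from [run_coding()] or
#'   [run_noncoding()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, the two file paths written.
#' @export
write_results <- function(results, out_prefix) {
  stopifnot(inherits(results, "burden_results"))
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  fr <- results$features
  ord <- order(fr$combined_q, fr$combined_p, fr$feature_id)
  fr <- fr[ord, , drop = FALSE]
  num_cols <- c("bg_rate", "burden_p", "burden_q", "best_hotspot_p",
                "wap_p", "wap_q", "combined_p", "combined_q")
  for (cc in intersect(num_cols, names(fr))) fr[[cc]] <- fmt_num(fr[[cc]])
  f_path <- paste0(out_prefix, "_feature_results.tsv")
  write.table(fr, f_path, sep = "\t", quote = FALSE, row.names = FALSE)
  hs <- results$hotspots
  if (nrow(hs) > 0) {
    ord <- order(hs$q, hs$p, hs$feature_id, hs$start)
    hs <- hs[ord, , drop = FALSE]
    for (cc in intersect(c("p", "q"), names(hs))) hs[[cc]] <- fmt_num(hs[[cc]])
  }
  h_path <- paste0(out_prefix, "_hotspots.tsv")
  write.table(hs, h_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(features = f_path, hotspots = h_path))
}

## Plain-text run log: resolved parameters, one per line.
write_run_log <- function(params, out_prefix) {
  path <- paste0(out_prefix, "_run_log.txt")
  lines <- c(
    sprintf("somaticburden version %s",
            as.character(utils::packageVersion("somaticburden"))),
    vapply(names(params), function(k) {
      v <- params[[k]]
      sprintf("%s = %s", k,
              if (is.null(v)) "NULL" else paste(format(v), collapse = ","))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
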