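## Synthetic cohort generator.
##
## Builds fully self-contained test inputs: a toy genome FASTA, tiled
## multi-exon gene models (GTF), short/long promoter definitions (BED),
## and per-sample bgzip-compressed, tabix-indexed VCFs with Poisson
## background mutations, optional feature-level rate multipliers, and
## tight positional hotspots shared across chosen carrier samples. A
## machine-readable truth table records every feature's generating class.
##
## Placement is positionally uniform within feature intervals: the
## statistical machinery under test assumes position-homogeneous
## backgrounds per feature, and the generator emulates exactly that null
## (no mutational-signature or sequence-context bias).

#' Generate a toy genome with gene models and promoter regions
#'
#' Writes a random-sequence FASTA, a GTF of two-exon genes tiled along
#' each chromosome on alternating strands, and two promoter BED files:
#' a "short" definition (100 nt immediately upstream of each TSS) and a
#' "long" one (2000 nt upstream). Minus-strand promoters lie downstream
#' of the gene's rightmost coordinate, following the TSS convention.
#'
#' @param out_dir Output directory (created if needed).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param genes_per_chrom Genes tiled per chromosome; default as many as
#'   fit at `gene_pitch` spacing with promoter head-room.
#' @param gene_length Genomic span of each gene (two 40% exons split by
#'   a 20% intron).
#' @param gene_pitch Distance between consecutive gene starts.
#' @param promoter_short,promoter_long Promoter lengths in nucleotides
#'   (defaults 100 and 2000).
#' @param seed Integer seed for the random genome sequence.
#' @return List with paths (`fasta`, `gtf`, `bed_short`, `bed_long`) and
#'   a `genes` data frame (id, chrom, start, end, strand, TSS).
#' @export
generate_toy_annotations <- function(out_dir, chrom_lengths,
                                     genes_per_chrom = NULL,
                                     gene_length = 1000, gene_pitch = 10000,
                                     promoter_short = 100,
                                     promoter_long = 2000, seed = 1) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  margin <- promoter_long + 1000
  rows <- list()
  for (ci in seq_along(chrom_lengths)) {
    chrom <- names(chrom_lengths)[ci]
    clen <- chrom_lengths[[ci]]
    ng <- if (is.null(genes_per_chrom)) {
      max(0L, as.integer((clen - 2 * margin - gene_length) %/% gene_pitch) + 1L)
    } else {
      genes_per_chrom
    }
    if (ng == 0) next
    gs <- margin + 1 + (seq_len(ng) - 1) * gene_pitch
    ge <- gs + gene_length - 1
    if (any(ge > clen - margin)) {
      stop("genes do not fit on chromosome '", chrom,
           "' with the requested pitch")
    }
    strand <- rep(c("+", "-"), length.out = ng)
    rows[[ci]] <- data.frame(
      gene_id = sprintf("g_%s_%03d", chrom, seq_len(ng)),
      chrom = chrom, start = gs, end = ge, strand = strand,
      tss = ifelse(strand == "+", gs, ge),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  if (is.null(genes) || nrow(genes) == 0) stop("no genes fit the layout")

  fasta <- file.path(out_dir, "genome.fa")
  with_local_seed(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1)))
    names(seqs) <- names(chrom_lengths)
    Biostrings::writeXStringSet(seqs, fasta)
  })

  ## two exons of 40% of the span each, separated by a 20% intron
  exon_len <- floor(gene_length * 0.4)
  gtf <- file.path(out_dir, "genes.gtf")
  gtf_lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      g$gene_id, g$gene_id)
    e1 <- c(g$start, g$start + exon_len - 1)
    e2 <- c(g$end - exon_len + 1, g$end)
    fmt <- "%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s"
    c(sprintf(fmt, g$chrom, "gene", g$start, g$end, g$strand, attr_g),
      sprintf(fmt, g$chrom, "transcript", g$start, g$end, g$strand, attr_t),
      sprintf(fmt, g$chrom, "exon", e1[1], e1[2], g$strand, attr_t),
      sprintf(fmt, g$chrom, "exon", e2[1], e2[2], g$strand, attr_t))
  }))
  writeLines(gtf_lines, gtf)

  write_promoters <- function(plen, path) {
    ## BED: 0-based half-open, exactly plen nt upstream of the TSS
    start0 <- ifelse(genes$strand == "+", genes$tss - 1 - plen, genes$tss)
    end0 <- start0 + plen
    if (any(start0 < 0)) stop("promoter extends past chromosome start")
    lines <- sprintf("%s\t%d\t%d\t%s", genes$chrom, as.integer(start0),
                     as.integer(end0), paste0("prom_", genes$gene_id))
    writeLines(lines, path)
    path
  }
  bed_short <- write_promoters(promoter_short,
                               file.path(out_dir, "promoters_short.bed"))
  bed_long <- write_promoters(promoter_long,
                              file.path(out_dir, "promoters_long.bed"))
  list(fasta = fasta, gtf = gtf, bed_short = bed_short, bed_long = bed_long,
       genes = genes)
}

#' Generate a synthetic somatic mutation cohort
#'
#' For every sample and feature, draws a Poisson number of mutations
#' with mean `background_rate * multiplier * L` and places them uniformly
#' within the feature's intervals. Planted hotspots add one mutation at a
#' uniform position inside the planted window for each of `n_carriers`
#' randomly chosen samples. Coding-style fixtures label each mutation
#' silent with probability `silent_fraction` (planted hotspot mutations
#' are always non-silent), written to the `anno_field` INFO key. VCFs
#' are position-sorted, bgzip-compressed and tabix-indexed; a cohort
#' list file and a truth table accompany them. The same seed reproduces
#' the file set exactly.
#'
#' @param features A `feature_set` defining where mutations may fall.
#' @param out_dir Output directory.
#' @param n_samples Cohort size.
#' @param chrom_lengths Named numeric vector (written as VCF contigs).
#' @param background_rate Per-nucleotide per-sample mutation probability.
#' @param enriched_features Named numeric vector of rate multipliers
#'   (`>= 1`) keyed by feature id.
#' @param hotspot_plants Data frame with columns `feature_id`,
#'   `window_start` (1-based genomic), `window_length`, `n_carriers`.
#'   Windows must lie inside their feature's intervals.
#' @param silent_fraction Probability a background genic mutation is
#'   labelled silent (default 0).
#' @param anno_field INFO key for the impact annotation (default
#'   `"ANNO"`).
#' @param genome Optional FASTA path; when given, REF alleles are read
#'   from the sequence (otherwise `"A"` is written).
#' @param seed Integer seed.
#' @param write_maf Also write the same cohort as a single MAF file.
#' @return List with `vcf_list` (cohort list file), `vcf_paths`,
#'   `truth` (truth-table TSV path), `maf` (or `NULL`), and the truth
#'   data frame.
#' @export
generate_cohort <- function(features, out_dir, n_samples, chrom_lengths,
                            background_rate, enriched_features = NULL,
                            hotspot_plants = NULL, silent_fraction = 0,
                            anno_field = "ANNO", genome = NULL, seed = 1,
                            write_maf = FALSE) {
  stopifnot(inherits(features, "feature_set"), n_samples >= 1,
            background_rate >= 0, silent_fraction >= 0, silent_fraction <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fids <- names(features)
  mult <- stats::setNames(rep(1, length(fids)), fids)
  if (!is.null(enriched_features)) {
    if (any(enriched_features < 1)) stop("multipliers must be >= 1")
    unknown <- setdiff(names(enriched_features), fids)
    if (length(unknown) > 0) {
      stop("enriched feature(s) not in the feature set: ",
           paste(unknown, collapse = ", "))
    }
    mult[names(enriched_features)] <- enriched_features
  }
  if (!is.null(hotspot_plants)) {
    need <- c("feature_id", "window_start", "window_length", "n_carriers")
    stopifnot(all(need %in% names(hotspot_plants)))
    for (i in seq_len(nrow(hotspot_plants))) {
      hp <- hotspot_plants[i, ]
      if (!hp$feature_id %in% fids) {
        stop("planted hotspot references unknown feature '",
             hp$feature_id, "'")
      }
      iv <- features$grl[[hp$feature_id]]
      win <- GRanges(features$table$chrom[match(hp$feature_id, fids)],
                     IRanges(hp$window_start,
                             hp$window_start + hp$window_length - 1))
      covered <- sum(width(GenomicRanges::intersect(iv, win)))
      if (covered < hp$window_length) {
        stop("planted window for '", hp$feature_id,
             "' does not lie inside the feature")
      }
      if (hp$n_carriers > n_samples) {
        stop("planted hotspot asks for more carriers than samples")
      }
    }
  }
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  fa <- if (!is.null(genome)) {
    if (!file.exists(paste0(genome, ".fai"))) Rsamtools::indexFa(genome)
    Rsamtools::FaFile(genome)
  } else NULL

  muts <- with_local_seed(seed, {
    lam <- background_rate * as.numeric(mult) * features$table$length
    per_sample <- lapply(seq_len(n_samples), function(si) {
      cnts <- stats::rpois(length(lam), lam)
      hit <- which(cnts > 0)
      rows <- lapply(hit, function(fi) {
        cnt <- cnts[fi]
        off <- sample.int(features$table$length[fi], cnt, replace = TRUE)
        pos <- map_offsets(features$grl[[fi]], off)
        silent <- stats::runif(cnt) < silent_fraction
        data.frame(chrom = features$table$chrom[fi], pos = pos,
                   silent = silent, stringsAsFactors = FALSE)
      })
      if (length(rows) == 0) {
        data.frame(chrom = character(0), pos = numeric(0),
                   silent = logical(0))
      } else {
        do.call(rbind, rows)
      }
    })
    if (!is.null(hotspot_plants)) {
      for (i in seq_len(nrow(hotspot_plants))) {
        hp <- hotspot_plants[i, ]
        carriers <- sample.int(n_samples, hp$n_carriers)
        wpos <- hp$window_start +
          sample.int(hp$window_length, hp$n_carriers, replace = TRUE) - 1
        chrom <- features$table$chrom[match(hp$feature_id, fids)]
        for (j in seq_along(carriers)) {
          per_sample[[carriers[j]]] <- rbind(
            per_sample[[carriers[j]]],
            data.frame(chrom = chrom, pos = wpos[j], silent = FALSE,
                       stringsAsFactors = FALSE))
        }
      }
    }
    ## alleles: REF from the genome when available, ALT a different base
    lapply(per_sample, function(df) {
      if (nrow(df) == 0) {
        df$ref <- character(0); df$alt <- character(0)
        return(df)
      }
      df$ref <- if (!is.null(fa)) {
        as.character(scanFa(fa, GRanges(df$chrom, IRanges(df$pos, df$pos))))
      } else rep("A", nrow(df))
      bases <- c("A", "C", "G", "T")
      df$alt <- vapply(df$ref, function(r)
        sample(setdiff(bases, r), 1), character(1), USE.NAMES = FALSE)
      chrom_rank <- match(df$chrom, names(chrom_lengths))
      df <- df[order(chrom_rank, df$pos, df$alt), , drop = FALSE]
      df[!duplicated(df[, c("chrom", "pos", "ref", "alt")]), , drop = FALSE]
    })
  })

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    sprintf(paste0('##INFO=<ID=%s,Number=1,Type=String,',
                   'Description="Coding impact annotation">'), anno_field),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  vcf_paths <- character(n_samples)
  for (si in seq_len(n_samples)) {
    df <- muts[[si]]
    body <- if (nrow(df) == 0) character(0) else {
      term <- ifelse(df$silent, "synonymous_SNV", "nonsynonymous_SNV")
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s=%s", df$chrom,
              as.integer(df$pos), df$ref, df$alt, anno_field, term)
    }
    raw <- file.path(out_dir, paste0(sample_ids[si], ".vcf"))
    writeLines(c(header, body), raw)
    bg <- Rsamtools::bgzip(raw, overwrite = TRUE)
    file.remove(raw)
    Rsamtools::indexTabix(bg, format = "vcf")
    vcf_paths[si] <- bg
  }
  vcf_list <- file.path(out_dir, "cohort_vcfs.txt")
  writeLines(sprintf("%s\t%s", vcf_paths, sample_ids), vcf_list)

  planted <- if (is.null(hotspot_plants)) character(0)
             else hotspot_plants$feature_id
  truth <- data.frame(
    feature_id = fids,
    multiplier = as.numeric(mult),
    planted_hotspot = fids %in% planted,
    stringsAsFactors = FALSE)
  truth$class <- ifelse(truth$multiplier > 1 & truth$planted_hotspot,
                        "enriched_hotspot",
                 ifelse(truth$multiplier > 1, "enriched",
                 ifelse(truth$planted_hotspot, "hotspot_only", "null")))
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  maf_path <- NULL
  if (write_maf) {
    maf_path <- file.path(out_dir, "cohort.maf")
    rows <- do.call(rbind, lapply(seq_len(n_samples), function(si) {
      df <- muts[[si]]
      if (nrow(df) == 0) return(NULL)
      data.frame(Hugo_Symbol = "unknown", Chromosome = df$chrom,
                 Start_Position = as.integer(df$pos),
                 End_Position = as.integer(df$pos),
                 Variant_Classification = ifelse(df$silent, "Silent",
                                                 "Missense_Mutation"),
                 Reference_Allele = df$ref, Tumor_Seq_Allele2 = df$alt,
                 Tumor_Sample_Barcode = sample_ids[si],
                 stringsAsFactors = FALSE)
    }))
    write.table(rows, maf_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(vcf_list = vcf_list, vcf_paths = vcf_paths, truth = truth_path,
       maf = maf_path, truth_table = truth, sample_ids = sample_ids)
}
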