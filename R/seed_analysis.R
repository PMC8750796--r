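# Seed-focused stages: expression binning, siren calling, phasing,
# region methylation and integrative siRNA24 target prediction.

#' Bin genes by mean expression
#'
#' high: FPKM > 10; medium: 2 < FPKM <= 10; low: 0 < FPKM <= 2;
#' none: FPKM == 0.
#'
#' @param expr named numeric vector of mean FPKM per gene (>= 0).
#' @return data.frame with `gene_id`, `fpkm`, `bin`.
#' @export
bin_gene_expression <- function(expr) {
  if (any(expr < 0)) stopf("bin_gene_expression: negative FPKM")
  bin <- ifelse(expr > 10, "high",
                ifelse(expr > 2, "medium",
                       ifelse(expr > 0, "low", "none")))
  data.frame(gene_id = names(expr), fpkm = as.numeric(expr), bin = bin,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Promoter, gene-body and downstream regions of genes
#'
#' Strand-aware 1 kb (default) flanks: for a minus-strand gene the
#' promoter lies at higher coordinates. Flanks are truncated at
#' chromosome edges when `genome_sizes` is supplied.
#'
#' @param genes stranded `GRanges` with `feature_id`.
#' @param flank_bp flank width.
#' @param genome_sizes optional named chromosome lengths for
#'   truncation.
#' @return named list of `GRanges`: `promoter`, `gene_body`,
#'   `downstream`, each carrying `gene_id`.
#' @export
gene_flanks <- function(genes, flank_bp = 1000, genome_sizes = NULL) {
  if (!is.null(genome_sizes)) {
    seqlevels(genes) <- names(genome_sizes)
    seqlengths(genes) <- genome_sizes
  }
  prom <- trim(suppressWarnings(flank(genes, flank_bp, start = TRUE)))
  down <- trim(suppressWarnings(flank(genes, flank_bp, start = FALSE)))
  ids <- genes$feature_id
  out <- list(promoter = prom, gene_body = granges(genes), downstream = down)
  lapply(out, function(g) {
    mcols(g) <- DataFrame(gene_id = ids)
    g
  })
}

#' Methylation fraction of a region
#'
#' Fraction of methylated cytosines over all cytosines in the region,
#' counting cytosines on both strands (a minus-strand cytosine appears
#' as G on the plus-strand reference). Contexts are pooled. Regions
#' with zero cytosines yield `NA` (missing, not 0).
#'
#' @param region `GRanges` (one or more regions).
#' @param genome named `DNAStringSet`.
#' @param calls data.frame of per-cytosine calls with columns `chrom`,
#'   `pos` (1-based), `methylated` (logical).
#' @return data.frame per region: `total_c`, `methylated_c`,
#'   `fraction`.
#' @export
methylation_fraction <- function(region, genome, calls) {
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  seqs <- extract_sequence(genome, granges_unstranded(region))
  total_c <- as.integer(letterFrequency(DNAStringSet(seqs), "CG"))
  mcalls <- calls[calls$methylated, , drop = FALSE]
  cgr <- GRanges(mcalls$chrom, IRanges(mcalls$pos, width = 1))
  meth <- countOverlaps(granges_unstranded(region), cgr)
  frac <- ifelse(total_c > 0, meth / total_c, NA_real_)
  data.frame(total_c = total_c, methylated_c = as.integer(meth),
             fraction = frac, stringsAsFactors = FALSE)
}

granges_unstranded <- function(gr) {
  gr <- granges(gr)
  strand(gr) <- "*"
  gr
}

#' Call siren loci
#'
#' Sirens are exceptionally highly expressed siRNA loci of a given
#' length class in a focal tissue: mean FPKM over the tissue's
#' replicates above `10^siren_log10_fpkm` (default `10^2.25`, about
#' 177.8). The classic endosperm definition uses the 21 nt class in
#' solid endosperm (24 nt in milky-stage endosperm).
#'
#' @param x classified `srna_loci`.
#' @param tissue focal tissue.
#' @param length_class siRNA length class (default 21).
#' @param config [analysis_config()].
#' @return character vector of siren locus ids.
#' @export
call_sirens <- function(x, tissue, length_class = 21,
                        config = analysis_config()) {
  lab <- sprintf("siRNA%d", length_class)
  idx <- which(x$loci$class == lab)
  if (length(idx) == 0) return(character(0))
  fpkm <- loci_fpkm(x)
  cols <- x$samples$sample_id[x$samples$tissue == tissue]
  if (length(cols) == 0) stopf("call_sirens: no replicates for '%s'", tissue)
  mfpkm <- rowMeans(fpkm[idx, cols, drop = FALSE])
  x$loci$locus_id[idx][mfpkm > 10^config$siren_log10_fpkm]
}

#' In-register (phasing) fraction of a locus
#'
#' Operational phasing definition: the maximum, over offsets
#' `o in [0, phase)`, of the fraction of reads whose 5' end position is
#' congruent to `o` modulo the phase. A locus is called phased when
#' this fraction reaches `register_threshold`. Loci with fewer than
#' `min_reads` reads are excluded (both values `NA`).
#'
#' @param starts 5' end positions of the locus's reads (use the end
#'   coordinate for minus-strand reads).
#' @param phase register period in nt (default 21).
#' @param register_threshold fraction at or above which the locus is
#'   phased.
#' @param min_reads minimum read count.
#' @return list with `fraction` and `phased`.
#' @export
phasing_fraction <- function(starts, phase = 21, register_threshold = 0.5,
                             min_reads = 10) {
  if (length(starts) < min_reads) {
    return(list(fraction = NA_real_, phased = NA))
  }
  reg <- starts %% phase
  frac <- max(tabulate(reg + 1, nbins = phase)) / length(starts)
  list(fraction = frac, phased = frac >= register_threshold)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of non-negative counts with non-zero margins.
#' @return list with `statistic` and `p.value`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("chi_square_2x2: need a 2x2 table")
  if (any(tab < 0)) stopf("chi_square_2x2: negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("chi_square_2x2: zero margin")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Predict siRNA24 target genes from overlap, methylation and expression
#'
#' A gene is called a putative RdDM-style siRNA24 target in region
#' class R (promoter / gene body / downstream) for the focal tissue iff
#' (i) at least one tissue-expressed siRNA24 locus overlaps its R
#' region by >= 1 bp, (ii) the methylation fraction of R reaches the
#' tissue's upper-quantile threshold, and (iii) the gene's FPKM in the
#' tissue is <= `fpkm_expressed`. Genes may appear under several region
#' classes. Candidate regions without a methylation summary (zero
#' cytosines) are skipped with a warning.
#'
#' @param sirna24 `GRanges` of siRNA24 loci expressed in the tissue
#'   (with `locus_id`).
#' @param flanks region list from [gene_flanks()].
#' @param gene_fpkm named vector: gene FPKM in the focal tissue.
#' @param methylation named list of data.frames from
#'   [methylation_fraction()], one per region class, rows parallel to
#'   `flanks`.
#' @param tissue focal tissue; its threshold comes from
#'   `config$methylation_quantile`, or is computed as the upper
#'   quartile of the tissue's per-region methylation distribution when
#'   `quantile_mode = "computed"`.
#' @param config [analysis_config()].
#' @param quantile_mode `"fixed"` (default) or `"computed"`.
#' @return data.frame of target calls: `gene_id`, `region_class`,
#'   `locus_ids`, `methylation`, `fpkm`, `tissue`.
#' @export
predict_targets <- function(sirna24, flanks, gene_fpkm, methylation,
                            tissue, config = analysis_config(),
                            quantile_mode = c("fixed", "computed")) {
  quantile_mode <- match.arg(quantile_mode)
  if (quantile_mode == "fixed") {
    if (!tissue %in% names(config$methylation_quantile)) {
      stopf("predict_targets: no methylation threshold configured for '%s'",
            tissue)
    }
    thr <- config$methylation_quantile[[tissue]]
  } else {
    pool <- unlist(lapply(methylation, function(m) m$fraction))
    thr <- quantile(pool, 0.75, na.rm = TRUE, names = FALSE)
  }
  rows <- list()
  for (rc in names(flanks)) {
    regions <- flanks[[rc]]
    meth <- methylation[[rc]]
    ov <- findOverlaps(regions, sirna24, ignore.strand = TRUE)
    if (length(ov) == 0) next
    for (gi in unique(queryHits(ov))) {
      gene <- regions$gene_id[gi]
      mfrac <- meth$fraction[gi]
      if (is.na(mfrac)) {
        warning(sprintf("no methylation summary for %s %s; skipped",
                        gene, rc))
        next
      }
      fp <- gene_fpkm[[gene]]
      if (mfrac >= thr && !is.null(fp) && fp <= config$fpkm_expressed) {
        loc <- sort(sirna24$locus_id[subjectHits(ov)[queryHits(ov) == gi]])
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gene, region_class = rc,
          locus_ids = paste(loc, collapse = ","),
          methylation = mfrac, fpkm = fp, tissue = tissue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), region_class = character(0),
                      locus_ids = character(0), methylation = numeric(0),
                      fpkm = numeric(0), tissue = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$region_class, out$gene_id), , drop = FALSE]
}
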