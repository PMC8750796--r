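# Locus calling, DicerCall classification, FPKM quantification and the
# expressed / novel / tissue-specific filters.

#' Cluster aligned reads into sRNA loci
#'
#' Reads whose intervals lie within `cluster_merge_gap` nt of each other
#' (strand-agnostic) are merged into one locus; the locus interval spans
#' the member reads. Loci whose pooled read count falls below the
#' `min_rpm` coverage floor -- `ceiling(min_rpm * total mapped reads /
#' 1e6)` over all samples pooled -- are discarded.
#'
#' @param reads `GRanges` of reads ([aligned_reads()]).
#' @param samples [sample_table()]; library sizes define the coverage
#'   floor and are retained for FPKM normalization.
#' @param config [analysis_config()].
#' @return An object of class `srna_loci`: a list with elements `loci`
#'   (`GRanges` with `locus_id`, `class`, `major_rna`), `counts`
#'   (locus x sample matrix), `length_hist` (locus x read-length
#'   matrix) and `samples`.
#' @export
cluster_reads <- function(reads, samples, config = analysis_config()) {
  empty <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(locus_id = character(0), class = character(0),
                          major_rna = character(0))
    structure(list(loci = g,
                   counts = matrix(0, 0, nrow(samples),
                                   dimnames = list(NULL, samples$sample_id)),
                   length_hist = matrix(0L, 0, 0),
                   samples = samples),
              class = "srna_loci")
  }
  if (length(reads) == 0) return(empty())
  merged <- reduce(granges(reads), min.gapwidth = config$cluster_merge_gap + 1L,
                   ignore.strand = TRUE)
  strand(merged) <- "*"
  merged <- merged[order(as.character(seqnames(merged)), start(merged))]
  ov <- findOverlaps(reads, merged, ignore.strand = TRUE)
  stopifnot(length(ov) == length(reads))  # reduced cover: one locus per read
  li <- subjectHits(ov)

  total_mapped <- sum(samples$total_reads)
  floor_count <- ceiling(config$min_rpm * total_mapped / 1e6)
  pooled <- tabulate(li, nbins = length(merged))
  keep <- which(pooled >= floor_count)
  if (length(keep) == 0) return(empty())
  merged <- merged[keep]
  sel <- li %in% keep
  li <- match(li[sel], keep)
  reads <- reads[sel]

  sample_f <- factor(reads$sample_id, levels = samples$sample_id)
  counts <- unclass(table(factor(li, levels = seq_along(merged)), sample_f))
  dimnames(counts) <- list(NULL, samples$sample_id)

  lens <- width(reads)
  len_levels <- sort(unique(lens))
  length_hist <- unclass(table(factor(li, levels = seq_along(merged)),
                               factor(lens, levels = len_levels)))
  dimnames(length_hist) <- list(NULL, as.character(len_levels))

  major_rna <- vapply(seq_along(merged), function(i) {
    tab <- sort(table(reads$sequence[li == i]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]
  }, character(1))

  mcols(merged) <- DataFrame(
    locus_id = sprintf("locus_%05d", seq_along(merged)),
    class = rep(NA_character_, length(merged)),
    major_rna = major_rna)
  structure(list(loci = merged, counts = counts, length_hist = length_hist,
                 samples = samples),
            class = "srna_loci")
}

# Subset an srna_loci container, keeping parallel slots aligned.
subset_loci <- function(x, idx) {
  x$loci <- x$loci[idx]
  x$counts <- x$counts[idx, , drop = FALSE]
  x$length_hist <- x$length_hist[idx, , drop = FALSE]
  x
}

#' @export
print.srna_loci <- function(x, ...) {
  cat(sprintf("srna_loci: %d loci x %d samples\n",
              length(x$loci), ncol(x$counts)))
  if (!all(is.na(x$loci$class))) print(table(x$loci$class))
  invisible(x)
}

#' Classify one locus by the 80% DicerCall rule
#'
#' If the fraction of reads with length 20-24 nt reaches
#' `dcl_fraction` (default 0.8), the locus is called `siRNAx` where x is
#' the modal read length within 20-24 nt (ties broken toward the longer
#' length); otherwise it is `OtherRNA`, presumed not Dicer-processed.
#'
#' @param length_hist named numeric vector mapping read length to count.
#' @param config [analysis_config()].
#' @return A class label string.
#' @export
classify_locus <- function(length_hist, config = analysis_config()) {
  length_hist <- length_hist[length_hist > 0]
  if (length(length_hist) == 0 || sum(length_hist) == 0) {
    stopf("classify_locus: empty length histogram")
  }
  lens <- as.integer(names(length_hist))
  if (anyNA(lens)) stopf("classify_locus: histogram names must be lengths")
  in_dcl <- lens >= 20L & lens <= 24L
  frac <- sum(length_hist[in_dcl]) / sum(length_hist)
  if (frac < config$dcl_fraction) return("OtherRNA")
  h <- length_hist[in_dcl]
  l <- lens[in_dcl]
  best <- max(l[h == max(h)])  # tie toward longer length
  sprintf("siRNA%d", best)
}

#' Classify every locus in an `srna_loci` container
#'
#' Applies [classify_locus()] row-wise and, when a set of known miRNA
#' annotations is supplied, relabels loci fully contained in an
#' annotated miRNA locus as `known_miRNA` (hairpin-based de novo miRNA
#' calling is out of scope).
#'
#' @param x `srna_loci`.
#' @param config [analysis_config()].
#' @param known_mirna optional `GRanges` of annotated miRNA loci.
#' @return `x` with `class` labels filled in.
#' @export
classify_loci <- function(x, config = analysis_config(), known_mirna = NULL) {
  labs <- vapply(seq_len(nrow(x$length_hist)), function(i) {
    classify_locus(x$length_hist[i, ], config)
  }, character(1))
  if (!is.null(known_mirna) && length(known_mirna)) {
    within <- overlapsAny(x$loci, known_mirna, type = "within",
                          ignore.strand = TRUE)
    labs[within] <- "known_miRNA"
  }
  x$loci$class <- labs
  x
}

#' Compute FPKM from raw counts
#'
#' FPKM = count / (locus length in kb x library size in millions).
#'
#' @param counts locus x sample count matrix.
#' @param locus_lengths locus lengths in nt (strictly positive).
#' @param library_sizes per-sample total mapped reads, in `counts`
#'   column order.
#' @return matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, locus_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(locus_lengths <= 0)) stopf("compute_fpkm: zero-length locus")
  if (any(library_sizes <= 0)) stopf("compute_fpkm: library size must be > 0")
  kb <- locus_lengths / 1000
  mm <- library_sizes / 1e6
  counts / outer(kb, mm)
}

#' FPKM table for an `srna_loci` container
#' @param x `srna_loci`.
#' @return locus x sample FPKM matrix (rownames = locus ids).
#' @export
loci_fpkm <- function(x) {
  f <- compute_fpkm(x$counts, width(x$loci),
                    x$samples$total_reads[match(colnames(x$counts),
                                                x$samples$sample_id)])
  rownames(f) <- x$loci$locus_id
  f
}

#' Call loci expressed per tissue
#'
#' A locus is expressed in a tissue iff FPKM exceeds `fpkm_expressed`
#' (strict `>`) in every biological replicate of that tissue.
#'
#' @param fpkm locus x sample FPKM matrix with locus-id rownames.
#' @param samples [sample_table()].
#' @param config [analysis_config()].
#' @return named list: tissue -> character vector of locus ids.
#' @export
call_expressed <- function(fpkm, samples, config = analysis_config()) {
  tissues <- unique(samples$tissue)
  out <- lapply(tissues, function(tt) {
    cols <- samples$sample_id[samples$tissue == tt]
    ok <- rowSums(fpkm[, cols, drop = FALSE] > config$fpkm_expressed) ==
      length(cols)
    rownames(fpkm)[ok]
  })
  setNames(out, tissues)
}

#' Filter candidate loci down to novel sRNA loci
#'
#' Three removals, applied in order: (i) candidates overlapping a
#' structural ncRNA feature (rRNA/tRNA/snRNA/snoRNA) where the
#' intersection covers at least `ncRNA_overlap_fraction` of the
#' annotated feature (or of the candidate, if so configured); (ii)
#' candidates contained in a known sRNA locus (overlap fraction of the
#' candidate >= `known_locus_overlap_fraction`, default full
#' containment); (iii) candidates not reaching FPKM >
#' `fpkm_expressed` in at least `novel_min_samples` samples (samples,
#' not tissues).
#'
#' @param x `srna_loci` candidates.
#' @param ncRNA `GRanges` of structural ncRNA features.
#' @param known_srna `GRanges` of known sRNA loci.
#' @param config [analysis_config()].
#' @return filtered `srna_loci`.
#' @export
filter_novel_loci <- function(x, ncRNA, known_srna,
                              config = analysis_config()) {
  keep <- rep(TRUE, length(x$loci))
  if (length(ncRNA)) {
    ov <- findOverlaps(x$loci, ncRNA, ignore.strand = TRUE)
    if (length(ov)) {
      inter <- width(pintersect(x$loci[queryHits(ov)],
                                ncRNA[subjectHits(ov)], ignore.strand = TRUE))
      anchor <- if (config$ncRNA_overlap_anchor == "feature") {
        width(ncRNA)[subjectHits(ov)]
      } else {
        width(x$loci)[queryHits(ov)]
      }
      bad <- unique(queryHits(ov)[inter / anchor >=
                                    config$ncRNA_overlap_fraction])
      keep[bad] <- FALSE
    }
  }
  if (length(known_srna)) {
    ov <- findOverlaps(x$loci, known_srna, ignore.strand = TRUE)
    if (length(ov)) {
      inter <- width(pintersect(x$loci[queryHits(ov)],
                                known_srna[subjectHits(ov)],
                                ignore.strand = TRUE))
      frac <- inter / width(x$loci)[queryHits(ov)]
      bad <- unique(queryHits(ov)[frac >= config$known_locus_overlap_fraction])
      keep[bad] <- FALSE
    }
  }
  x <- subset_loci(x, which(keep))
  if (length(x$loci)) {
    fpkm <- loci_fpkm(x)
    n_expr <- rowSums(fpkm > config$fpkm_expressed)
    x <- subset_loci(x, which(n_expr >= config$novel_min_samples))
  }
  x
}

#' Call tissue/group-specific loci
#'
#' A locus is specific to a sample group iff FPKM exceeds
#' `fpkm_expressed` in every sample of the group and the raw count is
#' zero in every sample outside the group. Groups may pool tissues
#' (e.g. root = vegetative + generative root, or an embryo + endosperm
#' union).
#'
#' @param fpkm locus x sample FPKM matrix (locus-id rownames).
#' @param counts matching raw count matrix.
#' @param groups named list: group label -> sample ids in the group.
#' @param config [analysis_config()].
#' @return named list: group -> character vector of locus ids.
#' @export
call_tissue_specific <- function(fpkm, counts, groups,
                                 config = analysis_config()) {
  all_samples <- colnames(fpkm)
  out <- lapply(groups, function(ids) {
    outside <- setdiff(all_samples, ids)
    expr_in <- rowSums(fpkm[, ids, drop = FALSE] > config$fpkm_expressed) ==
      length(ids)
    silent_out <- if (length(outside)) {
      rowSums(counts[, outside, drop = FALSE]) == 0
    } else {
      rep(TRUE, nrow(fpkm))
    }
    rownames(fpkm)[expr_in & silent_out]
  })
  setNames(out, names(groups))
}

#' Read length and 5' nucleotide profiles
#'
#' @param reads `GRanges` of reads.
#' @return list with `length_counts` (named counts per read length),
#'   `five_prime_by_length` (length x nucleotide frequency matrix, rows
#'   summing to 1) and `five_prime` (overall 5' nucleotide
#'   frequencies).
#' @export
profile_reads <- function(reads) {
  if (length(reads) == 0) {
    return(list(length_counts = integer(0),
                five_prime_by_length = matrix(numeric(0), 0, 0),
                five_prime = numeric(0)))
  }
  lens <- width(reads)
  nt <- substr(reads$sequence, 1, 1)
  length_counts <- table(lens)
  tab <- table(factor(lens), factor(nt, levels = c("A", "C", "G", "T", "N")))
  by_len <- sweep(unclass(tab), 1, rowSums(tab), "/")
  overall <- table(factor(nt, levels = c("A", "C", "G", "T", "N")))
  list(length_counts = c(unclass(length_counts)),
       five_prime_by_length = by_len,
       five_prime = c(unclass(overall)) / length(reads))
}
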