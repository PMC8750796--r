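# tRNA-derived small RNA identification and classification.
#
# Two reference sequences per tRNA gene: the mature tRNA (annotated
# genomic span, strand-aware, with the post-transcriptional 3' CCA
# appended) and the primary transcript (genomic span extended 40 nt
# upstream and downstream, no CCA). Reads of 14-40 nt are identified by
# exact full-length substring matching against these references and
# classified positionally: start at mature base 1 -> tRF-5 (14-30 nt)
# or 5tiR (31-40 nt); end at the final mature(+CCA) base -> tRF-3 or
# 3tiR; entirely within the 40 nt 3' trailer of the primary and
# 14-30 nt -> tRF-1. Exact matches anchored nowhere are discarded.

#' Build mature and primary tRNA references
#'
#' @param genome named `DNAStringSet` of chromosome sequences.
#' @param trna_features `GRanges` of tRNA gene annotations
#'   (`feature_type == "tRNA"`); minus-strand genes are
#'   reverse-complemented before extension. Features with a logical
#'   metadata column `intron` set are skipped with a warning (intron
#'   splicing is not modelled).
#' @param config [analysis_config()]; `trailer_bp` sets the flank.
#' @return data.frame with one row per tRNA: `trna_id`, `mature_seq`
#'   (span + CCA), `primary_seq` (span +/- `trailer_bp`),
#'   `mature_offset` (1-based start of the genomic span within the
#'   primary), `trailer_start`/`trailer_end` (trailer interval within
#'   the primary) and `anticodon` when annotated.
#' @export
build_trna_reference <- function(genome, trna_features,
                                 config = analysis_config()) {
  if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
  fl <- config$trailer_bp
  if (!is.null(trna_features$feature_type)) {
    trna_features <- trna_features[trna_features$feature_type == "tRNA"]
  }
  if (!is.null(trna_features$intron)) {
    skip <- !is.na(trna_features$intron) & trna_features$intron
    if (any(skip)) {
      warning(sprintf("skipping %d intron-containing tRNA(s)", sum(skip)))
      trna_features <- trna_features[!skip]
    }
  }
  lens <- setNames(width(genome), names(genome))
  chr <- as.character(seqnames(trna_features))
  low <- start(trna_features) - fl
  high <- end(trna_features) + fl
  bad <- which(low < 1L | high > lens[chr])
  if (length(bad)) {
    stopf("build_trna_reference: tRNA '%s' lacks %d nt flank room",
          trna_features$feature_id[bad[1]], fl)
  }
  mature_core <- extract_sequence(genome, trna_features)
  ext <- GRanges(chr, IRanges(low, high), strand = strand(trna_features))
  primary <- extract_sequence(genome, ext)
  n <- length(trna_features)
  data.frame(
    trna_id = trna_features$feature_id,
    chrom = chr,
    start = start(trna_features),
    end = end(trna_features),
    strand = as.character(strand(trna_features)),
    anticodon = if (!is.null(trna_features$anticodon)) {
      as.character(trna_features$anticodon)
    } else {
      rep(NA_character_, n)
    },
    mature_seq = paste0(mature_core, "CCA"),
    primary_seq = primary,
    mature_offset = rep(fl + 1L, n),
    trailer_start = nchar(primary) - fl + 1L,
    trailer_end = nchar(primary),
    stringsAsFactors = FALSE)
}

#' Identify and classify tRNA-derived reads
#'
#' Applies exact full-length matching of each 14-40 nt read against the
#' mature(+CCA) and primary references and the positional class rules
#' (see the module notes above). When a read carries both a 5' and a 3'
#' anchor (a near-intact tRNA), the 5' anchor takes precedence. Trailer
#' matches of 31-40 nt are discarded (tRF-1 is defined for 14-30 nt
#' only). A read matching several tRNAs is reported once, with all
#' matching `trna_id`s recorded.
#'
#' @param reads `GRanges` of reads ([aligned_reads()]); reads outside
#'   the 14-40 nt window are silently never candidates.
#' @param refs reference table from [build_trna_reference()].
#' @param config [analysis_config()]; `trf3_anchor_cca = FALSE` anchors
#'   tRF-3/3tiR at the final genomic base instead of the appended CCA.
#' @return data.frame of hits: `read_id`, `sample_id`, `trna_ids`
#'   (comma-separated), `ts_class`, `ref_space`, `match_start`,
#'   `match_end` (1-based within the matched reference sequence),
#'   `length`, `five_prime_nt`. No-hit reads are absent.
#' @export
classify_tsrna_read <- function(reads, refs, config = analysis_config()) {
  lo <- config$tsrna_len_trf[1]; hi <- config$tsrna_len_tir[2]
  trf_hi <- config$tsrna_len_trf[2]
  lens <- nchar(reads$sequence)
  cand <- which(lens >= lo & lens <= hi)
  seqs <- reads$sequence[cand]
  n <- length(cand)
  empty_hits <- data.frame(read_id = character(0), sample_id = character(0),
                           trna_ids = character(0), ts_class = character(0),
                           ref_space = character(0), match_start = integer(0),
                           match_end = integer(0), length = integer(0),
                           five_prime_nt = character(0),
                           stringsAsFactors = FALSE)
  if (n == 0 || nrow(refs) == 0) return(empty_hits)
  L <- nchar(refs$mature_seq)
  rl <- lens[cand]

  hit5 <- vector("list", n); hit3 <- vector("list", n); hitT <- vector("list", n)
  t_pos <- rep(NA_integer_, n)
  # unique sequences once; map back at the end
  uq <- !duplicated(seqs)
  useq <- seqs[uq]; ulen <- nchar(useq)
  u5 <- vector("list", length(useq)); u3 <- u5; uT <- u5
  uTpos <- rep(NA_integer_, length(useq))
  for (r in seq_len(nrow(refs))) {
    mat <- refs$mature_seq[r]
    anchor_end <- if (config$trf3_anchor_cca) L[r] else L[r] - 3L
    pre <- substring(mat, 1L, ulen) == useq
    suf <- substring(mat, anchor_end - ulen + 1L, anchor_end) == useq
    suf[ulen > anchor_end] <- FALSE
    trailer <- substring(refs$primary_seq[r], refs$trailer_start[r],
                         refs$trailer_end[r])
    for (i in which(pre)) u5[[i]] <- c(u5[[i]], r)
    for (i in which(suf)) u3[[i]] <- c(u3[[i]], r)
    idx_t <- which(ulen <= trf_hi)
    if (length(idx_t)) {
      pos <- vapply(useq[idx_t], function(s) {
        regexpr(s, trailer, fixed = TRUE)[[1]]
      }, integer(1), USE.NAMES = FALSE)
      for (j in seq_along(idx_t)) {
        if (pos[j] > 0) {
          i <- idx_t[j]
          uT[[i]] <- c(uT[[i]], r)
          if (is.na(uTpos[i])) uTpos[i] <- pos[j]
        }
      }
    }
  }
  map <- match(seqs, useq)
  hit5 <- u5[map]; hit3 <- u3[map]; hitT <- uT[map]; t_pos <- uTpos[map]

  cls <- rep(NA_character_, n)
  space <- rep(NA_character_, n)
  ms <- rep(NA_integer_, n); me <- rep(NA_integer_, n)
  ids <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    len <- rl[i]
    if (length(hit5[[i]])) {
      cls[i] <- if (len <= trf_hi) "tRF-5" else "5tiR"
      space[i] <- "mature"; ms[i] <- 1L; me[i] <- len
      ids[i] <- paste(refs$trna_id[hit5[[i]]], collapse = ",")
    } else if (length(hit3[[i]])) {
      cls[i] <- if (len <= trf_hi) "tRF-3" else "3tiR"
      r <- hit3[[i]][1]
      anchor_end <- if (config$trf3_anchor_cca) L[r] else L[r] - 3L
      space[i] <- "mature"; ms[i] <- anchor_end - len + 1L; me[i] <- anchor_end
      ids[i] <- paste(refs$trna_id[hit3[[i]]], collapse = ",")
    } else if (length(hitT[[i]]) && len <= trf_hi) {
      cls[i] <- "tRF-1"
      r <- hitT[[i]][1]
      space[i] <- "primary"
      ms[i] <- refs$trailer_start[r] + t_pos[i] - 1L
      me[i] <- ms[i] + len - 1L
      ids[i] <- paste(refs$trna_id[hitT[[i]]], collapse = ",")
    }
  }
  keep <- which(!is.na(cls))
  data.frame(read_id = reads$read_id[cand][keep],
             sample_id = reads$sample_id[cand][keep],
             trna_ids = ids[keep],
             ts_class = cls[keep],
             ref_space = space[keep],
             match_start = ms[keep],
             match_end = me[keep],
             length = rl[keep],
             five_prime_nt = substr(seqs[keep], 1, 1),
             stringsAsFactors = FALSE)
}

#' Start/end positional profiles of tsRNA hits
#'
#' Start positions are reported 1-based from the 5' end of the matched
#' reference (mature for anchored classes, primary for tRF-1); end
#' positions as the offset from the reference 3' end (0 = final base),
#' so 5'-anchored classes pile up at start 1 and 3'-anchored classes at
#' end offset 0 regardless of tRNA length.
#'
#' @param hits data.frame from [classify_tsrna_read()].
#' @param refs reference table from [build_trna_reference()].
#' @return list with `start` and `end_offset` count tables; counts are
#'   conserved (each hit appears once in each).
#' @export
positional_profiles <- function(hits, refs) {
  if (nrow(hits) == 0) {
    return(list(start = table(integer(0)), end_offset = table(integer(0))))
  }
  first_id <- vapply(strsplit(hits$trna_ids, ",", fixed = TRUE), `[[`, "", 1)
  r <- match(first_id, refs$trna_id)
  ref_len <- ifelse(hits$ref_space == "mature",
                    nchar(refs$mature_seq)[r], nchar(refs$primary_seq)[r])
  list(start = table(hits$match_start),
       end_offset = table(ref_len - hits$match_end))
}

#' Select stably expressed reference sRNA loci
#'
#' Stand-in for a likelihood-ratio "not differentially expressed"
#' screen: among loci with FPKM above the expressed cut-off in every
#' sample, returns the `k` loci with the lowest coefficient of
#' variation of FPKM across samples (ties broken by locus id).
#'
#' @param fpkm locus x sample FPKM matrix with locus-id rownames.
#' @param k number of reference loci (default 4).
#' @param config [analysis_config()].
#' @return character vector of `k` locus ids.
#' @export
select_reference_loci <- function(fpkm, k = 4, config = analysis_config()) {
  eligible <- rowSums(fpkm > config$fpkm_expressed) == ncol(fpkm)
  f <- fpkm[eligible, , drop = FALSE]
  if (nrow(f) < k) {
    stopf("select_reference_loci: only %d loci eligible, need %d", nrow(f), k)
  }
  cv <- apply(f, 1, function(v) sd(v) / mean(v))
  ord <- order(cv, rownames(f))
  rownames(f)[ord][seq_len(k)]
}

#' Reference-normalized tsRNA abundance and log2 fold change
#'
#' Per sample: the fraction of tRNA-derived reads among all 14-40 nt
#' reads is divided by the mean fraction of 14-40 nt reads falling in
#' `k` stable reference loci; the log2 fold change is then taken
#' against the mean normalized value over the baseline tissue's
#' replicates.
#'
#' @param tsrna_counts named vector: tRNA-derived 14-40 nt read count
#'   per sample.
#' @param total_counts named vector: all 14-40 nt reads per sample.
#' @param ref_fractions sample x reference-locus matrix of 14-40 nt
#'   read fractions (each column one reference locus).
#' @param samples [sample_table()].
#' @param baseline_tissue tissue whose replicate mean defines log2FC 0.
#' @return data.frame per sample: `tsrna_fraction`, `ref_fraction`,
#'   `normalized`, `log2fc`.
#' @export
tsrna_abundance <- function(tsrna_counts, total_counts, ref_fractions,
                            samples, baseline_tissue) {
  ids <- samples$sample_id
  if (!baseline_tissue %in% samples$tissue) {
    stopf("tsrna_abundance: baseline tissue '%s' not in sample table",
          baseline_tissue)
  }
  tot <- total_counts[ids]
  if (any(is.na(tot)) || any(tot == 0)) {
    stopf("tsrna_abundance: zero or missing 14-40 nt totals")
  }
  ts <- tsrna_counts[ids]
  ts[is.na(ts)] <- 0
  rf <- rowMeans(as.matrix(ref_fractions)[ids, , drop = FALSE])
  if (any(rf <= 0)) stopf("tsrna_abundance: zero reference fraction")
  normalized <- (ts / tot) / rf
  base <- mean(normalized[samples$tissue == baseline_tissue])
  data.frame(sample_id = ids,
             tissue = samples$tissue,
             tsrna_fraction = as.numeric(ts / tot),
             ref_fraction = as.numeric(rf),
             normalized = as.numeric(normalized),
             log2fc = as.numeric(log2(normalized / base)),
             stringsAsFactors = FALSE)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau with a two-sided p-value (normal
#' approximation under ties, exact otherwise).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `tau` and `p.value`.
#' @export
kendall_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("kendall_correlation: length mismatch")
  if (length(x) < 3) stopf("kendall_correlation: need n >= 3")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p.value = ct$p.value)
}
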