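# Shared fixtures and independent oracles. Everything is built in code;
# no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Cache generated datasets across test files (generation is seconds,
# several files want the same default world).
.dataset_cache <- new.env(parent = emptyenv())
shared_dataset <- function(key = "default", config = synth_config(seed = 7)) {
  if (is.null(.dataset_cache[[key]])) {
    .dataset_cache[[key]] <- generate_dataset(config)
  }
  .dataset_cache[[key]]
}

# Minimal sample table: 2 tissues x 2 replicates, 1e6 mapped reads.
tiny_samples <- function(tissues = c("root", "endosperm"), reps = 2,
                         total = 1e6) {
  sample_table(
    sample_id = as.vector(t(outer(tissues, seq_len(reps),
                                  function(t, r) sprintf("%s_r%d", t, r)))),
    tissue = rep(tissues, each = reps),
    replicate = rep(seq_len(reps), times = length(tissues)),
    total_reads = total)
}

# Reads at given 1-based closed intervals, all in one sample; sequences
# are arbitrary A-runs of matching width.
make_reads <- function(start, end, chrom = "c1", strand = "+",
                       sample_id = "root_r1", seq = NULL) {
  n <- length(start)
  if (is.null(seq)) seq <- strrep("A", end - start + 1)
  aligned_reads(sprintf("r%03d", seq_len(n)), seq, rep_len(chrom, n),
                start, end, rep_len(strand, n), rep_len(sample_id, n))
}

# Sequence-only reads for the tsRNA classifier (placement irrelevant).
seq_reads <- function(seqs, sample_id = "s1") {
  n <- length(seqs)
  aligned_reads(sprintf("q%05d", seq_len(n)), seqs, rep("dummy", n),
                rep(1L, n), nchar(seqs), rep("+", n), rep_len(sample_id, n))
}

# Random tRNA reference rows (no genome needed): mature = span + CCA,
# primary = 40 nt flanks around the span, consistent by construction.
random_trna_refs <- function(n, span = 72, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    spanseq <- paste(sample(c("A", "C", "G", "T"), span, replace = TRUE),
                     collapse = "")
    up <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
    data.frame(trna_id = sprintf("t%02d", i), chrom = "c1",
               start = 1000L * i, end = 1000L * i + span - 1L,
               strand = "+", anticodon = NA_character_,
               mature_seq = paste0(spanseq, "CCA"),
               primary_seq = paste0(up, spanseq, down),
               mature_offset = 41L,
               trailer_start = 40L + span + 1L,
               trailer_end = 40L + span + 40L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Independent tsRNA oracle: enumerate every anchored substring of every
# reference into lookup sets, then classify by set membership with the
# 5' > 3' > trailer precedence. Never touches the anchored-comparison
# code path of classify_tsrna_read.
tsrna_oracle <- function(refs, seqs, trf = c(14, 30), tir = c(31, 40)) {
  set5 <- character(0); set3 <- character(0); setT <- character(0)
  for (r in seq_len(nrow(refs))) {
    mat <- refs$mature_seq[r]
    L <- nchar(mat)
    for (l in trf[1]:tir[2]) {
      if (l <= L) {
        set5 <- c(set5, substr(mat, 1, l))
        set3 <- c(set3, substr(mat, L - l + 1, L))
      }
    }
    trailer <- substr(refs$primary_seq[r], refs$trailer_start[r],
                      refs$trailer_end[r])
    for (l in trf[1]:trf[2]) {
      for (p in 1:(nchar(trailer) - l + 1)) {
        setT <- c(setT, substr(trailer, p, p + l - 1))
      }
    }
  }
  l <- nchar(seqs)
  in5 <- seqs %in% set5
  in3 <- seqs %in% set3
  inT <- seqs %in% setT
  out <- rep("nohit", length(seqs))
  ok <- l >= trf[1] & l <= tir[2]
  short <- l <= trf[2]
  out[ok & in5 & short] <- "tRF-5"
  out[ok & in5 & !short] <- "5tiR"
  out[ok & !in5 & in3 & short] <- "tRF-3"
  out[ok & !in5 & in3 & !short] <- "3tiR"
  out[ok & !in5 & !in3 & inT & short] <- "tRF-1"
  out
}

# Brute-force single-linkage read clustering by transitive closure of
# "interval gap <= max_gap" (strand-agnostic).
brute_cluster <- function(start, end, max_gap) {
  n <- length(start)
  parent <- seq_len(n)
  find2 <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1
      if (gap <= max_gap) {
        ri <- find2(i); rj <- find2(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find2, integer(1))
}

# Exhaustive Kendall tau-b by pair counting with tie correction.
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Closed-form Pearson chi-squared on a 2x2 via the ad-bc formula.
brute_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
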