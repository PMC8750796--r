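test_that("tRNA references carry CCA, flanks and strand correctly", {
  set.seed(5)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = chrseq))
  tr <- GRanges("c1", IRanges(c(101, 251), width = 73), strand = c("+", "-"))
  tr$feature_id <- c("tp", "tm"); tr$feature_type <- "tRNA"
  refs <- build_trna_reference(genome, tr)
  expect_equal(nchar(refs$mature_seq), c(76, 76))     # 73 + CCA
  expect_equal(nchar(refs$primary_seq), c(153, 153))  # 73 + 2 x 40
  expect_equal(refs$mature_seq[1],
               paste0(substr(chrseq, 101, 173), "CCA"))
  rcspan <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrseq, 251, 323))))
  expect_equal(refs$mature_seq[2], paste0(rcspan, "CCA"))
  # the genomic span sits at mature_offset within the primary
  expect_equal(substr(refs$primary_seq[1], refs$mature_offset[1],
                      refs$mature_offset[1] + 72),
               substr(refs$mature_seq[1], 1, 73))
  # too close to the chromosome start
  tr_bad <- GRanges("c1", IRanges(10, 82), strand = "+")
  tr_bad$feature_id <- "edge"; tr_bad$feature_type <- "tRNA"
  expect_error(build_trna_reference(genome, tr_bad), "edge")
})

test_that("positional class rules drive tsRNA classification", {
  refs <- random_trna_refs(1, seed = 2)
  mat <- refs$mature_seq
  trailer <- substr(refs$primary_seq, refs$trailer_start, refs$trailer_end)
  L <- nchar(mat)
  cases <- list(
    list(seq = substr(mat, 1, 20), cls = "tRF-5"),
    list(seq = substr(mat, 1, 33), cls = "5tiR"),
    list(seq = substr(mat, L - 24, L), cls = "tRF-3"),   # ends at CCA
    list(seq = substr(mat, L - 34, L), cls = "3tiR"),
    list(seq = substr(trailer, 6, 25), cls = "tRF-1"))
  hits <- classify_tsrna_read(seq_reads(vapply(cases, `[[`, "", "seq")),
                              refs)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$ts_class, vapply(cases, `[[`, "", "cls"))
  expect_equal(hits$match_start[1], 1)
  expect_equal(hits$match_end[3], L)
  # internal fragment: exact substring but no positional anchor -> no hit
  internal <- seq_reads(substr(mat, 11, 34))
  expect_equal(nrow(classify_tsrna_read(internal, refs)), 0)
  # outside the 14-40 nt window reads are never candidates
  long41 <- seq_reads(substr(refs$primary_seq, 41, 81))
  expect_equal(nrow(classify_tsrna_read(long41, refs)), 0)
  # 31-40 nt trailer matches are discarded (tRF-1 is 14-30 nt only)
  t31 <- seq_reads(substr(trailer, 1, 31))
  expect_equal(nrow(classify_tsrna_read(t31, refs)), 0)
})

test_that("classifier agrees with the enumeration oracle on small cases", {
  refs <- random_trna_refs(3, span = 60, seed = 9)
  seqs <- unique(unlist(lapply(seq_len(nrow(refs)), function(r) {
    src <- c(refs$mature_seq[r], refs$primary_seq[r])
    unlist(lapply(src, function(s) {
      unlist(lapply(c(14, 20, 30, 31, 40), function(l) {
        if (nchar(s) < l) return(character(0))
        starts <- seq(1, nchar(s) - l + 1, by = 3)
        substring(s, starts, starts + l - 1)
      }))
    }))
  })))
  want <- tsrna_oracle(refs, seqs)
  hits <- classify_tsrna_read(seq_reads(seqs), refs)
  got <- setNames(rep("nohit", length(seqs)), sprintf("q%05d", seq_along(seqs)))
  got[hits$read_id] <- hits$ts_class
  expect_identical(unname(got), want)
})

test_that("positional profiles are anchored bookkeeping", {
  refs <- random_trna_refs(2, seed = 4)
  mk <- function(r, cls, n) {
    ref <- refs[r, , drop = FALSE]
    L <- nchar(ref$mature_seq)
    seqs <- switch(cls,
                   "tRF-5" = substring(ref$mature_seq, 1, 13 + seq_len(n)),
                   "tRF-3" = substring(ref$mature_seq, L - 13 - seq_len(n) + 1, L),
                   "3tiR" = substring(ref$mature_seq, L - 30 - seq_len(n) + 1, L))
    seqs
  }
  seqs <- c(mk(1, "tRF-5", 10), mk(1, "tRF-3", 4), mk(2, "3tiR", 3))
  hits <- classify_tsrna_read(seq_reads(seqs), refs)
  prof <- positional_profiles(hits, refs)
  expect_equal(sum(prof$start), nrow(hits))
  expect_equal(sum(prof$end_offset), nrow(hits))
  expect_equal(unname(prof$start[["1"]]), 10)         # all tRF-5 at base 1
  expect_equal(unname(prof$end_offset[["0"]]), 4 + 3) # tRF-3 + 3tiR at 3' end
  empty <- positional_profiles(classify_tsrna_read(seq_reads(character(0)),
                                                   refs), refs)
  expect_equal(sum(empty$start), 0)
})

test_that("reference loci are the lowest-CV universally expressed loci", {
  f <- rbind(L_flat = c(10, 10, 10, 10),
             L_low = c(1.9, 10, 10, 10),     # ineligible (one rep <= 2)
             L_var1 = c(5, 10, 5, 10),
             L_var2 = c(4, 12, 4, 12),
             L_mild = c(9, 10, 9, 10),
             L_big = c(100, 104, 98, 102))
  colnames(f) <- paste0("s", 1:4)
  got <- select_reference_loci(f, k = 4)
  cv <- apply(f[rownames(f) != "L_low", ], 1, function(v) sd(v) / mean(v))
  want <- names(sort(cv))[1:4]
  expect_equal(got, want)
  expect_equal(got[1], "L_flat")  # CV 0 first
  expect_error(select_reference_loci(f, k = 6), "eligible")
})

test_that("tsRNA abundance normalization and log2FC follow closed forms", {
  smp <- tiny_samples()  # root_r1 root_r2 endosperm_r1 endosperm_r2
  total <- setNames(rep(1000, 4), smp$sample_id)
  # tRNA fraction 0.02, reference fraction 0.01 -> normalized 2
  ts <- setNames(c(20, 20, 5, 5), smp$sample_id)
  rf <- matrix(0.01, 4, 4, dimnames = list(smp$sample_id, NULL))
  ab <- tsrna_abundance(ts, total, rf, smp, baseline_tissue = "root")
  expect_equal(ab$normalized[1], 2.0)
  expect_equal(ab$log2fc[1:2], c(0, 0))            # baseline vs own mean
  expect_equal(ab$log2fc[3:4], c(-2, -2))          # 0.5 vs baseline 2.0
  expect_error(tsrna_abundance(ts, setNames(rep(0, 4), smp$sample_id),
                               rf, smp, "root"), "total")
  expect_error(tsrna_abundance(ts, total, rf * 0, smp, "root"), "reference")
  # monotonicity: fewer tsRNA reads in one tissue lowers its log2FC
  prev <- Inf
  for (k in c(20, 10, 5, 1)) {
    ts2 <- setNames(c(20, 20, k, k), smp$sample_id)
    lfc <- tsrna_abundance(ts2, total, rf, smp, "root")$log2fc[3]
    expect_lt(lfc, prev)
    prev <- lfc
  }
})

test_that("Kendall tau matches exhaustive pair counting", {
  expect_equal(kendall_correlation(1:3, 3:1)$tau, -1)
  expect_equal(kendall_correlation(1:3, 1:3)$tau, 1)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_correlation(x, y)$tau, brute_tau_b(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_correlation(1:3, 1:4), "length")
  expect_error(kendall_correlation(1:2, 1:2), "n >= 3")
})
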