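test_that("cluster_reads merges by gap and applies the coverage floor", {
  cfg <- analysis_config()
  smp <- tiny_samples(total = 0.5e6)  # 4 samples -> 2e6 pooled, floor 1
  # 0-based [100,124) and [150,171) are 1-based [101,124], [151,171]:
  # gap 26 <= 75 -> one locus spanning 101..171
  rd <- make_reads(c(101, 151), c(124, 171))
  x <- cluster_reads(rd, smp, cfg)
  expect_length(x$loci, 1)
  expect_equal(start(x$loci), 101)
  expect_equal(end(x$loci), 171)
  # gap 176 > 75 -> two loci
  rd2 <- make_reads(c(101, 301), c(124, 324))
  expect_length(cluster_reads(rd2, smp, cfg)$loci, 2)
  # floor = ceiling(0.5 * 2e6 / 1e6) = 1: a single-read cluster is kept
  x1 <- cluster_reads(make_reads(500, 523), smp, cfg)
  expect_length(x1$loci, 1)
  # at 14e6 pooled the floor is 7: 6 stacked reads are dropped, 7 kept
  smp_big <- tiny_samples(total = 3.5e6)
  six <- make_reads(rep(1000, 6), rep(1023, 6))
  seven <- make_reads(rep(1000, 7), rep(1023, 7))
  expect_length(cluster_reads(six, smp_big, cfg)$loci, 0)
  expect_length(cluster_reads(seven, smp_big, cfg)$loci, 1)
  # empty input is an empty result, not an error
  expect_length(cluster_reads(make_reads(integer(0), integer(0)),
                              smp, cfg)$loci, 0)
})

test_that("cluster_reads agrees with brute-force transitive closure", {
  cfg <- analysis_config()
  smp <- tiny_samples(total = 0.5e6)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    st <- sample(1:3000, n, replace = TRUE)
    en <- st + sample(18:40, n, replace = TRUE) - 1
    x <- cluster_reads(make_reads(st, en), smp, cfg)
    comp <- brute_cluster(st, en, cfg$cluster_merge_gap)
    expect_equal(length(x$loci), length(unique(comp)))
    spans <- t(vapply(split(seq_len(n), comp), function(i) {
      c(min(st[i]), max(en[i]))
    }, numeric(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    expect_equal(start(x$loci), unname(spans[, 1]))
    expect_equal(end(x$loci), unname(spans[, 2]))
  }
})

test_that("read counts are conserved across clustering", {
  ds <- shared_dataset()
  x <- cluster_reads(ds$reads, ds$samples)
  assigned <- sum(countOverlaps(ds$reads, x$loci, ignore.strand = TRUE) > 0)
  expect_equal(sum(x$counts), assigned)
  expect_equal(unname(rowSums(x$length_hist)), unname(rowSums(x$counts)))
})

test_that("the 80% DicerCall rule classifies histogram edge cases", {
  cases <- list(
    list(h = c(`24` = 90, `30` = 10), lab = "siRNA24"),   # 0.90 >= 0.8
    list(h = c(`21` = 79, `35` = 21), lab = "OtherRNA"),  # 0.79 < 0.8
    list(h = c(`21` = 80, `35` = 20), lab = "siRNA21"),   # 0.80 boundary
    list(h = c(`21` = 81, `35` = 19), lab = "siRNA21"),
    list(h = c(`21` = 50, `24` = 50), lab = "siRNA24"),   # tie -> longer
    list(h = c(`20` = 30, `22` = 30, `24` = 40), lab = "siRNA24"),
    list(h = c(`20` = 100), lab = "siRNA20"),
    list(h = c(`23` = 5, `24` = 4, `25` = 1), lab = "siRNA23"),
    list(h = c(`19` = 21, `24` = 79), lab = "OtherRNA"),  # 19 nt outside
    list(h = c(`19` = 20, `24` = 80), lab = "siRNA24"),
    list(h = c(`30` = 10), lab = "OtherRNA"),
    list(h = c(`22` = 2, `23` = 2, `21` = 2, `20` = 2, `24` = 2),
         lab = "siRNA24"),                                 # 5-way tie
    list(h = c(`40` = 99, `24` = 1), lab = "OtherRNA"))
  for (cs in cases) {
    expect_identical(classify_locus(cs$h), cs$lab,
                     label = paste(names(cs$h), cs$h, collapse = " "))
  }
  expect_error(classify_locus(numeric(0)), "empty")
  expect_error(classify_locus(c(`24` = 0)), "empty")
})

test_that("classification is invariant to histogram scaling", {
  set.seed(3)
  for (i in 1:20) {
    h <- setNames(sample(0:30, 6, replace = TRUE),
                  sample(18:40, 6))
    if (sum(h) == 0) next
    k <- sample(c(2, 5, 10), 1)
    expect_identical(classify_locus(h), classify_locus(h * k))
  }
})

test_that("FPKM follows the closed form", {
  expect_equal(compute_fpkm(matrix(10), 1000, 1e6)[1], 10)
  expect_equal(compute_fpkm(matrix(0), 1000, 1e6)[1], 0)
  expect_equal(compute_fpkm(matrix(7), 500, 2e6)[1], 7)
  expect_error(compute_fpkm(matrix(1), 0, 1e6), "zero-length")
  expect_error(compute_fpkm(matrix(1), 100, 0), "library")
})

test_that("expressed calls require FPKM > 2 in every replicate", {
  smp <- sample_table(c("a1", "a2", "a3"), "embryo", 1:3, 1e6)
  f <- matrix(c(2.1, 3.0, 2.5,
                2.0, 5.0, 9.0,
                2.01, 2.01, 2.01), nrow = 3, byrow = TRUE,
              dimnames = list(c("L1", "L2", "L3"), c("a1", "a2", "a3")))
  expect_setequal(call_expressed(f, smp)$embryo, c("L1", "L3"))
  # single replicate at 2.01 is expressed
  smp1 <- sample_table("b1", "endosperm", 1, 1e6)
  f1 <- matrix(2.01, 1, 1, dimnames = list("L1", "b1"))
  expect_equal(call_expressed(f1, smp1)$endosperm, "L1")
})

test_that("novel-locus filtering removes ncRNA/known overlaps", {
  smp <- tiny_samples(total = 0.1e6)   # low libs so FPKM is generous
  # three candidate clusters
  rd <- make_reads(c(rep(1000, 5), rep(5000, 5), rep(9000, 5)),
                   c(rep(1023, 5), rep(5023, 5), rep(9023, 5)),
                   sample_id = rep(c("root_r1", "root_r2"), length.out = 15))
  x <- cluster_reads(rd, smp)
  expect_length(x$loci, 3)
  # ncRNA feature exactly half-covered by candidate 1 -> removed
  ncrna <- GRanges("c1", IRanges(1012, 1035))  # 24 nt rRNA, 12 nt overlap
  ncrna$feature_id <- "rrna1"; ncrna$feature_type <- "rRNA"
  # candidate 2 identical to a known locus -> removed (full containment)
  known <- GRanges("c1", IRanges(5000, 5023))
  out <- filter_novel_loci(x, ncrna, known)
  expect_equal(start(out$loci), 9000)
  # expression filter: counted over samples, not tissues
  f <- loci_fpkm(out)
  expect_true(sum(f > 2) >= 2)
})

test_that("tissue-specific calls demand silence elsewhere", {
  smp <- tiny_samples()  # root_r1 root_r2 endosperm_r1 endosperm_r2
  counts <- matrix(c(40, 45, 0, 0,
                     40, 45, 1, 0,
                     0, 0, 50, 55), nrow = 3, byrow = TRUE,
                   dimnames = list(c("L1", "L2", "L3"), smp$sample_id))
  f <- compute_fpkm(counts, rep(200, 3), smp$total_reads)
  groups <- list(root = c("root_r1", "root_r2"),
                 endosperm = c("endosperm_r1", "endosperm_r2"),
                 both = smp$sample_id)
  ts <- call_tissue_specific(f, counts, groups)
  expect_equal(ts$root, "L1")       # L2 leaks one read elsewhere
  expect_equal(ts$endosperm, "L3")
  expect_length(ts$both, 0)  # nothing is expressed in every sample
  expressed <- call_expressed(f, smp)
  for (tt in names(expressed)) {
    spec <- call_tissue_specific(
      f, counts, setNames(list(smp$sample_id[smp$tissue == tt]), tt))[[tt]]
    expect_true(all(spec %in% expressed[[tt]]))
  }
})

test_that("read profiles conserve counts and recover the planted 5' bias", {
  rd <- make_reads(c(1, 30, 60, 90), c(21, 50, 80, 110),
                   seq = c(paste0("A", strrep("G", 20)),
                           paste0("A", strrep("G", 20)),
                           paste0("C", strrep("G", 20)),
                           paste0("G", strrep("G", 20))))
  p <- profile_reads(rd)
  expect_equal(unname(p$five_prime[c("A", "C", "G", "T")]),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(sum(p$length_counts), 4)

  empty <- profile_reads(make_reads(integer(0), integer(0)))
  expect_length(empty$length_counts, 0)

  ds <- shared_dataset()
  pp <- profile_reads(ds$reads)
  expect_equal(sum(pp$length_counts), length(ds$reads))
  # generator plants an A bias at the 5' end of 24 nt reads
  expect_equal(names(which.max(pp$five_prime_by_length["24", ])), "A")
  expect_equal(names(which.max(pp$five_prime_by_length["21", ])), "T")
})
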