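test_that("expression bins partition genes with the printed boundaries", {
  expr <- c(g1 = 10, g2 = 0, g3 = 10.01, g4 = 2, g5 = 0.5, g6 = 300)
  bins <- bin_gene_expression(expr)
  expect_equal(bins$bin, c("medium", "none", "high", "low", "low", "high"))
  expect_error(bin_gene_expression(c(g = -1)), "negative")
  set.seed(2)
  x <- setNames(round(rexp(200, 0.1), 2), paste0("g", 1:200))
  b <- bin_gene_expression(x)
  expect_equal(sum(table(b$bin)), 200)  # partition, no gene unbinned
})

test_that("gene flanks are strand-aware and edge-truncated", {
  g <- GRanges(c("c1", "c1", "c1"), IRanges(c(5000, 5000, 300),
                                            c(5999, 5999, 900)),
               strand = c("+", "-", "+"))
  g$feature_id <- c("gp", "gm", "ge")
  fl <- gene_flanks(g, flank_bp = 1000, genome_sizes = c(c1 = 20000))
  expect_equal(start(fl$promoter)[1], 4000)  # [4000,4999] upstream of +
  expect_equal(end(fl$promoter)[1], 4999)
  expect_equal(start(fl$promoter)[2], 6000)  # minus strand: higher coords
  expect_equal(end(fl$promoter)[2], 6999)
  expect_equal(start(fl$downstream)[1], 6000)
  expect_equal(start(fl$promoter)[3], 1)     # truncated at the edge
  expect_equal(end(fl$promoter)[3], 299)
  expect_equal(start(fl$gene_body), start(g))
})

test_that("methylation fractions count cytosines on both strands", {
  genome <- Biostrings::DNAStringSet(c(c1 = "CCCCCGGGGGAAAAATTTTT"))
  region <- GRanges("c1", IRanges(1, 20))
  # 5 C + 5 G = 10 cytosine positions; methylate 2 of them
  calls <- data.frame(chrom = "c1", pos = c(1, 6, 11),
                      methylated = c(TRUE, TRUE, FALSE))
  m <- methylation_fraction(region, genome, calls)
  expect_equal(m$total_c, 10)
  expect_equal(m$methylated_c, 2)
  expect_equal(m$fraction, 0.2)
  # zero cytosines -> missing, not zero
  m0 <- methylation_fraction(GRanges("c1", IRanges(11, 20)), genome, calls)
  expect_true(is.na(m0$fraction))
  # planted-target region in the generator hits its Bernoulli rate
  ds <- shared_dataset()
  genes <- ds$annotations[ds$annotations$feature_type == "gene"]
  fl <- gene_flanks(genes, 1000, setNames(width(ds$genome),
                                          names(ds$genome)))
  tg <- ds$manifest$targets[1, ]
  idx <- which(fl[[tg$region_class]]$gene_id == tg$gene_id)
  mm <- methylation_fraction(fl[[tg$region_class]][idx], ds$genome,
                             ds$methylation)
  se <- sqrt(0.3 * 0.7 / mm$total_c)
  expect_lt(abs(mm$fraction - 0.30), 3 * se)
})

test_that("siren calling thresholds mean tissue FPKM at 10^2.25", {
  smp <- tiny_samples()
  counts <- matrix(c(1, 1, 40, 41,
                     1, 1, 20, 20,
                     1, 1, 45, 44), nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, smp$sample_id))
  loci <- GRanges("c1", IRanges(c(100, 600, 1100), width = 200))
  loci$locus_id <- c("La", "Lb", "Lc")
  loci$class <- c("siRNA21", "siRNA21", "siRNA24")
  x <- structure(list(loci = loci, counts = counts,
                      length_hist = matrix(0, 3, 0), samples = smp),
                 class = "srna_loci")
  # La endosperm mean FPKM = 40.5/0.2 = 202.5 > 177.8 -> siren
  # Lb mean 100 < 177.8; Lc is siRNA24, not in the 21 nt class
  expect_equal(call_sirens(x, "endosperm", 21), "La")
  expect_equal(call_sirens(x, "endosperm", 24), "Lc")
  expect_length(call_sirens(x, "root", 21), 0)
})

test_that("phasing is the max register fraction", {
  perfect <- phasing_fraction(c(0, 21, 42, 63), min_reads = 4)
  expect_equal(perfect$fraction, 1.0)
  expect_true(perfect$phased)
  half <- phasing_fraction(c(rep(0, 5), 1, 2, 3, 4, 5))
  expect_equal(half$fraction, 0.5)
  expect_true(half$phased)
  few <- phasing_fraction(1:5)
  expect_true(is.na(few$fraction))
  set.seed(12)
  unif <- phasing_fraction(sample(0:10000, 210, replace = TRUE))
  expect_lt(unif$fraction, 0.5)   # expected near 1/21
  expect_false(unif$phased)
})

test_that("chi-squared 2x2 matches the closed form", {
  res <- chi_square_2x2(matrix(c(10, 90, 20, 80), 2, byrow = TRUE))
  expect_equal(res$statistic, 3.9216, tolerance = 1e-4)
  expect_equal(res$p.value, 0.0477, tolerance = 1e-3)
  flat <- chi_square_2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(sample(1:100, 4, replace = TRUE), 2)
    expect_equal(chi_square_2x2(tab)$statistic, brute_chisq_2x2(tab),
                 tolerance = 1e-9)
  }
})

test_that("target prediction enforces all three conditions", {
  cfg <- analysis_config()
  g <- GRanges("c1", IRanges(5000, 5999), strand = "+")
  g$feature_id <- "g1"
  fl <- gene_flanks(g, 1000, c(c1 = 20000))
  s24 <- GRanges("c1", IRanges(4500, 4599))  # in the promoter
  s24$locus_id <- "locus_A"
  meth_at <- function(p) {
    lapply(fl, function(x) data.frame(total_c = 100,
                                      methylated_c = round(100 * p),
                                      fraction = p))
  }
  hit <- predict_targets(s24, fl, c(g1 = 1), meth_at(0.25), "embryo", cfg)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$region_class, "promoter")
  expect_equal(hit$locus_ids, "locus_A")
  # FPKM 5 > 2 -> rejected
  expect_equal(nrow(predict_targets(s24, fl, c(g1 = 5), meth_at(0.25),
                                    "embryo", cfg)), 0)
  # methylation 0.10 < embryo threshold 0.20 -> rejected
  expect_equal(nrow(predict_targets(s24, fl, c(g1 = 1), meth_at(0.10),
                                    "embryo", cfg)), 0)
  # 0.15 passes the endosperm threshold (0.12) but not embryo's
  expect_equal(nrow(predict_targets(s24, fl, c(g1 = 1), meth_at(0.15),
                                    "endosperm", cfg)), 1)
  expect_equal(nrow(predict_targets(s24, fl, c(g1 = 1), meth_at(0.15),
                                    "embryo", cfg)), 0)
})

test_that("sirens sit in gene bodies more than other siRNA21 loci", {
  ds <- shared_dataset()
  loci <- classify_loci(cluster_reads(ds$reads, ds$samples))
  sirens <- call_sirens(loci, "endosperm", 21)
  s21 <- loci$loci[loci$loci$class == "siRNA21"]
  genes <- ds$annotations[ds$annotations$feature_type == "gene"]
  in_body <- overlapsAny(s21, genes, ignore.strand = TRUE)
  is_siren <- s21$locus_id %in% sirens
  expect_gt(mean(in_body[is_siren]), mean(in_body[!is_siren]))
  tab <- rbind(c(sum(in_body & is_siren), sum(!in_body & is_siren)),
               c(sum(in_body & !is_siren), sum(!in_body & !is_siren)))
  expect_lt(chi_square_2x2(tab)$p.value, 0.05)
})

test_that("the pipeline recovers planted targets and reports stage errors", {
  ds <- shared_dataset()
  d_in <- withr::local_tempdir()
  d_out <- withr::local_tempdir()
  write_dataset(ds, d_in)
  res <- run_seed_pipeline(d_in, d_out, tissue = "endosperm")
  expect_setequal(res$targets$gene_id, ds$manifest$targets$gene_id)
  got <- res$targets[, c("gene_id", "region_class")]
  want <- ds$manifest$targets[, c("gene_id", "region_class")]
  expect_setequal(paste(got$gene_id, got$region_class),
                  paste(want$gene_id, want$region_class))
  expect_true(all(file.exists(file.path(
    d_out, c("loci.gff3", "fpkm.tsv", "expressed.tsv", "sirens.tsv",
             "targets.tsv", "run_log.txt")))))
  # a missing input names the failing stage
  file.remove(file.path(d_in, "methylation.tsv"))
  expect_error(run_seed_pipeline(d_in, withr::local_tempdir()),
               "load_inputs")
})
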