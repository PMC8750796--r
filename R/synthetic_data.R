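# Synthetic toy dataset with planted ground truth.
#
# The generator builds a random genome, places non-overlapping tRNA, TE
# and protein-coding gene annotations, then plants reads with known
# truth: background sRNA clusters with 21/24 nt length modes and
# 5'-nucleotide biases (A for 24 nt, U/T for 20-22 nt), tsRNA reads of
# each class, endosperm-restricted siren loci, TE-enriched siRNA24
# clusters and silenced/hypermethylated siRNA24 target genes (plus two
# decoy genes that each fail exactly one target condition).
#
# So that planted tRF-3/3tiR reads -- whose sequences end in the
# post-transcriptional CCA -- are still genuine ungapped genomic
# alignments, the generator writes a literal CCA into the genome
# immediately 3' of every tRNA span (strand-aware). The mature(+CCA)
# reference then coincides with genomic sequence, without touching the
# reference-construction or matching logic.

#' Simulate tsRNA reads of one class from a tRNA reference
#'
#' Lengths are drawn uniformly from the class window (14-30 nt for tRF
#' classes, 31-40 nt for tiR classes) and positions satisfy the class
#' rule exactly: tRF-5/5tiR start at mature base 1, tRF-3/3tiR end at
#' the final mature(+CCA) base, tRF-1 lies entirely within the 40 nt
#' trailer. Reads are mapped back to genomic coordinates (strand-aware)
#' and carry the transcript-orientation sequence.
#'
#' @param ref one row of [build_trna_reference()] output (needs the
#'   genomic `chrom`/`start`/`end`/`strand` columns).
#' @param class one of tRF-5, tRF-3, tRF-1, 5tiR, 3tiR.
#' @param n number of reads.
#' @param seed optional seed.
#' @param sample_id sample label(s), recycled over reads.
#' @param read_prefix prefix for read ids.
#' @return `GRanges` of reads ([aligned_reads()]).
#' @export
simulate_tsrna_reads <- function(ref, class, n, seed = NULL,
                                 sample_id = "s1", read_prefix = "ts") {
  if (!class %in% TSRNA_CLASSES) {
    stopf("simulate_tsrna_reads: unknown tsRNA class '%s'", class)
  }
  with_seed(seed, {
    lens <- switch(class,
                   "tRF-5" = , "tRF-3" = , "tRF-1" =
                     sample(14:30, n, replace = TRUE),
                   "5tiR" = , "3tiR" = sample(31:40, n, replace = TRUE))
    s <- ref$start; e <- ref$end
    plus <- ref$strand == "+"
    if (class %in% c("tRF-5", "5tiR")) {
      gs <- if (plus) rep(s, n) else e - lens + 1L
      ge <- if (plus) s + lens - 1L else rep(e, n)
    } else if (class %in% c("tRF-3", "3tiR")) {
      # final mature base is the planted genomic CCA, 3 nt past the span
      gs <- if (plus) e + 3L - lens + 1L else rep(s - 3L, n)
      ge <- if (plus) rep(e + 3L, n) else s - 3L + lens - 1L
    } else { # tRF-1: trailer position p in 1..(40 - len + 1)
      p <- vapply(lens, function(l) sample.int(40L - l + 1L, 1), integer(1))
      gs <- if (plus) e + p else s - p - lens + 1L
      ge <- if (plus) e + p + lens - 1L else s - p
    }
    strand_lab <- if (plus) "+" else "-"
    iv <- GRanges(ref$chrom, IRanges(gs, ge), strand = strand_lab)
    seqs <- extract_sequence(attr(ref, "genome") %||%
                               stop("simulate_tsrna_reads: ref must carry a 'genome' attribute"),
                             iv)
    aligned_reads(sprintf("%s_%s_%03d", read_prefix, gsub("-", "", class),
                          seq_len(n)),
                  seqs, ref$chrom, gs, ge, strand_lab,
                  rep_len(sample_id, n))
  })
}

# ---------------------------------------------------------------------
# feature placement: sequential slots with random gaps, hard error when
# the chromosome cannot hold everything.
place_on_chrom <- function(chrom_len, widths, pads) {
  n <- length(widths)
  if (n == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  need <- sum(widths + 2 * pads)
  slack <- chrom_len - need
  if (slack < 0) {
    stopf("generate_dataset: infeasible placement (%d nt needed, %d available)",
          need, chrom_len)
  }
  u <- runif(n + 1)
  gaps <- floor(slack * u / sum(u))
  ord <- sample.int(n)  # interleave categories along the chromosome
  starts <- integer(n); cursor <- 1L
  for (k in seq_len(n)) {
    i <- ord[k]
    cursor <- cursor + gaps[k] + pads[i]
    starts[i] <- cursor
    cursor <- cursor + widths[i] + pads[i]
  }
  data.frame(start = starts, end = starts + widths - 1L)
}

# 5' nucleotide of a read at genomic (start,end,strand)
five_prime_base <- function(genome_chr, start, end, strand) {
  b <- substr(genome_chr, if (strand == "+") start else end,
              if (strand == "+") start else end)
  if (strand == "-") chartr("ACGT", "TGCA", b) else b
}

# Sample read intervals in a window with a 5'-nucleotide bias:
# 24 nt reads prefer a 5' A, 20-22 nt reads a 5' U(T), by rejection.
sample_biased_reads <- function(genome_chr, win_start, win_end, lens) {
  n <- length(lens)
  starts <- integer(n); strands <- character(n)
  for (i in seq_len(n)) {
    l <- lens[i]
    target <- if (l == 24) "A" else if (l >= 20 && l <= 22) "T" else NA
    for (try in 1:20) {
      st <- sample(win_start:(win_end - l + 1L), 1)
      sd <- sample(c("+", "-"), 1)
      if (is.na(target)) break
      b <- five_prime_base(genome_chr, st, st + l - 1L, sd)
      if (b == target || runif(1) < 0.25) break
    }
    starts[i] <- st; strands[i] <- sd
  }
  data.frame(start = starts, end = starts + lens - 1L, strand = strands)
}

bg_length_mixture <- function(type, n) {
  switch(type,
         siRNA24 = sample(c(24, 23, 22, 21, 20, 25:33), n, replace = TRUE,
                          prob = c(.75, .08, .05, .04, .03,
                                   rep(.05 / 9, 9))),
         siRNA21 = sample(c(21, 20, 22, 23, 24, 25:33), n, replace = TRUE,
                          prob = c(.75, .07, .08, .03, .02,
                                   rep(.05 / 9, 9))),
         OtherRNA = sample(c(20:24, 25:40), n, replace = TRUE,
                           prob = c(rep(.3 / 5, 5), rep(.7 / 16, 16))))
}

#' Generate the full synthetic dataset
#'
#' Deterministic given the configuration (including its seed). See
#' [synth_config()] for the knobs and the module notes above for what
#' is planted.
#'
#' @param config [synth_config()].
#' @return list of class `synth_dataset` with elements `genome`
#'   (`DNAStringSet`), `annotations` (`GRanges`), `samples`
#'   ([sample_table()]), `reads` (`GRanges`), `methylation`
#'   (per-cytosine call data.frame), `mrna_fpkm` (gene x tissue
#'   matrix), `manifest` (planted-truth lists) and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_chr <- cfg$n_chromosomes
  chr_names <- sprintf("chr%d", seq_len(n_chr))
  genome_chr <- vapply(seq_len(n_chr), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(genome_chr) <- chr_names

  # -- place annotation slots ------------------------------------------
  trna_w <- 72L
  te_w <- 500L
  gene_w <- 1000L
  win_w <- 200L
  n_te <- cfg$n_te_per_family * length(TE_FAMILIES)
  cat_tab <- data.frame(
    cat = c("trna", "te", "gene", "bg", "s24"),
    n = c(cfg$n_trna, n_te, cfg$n_genes, cfg$background_clusters,
          cfg$n_sirna24_loci),
    width = c(trna_w, te_w, gene_w, win_w, win_w),
    pad = c(50L, 60L, 1050L, 50L, 50L))
  items <- data.frame(cat = rep(cat_tab$cat, cat_tab$n),
                      width = rep(cat_tab$width, cat_tab$n),
                      pad = rep(cat_tab$pad, cat_tab$n))
  items$chrom <- chr_names[rep_len(seq_len(n_chr), nrow(items))]
  placed <- do.call(rbind, lapply(chr_names, function(ch) {
    sub <- items[items$chrom == ch, , drop = FALSE]
    pos <- place_on_chrom(cfg$chrom_length, sub$width, sub$pad)
    cbind(sub, pos)
  }))

  take <- function(cat) placed[placed$cat == cat, , drop = FALSE]
  trna <- take("trna"); te <- take("te"); gene <- take("gene")
  bg <- take("bg"); s24 <- take("s24")

  # -- annotations ------------------------------------------------------
  trna_strand <- rep_len(c("+", "-"), nrow(trna))
  # plant the genomic CCA directly 3' of each tRNA span (strand-aware)
  for (i in seq_len(nrow(trna))) {
    ch <- trna$chrom[i]
    if (trna_strand[i] == "+") {
      substr(genome_chr[ch], trna$end[i] + 1L, trna$end[i] + 3L) <- "CCA"
    } else {
      substr(genome_chr[ch], trna$start[i] - 3L, trna$start[i] - 1L) <- "TGG"
    }
  }
  genome <- DNAStringSet(genome_chr)

  ann <- c(
    GRanges(trna$chrom, IRanges(trna$start, trna$end), strand = trna_strand,
            feature_id = sprintf("trna_%02d", seq_len(nrow(trna))),
            feature_type = "tRNA", te_family = NA_character_),
    GRanges(te$chrom, IRanges(te$start, te$end), strand = "+",
            feature_id = sprintf("te_%02d", seq_len(nrow(te))),
            feature_type = "TE",
            te_family = rep_len(TE_FAMILIES, nrow(te))),
    GRanges(gene$chrom, IRanges(gene$start, gene$end),
            strand = rep_len(c("+", "-"), nrow(gene)),
            feature_id = sprintf("gene_%02d", seq_len(nrow(gene))),
            feature_type = "gene", te_family = NA_character_))
  seqlevels(ann) <- chr_names
  seqlengths(ann) <- setNames(rep(cfg$chrom_length, n_chr), chr_names)

  samples <- sample_table(
    sample_id = as.vector(t(outer(cfg$tissues, seq_len(cfg$n_replicates),
                                  function(t, r) sprintf("%s_r%d", t, r)))),
    tissue = rep(cfg$tissues, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(cfg$tissues)),
    total_reads = cfg$library_size)
  endosperm <- cfg$tissues[length(cfg$tissues)]
  endo_samples <- samples$sample_id[samples$tissue == endosperm]

  reads_list <- list()
  emit <- function(df) reads_list[[length(reads_list) + 1]] <<- df
  read_counter <- 0L
  new_ids <- function(n, prefix = "read") {
    ids <- sprintf("%s_%07d", prefix, read_counter + seq_len(n))
    read_counter <<- read_counter + n
    ids
  }
  emit_window_reads <- function(ch, ws, we, lens, sample_ids, prefix) {
    n <- length(lens)
    if (n == 0) return(invisible())
    iv <- sample_biased_reads(genome_chr[[ch]], ws, we, lens)
    emit(data.frame(read_id = new_ids(n, prefix),
                    chrom = ch, start = iv$start, end = iv$end,
                    strand = iv$strand, sample_id = sample_ids,
                    stringsAsFactors = FALSE))
  }

  # -- background clusters ---------------------------------------------
  bg_types <- sample(c("siRNA24", "siRNA21", "OtherRNA"),
                     nrow(bg), replace = TRUE, prob = c(.6, .25, .15))
  lambda_bg <- cfg$background_read_depth / max(1, nrow(bg))
  for (i in seq_len(nrow(bg))) {
    for (s in samples$sample_id) {
      k <- rpois(1, lambda_bg)
      emit_window_reads(bg$chrom[i], bg$start[i], bg$end[i],
                        bg_length_mixture(bg_types[i], k),
                        rep(s, k), "bg")
    }
  }

  # -- TE-enriched siRNA24 clusters ------------------------------------
  te_frac <- n_te * te_w / (n_chr * cfg$chrom_length)
  p_te <- min(0.95, cfg$te_enrichment_factor * te_frac)
  s24_in_te <- runif(nrow(s24)) < p_te
  s24_windows <- s24
  for (i in which(s24_in_te)) {
    j <- sample.int(nrow(te), 1)
    off <- sample.int(te_w - win_w, 1)
    s24_windows$chrom[i] <- te$chrom[j]
    s24_windows$start[i] <- te$start[j] + off
    s24_windows$end[i] <- s24_windows$start[i] + win_w - 1L
  }
  for (i in seq_len(nrow(s24_windows))) {
    for (s in samples$sample_id) {
      k <- rpois(1, 8)
      emit_window_reads(s24_windows$chrom[i], s24_windows$start[i],
                        s24_windows$end[i],
                        rep(24L, k), rep(s, k), "s24")
    }
  }

  # -- planted sirens (21 nt, endosperm only high) ----------------------
  n_siren <- cfg$planted_siren
  if (n_siren > nrow(gene) - cfg$planted_targets - 2) {
    stopf("generate_dataset: not enough genes to host sirens and targets")
  }
  siren_genes <- seq_len(n_siren)  # first genes host sirens
  siren_windows <- data.frame(
    chrom = gene$chrom[siren_genes],
    start = gene$start[siren_genes] + (gene_w - win_w) %/% 2L)
  siren_windows$end <- siren_windows$start + win_w - 1L
  count_endo <- max(1L, round(cfg$siren_fpkm_multiplier * 40 * (win_w / 1000) *
                                (cfg$library_size / 1e6) * 1.1))
  for (i in seq_len(n_siren)) {
    for (s in samples$sample_id) {
      k <- if (s %in% endo_samples) count_endo else rpois(1, 5)
      emit_window_reads(siren_windows$chrom[i], siren_windows$start[i],
                        siren_windows$end[i],
                        rep(21L, k), rep(s, k), "siren")
    }
  }

  # -- planted targets and decoys --------------------------------------
  region_cycle <- c("promoter", "gene_body", "downstream")
  n_tg <- cfg$planted_targets
  target_genes <- n_siren + seq_len(n_tg)
  decoy_genes <- n_siren + n_tg + 1:2
  target_region <- rep_len(region_cycle, n_tg)
  gene_strand <- rep_len(c("+", "-"), nrow(gene))
  region_window <- function(gi, rc) {
    gs <- gene$start[gi]; ge <- gene$end[gi]; st <- gene_strand[gi]
    span <- switch(rc,
                   promoter = if (st == "+") c(gs - 1000L, gs - 1L)
                              else c(ge + 1L, ge + 1000L),
                   gene_body = c(gs, ge),
                   downstream = if (st == "+") c(ge + 1L, ge + 1000L)
                                else c(gs - 1000L, gs - 1L))
    mid <- (span[1] + span[2]) %/% 2L
    c(mid - win_w %/% 2L, mid + win_w %/% 2L - 1L)
  }
  plant_target_cluster <- function(gi, rc) {
    w <- region_window(gi, rc)
    for (s in samples$sample_id) {
      k <- if (s %in% endo_samples) 10L else 1L
      emit_window_reads(gene$chrom[gi], w[1], w[2], rep(24L, k),
                        rep(s, k), "tgt")
    }
    w
  }
  target_truth <- data.frame(gene_id = sprintf("gene_%02d", target_genes),
                             region_class = target_region,
                             tissue = endosperm,
                             stringsAsFactors = FALSE)
  for (i in seq_len(n_tg)) {
    plant_target_cluster(target_genes[i], target_region[i])
  }
  # decoy 1: siRNA24 + methylation, but expressed (fails FPKM <= 2)
  # decoy 2: siRNA24 + silent gene, background methylation (fails quantile)
  plant_target_cluster(decoy_genes[1], "promoter")
  plant_target_cluster(decoy_genes[2], "promoter")

  # -- planted tsRNA reads ---------------------------------------------
  refs <- build_trna_reference(genome, ann[ann$feature_type == "tRNA"])
  ts_truth <- list()
  for (cl in names(cfg$planted_tsrna)) {
    n_cl <- cfg$planted_tsrna[[cl]]
    if (n_cl == 0) next
    per_ref <- tabulate(rep_len(seq_len(nrow(refs)), n_cl), nrow(refs))
    done <- 0L
    for (r in which(per_ref > 0)) {
      ref_row <- refs[r, , drop = FALSE]
      attr(ref_row, "genome") <- genome
      ids <- samples$sample_id[
        (done + seq_len(per_ref[r]) - 1L) %% nrow(samples) + 1L]
      rd <- simulate_tsrna_reads(ref_row, cl, per_ref[r],
                                 sample_id = ids,
                                 read_prefix = sprintf("ts%02d", r))
      rd$read_id <- paste0(rd$read_id, "_", done + seq_len(per_ref[r]))
      emit(data.frame(read_id = rd$read_id,
                      chrom = as.character(seqnames(rd)),
                      start = start(rd), end = end(rd),
                      strand = as.character(strand(rd)),
                      sample_id = rd$sample_id,
                      sequence = rd$sequence,
                      stringsAsFactors = FALSE))
      ts_truth[[length(ts_truth) + 1]] <-
        data.frame(read_id = rd$read_id, class = cl,
                   trna_id = refs$trna_id[r], stringsAsFactors = FALSE)
      done <- done + per_ref[r]
    }
  }

  # -- assemble reads ---------------------------------------------------
  rd <- do.call(rbind, lapply(reads_list, function(d) {
    if (is.null(d$sequence)) d$sequence <- NA_character_
    d[, c("read_id", "sequence", "chrom", "start", "end", "strand",
          "sample_id")]
  }))
  need_seq <- is.na(rd$sequence)
  if (any(need_seq)) {
    iv <- GRanges(rd$chrom[need_seq],
                  IRanges(rd$start[need_seq], rd$end[need_seq]),
                  strand = rd$strand[need_seq])
    rd$sequence[need_seq] <- extract_sequence(genome, iv)
  }
  reads <- aligned_reads(rd$read_id, rd$sequence, rd$chrom, rd$start,
                         rd$end, rd$strand, rd$sample_id, samples = samples)

  # -- methylation ------------------------------------------------------
  genes_gr <- ann[ann$feature_type == "gene"]
  flanks <- gene_flanks(genes_gr, flank_bp = 1000,
                        genome_sizes = seqlengths(ann))
  hot <- paste(target_truth$gene_id, target_truth$region_class)
  hot <- c(hot, paste(sprintf("gene_%02d", decoy_genes[1]), "promoter"))
  meth_rows <- list()
  for (rc in names(flanks)) {
    regions <- flanks[[rc]]
    seqs <- extract_sequence(genome, granges_unstranded(regions))
    for (i in seq_along(regions)) {
      chars <- strsplit(seqs[i], "")[[1]]
      is_c <- chars == "C"; is_g <- chars == "G"
      pos <- start(regions)[i] + which(is_c | is_g) - 1L
      strands <- ifelse(is_c[is_c | is_g], "+", "-")
      rate <- if (paste(regions$gene_id[i], rc) %in% hot) {
        cfg$methylation_target
      } else {
        cfg$methylation_background
      }
      meth_rows[[length(meth_rows) + 1]] <- data.frame(
        chrom = as.character(seqnames(regions))[i],
        pos = pos, strand = strands,
        methylated = runif(length(pos)) < rate,
        stringsAsFactors = FALSE)
    }
  }
  methylation <- do.call(rbind, meth_rows)
  methylation <- methylation[!duplicated(methylation[, c("chrom", "pos")]), ]
  methylation <- methylation[order(methylation$chrom, methylation$pos), ]
  rownames(methylation) <- NULL

  # -- mRNA expression --------------------------------------------------
  gene_ids <- genes_gr$feature_id
  base <- sample(c(0, 1, 5, 50), length(gene_ids), replace = TRUE,
                 prob = c(.2, .2, .3, .3))
  mrna <- matrix(rep(base, length(cfg$tissues)), ncol = length(cfg$tissues),
                 dimnames = list(gene_ids, cfg$tissues))
  noise <- matrix(exp(rnorm(length(mrna), 0, 0.2)), nrow = nrow(mrna))
  mrna <- mrna * noise
  mrna[sprintf("gene_%02d", target_genes), endosperm] <- 0.5
  mrna[sprintf("gene_%02d", decoy_genes[1]), endosperm] <- 8  # expressed
  mrna[sprintf("gene_%02d", decoy_genes[2]), endosperm] <- 0  # silent

  manifest <- list(
    tsrna = if (length(ts_truth)) do.call(rbind, ts_truth) else
      data.frame(read_id = character(0), class = character(0),
                 trna_id = character(0)),
    sirens = data.frame(siren_id = sprintf("siren_%02d", seq_len(n_siren)),
                        chrom = siren_windows$chrom,
                        start = siren_windows$start,
                        end = siren_windows$end,
                        stringsAsFactors = FALSE),
    te_sirna24 = data.frame(
      cluster_id = sprintf("s24_%02d", seq_len(nrow(s24_windows))),
      chrom = s24_windows$chrom, start = s24_windows$start,
      end = s24_windows$end, in_te = s24_in_te,
      stringsAsFactors = FALSE),
    targets = target_truth,
    decoys = data.frame(gene_id = sprintf("gene_%02d", decoy_genes),
                        region_class = "promoter",
                        mode = c("expressed", "unmethylated"),
                        stringsAsFactors = FALSE))

  structure(list(genome = genome, annotations = ann, samples = samples,
                 reads = reads, methylation = methylation,
                 mrna_fpkm = mrna, manifest = manifest, config = cfg),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "synth_dataset: %d chromosomes, %d features, %d reads in %d samples\n",
    length(x$genome), length(x$annotations), length(x$reads),
    nrow(x$samples)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits only plain-text formats: genome FASTA, annotation GFF3, read
#' alignment TSV, sample/methylation/mRNA TSVs and the ground-truth
#' manifest as JSON. Byte-identical across runs for identical datasets.
#'
#' @param dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeXStringSet(dataset$genome, file.path(dir, "genome.fa"))
  write_features_gff3(dataset$annotations, file.path(dir, "annotations.gff3"))
  write_tsv(dataset$samples, file.path(dir, "samples.tsv"))
  write_read_alignments(dataset$reads, file.path(dir, "reads.tsv"))
  write_tsv(dataset$methylation, file.path(dir, "methylation.tsv"))
  mr <- data.frame(gene_id = rownames(dataset$mrna_fpkm),
                   dataset$mrna_fpkm, check.names = FALSE)
  write_tsv(mr, file.path(dir, "mrna_fpkm.tsv"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a synthetic dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @return list mirroring [generate_dataset()] output (minus `config`).
#' @export
read_dataset <- function(dir) {
  ds <- read_dataset_inputs(dir)
  ds$manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                     simplifyVector = TRUE)
  ds
}
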