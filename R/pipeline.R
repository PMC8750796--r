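# End-to-end orchestration of the seed-focused analysis and the
# command-line entry point.

#' Run the seed analysis pipeline on a dataset directory
#'
#' Executes, in order: read clustering and the coverage floor -> locus
#' classification (80% DicerCall rule) -> FPKM quantification ->
#' per-tissue expressed calls -> siren calling in the focal tissue ->
#' gene flank construction and region methylation -> siRNA24 target
#' prediction. All outputs are plain text and byte-deterministic, so
#' re-running on the same inputs reproduces the output tree exactly.
#'
#' @param input_dir dataset directory as written by [write_dataset()]
#'   (genome.fa, annotations.gff3, samples.tsv, reads.tsv,
#'   methylation.tsv, mrna_fpkm.tsv).
#' @param out_dir output directory.
#' @param tissue focal seed tissue (default endosperm).
#' @param config [analysis_config()].
#' @param siren_class siRNA length class used for siren calling.
#' @return invisible list with the main intermediate objects
#'   (`loci`, `fpkm`, `expressed`, `sirens`, `targets`).
#' @export
run_seed_pipeline <- function(input_dir, out_dir, tissue = "endosperm",
                              config = analysis_config(),
                              siren_class = 21) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  ds <- stage("load_inputs", {
    for (f in c("genome.fa", "annotations.gff3", "samples.tsv",
                "reads.tsv", "methylation.tsv", "mrna_fpkm.tsv")) {
      if (!file.exists(file.path(input_dir, f))) {
        stopf("missing input file '%s'", f)
      }
    }
    read_dataset_inputs(input_dir)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  loci <- stage("cluster_reads",
                cluster_reads(ds$reads, ds$samples, config))
  loci <- stage("classify_loci", classify_loci(loci, config))
  fpkm <- stage("compute_fpkm", loci_fpkm(loci))
  expressed <- stage("call_expressed",
                     call_expressed(fpkm, ds$samples, config))
  sirens <- stage("call_sirens",
                  call_sirens(loci, tissue, siren_class, config))

  genes <- ds$annotations[ds$annotations$feature_type == "gene"]
  flanks <- stage("gene_flanks",
                  gene_flanks(genes, config$flank_bp,
                              setNames(width(ds$genome), names(ds$genome))))
  meth <- stage("methylation_fraction",
                lapply(flanks, methylation_fraction, genome = ds$genome,
                       calls = ds$methylation))
  s24 <- loci$loci[loci$loci$class == "siRNA24" &
                     loci$loci$locus_id %in% expressed[[tissue]]]
  gene_expr <- setNames(ds$mrna_fpkm[, tissue], rownames(ds$mrna_fpkm))
  targets <- stage("predict_targets",
                   predict_targets(s24, flanks, gene_expr, meth, tissue,
                                   config))

  # -- outputs ----------------------------------------------------------
  write_locus_gff3(loci$loci, file.path(out_dir, "loci.gff3"))
  write_tsv(data.frame(locus_id = loci$loci$locus_id,
                       round(fpkm, 6), check.names = FALSE),
            file.path(out_dir, "fpkm.tsv"))
  expr_df <- do.call(rbind, lapply(names(expressed), function(tt) {
    if (length(expressed[[tt]]) == 0) return(NULL)
    data.frame(tissue = tt, locus_id = expressed[[tt]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(expr_df %||% data.frame(tissue = character(0),
                                    locus_id = character(0)),
            file.path(out_dir, "expressed.tsv"))
  write_tsv(data.frame(siren_id = sirens), file.path(out_dir, "sirens.tsv"))
  write_tsv(targets, file.path(out_dir, "targets.tsv"))
  cfg_flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                     character(1))
  writeLines(c("srnaland seed pipeline run",
               sprintf("tissue: %s", tissue),
               sprintf("siren_class: %d", siren_class),
               sprintf("%s: %s", names(cfg_flat), cfg_flat)),
             file.path(out_dir, "run_log.txt"))
  invisible(list(loci = loci, fpkm = fpkm, expressed = expressed,
                 sirens = sirens, targets = targets))
}

# Input loading shared by run_seed_pipeline and read_dataset.
read_dataset_inputs <- function(dir) {
  genome <- readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  samples <- read.delim(file.path(dir, "samples.tsv"),
                        stringsAsFactors = FALSE)
  ann <- parse_features(file.path(dir, "annotations.gff3"), "gff3",
                        seqlengths = setNames(width(genome), names(genome)))
  reads <- load_read_alignments(file.path(dir, "reads.tsv"), samples)
  methylation <- read.delim(file.path(dir, "methylation.tsv"),
                            stringsAsFactors = FALSE)
  mr <- read.delim(file.path(dir, "mrna_fpkm.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  mrna <- as.matrix(mr[, -1, drop = FALSE])
  rownames(mrna) <- mr$gene_id
  list(genome = genome, annotations = ann, samples = samples,
       reads = reads, methylation = methylation, mrna_fpkm = mrna)
}

#' Command-line entry point
#'
#' Dispatcher behind the `srnaland` script (installed under
#' `exec/`). Subcommands: `simulate` (write a synthetic dataset),
#' `loci` (cluster + classify + FPKM), `tsrna` (reference build +
#' classification), `assoc` (siRNA24 vs TE permutation test), `siren`,
#' `targets` and `run-all` (the full seed pipeline).
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return exit status, invisibly.
#' @export
srnaland_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: srnaland <command> [options]",
    "commands:",
    "  simulate --out DIR [--seed N]        write a synthetic dataset",
    "  loci     --in DIR --out DIR          call/classify loci, FPKM",
    "  tsrna    --in DIR --out DIR          tsRNA identification",
    "  assoc    --in DIR --out DIR [--seed N] [--nperm N]",
    "  siren    --in DIR --out DIR [--tissue T]",
    "  targets  --in DIR --out DIR [--tissue T]",
    "  run-all  --in DIR --out DIR [--tissue T]",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  tissue <- opt("tissue", "endosperm")
  indir <- opt("in"); outdir <- opt("out")
  need_io <- function() {
    if (is.null(indir) || is.null(outdir)) {
      stopf("command '%s' needs --in and --out", cmd)
    }
  }
  switch(cmd,
    "simulate" = {
      if (is.null(outdir)) stopf("simulate needs --out")
      write_dataset(generate_dataset(synth_config(seed = seed)), outdir)
    },
    "loci" = {
      need_io()
      ds <- read_dataset_inputs(indir)
      loci <- classify_loci(cluster_reads(ds$reads, ds$samples))
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_locus_gff3(loci$loci, file.path(outdir, "loci.gff3"))
      write_tsv(data.frame(locus_id = loci$loci$locus_id,
                           round(loci_fpkm(loci), 6), check.names = FALSE),
                file.path(outdir, "fpkm.tsv"))
    },
    "tsrna" = {
      need_io()
      ds <- read_dataset_inputs(indir)
      refs <- build_trna_reference(
        ds$genome, ds$annotations[ds$annotations$feature_type == "tRNA"])
      hits <- classify_tsrna_read(ds$reads, refs)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(refs[, c("trna_id", "mature_seq", "primary_seq")],
                file.path(outdir, "trna_reference.tsv"))
      write_tsv(hits, file.path(outdir, "tsrna_hits.tsv"))
    },
    "assoc" = {
      need_io()
      ds <- read_dataset_inputs(indir)
      loci <- classify_loci(cluster_reads(ds$reads, ds$samples))
      sizes <- setNames(width(ds$genome), names(ds$genome))
      tab <- association_table(
        list(siRNA24 = loci$loci[loci$loci$class == "siRNA24"]),
        list(TE = ds$annotations[ds$annotations$feature_type == "TE"]),
        sizes, n = as.integer(opt("nperm", "1000")), seed = seed)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(tab, file.path(outdir, "association.tsv"))
    },
    "siren" = {
      need_io()
      ds <- read_dataset_inputs(indir)
      loci <- classify_loci(cluster_reads(ds$reads, ds$samples))
      sirens <- call_sirens(loci, tissue)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(data.frame(siren_id = sirens),
                file.path(outdir, "sirens.tsv"))
    },
    "targets" = ,
    "run-all" = {
      need_io()
      run_seed_pipeline(indir, outdir, tissue = tissue)
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
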