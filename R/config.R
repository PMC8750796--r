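#' Analysis configuration
#'
#' Bundles every numeric threshold used across the pipeline. Defaults
#' follow the standard small-RNA conventions for this kind of analysis:
#' an FPKM of 2 as the expressed cut-off (strict inequality, required in
#' every biological replicate), the 80% DicerCall fraction for 20-24 nt
#' locus classification, a 0.5 reads-per-million pooled coverage floor
#' for cluster calling, a 75 nt cluster merge gap, the `10^2.25` FPKM
#' siren threshold, 1 kb gene flanks, 1000 permutations for overlap
#' tests and tissue-specific upper-quantile methylation thresholds
#' (embryo 20%, endosperm 12%).
#'
#' @param fpkm_expressed FPKM above which a locus/gene counts as
#'   expressed (strict `>`).
#' @param dcl_fraction minimum fraction of 20-24 nt reads for a locus to
#'   be called Dicer-processed (siRNAx).
#' @param min_rpm pooled reads-per-million coverage floor for cluster
#'   calling.
#' @param cluster_merge_gap maximum gap (nt) between read intervals
#'   merged into one locus.
#' @param siren_log10_fpkm log10 FPKM threshold for siren calling.
#' @param flank_bp promoter/downstream flank width in bp.
#' @param n_permutations permutations for overlap testing.
#' @param methylation_quantile named vector of per-tissue methylation
#'   fraction thresholds for target calling.
#' @param tsrna_len_trf,tsrna_len_tir inclusive length windows (nt) for
#'   tRNA fragments and tRNA halves.
#' @param trailer_bp length of the 3' trailer of the primary tRNA
#'   transcript.
#' @param novel_min_samples number of samples with FPKM above
#'   `fpkm_expressed` required to keep a novel locus.
#' @param ncRNA_overlap_fraction fraction of a structural ncRNA feature
#'   that a candidate must cover for the candidate to be removed.
#' @param ncRNA_overlap_anchor whether the removal fraction is anchored
#'   to the annotated `"feature"` (default) or to the `"candidate"`.
#' @param known_locus_overlap_fraction overlap fraction (of the
#'   candidate) with a known sRNA locus that triggers removal; 1 means
#'   full containment.
#' @param phase phasing register period in nt.
#' @param phasing_min_reads minimum reads for a locus to enter phasing
#'   statistics.
#' @param phasing_register_threshold in-register fraction at or above
#'   which a locus is called phased.
#' @param trf3_anchor_cca logical; anchor tRF-3/3tiR to the final base
#'   of the mature tRNA including the post-transcriptional CCA (default)
#'   rather than the final genomic base.
#' @return A list of class `srna_config`.
#' @export
analysis_config <- function(fpkm_expressed = 2,
                            dcl_fraction = 0.8,
                            min_rpm = 0.5,
                            cluster_merge_gap = 75,
                            siren_log10_fpkm = 2.25,
                            flank_bp = 1000,
                            n_permutations = 1000,
                            methylation_quantile = c(embryo = 0.20,
                                                     endosperm = 0.12),
                            tsrna_len_trf = c(14L, 30L),
                            tsrna_len_tir = c(31L, 40L),
                            trailer_bp = 40,
                            novel_min_samples = 2,
                            ncRNA_overlap_fraction = 0.5,
                            ncRNA_overlap_anchor = c("feature", "candidate"),
                            known_locus_overlap_fraction = 1.0,
                            phase = 21,
                            phasing_min_reads = 10,
                            phasing_register_threshold = 0.5,
                            trf3_anchor_cca = TRUE) {
  ncRNA_overlap_anchor <- match.arg(ncRNA_overlap_anchor)
  cfg <- list(fpkm_expressed = fpkm_expressed,
              dcl_fraction = dcl_fraction,
              min_rpm = min_rpm,
              cluster_merge_gap = cluster_merge_gap,
              siren_log10_fpkm = siren_log10_fpkm,
              flank_bp = flank_bp,
              n_permutations = n_permutations,
              methylation_quantile = methylation_quantile,
              tsrna_len_trf = as.integer(tsrna_len_trf),
              tsrna_len_tir = as.integer(tsrna_len_tir),
              trailer_bp = trailer_bp,
              novel_min_samples = novel_min_samples,
              ncRNA_overlap_fraction = ncRNA_overlap_fraction,
              ncRNA_overlap_anchor = ncRNA_overlap_anchor,
              known_locus_overlap_fraction = known_locus_overlap_fraction,
              phase = phase,
              phasing_min_reads = phasing_min_reads,
              phasing_register_threshold = phasing_register_threshold,
              trf3_anchor_cca = trf3_anchor_cca)
  num <- c("fpkm_expressed", "dcl_fraction", "min_rpm", "cluster_merge_gap",
           "flank_bp", "n_permutations", "trailer_bp", "novel_min_samples")
  for (nm in num) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stopf("analysis_config: '%s' must be strictly positive", nm)
    }
  }
  frac <- c("dcl_fraction", "ncRNA_overlap_fraction",
            "known_locus_overlap_fraction", "phasing_register_threshold")
  for (nm in frac) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] > 1) {
      stopf("analysis_config: '%s' must lie in (0, 1]", nm)
    }
  }
  structure(cfg, class = "srna_config")
}

#' Synthetic dataset configuration
#'
#' Describes the toy world that [generate_dataset()] builds: a small
#' multi-chromosome genome with non-overlapping tRNA, TE and
#' protein-coding gene annotations; six tissues with three biological
#' replicates each; background read clusters whose length mixture has
#' modes at 21 and 24 nt; and planted features with known truth --
#' tsRNA reads of each class, endosperm-restricted high-expression siren
#' loci, TE-enriched 24 nt siRNA clusters and silenced, hypermethylated
#' siRNA24 target genes.
#'
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration including this seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_trna number of nuclear tRNA genes.
#' @param n_te_per_family TE count for each of the five families
#'   (DTM, RSU, RLC, RLG, RLX).
#' @param n_genes number of protein-coding genes.
#' @param tissues tissue labels; the last one is treated as the seed
#'   endosperm for siren planting.
#' @param n_replicates biological replicates per tissue.
#' @param background_clusters number of background sRNA read clusters.
#' @param background_read_depth background reads per sample.
#' @param n_sirna24_loci number of dedicated siRNA24 clusters subject to
#'   TE enrichment.
#' @param te_enrichment_factor multiple of the genomic TE fraction used
#'   as the probability that an siRNA24 cluster is placed inside a TE.
#' @param planted_siren number of siren loci planted in endosperm.
#' @param siren_fpkm_multiplier endosperm expression of planted sirens,
#'   as a multiple of a typical expressed-locus FPKM of 40; at the
#'   default 10 the planted sirens sit far above the `10^2.25` call
#'   threshold.
#' @param planted_tsrna named integer vector of planted read counts per
#'   tsRNA class.
#' @param planted_targets number of planted silenced/methylated siRNA24
#'   target genes (cycled over region classes promoter/gene body/
#'   downstream, all in the endosperm).
#' @param methylation_background,methylation_target per-cytosine
#'   Bernoulli methylation rates outside/inside planted target regions.
#' @param library_size nominal total mapped reads per sample used for
#'   FPKM normalization.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_chromosomes = 2L,
                         chrom_length = 100000L,
                         n_trna = 8L,
                         n_te_per_family = 4L,
                         n_genes = 20L,
                         tissues = c("veg_root", "veg_shoot", "gen_root",
                                     "gen_shoot", "embryo", "endosperm"),
                         n_replicates = 3L,
                         background_clusters = 30L,
                         background_read_depth = 600L,
                         n_sirna24_loci = 40L,
                         te_enrichment_factor = 5,
                         planted_siren = 5L,
                         siren_fpkm_multiplier = 10,
                         planted_tsrna = c(`tRF-5` = 20L, `tRF-3` = 20L,
                                           `tRF-1` = 20L, `5tiR` = 20L,
                                           `3tiR` = 20L),
                         planted_targets = 6L,
                         methylation_background = 0.05,
                         methylation_target = 0.30,
                         library_size = 1e6) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "chrom_length", "n_trna", "n_te_per_family",
              "n_genes", "n_replicates", "background_clusters",
              "background_read_depth", "n_sirna24_loci", "planted_siren",
              "planted_targets")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || any(cfg[[nm]] < 0)) {
      stopf("synth_config: '%s' must be a non-negative count", nm)
    }
  }
  if (any(planted_tsrna < 0)) stopf("synth_config: planted_tsrna must be >= 0")
  bad <- setdiff(names(planted_tsrna), TSRNA_CLASSES)
  if (length(bad)) stopf("synth_config: unknown tsRNA class '%s'", bad[1])
  structure(cfg, class = "synth_config")
}

TSRNA_CLASSES <- c("tRF-5", "tRF-3", "tRF-1", "5tiR", "3tiR")
TE_FAMILIES <- c("DTM", "RSU", "RLC", "RLG", "RLX")
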