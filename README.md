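# srnaland

Small RNA landscape analysis for plant genomes: sRNA locus calling and
classification, tRNA-derived small RNA (tsRNA) identification,
permutation-based region association, siren detection in endosperm, and
RdDM-style siRNA24 target-gene prediction — plus a synthetic-data
generator with a planted ground-truth manifest so the whole pipeline is
testable without any external data.

## Who it is for

Plant small-RNA researchers who have genome-aligned sRNA-seq reads from
multiple tissues/replicates and want the classic seed-tissue analysis
chain as tested, reusable R functions rather than a pile of one-off
scripts: which genomic clusters produce Dicer-processed siRNAs, which
tRNA fragments are present, which loci associate with transposable
elements, which endosperm loci are sirens and which protein-coding
genes look like 24 nt siRNA methylation targets.

## The models and statistics at the core

- **Locus classification (DicerCall rule).** Reads within 75 nt of each
  other merge into a locus (pooled coverage floor 0.5 reads per million
  mapped). For a locus with read-length histogram *h*, if
  Σ<sub>l=20..24</sub> h(l) / Σ h(l) ≥ 0.8 the locus is `siRNAx` with
  x = argmax h(l) over 20–24 nt (ties toward the longer length);
  otherwise `OtherRNA`. FPKM = count / (kb × library size in millions);
  a locus is *expressed* in a tissue iff FPKM > 2 in every replicate.
- **tsRNA classification.** Two references per tRNA: mature (genomic
  span + 3′ `CCA`) and primary (span ± 40 nt). A 14–40 nt read must
  match a reference exactly over its full length; classes by position
  and length: `tRF-5`/`5tiR` start at mature base 1 (14–30 / 31–40 nt),
  `tRF-3`/`3tiR` end at the final mature(+CCA) base, `tRF-1` lies in
  the 40 nt 3′ trailer (14–30 nt). Abundance is the tRNA-derived
  fraction of 14–40 nt reads normalized to four stably expressed
  reference loci, reported as log2 fold change against a baseline
  tissue.
- **Region association.** The number of query regions overlapping a
  feature set by ≥ 1 bp is compared with a null built by re-placing the
  query uniformly at random (1000 permutations);
  z = (obs − μ₀)/σ₀, empirical p with plus-one correction, and a
  D'Agostino–Pearson normality gate on the null sample.
- **Sirens and targets.** A `siRNA21` locus is a siren when its mean
  endosperm FPKM exceeds 10^2.25 (≈ 177.8). A gene is a putative
  siRNA24 target in a region class (1 kb promoter / gene body / 1 kb
  downstream) when an expressed siRNA24 locus overlaps the region, the
  region's methylated-cytosine fraction reaches the tissue's
  upper-quantile threshold (embryo 20%, endosperm 12%) and the gene's
  FPKM ≤ 2. Phasing is the maximal fraction of read 5′ ends sharing one
  register modulo 21.

## Worked example

```r
library(srnaland)

ds <- generate_dataset(synth_config(seed = 1))
loci <- classify_loci(cluster_reads(ds$reads, ds$samples))
loci
#> srna_loci: 91 loci x 18 samples
#> OtherRNA  siRNA21  siRNA24
#>       13       13       65

sirens <- call_sirens(loci, "endosperm", 21)
sirens
#> [1] "locus_00015" "locus_00027" "locus_00032" "locus_00033" "locus_00041"

refs <- build_trna_reference(ds$genome,
          ds$annotations[ds$annotations$feature_type == "tRNA"])
table(classify_tsrna_read(ds$reads, refs)$ts_class)
#>  3tiR  5tiR tRF-1 tRF-3 tRF-5
#>    20    20    20    20    20

te <- ds$annotations[ds$annotations$feature_type == "TE"]
planted <- GenomicRanges::GRanges(ds$manifest$te_sirna24$chrom,
             IRanges::IRanges(ds$manifest$te_sirna24$start,
                              ds$manifest$te_sirna24$end))
query <- loci$loci[loci$loci$class == "siRNA24" &
                     IRanges::overlapsAny(loci$loci, planted,
                                          ignore.strand = TRUE)]
permutation_overlap_test(query, te,
  GenomeInfoDb::seqlengths(ds$annotations), n = 1000, seed = 1)
#> permutation overlap test (enrichment, n = 1000)
#>   observed = 9, null = 2.87 +/- 1.62, z = 3.78, p = 0.003996
#>   [null not ~normal: z unusable]
```

Reading the output: the generator planted five endosperm-restricted
high-expression 21 nt loci and `call_sirens` recovers exactly those
five (mean endosperm FPKM ≈ 440, well above the 10^2.25 ≈ 177.8 cut).
All 100 planted tsRNA reads come back with their intended class. The
dedicated siRNA24 clusters were placed inside transposable elements at
5× the genomic TE density; the permutation test sees 9 overlaps against
a null of 2.9 ± 1.6 (z = 3.8, p ≈ 0.004). The normality flag is off
because a near-zero overlap count null is right-skewed, so the z-score
should not be read as a calibrated normal deviate — the empirical p is
the honest quantity, exactly why the flag exists.

The full seed pipeline (cluster → classify → FPKM → expressed → sirens
→ methylation → targets) runs from a directory of plain-text inputs:

```r
write_dataset(ds, "ds")
res <- run_seed_pipeline("ds", "out", tissue = "endosperm")
res$targets[, c("gene_id", "region_class", "methylation", "fpkm")]
```

A command-line wrapper is installed under `exec/`:
`srnaland simulate --out ds --seed 1`, `srnaland run-all --in ds --out out`.

## Vignette

`vignettes/srnaland-methods.Rmd` documents the models, the thresholds
and their defaults, what the synthetic generator does and does not
emulate, and the numerical/design choices.
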