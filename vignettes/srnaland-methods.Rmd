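---
title: "srnaland: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnaland: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaland)
```

This vignette is the package's own account of its science: the models
and procedures it implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator emulates
(and deliberately does not), and the numerical and design choices made
where the method description left room. It states no empirical result
that the test suite does not itself compute.

## 1. The analysis chain

Plant genomes produce several distinct populations of small RNAs.
Dicer-like (DCL) enzymes cut precursors into 20–24 nt products —
miRNAs and, massively in plants, 24 nt heterochromatic siRNAs that
guide RNA-directed DNA methylation (RdDM) onto transposable elements
and gene flanks. Independently, tRNAs are cleaved into tRNA-derived
small RNAs (tsRNAs): 14–30 nt fragments (tRFs) and 31–40 nt halves
(tiRs), named by their position on the tRNA. In seeds, a third
phenomenon appears: *sirens*, a small number of loci whose expression
in endosperm is orders of magnitude above everything else. `srnaland`
implements the desk side of this biology: given genome-aligned reads,
annotations, methylation calls and mRNA expression, it calls and
classifies loci, identifies tsRNAs, tests region associations, calls
sirens, and predicts siRNA24 target genes.

## 2. Locus calling and the DicerCall rule

`cluster_reads()` merges reads whose intervals lie within
`cluster_merge_gap` (default **75 nt**, the documented cluster padding
of the standard ShortStack-style cluster callers — recorded here as a
plain config value, not a tool dependency) and discards clusters below
a pooled coverage floor of `min_rpm` (default **0.5 reads per million
mapped**, i.e. `ceiling(0.5 × total mapped / 10^6)` pooled reads; at a
typical 14 M-read experiment that floor is 7 reads).

`classify_locus()` applies the 80% rule: a locus is Dicer-processed
when at least `dcl_fraction` (default **0.8**) of its reads are
20–24 nt long, and is then labelled `siRNAx` by the modal length within
20–24 nt. The fraction boundary is inclusive (exactly 80% passes), and
modal-length ties break **toward the longer length**: the 24 nt class
dominates plant tissues, so the deterministic tie rule follows the
prior; it is documented rather than hidden in hash order.

Expression is FPKM (`count / (kb × millions mapped)`); "expressed"
means FPKM **strictly greater than 2 in every biological replicate**
of a tissue — note 2.0 itself fails. Novel-locus filtering removes
candidates that (i) cover ≥ 50% of an annotated rRNA/tRNA/snRNA/snoRNA
feature, (ii) are fully contained in a known sRNA locus, or (iii) lack
FPKM > 2 in at least 2 *samples* (samples, not tissues — a locus
expressed in two replicates of one tissue survives). The 50% fraction
is anchored to the annotated feature by default; the wording that
motivated it ("overlap with the gene") is ambiguous, so
`ncRNA_overlap_anchor = "candidate"` provides the other reading.
De novo miRNA calling needs hairpin evaluation and is out of scope;
loci contained in annotated miRNA loci are passed through as
`known_miRNA`.

## 3. tsRNA identification

`build_trna_reference()` makes two sequences per nuclear tRNA gene,
both strand-aware:

* **mature** — the annotated genomic span plus the post-transcriptional
  3′ `CCA` (not genome-encoded, added by nucleotidyl transferase);
* **primary** — the span extended 40 nt upstream and downstream
  (`trailer_bp`), without CCA. The last 40 nt are the 3′ trailer, the
  leftover of RNase Z processing that gives rise to tRF-1.

Intron-containing tRNAs are skipped with a warning; splicing is not
modelled.

`classify_tsrna_read()` requires an **exact, full-length** substring
match of the read in a reference — the same acceptance condition as a
short-read BLAST at 100% identity over the whole read, implemented as
anchored string comparison without the BLAST dependency. Position
rules: start at mature base 1 → `tRF-5` (14–30 nt) or `5tiR`
(31–40 nt); end at the final mature(+CCA) base → `tRF-3`/`3tiR`;
entirely inside the trailer and 14–30 nt → `tRF-1`. Exact matches with
no positional anchor (internal fragments) are discarded; 31–40 nt
trailer matches are discarded (tiR classes are defined on the mature
ends only). Two documented edge rules: a read carrying both anchors (a
near-intact tRNA) is classified by its 5′ anchor, and a read matching
several tRNAs is counted once, with all matching ids recorded.
Whether "the last base of the tRNA" includes the appended CCA is not
fixed by the method description; the default anchors to the final CCA
base (consistent with how the matching database is built), and
`trf3_anchor_cca = FALSE` switches to the final genomic base.

Relative abundance divides each sample's tRNA-derived fraction of
14–40 nt reads by the mean fraction falling in `k = 4` stable
reference loci, then takes log2 against the baseline tissue's replicate
mean. Reference loci are chosen as the lowest coefficient-of-variation
loci among those with FPKM > 2 everywhere — a deliberate stand-in for
the original likelihood-ratio "not differentially expressed" screen,
which would drag in a full DE framework for four ids.

## 4. Permutation region association

`permutation_overlap_test()` counts query regions overlapping ≥ 1
feature by ≥ 1 bp and rebuilds that count under `n = 1000` random
re-placements of the query (each region keeps its length, lands on a
chromosome with probability proportional to chromosome length among
those long enough, uniformly within bounds; strand is ignored; a
per-chromosome mode that preserves chromosome assignment is available
for sensitivity analysis). It reports `z = (obs − μ₀)/σ₀` and the
plus-one-corrected empirical p `(#{null ≥ obs}+1)/(n+1)` (mirrored for
depletion), which can never be exactly zero.

Because a z-score is only interpretable against a roughly normal null,
each result carries a `normality_ok` flag from a D'Agostino–Pearson
skewness/kurtosis omnibus test on the null sample at α = 0.05
(implemented in-package; no pre-installed R package provides it).
Overlap-count nulls near zero are right-skewed and fail the gate — the
empirical p remains valid and is the quantity to trust there. The flag
gates *reporting* of z, never the test itself. Nulls with fewer than
20 usable values or zero variance never pass; with zero variance z is
`NA` while the empirical p is still returned.

For speed the null is drawn fully vectorized (numeric starts scored
against merged feature intervals with a `findInterval` lookup), which
is distributionally identical to calling `randomize_regions()` n
times; `randomize_regions()` remains the exported, tested primitive.

## 5. Seed analysis: sirens, phasing, targets

* **Expression bins** for protein-coding genes: high (FPKM > 10),
  medium (2 < FPKM ≤ 10), low (0 < FPKM ≤ 2), none (FPKM = 0). The
  boundaries are inclusive exactly as printed — 10 is medium, 2 is low.
* **Sirens**: among loci of a chosen length class (21 nt for solid
  endosperm; 24 nt fits the milky-stage definition), a locus is a siren
  when its mean FPKM over the focal tissue's replicates exceeds
  `10^siren_log10_fpkm` with `siren_log10_fpkm = 2.25` (≈ 177.8).
* **Phasing**: no public definition exists for the phasing caller the
  percentages in this literature come from, so `phasing_fraction()` is
  an explicit operational stand-in: the maximum over the 21 offsets of
  the fraction of read 5′ ends congruent to that offset modulo 21,
  phased at ≥ 0.5 by default, loci under 10 reads excluded. Outputs are
  flagged implementation-defined; no literature percentage is asserted
  against it.
* **Methylation**: region methylation is methylated cytosines over all
  cytosines in the region, counting cytosines on *both* strands (a
  minus-strand cytosine is a G on the plus reference) and pooling
  CpG/CHG/CHH contexts into the single percentage the target filter
  uses. A region with zero cytosines yields `NA` — missing, never 0 —
  and is skipped with a warning downstream.
* **Targets**: gene × region class (1 kb promoter, gene body, 1 kb
  downstream; strand-aware, edge-truncated) is a putative siRNA24
  target when (i) a tissue-expressed siRNA24 locus overlaps the region
  by ≥ 1 bp, (ii) region methylation reaches the tissue threshold
  (fixed defaults embryo 0.20 / endosperm 0.12; "upper quantile" is
  read as upper quartile, and `quantile_mode = "computed"` recomputes
  the 75th percentile from the data), and (iii) the gene's FPKM in the
  tissue is ≤ 2 (the `<= 2` reading; a stray `< 2` phrasing in prose is
  treated as informal). The target set is provably monotone in both
  thresholds, and the tests assert it.

## 6. The synthetic world

`generate_dataset()` builds a deterministic function of its seed: a
2 × 100 kb uniform-random genome; 8 tRNAs (half minus-strand), 20 TEs
across the five families (DTM, RSU, RLC, RLG, RLX), 20 genes; 6 tissues
(vegetative/generative root and shoot, embryo, endosperm) × 3
biological replicates at a nominal library size of 10^6. Planted truth,
all recorded in a manifest:

* background clusters whose read-length mixture peaks at 21 and 24 nt,
  with a 5′ A bias for 24 nt reads and a 5′ U(T) bias for 20–22 nt
  reads (rejection sampling against the genome, so sequences stay
  genuine genomic substrings);
* 20 reads per tsRNA class, generated from the built references with
  class rules satisfied by construction. So that tRF-3/3tiR reads —
  which end in the non-genomic CCA — remain honest ungapped genomic
  alignments, the generator writes a literal `CCA` into the genome
  immediately 3′ of each tRNA span (strand-aware). The reference
  builder is unaware of this and appends CCA itself; the two coincide
  by construction. Real genomes are under no such obligation, which is
  precisely why real tRF-3 reads need transcript-space matching;
* 5 siren loci in gene-body centres: ~88 × 21 nt reads per endosperm
  replicate (mean FPKM ≈ 400–440, comfortably above 177.8 yet far from
  tuned to the boundary) and Poisson(5) reads elsewhere;
* 40 dedicated siRNA24 clusters, each placed inside a TE with
  probability `min(0.95, te_enrichment_factor × genomic TE fraction)` —
  at the default 5× and 5% TE content, a 25% placement rate against a
  5% null;
* 6 target genes (cycling promoter/gene body/downstream, all scored in
  endosperm): a planted expressed siRNA24 cluster in the region,
  per-cytosine Bernoulli methylation at 0.30 against a 0.05 background,
  gene FPKM 0.5; plus two decoy genes that fail exactly one condition
  each (one expressed at FPKM 8, one left at background methylation),
  so "recovered exactly" in the tests actually exercises the filters.

Feature placement reserves padding around every feature (1050 nt around
genes, covering their 1 kb flanks), so planted signals cannot bleed
into each other's loci and placement that does not fit is a hard error
rather than a silent overlap.

What the generator does **not** emulate: sequencing error, quality
scores, adapter remnants, multimapping ambiguity, realistic chromatin
context, intron-containing tRNAs, or biological correlation structure
beyond what is planted. A green test therefore establishes that the
implementations compute their definitions correctly and recover planted
truth under honest noise — not that the thresholds are biologically
optimal for any real dataset.

## 7. Numerical and interface choices

* Internal coordinates are 1-based closed via `GRanges` — the native
  convention of the interval stack used throughout; BED converts at the
  boundary, GFF3 maps 1:1. Unknown chromosomes in inputs are hard
  errors: silently dropped regions would corrupt permutation nulls.
* GFF3 output is written directly without a date stamp so that
  identical runs are byte-identical; parsing goes through rtracklayer
  behind a line-level validator that produces line-numbered errors.
* All randomness flows through seeds passed explicitly; library code
  saves and restores the caller's RNG state. `run_seed_pipeline()`
  writes no timestamps, making the whole output tree reproducible
  byte for byte.
* Kendall correlation delegates to `stats::cor.test` (tau-b, tie
  corrected, normal approximation under ties) and is checked against
  exhaustive pair counting in the tests; the 2×2 chi-squared is the
  plain Pearson statistic without continuity correction, df = 1,
  erroring on zero margins.
* Known limitations: the clustering is single-linkage by gap (no
  read-depth valleys), multimapping reads are assumed pre-resolved to
  one placement, the phasing caller is a stand-in, and miRNA discovery
  is annotation pass-through.
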