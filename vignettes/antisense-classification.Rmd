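---
title: "Classifying genes by their Rrp6-sensitive antisense RNAs: methods and design"
author: "asRNAclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying genes by their Rrp6-sensitive antisense RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In budding yeast, many protein-coding genes are overlapped by antisense
non-coding RNAs (asRNAs) that are degraded by the nuclear exosome and
become visible only when its 3'-5' exonuclease Rrp6 is deleted. For a
subset of genes this antisense transcription silences the sense gene
through chromatin: histone deacetylases (the Hda1 complex, Rpd3) and the
H3K4 methyl-transferase Set1 are required for the repression. The
question this package addresses genome-wide is: **which genes are
regulated by their Rrp6-sensitive asRNA, and through which chromatin
pathway?**

The experimental design the package models is strand-specific tiling
expression data (normalised log2 intensities) for five strains in
triplicate: wild type (WT), the exosome mutant (rrp6), and the three
double mutants set1 rrp6, hda2 rrp6, rpd3 rrp6.

## The classification procedure

For every annotated ORF, differential expression is computed for four
contrasts — rrp6 vs WT, and each double mutant vs rrp6 — in two
orientations:

* **sense**: the window TSS $-100..+750$ bp on the gene's own strand;
* **antisense**: the window TTS $-100..+750$ bp on the opposite strand.

Offsets are applied in transcript orientation (positive = direction of
sense transcription); each window is tiled with 20-bp bins, and per bin
the differential expression is the difference of mean-over-replicates
log2 signal (numerator minus denominator). The window length (850 bp) is
not a multiple of 20, so the final bin is truncated to 10 bp: 43 bins
per window, $4 \times 2 \times 43 = 344$ features per gene after
concatenation. Genes in convergent overlapping configuration — two genes
on opposite strands whose 3' ends face each other across a shared
interval — are excluded before feature construction, because sense and
antisense signal cannot be attributed to one gene there.

Genes are then clustered with **partitioning around medoids** (PAM,
$k = 15$, Euclidean distance on the concatenated log2 features). The
implementation is the classic BUILD phase (greedy cost-minimising medoid
addition, ties to the smallest row index) followed by an exact
steepest-descent SWAP phase: each iteration scores every
medoid/non-medoid exchange and applies the best strictly cost-decreasing
one. The swap deltas are accumulated in $O(n^2)$ per iteration from the
nearest- and second-nearest-medoid distances, which reproduces the naive
$O(k\,n^2)$ scan exactly; the cost trace is recorded and is
non-increasing by construction. The algorithm is fully deterministic,
which makes every clustering reproducible and testable. Note that
BUILD+SWAP is a local search: it stops at swap-local optima, which on
adversarial instances may differ from the global medoid optimum (the
reference implementation in the `cluster` package behaves identically).

**Robustness.** 120 additional clusterings are run — $k = 10..15$, 20
runs each — every run on a fresh uniform random subsample of 80% of the
genes (without replacement). For every gene pair the procedure counts
how often both were sampled and how often they were co-assigned; the
ratio is the pair's co-clustering frequency. A gene's score is the mean
frequency with its base-cluster mates (conditional on co-sampling), and
genes scoring at least 60% form the **core set** of their cluster.
The boundary is inclusive; singleton clusters are core by convention;
a gene never co-sampled with any mate is non-core (both cases are
reported). Run $r$ draws its subsample from a stream seeded from
(master seed, $r$), so the whole procedure replays exactly from one
seed.

**From clusters to classes.** Each cluster is summarised per (contrast,
orientation) by the median over member genes of the gene's mean over its
non-imputed bins. Classes are assigned by explicit rules on these
summaries, with a dead zone $\varepsilon$ (default 0.2 log2 units)
replacing a strict sign test — under probe noise a median is almost
never exactly zero, so a strict "above or below 0" rule would classify
every cluster. In rule order:

1. **Class IV** — all three double-mutant sense summaries above
   $\varepsilon$ while the antisense response in rrp6 vs WT stays at or
   below $\varepsilon$: genes repressed by the HDACs/HMT already in WT,
   without a strong Rrp6-sensitive asRNA. This rule fires first so that
   HDAC/HMT de-repression with weak antisense is not captured by the
   asRNA classes.
2. **Class I** — asRNA up and sense down in rrp6, sense de-repressed
   (above $\varepsilon$) in all three double mutants: asRNA-mediated
   silencing through Hda1/Rpd3/Set1.
3. **Class II** — asRNA up and sense down in rrp6, but all double-mutant
   sense summaries within $\pm\varepsilon$: silencing largely
   independent of these chromatin factors.
4. **Class III** — asRNA up in rrp6 with sense unchanged
   ($|S| \le \varepsilon$): non-functional (bystander) asRNA.
5. otherwise **unclassified**. Clusters whose antisense rises only in a
   double-mutant contrast but not in rrp6 vs WT fall through to
   unclassified by construction.

Gene-level labels are restricted to core genes; non-core genes are
unclassified. The whole procedure is exposed as one fitting function,
`asrna_classify()`, returning an `asrna_fit` object with print, summary,
plot and as.data.frame methods.

## Downstream characterisation

* **Metagene profiles** (`antisense_metagene()`): per class, the median
  across genes of the mean-replicate antisense signal in 10-bp bins
  aligned to the TSS or TTS, smoothed with a centered 150-bp moving
  average stepped one bin at a time. Edges use shrinking windows (the
  mean renormalises over available bins) so the smoothed curve stays
  aligned with its positions; windows with no data stay missing.
* **Nrd1/Nab3 motifs** (`count_motifs()`): occurrences of the Nab3
  consensus TCTT and the Nrd1 consensus GTA[AG] in the window TTS
  $-400..0$ on the antisense strand — the antisense transcript's 5'
  region, where early (NNS) termination signals act. Overlapping
  occurrences are counted (no exclusion rule exists that would justify
  skipping them); ambiguous bases never match; windows clipped at
  chromosome ends record their coverage.
* **PAR-CLiP binding** (`aggregate_binding()`): cross-link signal summed
  over the same window and divided by the *linear-scale* WT expression
  of the region ($2^{\text{mean log2}}$) — a ratio of a count to a log
  value would be dimensionally incoherent.
* **Group comparisons** (`compare_groups()`): Wilcoxon rank-sum,
  exact two-sided when the smaller group has at most 8 values and no
  ties, otherwise the normal approximation with tie and continuity
  correction.
* **Promoter structure** (`promoter_enrichment()`): per class 2x2
  Fisher's exact test (two-sided as the sum of tables with point
  probability at most the observed) against all other genes, with the
  sample odds ratio $(ad)/(bc)$ and a star at $p < 0.05$.
* **H3K4me3** (`window_score()`): chromatin marks are strandless, so the
  track is stored on a single key and read strand-agnostically, but
  windows (promoter TSS $-100..+300$; 3' end TTS $-300..0$) are still
  resolved through gene orientation.
* **ncRNA annotation** (`segment_track()`, `annotate_ncrnas()`):
  expressed segments in the exosome mutant (runs of probes at or above a
  threshold, gaps below `seg_max_gap` merged) are intersected with the
  known transcript catalog; same-strand overlaps are removed
  (strandedness is essential for antisense work), survivors shorter than
  200 bp dropped, and the rest labelled CUT when at least 2-fold up in
  the mutant (log2 ratio $\ge 1$), else SUT when detectable in WT at the
  segmentation threshold, else ncRNA-other. The segmenter here is
  deliberately simple plumbing — the package's contribution is the rule
  logic, not a segmentation algorithm.
* **Half-lives** (`half_life()`): $k$ is minus the OLS slope of
  $\ln(\text{level})$ against time for control-normalised abundances and
  $t_{1/2} = 0.693/k$. The coefficient 0.693 is kept as stated rather
  than replaced by $\ln 2$, so a series halving exactly every 10 minutes
  reports $t_{1/2} = 9.9979$ min, not 10. Slopes below $10^{-12}$ per
  minute are treated as zero (no decay, infinite half-life).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sense_window` / `antisense_window` | TSS/TTS $-100..+750$ | bp | DE feature windows |
| `de_bin` | 20 | bp | feature bin width |
| `k_main` | 15 | – | base clustering medoids |
| `k_range`, `runs_per_k` | 10..15, 20 | – | robustness runs (120 total) |
| `subsample_fraction` | 0.8 | – | genes per robustness run |
| `core_cutoff` | 0.60 | – | core-gene frequency threshold |
| `class_epsilon` | 0.2 | log2 | class-rule dead zone |
| `fold_threshold` | 2.0 | linear | CUT / silenced threshold |
| `min_ncrna_len` | 200 | bp | minimum ncRNA length |
| `motif_window` | TTS $-400..0$ | bp | motif/binding window |
| `profile_bin`, `smooth_window` | 10, 150 | bp | metagene binning/smoothing |
| `seg_min_level`, `seg_max_gap` | 6.0, 50 | log2, bp | segmentation |

All of these live in `asrna_config()` and in the pipeline YAML, because
class counts are sensitive to the under-specified choices ($\varepsilon$,
distances, tie-breaks); users can sweep them.

## The synthetic study

`generate_dataset()` builds a complete, self-contained study so that
every stage can be exercised without external data: a BED6 annotation
(~1970 genes in four planted classes plus an unaffected majority, and 50
convergent decoy pairs), a genome with motifs planted at Poisson-drawn
positions in the motif windows, stranded bedGraph-style tracks for all
five strains in triplicate (per-gene baseline $\sim N(8,1)$ log2 over a
background of 4, additive class effects, per-probe Gaussian noise of
0.3 log2, per-replicate offsets of 0.05), a PAR-CLiP track with
intensity proportional to each gene's motif count, an H3K4me3/H3 track
with promoter and 3' elevation, a promoter table (Class I: TATA and
closed promoter with probability 0.7, others 0.25) and a ground-truth
table. One seed makes the bundle byte-identical.

Planted effects are additive on the log2 scale and mirror the class
definitions: classes I–III gain +2.0 log2 antisense in the rrp6 strains,
classes I–II lose 1.5 log2 sense in rrp6, Class I (and IV) regain +1.0
sense in the double mutants, and classes II–III lose 1.2 log2 antisense
without Set1. **Geometry:** the spec's window arithmetic places the
antisense feature window mostly downstream of the ORF 3' end, while the
class-dependent antisense *extents* (Class I reaching beyond the TSS,
Class III short) are measured from the TTS into the gene body. Each
planted antisense unit therefore spans the feature window downstream of
the TTS *plus* the class-dependent fraction of the gene body — so the
classification features see the full effect and TSS/TTS-anchored
metagenes still show the class-specific extents. Class IV's weak
(+0.3 log2) Rrp6 response is confined to a short unit near the TTS,
matching its description as low, mostly Rrp6-insensitive antisense, and
keeping its window-mean antisense response inside the class-rule dead
zone.

What the generator does **not** emulate: probe-level hybridisation
chemistry, cross-hybridisation and array spatial artifacts; gene-length
and GC biases; correlated (non-Gaussian) noise; partially overlapping
transcription units beyond the planted convergent pairs; and any
realistic background transcription structure. Passing tests on this
bundle therefore demonstrate that the pipeline recovers the structure it
is designed to detect under idealised noise — not that real tiling
arrays would yield the published class sizes. The published counts
(28/69/469/76/2024) depend on the deposited dataset's normalisation and
on manual cluster grouping and are not reproducible from synthetic data;
the package reports its own counts instead.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; GFF3 is
  shifted on read, BED taken as-is. One convention removes off-by-one
  drift from the window arithmetic.
* Anchors of minus-strand genes: TSS = interval end, TTS = interval
  start (transcript-orientation semantics; anchors are boundary
  coordinates).
* Missing signal is an explicit `NA`, never 0: an empty bin must not
  masquerade as "no change". Genes missing more than 20% of feature
  bins are dropped (reported); remaining missing bins are imputed with
  0 only inside the feature matrix, and the imputation mask is kept so
  cluster summaries can ignore imputed cells.
* Replicates are averaged before differencing (mean-then-difference);
  with probe-level averaging the alternative order only commutes
  approximately, so one order is fixed and documented.
* Quartile splits order transcripts by (expression, id) — a stable
  total order — and cut at ranks $\lfloor n i/4 \rfloor$.
* The consensus score conditions on co-sampling: pairs never drawn
  together contribute nothing rather than zero.
* Windows beyond chromosome ends are clipped and the covered fraction
  recorded, rather than guessing an extrapolation.
* Problem sizes in the test-suite: the full default study (~1970 genes,
  344 features, 120 consensus runs) is fitted once; the remaining tests
  use reduced studies (~50-200 genes) and constructed fixtures, which
  exercise identical code paths.

## Known limitations

* The class rules formalise published class descriptions; borderline
  clusters near the dead zone may split differently from a manual
  grouping of median profiles.
* PAM BUILD+SWAP stops at swap-local optima (as does the reference
  implementation); no silhouette-based selection of $k$ is attempted.
* The segmenter is a thresholding plumbing step, not a structural-change
  model; absolute ncRNA counts depend strongly on its threshold.
* The PAR-CLiP track unit is treated as arbitrary non-negative counts.
* Exact Wilcoxon p-values are only used for small tie-free groups; the
  approximation is standard but approximate.
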