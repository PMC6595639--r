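---
title: "Methods: subtype-specific TF network inference from DNase footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-specific TF network inference from DNase footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Acute myeloid leukemia (AML) and similar cancers fall into mutation-defined
subtypes whose gene expression programs are driven by rewired transcription
factor (TF) networks. Those networks can be read out of chromatin: open
regulatory regions appear as DNase I hypersensitive sites (DHSs), and a TF
bound within a DHS protects a short stretch of DNA from DNase cleavage,
leaving a *digital footprint* — a local depletion of 5′ cut ends flanked by
strand-specific pile-ups. Combining footprinted motifs with expression data
and promoter-capture conformation links yields a directed graph: which TF
families regulate which genes, in which subtype.

`footgrn` implements this inference chain as composable, tibble-first
functions, and pairs it with a seeded synthetic-data generator that plants a
known regulatory landscape. Every stage can therefore be tested against
ground truth without access to patient data.

## Pipeline model and assumptions

The pipeline runs in the order:

1. **Atlas** (`call_peaks()`): all samples' stranded cut profiles are summed
   position-wise and peaks are called on the merged track. Merging before
   calling flattens background noise and gives one union peak set, so all
   samples are afterwards quantified on identical regions. The caller is
   deliberately simple and fully deterministic: 50-bp bins are kept when
   their merged count beats a Poisson background (genome-wide mean rate,
   `p < 1e-5`), bins closer than 200 bp merge, and the summit is the argmax
   of the 150-bp-smoothed density (ties to the leftmost base). All four
   constants are exposed as arguments.
2. **Quantification and normalization** (`quantify_peaks()`,
   `normalize_rank()`): each peak is measured as total cuts in a fixed
   400-bp window centred on the summit. Per-sample depth is removed by
   ranked-peak normalization: each sample is rescaled by the value of its
   r-th largest peak count, with `r = min(16000, floor(0.125 * n_peaks))`.
   On a cohort-scale atlas of ~10^5 peaks the anchor is the peak ranked
   16 000 — close to the median number of peaks an individual sample
   contributes — and the 0.125 fraction keeps that proportion on the small
   atlases the generator produces. The transform is idempotent and invariant
   to global per-sample rescaling.
3. **Clustering and subtype-specific DHSs** (`cluster_samples()`,
   `subtype_specific_dhs()`): samples cluster hierarchically on distal peaks
   with distance `1 − Pearson` of `log2(1 + signal)`, average linkage. A peak
   is subtype-specific when its mean signal in the subtype is ≥ 2× the mean
   over all other samples and it is present (signal > 1) in at least half
   the subtype's samples. The clustering transform and the fold/presence
   rule are design choices of this package; they are recorded in the
   pipeline manifest so runs are self-describing.
4. **Footprinting** (`detect_footprints()`): the occupancy statistic is a
   strand-aware binomial shoulder test. For a candidate interval of length
   `L` with shoulders of `S = 35` bp, the forward-strand test asks whether
   the forward cuts concentrate in the upstream shoulder beyond what a
   uniform split of the `f_sh + f_fp` cuts (shoulder probability
   `S/(S+L)`) would give: `p_fwd = P[X ≥ f_sh]`, `X ~ Binomial(f_sh + f_fp,
   S/(S+L))`. The reverse strand is tested symmetrically on the downstream
   shoulder. The combined score `min(−log10 p_fwd, −log10 p_rev)` demands
   bidirectional protection; a single-strand mode exists for asymmetric
   assays. Candidate lengths 11–25 bp are scanned exhaustively within each
   peak and accepted greedily by descending score with no overlap (ties:
   leftmost start, then shortest length), so output is deterministic. An
   interval with zero shoulder cuts scores 0 by definition. The length
   range, shoulder width and score threshold (10) are package defaults, all
   configurable.
5. **Depth QC** (`qc_curve()`): raw sequencing depth predicts footprinting
   power poorly across datasets; the median *peak volume* (cuts per 400-bp
   peak window) is the better guide. The QC thins a profile binomially to a
   series of fractions and reports median volume and mean footprints per
   peak, recommending the smallest volume that still yields ≥ 1 footprint
   per peak. Thinning operates on counts (each cut kept independently),
   which is the exact count-space analogue of read subsampling.
6. **Motif catalog** (`condense_motifs()`, `scan_footprints()`): motif
   databases are redundant — whole TF families bind near-identical motifs
   and single factors carry several PWMs. Similarity between two PWMs is the
   maximum over ungapped offsets and both orientations of the mean
   column-wise Pearson correlation (overlap ≥ 5 columns); families are
   connected components at similarity ≥ 0.8, represented by the member with
   the highest information content (ties: lexicographically first name).
   A factor with a genuinely distinctive motif stays its own family, the
   way PU.1 separates from the other ETS factors. Footprints are scanned
   (± 5 bp) against family representatives with log-odds scores against
   genome base composition (pseudocount 1e-3); a hit needs ≥ 0.8 of the
   PWM's maximum achievable score. The fraction-of-max rule was chosen over
   p-value calibration because it is simple and exactly testable.
7. **Gene linking** (`link_targets()`): distal peaks (summit > 2 kb from the
   nearest TSS; ties to the lower coordinate) are linked to genes through
   promoter-capture interactions — a peak overlapping one anchor links to
   every gene whose promoter (TSS ± 2 kb) overlaps the other anchor, with
   anchors treated as unordered. Peaks without any interaction fall back to
   their nearest gene. Nearest-gene assignment alone is known to be wrong
   for roughly half of true promoter contacts, which is why conformation
   data take precedence.
8. **Networks** (`upregulated_families()`, `build_edges()`,
   `co_occupancy()`): a TF gene is upregulated in a subtype when
   `(mean + 0.1)/(control mean + 0.1) ≥ 3` (the pseudocount keeps
   zero-control genes finite; the threshold is inclusive). A family with an
   upregulated member becomes a node, carrying all expressed members with
   low/moderate/high expression bins (< 3, 3–20, > 20 FKPM — invented
   cutpoints for display). An edge `family → gene` requires an occupied
   motif of the family inside a footprint within a subtype-specific DHS
   linked to that gene. Co-occupancy counts occurrence pairs within 50 bp
   in the same peak; significance comes from permuting family labels within
   each peak (preserving per-peak density and per-family totals), empirical
   `p = (1 + #null ≥ obs)/(1 + B)`, BH-corrected across family pairs. The
   within-peak label permutation null and the BH correction are package
   choices; nothing in the method prescribes a particular null.

## The synthetic-data generator

`simulate_study()` draws a study whose statistical structure matches what
the pipeline assumes. Defaults define the study conditions used throughout
the tests:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 500 kb | random sequence, uniform base composition |
| genes | 80 | TSS on a jittered grid, ≥ 7 kb apart |
| peaks | 240 (20% promoter, 80% distal) | 400 bp, ≥ 2.3 kb from TSS when distal |
| subtypes | 2 × 3 samples + 2 controls | private-peak fraction 0.25 per subtype |
| depth | 1e6 cuts/sample | Poisson per base, rates rescaled to depth |
| peak enrichment | 50× background | background 0.05 relative cuts/bp |
| footprint depletion | 0.1 | interior rate multiplier |
| flank boost | 3× over 35 bp | forward upstream, reverse downstream |
| motif families | 8 × 2 TF genes | 12-bp consensus PWMs, p(major) = 0.85 |
| planted edges | 3 per subtype | source family → TF-gene target |
| HiC-linked distal fraction | 0.85 | exact count, not a coin flip |
| nearest-gene interaction fraction | 0.5 | exact count among linked peaks |
| TF upregulation | 3× × 1.5 margin | noise: lognormal, CV 0.2 |

Choices worth explaining:

* **Poisson cuts.** The cut-count distribution of real DNase data is not
  specified anywhere we could anchor to, so per-base counts are Poisson with
  a structured rate field; overdispersion and sequence-specific cut bias are
  deliberately not modelled.
* **Exact planted fractions.** The HiC-linked and nearest-gene fractions are
  planted as exact counts rather than Bernoulli draws, so recovered
  statistics differ from the settings only through rounding (± 1/n), not
  sampling noise.
* **Consensus embedding.** Each planted footprint embeds its family's
  consensus string into the genome, so motif scanning at the default
  threshold recovers planted instances with certainty. This decouples
  scanner calibration from truth recovery: a scan failure is a pipeline bug,
  not bad luck.
* **Mutually dissimilar families.** Library generation redraws any candidate
  family whose members reach 0.75 similarity to any existing member —
  short 5-column overlaps between random 12-mers otherwise reach the 0.8
  condensation threshold surprisingly often. Family identity is thereby
  unambiguous by construction.
* **Decoy footprints.** Every peak carries two planted footprints (so
  footprints-per-peak can cross 1 in the depth QC); decoys inside a
  subtype's private peaks never use that subtype's source families, which
  makes planted-truth precision well defined.
* **Upregulation margin.** Upregulated TFs change expression *at least*
  threefold; planting exactly at 3.0 would sit on the detection boundary
  (with the 0.1 pseudocount, a gene planted at exactly 3× control measures
  fractionally below 3). Planted folds are therefore 3 × 1.5 by default;
  the margin is a `sim_config()` field and the boundary behaviour is
  documented and tested under both conventions.
* **Per-sample seed streams.** Sample `i` draws from seed `seed + 100 + i`,
  so adding samples never perturbs existing ones, and every generator
  output is byte-identical under a fixed seed.

What the generator does **not** emulate: mappability artefacts, copy-number
variation, DNase sequence preference, overdispersed counts, correlated
biological replicates, overlapping regulatory elements, or realistic gene
density. Passing recovery tests therefore demonstrates internal consistency
of the inference chain under its stated assumptions — not performance on
patient cohorts, whose scale (~10^5 DHSs from > 10^8 reads per sample) this
package's test conditions do not approach.

## Numerical and degenerate-case conventions

* Coordinates are 0-based half-open throughout; BED output is native.
* Peak summits, nearest-TSS lookups and greedy footprint selection break
  ties toward the lower genomic coordinate (then shorter length).
* A footprint interval with zero shoulder cuts on a strand scores 0 on that
  strand; an all-zero profile yields no calls.
* Column pairs of two flat (zero-variance) PWM columns count as similarity
  1 when equal; a flat column against an informative one counts 0.
* Rank normalization errors on samples whose anchor count is zero rather
  than silently producing infinite factors; clustering errors on constant
  sample vectors where correlation is undefined.
* Undefined link-statistic fractions (empty denominators) are reported as
  `NA`, never as 0.
* Empirical permutation p-values use the add-one form, so `p ∈ (0, 1]`.

## Problem sizes used in the shipped checks

The test suite exercises a compact study (1 × 200 kb, 60 peaks, 2 × 2 + 1
samples, 3e5 cuts) for unit-level checks, and the full default conditions
(240 peaks, 2 × 3 + 2 samples, 1e6 cuts, five seeds) for end-to-end planted
recovery; the depth-convergence property uses a 1e7-cut profile. These sizes
keep a complete run in minutes on one core while leaving every planted
structure comfortably above detection thresholds.

## Known limitations

* The footprint statistic assumes cut counts are exchangeable within
  shoulders and interior; DNase sequence bias violates this on real data
  and typically requires bias-corrected variants.
* Subtype-specific DHS calling uses a fold/presence rule, not a count
  model with dispersion; with few samples per subtype it favours strong,
  clean differences (which the generator plants).
* Motif-family condensation keys on one representative per family; it does
  not model partial overlap between families or position-specific
  importance.
* Co-occupancy significance is relative to the within-peak label
  permutation null only; spacing preferences of cooperative TF pairs are
  not modelled.
* `run_pipeline()` footprintings each subtype's pooled profile rather than
  each sample, trading per-sample footprint maps for depth — appropriate at
  the simulated depths, configurable in principle by calling the stage
  functions directly.
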