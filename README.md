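# footgrn

Subtype-specific transcription factor (TF) gene-regulatory-network inference
from DNase I digital footprints.

Mutation-defined subtypes of cancers such as acute myeloid leukemia run on
rewired TF networks that can be read directly out of chromatin. Open
regulatory regions appear as DNase I hypersensitive sites (DHSs); a TF bound
inside a DHS shields its motif from DNase cleavage, leaving a *digital
footprint* — a depletion of 5′ cut ends flanked by strand-specific pile-ups.
`footgrn` turns per-sample stranded cut profiles into subtype-labelled TF
networks:

1. **DHS atlas** — peaks called once on the position-wise sum of all
   samples; every sample quantified on the same fixed 400-bp summit windows;
   per-sample depth removed by ranked-peak normalization (the count of the
   peak ranked `min(16000, ⌊0.125·n⌋)` by size).
2. **Digital footprints** — a strand-aware binomial statistic: with `f_sh`
   cuts in a 35-bp shoulder and `f_fp` in a candidate interval of length
   `L`, the strand score is `−log₁₀ P[X ≥ f_sh]`,
   `X ~ Binomial(f_sh + f_fp, 35/(35+L))`; both strands must pass
   (combined score = min). Includes the depth QC that recommends the
   minimum median peak volume yielding ≥ 1 footprint per peak.
3. **Non-redundant motif catalog** — redundant PWM libraries condensed into
   TF families (connected components at similarity ≥ 0.8, where similarity
   is the best offset/orientation mean column correlation), then footprints
   scanned for occupied motifs at ≥ 0.8 of each PWM's maximum log-odds.
4. **Target-gene linking** — distal DHSs tied to genes through
   promoter-capture interaction anchors, with nearest-gene (nearest-TSS)
   fallback for unlinked peaks.
5. **Networks** — nodes are TF families with a ≥ 3-fold upregulated member
   (pseudocount 0.1); edges require an occupied family motif inside a
   footprint within a subtype-specific DHS linked to the target gene; plus
   a 50-bp motif co-occupancy permutation test.

A seeded synthetic-data generator (`simulate_study()`) plants a known
regulatory landscape — peaks, strand-structured footprint depletions,
subtype-private peak subsets, interactions, upregulated TFs — so the entire
chain is verifiable against ground truth without any cohort data.

Everything is tibble-first and pipe-friendly; results come with
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

A compact simulated study (one 200-kb chromosome, 60 peaks, 2 subtypes × 2
samples + 1 control, 3×10⁵ cuts per sample, 2 planted edges per subtype),
run end to end:

```r
library(footgrn)

cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 200000,
                  n_genes = 20, n_peaks = 60, samples_per_subtype = 2,
                  n_control_samples = 1, reads_per_sample = 3e5,
                  edges_per_subtype = 2)
res <- run_pipeline(pipeline_config(seed = 1, sim = cfg), "example_run")

res
#> <fg_pipeline> 60 atlas peaks | 180 footprint calls | 4 network edges

tidy(res$network)[, 1:4]
#> # A tibble: 4 × 4
#>   subtype family_id target_gene n_supporting
#>   <chr>   <chr>     <chr>              <int>
#> 1 S1      FAM01_A   g009                   1
#> 2 S1      FAM02_A   g009                   1
#> 3 S2      FAM03_A   g001                   1
#> 4 S2      FAM04_A   g015                   1

evaluate_network(res$network, res$truth)
#> # A tibble: 1 × 5
#>   n_true n_called n_correct precision recall
#>    <int>    <int>     <int>     <dbl>  <dbl>
#> 1      4        4         4         1      1

res$link_stats
#> # A tibble: 1 × 3
#>   fraction_dhs_with_promoter_interaction fraction_interactions_nearest_gene …
#> 1                                  0.854                              0.488 …

tidy(res$clustering)
#> # A tibble: 5 × 2
#>   sample_id    cluster
#> 1 control_rep1       1
#> 2 S1_rep1            2
#> 3 S1_rep2            2
#> 4 S2_rep1            3
#> 5 S2_rep2            3
```

All four planted edges are recovered with no false calls
(`precision = recall = 1`); 85.4% of distal DHSs carry a promoter
interaction and 48.8% of those interactions point at the nearest gene —
matching the generator settings (0.85 / 0.50) up to rounding, because the
generator plants those fractions as exact counts. Hierarchical clustering
on distal DHS signal separates the two subtypes and the control cleanly.
The atlas BED, normalized count matrix, footprint calls, motif catalog,
links, GraphML network and a checksummed JSON manifest land in the output
directory; rerunning with the same seed reproduces every checksum.

Useful figures: `autoplot(res$network)` (subtype network diagrams),
`autoplot(res$clustering)` (sample distance structure), and
`autoplot(qc_curve(...))` (footprints-per-peak vs median peak volume with
the recommended depth marked).

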