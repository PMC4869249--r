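# structscore

Per-nucleotide RNA secondary-structure scores from high-throughput
structure-probing sequencing data.

RNA function depends on secondary structure — the pattern of base pairing a
molecule adopts in its cellular environment. Several sequencing-based assays
probe this pattern transcriptome-wide by treating RNA with a reagent whose
activity depends on pairing status, then reading the result out as read
coverage. Each assay family needs its own scoring model, which makes the
resulting data sets hard to compare. `structscore` implements the complete
desk-scale pipeline for four assay designs — from aligned reads, through
method-specific scoring, to an interval-queryable score store, strand-aware
meta-profiles over region collections, and harmonized visualization — for
anyone who wants to compute, query or compare such scores without a database
server.

## Scoring models

All four scorers consume strand-aware coverage tracks built from filtered
alignments (at most 2 mismatches, edit distance ≤ 2, ≤ 5 mapping locations).
PARS, DMS-seq and icSHAPE count only the 5′-most aligned base of each read
(the nuclease cut or reverse-transcriptase stop); ds/ssRNA-seq counts every
aligned base.

| Method | Score at position *i* | High score means |
|---|---|---|
| PARS | S_i = log2[(Σ_{j∈W_i} V1_j + \|W_i\|c) / (Σ_{j∈W_i} S1_j + \|W_i\|c)], W_i = [i−2, i+2] | paired |
| DMS-seq | R_i = (D_i/D_max) / (C_i/C_max) | unpaired (reactive) |
| icSHAPE | R_i = (D_i − C_i) / B_i | unpaired (reactive) |
| ds/ssRNA-seq | S_i = log2[(ONE_i + 1) / (V1_i + 1)] | paired |

Here V1/S1 are the double-/single-strand-specific nuclease libraries, D/C
treated and control libraries, B the control's per-base sequencing depth,
and c a per-position pseudocount (default 1) that keeps positions with
counts in only one library scoreable. For display, all methods are
z-standardized per window and the reactivity-type methods (DMS, icSHAPE)
are inverted, so that *higher always means more paired*; the untransformed
scores are always exported alongside.

Coordinates are 0-based half-open (BED convention) everywhere internally;
region strings like `chr19:9982728-9982762` at the command line follow the
1-based inclusive genome-browser convention.

## Worked example

Simulate PARS-like probing of a 35-nt hairpin (15-nt stems around a 5-nt
loop) at 200× depth, and score it:

```r
library(structscore)

mask   <- hairpin_mask()                     # TRUE = paired; loop at 16-20
tracks <- simulate_probe_counts(mask, "pars_like", depth = 200, seed = 1)
sc     <- pars_score(tracks$V1, tracks$S1)
round(sc$scores[14:22], 2)
#> [1]  1.22  0.41 -0.33 -1.16 -2.25 -1.25 -0.42  0.34  1.19
```

The scores dip through the loop (positions 16–20): V1 cuts dominate in the
stems (positive log ratio, paired) and S1 cuts dominate in the loop
(negative, unpaired). After display orientation the contrast reads directly
as pairing evidence:

```r
disp <- orient_polarity(sc$scores, "pars")   # identity for PARS
mean(disp[!mask$paired]); mean(disp[mask$paired])
#> [1] -1.08
#> [1] 2.10
```

Loop positions average −1.08 against 2.10 in the stems — the simulated
structure is recovered. The same tracks can be loaded into a store with
`add_scores()`, queried by interval (`query_interval()`), averaged across a
BED file of equal-length regions (`aggregate_mean()`), and drawn to SVG
with a lossless raw-score side file (`render_profiles()`). A thin shell
wrapper in `inst/scripts/structscore` exposes every stage as a subcommand
(`coverage`, `score`, `query`, `windows`, `scan`, `aggregate`, `plot`,
`simulate`).

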