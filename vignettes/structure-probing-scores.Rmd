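---
title: "Scoring RNA secondary structure probing data: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RNA secondary structure probing data: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structscore)
```

# The problem

High-throughput structure probing treats an RNA sample with a reagent that
reacts with nucleotides according to their base-pairing status and reads the
outcome out by sequencing. Four assay designs are in wide use, and they
differ in *what* the reads mean:

* **PARS** digests two aliquots under single-hit kinetics, one with the
  double-strand-specific RNase V1 and one with the single-strand-specific
  RNase S1. Each read's 5′ end marks one cleavage site, so the signal is
  5′-end coverage in two libraries.
* **ds/ssRNA-seq** uses similar nucleases (RNaseONE single-strand-specific,
  V1 double-strand-specific) but digests to completion; surviving protected
  fragments are sequenced, so *every aligned base* is signal.
* **DMS-seq** methylates unpaired A/C; the adduct stops reverse
  transcriptase, so 5′ read ends mark reactive positions. The control is a
  *denatured* sample — maximally reactive everywhere.
* **icSHAPE** acylates the 2′-OH of unpaired nucleotides of all four bases
  with a biotin-tagged reagent and enriches labeled fragments; the control
  is *solvent-only* (DMSO) — minimally reactive.

Because the readouts differ (cut sites vs stops vs protection; paired-
vs unpaired-preferring reagents; opposite control philosophies), each
design gets its own scoring model, and comparisons between methods are
made downstream on harmonized displays, never on raw scores.

# Scoring models

All scorers operate per chromosome (or transcript) and strand on aligned
count vectors. Missing values are `NA` throughout and are never conflated
with zero: a zero is an observed score, `NA` means the method cannot score
the position.

## PARS

$$S_i = \log_2\frac{\sum_{j\in W_i} V1_j + |W_i|\,c}
                   {\sum_{j\in W_i} S1_j + |W_i|\,c},
  \qquad W_i = [i-2,\, i+2] \cap \text{track}$$

The windowed sum implements the 5-nt rolling average; any common
per-position normalizing divisor cancels in the ratio, so only the additive
pseudocount total $|W_i|c$ matters. With the default $c = 1$ a full window
contributes $+5$ to numerator and denominator. The pseudocount is exposed
as a parameter (`pseudocount`, counts per position, default 1) because the
literature states the smoothing constant in more than one algebraic form;
we adopt one count per window position as the canonical reading and let
users reproduce any per-window total they need.

Two boundary decisions were genuinely open and are resolved as follows:

* **Track ends.** Windows are truncated to their in-bounds positions and
  the pseudocount scales with the actual window size $|W_i|$. The
  alternative — dropping the first and last two positions of every
  transcript — discards data systematically at feature boundaries, which is
  exactly where meta-profiles look.
* **Omission rule.** A position is unscoreable when its *window* has zero
  counts in both libraries (not merely the center position): the score is a
  window statistic, so the no-evidence condition is evaluated on the
  window. A positive score means more V1 cleavage (paired); negative means
  S1 (unpaired).

## DMS-seq

$$R_i = \frac{D_i / D_{max}}{C_i / C_{max}}$$

Positions with $C_i = 0$ are `NA` (the ratio is undefined; the denatured
control saw nothing there). An all-zero library over the scoring scope is
an error rather than a silent all-`NA` track. The **normalization scope**
for $D_{max}, C_{max}$ is configurable: `"per-region"` (default) uses the
maxima of the supplied tracks; `"global"` accepts caller-supplied
library-wide maxima. Per-region is the default because library-wide maxima
are dominated by rRNA-scale outliers, which flattens every other
transcript's scores toward zero; which scope the original curated data
used is not recoverable, so both are provided and the choice travels with
the scores' metadata. Scores are scale-invariant to library size by
construction.

## icSHAPE

$$R_i = (D_i - C_i) / B_i$$

$B_i$ is the *base density* — the full-read sequencing depth of the DMSO
library at $i$ — while $C_i$ is the same library's 5′-end count. Positions
with $B_i = 0$ are `NA`. Negative reactivities (control stops exceeding
treated) are retained by default so that display inversion is
information-preserving; a `floor_at_zero` flag clips them for users who
want the conventional non-negative reactivity. The upstream icSHAPE
pipeline's α-scaling and winsorization are deliberately *not* applied: this
package implements the plain background-subtracted, density-scaled form,
and documents that as its scope.

## ds/ssRNA-seq

$$S_i = \log_2\frac{ONE_i + 1}{V1_i + 1}$$

computed per position on full-read coverage. The pseudocount makes the
score finite everywhere, so ds/ss tracks have no missing positions within
the analyzed region. Positive = paired (protected from the single-strand
nuclease).

# From reads to counts

Alignments are filtered with inclusive thresholds — mismatches ≤ 2, edit
distance ≤ 2, mapping locations ≤ 5 — read from the standard `XM`, `NM`
and `NH` tags. Aligners differ in which tags they emit, so a `lenient`
policy can impute the missing one from its counterpart (`NH` absent ⇒ 1).
Multi-mapped reads that pass the filter contribute **full weight at every
reported location**; fractional weighting would require knowing the true
origin, which the data cannot provide, and the five-location cap bounds
the resulting double counting.

The biological 5′ end of a minus-strand read is its *rightmost* genomic
base — the read runs 3′→5′ in genomic coordinates — so 5′-end counting
increments `end − 1` on the minus strand. Spliced alignments contribute
full-read counts only over their aligned blocks (intron `N` gaps excluded)
and their terminal aligned base for 5′-end counting. Coordinates are
0-based half-open everywhere internally; the 1-based inclusive
genome-browser convention appears only in CLI region strings.

# Store, aggregation and display

The score store is an in-memory table keyed on
(method, chromosome, strand, position) — the moral equivalent of the
database behind a structure-browser web service, without the server.
Interval queries are binary searches on the sorted key; results are dense
score vectors over the half-open query span with `NA` at unscored
positions, and querying an unknown chromosome warns rather than errors,
because score-less regions are a routine feature of sparse probing data.

Meta-profiles average oriented score vectors across equal-length regions.
Orientation is strand-aware: minus-strand regions are reversed so offset 0
is always the transcript-5′ end, and flank construction
(`make_feature_windows()`) applies `up`/`down` in transcript orientation.
With 3-nt anchors and 9-nt flanks the feature occupies 0-based offsets
9–11 of a 21-nt window; 7-nt anchors with 21-nt flanks occupy offsets
21–27 of 49. The mean is unweighted across regions, missing values are
excluded from numerator and denominator, and the per-offset contributor
count is always reported so users can add their own confidence measures —
the package deliberately does not test profile dips for significance.
Overlapping regions are counted independently (no deduplication). Motif
scanning is exact IUPAC matching on both strands (`U` ≡ `T`); PWM-score
thresholding is out of scope, a documented simplification relative to how
such motifs are natively derived.

For display, each method's segment is z-transformed over its non-missing
values using the population (divide-by-$n$) standard deviation — chosen so
the examples `[1, 2, 3] → ±1.2247` and `[1, NA, 3] → ±1` hold exactly — a
constant segment maps to zeros rather than dividing by zero, and the
reactivity-type methods (DMS, icSHAPE) are negated so that *higher = more
paired* across all methods. Standardization and negation commute (up to
the sign being applied consistently), which the suite asserts numerically.
Standardization is per-window and per-method; whether a hosted service
would standardize per dataset instead is an open question, so the
transform is applied at render time only and the untransformed scores are
always written alongside the plot, making the display layer lossless.
Plots are SVG (vector, deterministic, diffable).

# The simulators

`simulate_probe_counts()` encodes only the contract the scorers rely on:
probing signal depends on pairing status. Counts are Poisson with rate
`depth` at baseline positions and `depth × unpaired_factor` at the
reagent's preferred positions (unpaired for DMS/icSHAPE/S1, paired for
V1/RNaseONE); controls are flat; the icSHAPE base density is flat at
`10 × depth`. Defaults are `depth = 200` expected counts per position and
`unpaired_factor = 5`, a signal contrast comparable to a well-covered
transcript in a deeply sequenced probing library. The default test
structure is a 35-nt hairpin (15-nt stems, 5-nt loop) — the shape of an
iron-response element, the classic stem-loop benchmark.

What the simulator does *not* emulate matters for interpreting green
tests: no ligation or RT sequence bias, no fragment-length structure, no
partial digestion kinetics, no correlated noise along the molecule, no
transcript-abundance variation. Passing the recovery suite therefore shows
the *scoring and orientation machinery* preserves a pairing contrast fed
to it; it does not show the assays themselves resolve structure in real
cells. `simulate_alignments()` similarly produces minimal valid SAM with
controlled `NM`/`XM`/`NH` tags for exercising the filter, and
`make_toy_annotation()` plants start codons on alternating strands of a
random sequence for window/aggregation tests. All simulators are
deterministic given `seed` and restore the caller's RNG state.

# Numerical choices and problem sizes

* Scorers are exact vectorized evaluations; the suite checks them against
  independent per-position loop oracles at 1e-12 on 200-position random
  tracks.
* The PARS perturbation membership check, the filter sweeps and the
  coordinate-convention checks are exact (integer) comparisons.
* Recovery tests use 100 seeded replicates of the 35-nt hairpin at depth
  200 per assay, judged by mean rank of displayed loop vs stem positions —
  rank-based so that monotone rescalings of a method's scores cannot
  change the outcome. These sizes keep the full suite under half a minute
  while leaving the Poisson noise clearly visible in individual tracks.
* Ties in ranks are handled by midranks (R's default); degenerate inputs
  (all-zero libraries, zero-variance display segments, empty read sets,
  empty query results) each have a defined behavior tested explicitly
  rather than left to propagate.

# Known limitations

* Scores are computed and stored in genomic coordinates; transcript-space
  scoring of spliced transcripts requires projecting coverage to the
  transcriptome before scoring (the store itself is coordinate-agnostic).
* The DMS and icSHAPE models implement the plain published ratio forms;
  method-specific refinements (winsorization, scaling factors) are out of
  scope.
* Aggregation offers no statistical testing — `n_contrib` is exported
  precisely so users can build their own.
* Paired-end mates are treated as independent reads; duplicate marking is
  upstream of this package.
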