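---
title: "Bag-of-motifs models of cis-regulatory sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bag-of-motifs models of cis-regulatory sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(motifbag)
```

# The model

`motifbag` asks whether the *composition* of transcription factor
binding motifs in a distal cis-regulatory element (CRE) — how many
matches of each motif it contains, regardless of their order, spacing or
strand — suffices to predict the cell type or condition in which the
element is active. Each CRE is a row of a count matrix whose columns are
motifs; a gradient-boosted tree ensemble maps that bag of counts to a
class probability. The approach trades positional grammar for three
properties: it needs no large training corpus, its features are named
biological objects, and exact per-feature attributions are available for
every prediction.

The central assumptions are (i) a 0-order background model of
non-functional sequence, (ii) motif occurrences informative for identity
are detectable as PWM matches at a lenient threshold, and (iii)
interactions between motifs can be captured by trees on counts alone.
Assumption (iii) is the substantive scientific bet; the package exists
to let users test it on their own data.

# CRE definition

Candidate intervals (typically accessibility peaks) are reduced to
fixed-width windows, 500 bp by default, centered on the peak summit when
one is recorded and on the interval midpoint otherwise. Windows are kept
only if they are **distal** — every window base more than 1 kb
(`min_tss_distance`) from every annotated transcription start site,
measured from the window edges, which is the stricter of the possible
readings — and **non-exonic**, meaning zero overlap with any annotated
exon of any transcript. Windows running past a chromosome end are
dropped rather than shifted, so all retained windows are exactly
comparable. The operation is idempotent: re-centering an already-centered
window returns it unchanged.

Negative flanking windows tile ±2 kb around each CRE (500-bp windows,
50-bp stride), anchored on the *original* interval, and any window
overlapping *any* CRE in the input set is discarded. An isolated CRE
therefore yields 31 windows per side.

# Motif scanning and exact p-values

Scores are log2 log-odds of the position probability matrix against the
background, with a pseudocount of 0.1 distributed proportionally to the
background frequencies (the FIMO convention):
`log2((p + 0.1 b) / (1.1 b))`. Both strands are scanned; a
reverse-strand hit is the forward-coordinates window whose reverse
complement matches. Because both strands are reported, the background is
symmetrized across complementary bases before scoring, which makes
scanning exactly mirror-symmetric: a sequence and its reverse complement
produce identical hit sets with strands and coordinates swapped.

P-values are exact, not asymptotic. Each motif's log-odds matrix is
discretized to integers over 1000 bins spanning its achievable score
range (`resolution` is tunable; more bins cost memory linearly), and the
distribution of the discretized score of a background-distributed word
is built by convolving one position at a time. The tail of that
distribution is the p-value map. Scanning uses the same integer scores,
so the p-value attached to a window is identical to what exhaustive
enumeration over all 4^w words would give — the test suite checks this
equality to 1e-9 for widths up to 8, and checks the scanner against a
brute-force per-window scorer at 1e-9. Windows containing N are skipped
entirely rather than scored against the background, keeping results
deterministic under ambiguous sequence.

Hits at `p <= 1e-4` are filtered per motif by Benjamini–Hochberg at
`q <= 0.5`. The lenient q-cutoff is deliberate: degenerate, low-affinity
matches carry a disproportionate share of the predictive signal, and the
package exposes `subsample_counts()` to probe that sensitivity (removing
a fraction of hit-units uniformly without replacement). Two notes on
divergence from FIMO: FIMO's internal q-value estimator is not plain BH
and is not documented as a formula, so BH is used; and palindromic
motifs legitimately produce two hits (one per strand) at one location —
both are counted by default. `remove_overlapping_hits()` implements the
position-sorted, lower-score-first overlap pruning (seeded uniform
choice on exact ties) used for sensitivity analyses; it is *not* part of
the default pipeline.

# Dataset assembly and training

A binary dataset for class *k* takes all of *k*'s CREs as positives and
an equal number of negatives stratified evenly over every other class:
each background class contributes `floor(n_pos / n_bg)` rows, with any
remainder filled one row at a time from the largest background classes
(seeded). If some background class cannot supply its share, the
per-class quota drops to the smallest background class size and the
positives are downsampled to match — both sides stay exactly equal.
Classes with fewer than 100 unique peaks are refused, a floor below
which the models are not considered trustworthy. CREs with zero motif
hits are retained as all-zero rows; exclusion would silently bias the
background composition.

Rows are split 60/20/20 into training/validation/test with per-label
stratification (largest-remainder rounding keeps every label within one
row of its exact share). Boosted trees use `binary:logistic` (or
`multi:softprob`, one-vs-rest binary ensembles for multilabel,
`reg:squarederror` for regression) with up to 10,000 rounds, learning
rate 0.01, maximum depth 6, row and column subsampling 0.5, and early
stopping after 100 rounds without validation improvement. The binary
early-stopping metric is validation logloss (the multiclass metric is
mlogloss; the binary one is configurable since only the multiclass
choice is canonical). Training defaults to one thread so that identical
seeds give bit-identical models; multithreading is opt-in. Predictions
at or above 0.5 are positive calls. A model scores any matrix sharing
its motif vocabulary: missing motif columns are imputed as zero counts
(a motif never scanned is indistinguishable from absent), which is what
makes cross-dataset and cross-species transfer possible; unknown extra
columns are an error unless strict mode is disabled.

# Evaluation conventions

auROC is the Mann–Whitney concordance probability with half-credit for
ties, which the tests verify against an independent implementation.
auPR uses step-wise precision integration (no linear interpolation
between PR points), the conservative standard. Zero-denominator cases
use total-report conventions (MCC = 0, F1 = 0) and are flagged in the
report rather than dropped.

# Shapley attributions

Attributions are reported in margin (log-odds) units so that the
efficiency identity — attributions plus base value equal the margin
prediction — is exact for tree ensembles, rather than approximate as it
would be in probability units.

Two computation routes exist. The default `explain()` uses the
booster's built-in TreeSHAP with tree-path-dependent expectations: this
is the established, C++-speed implementation and is what makes
explaining thousands of CREs over thousands of trees practical. Passing
a `reference` matrix switches to an interventional explainer implemented
in the package: for each reference row, each tree leaf contributes to
the features whose values decide between the instance reaching the leaf
and the reference reaching it, with the classical Shapley weights
`(a-1)! b! / (a+b)!`; results are averaged over reference rows and
computed entirely in double precision. The package had to choose a
default background: the path-dependent expectation (no explicit
reference) was chosen because a pure-R interventional pass over a
full-size model and reference set is not tractable, while the
interventional mode remains available — and is exactly what the
verification tests use, because with an all-zero reference it must equal
the brute-force subset-enumeration oracle `exact_shapley()` (feasible up
to 12 features), which the suite asserts to 1e-6 along with the
efficiency and dummy-feature axioms. One practical caveat: the
booster's own margins are float32, so efficiency against `predict`
margins closes to ~1e-6 only for moderately sized ensembles; the
double-precision route closes to machine precision.

Global motif importance is the sum of absolute attributions across
explained rows (mean absolute and signed mean are reported alongside;
exact ties break lexicographically by motif id). Explanations are
computed on the test split by default — the question being asked is what
the model uses on data it has not memorized. Local explanations report
the top `k` motifs (default 4) per CRE with signed attributions and raw
counts.

# Per-cell type assignment across species

Given a multiclass model over marker peaks and a cell-by-peak
accessibility matrix, a cell's profile is the arithmetic mean of peak
attributions over its accessible peaks (entry > 0; for binary matrices
that is exactly entry = 1), per motif and class, with each marker peak
contributing only under its own class's attribution slice (aggregation
over all slices is available behind a flag). Peaks used in model
training or validation should be excluded via `exclude_peaks`. Cells
with fewer than 20 accessible marker peaks are dropped; types with more
than 1000 annotated cells can be downsampled to the cap. Profiles are
normalized per cell by the sum of absolute values.

For assignment, each class gets the ratio of summed positive to summed
absolute attributions (0 for an all-zero slice), and the ratio is
z-scored *across cells within each class column* — the reading that
corrects class-specific ratio baselines; standardizing across classes
within a cell is the plausible alternative and is available via
`use_z = FALSE` plus manual scaling. The final label is the arg-max of
the z-scores (raw ratios when a class column has zero variance, or when
only one cell is scored). These two interpretation choices — the
standardization axis and whether the arg-max uses z or raw ratios — are
the genuinely open points of the procedure; the defaults are the ones
that make the clean-data invariant hold: with zero dropout and zero
contamination, every cell passing the peak filter is assigned to its
true type, which the acceptance suite asserts at 100%.

# Synthetic regulatory element design

The designer implants `copies_per_motif` (default 2) instances of each
of the top-ranked motifs (default 5) into a template sequence,
*replacing* template bases at seeded random non-overlapping positions so
the total length (e.g. 260 bp) never changes — replacement rather than
insertion is implied by the fixed final length of the assay construct.
Instances are PWM consensus strings by default (per-position arg-max,
A<C<G<T on ties); sampling instances from the PWM per implant is
available, as the realization of instances from matrices is not
canonical. Implantation is forward-strand by default. Every design
carries an implant record, and the scanner recovers every implant at its
recorded coordinate at the default thresholds — an invariant the tests
check per design.

# The synthetic data generator

The generator is the package's stand-in for labeled single-cell
accessibility datasets: i.i.d. background sequence at a set GC fraction
(default 0.41, a vertebrate-like average), per-class Bernoulli implant
rates per motif, one non-overlapping PWM-sampled instance per implant,
and a truth table of all implants. Accessibility matrices are binary
with per-type marker peaks, a dropout rate for own-type peaks and a
contamination rate for other types' peaks. Default motif widths are
8–12: a width-6 motif cannot pass the 1e-4 scanning threshold even as a
perfect consensus match (its best word has p = 4^-6 ≈ 2.4e-4), so
narrower widths are supported but pointless for implant-recovery
designs.

What the generator does *not* emulate matters for interpreting green
tests: real CREs have repeat structure, GC heterogeneity, nucleosome
positioning signals, motif clustering and syntax, and label noise from
imperfect peak-to-cell-type assignment. Passing the recovery tests shows
the machinery is correct — scanning finds what is there, training
separates what is separable, attributions point at the implanted signal
— not that real enhancers are this easy.

The reference recovery design (two classes of 500 CREs at 500 bp, five
discriminative motifs at implant rates 0.8 vs 0.05, twenty shared decoys
at 0.3, scanned at p ≤ 1e-4 / q ≤ 0.5 and trained with the full
hyperparameters) is both the flagship test and the acceptance script's
main computation. Auxiliary checks run scaled down — e.g. the
three-class assignment design uses 120 CREs of 300 bp per class and
2,000-round training, and the orchestration tests use 60–80 CREs per
class — sizes chosen to exercise every code path at desk scale.

# Numerical choices and degenerate inputs

* Score discretization: 1000 bins per motif over the achievable range;
  a zero-range (constant) score matrix yields p = 1 everywhere.
* Min-max display normalization maps constant vectors to zeros.
* `split_dataset` errors on any empty partition; `assemble_balanced`
  refuses sub-minimum positive classes rather than silently shrinking.
* All sampling (balancing, splits, subsampling, implants, placement,
  tie-breaks) flows through per-call seeds that are recorded in outputs;
  the global RNG state of the caller is never disturbed.
* Boosted-tree determinism holds for fixed seed and single-thread
  execution; the manifests written by `run_pipeline()` contain content
  hashes so reruns can be verified byte for byte.

# Known limitations

Motif grammar (order, spacing, orientation) is out of representation by
design; the scanner supports only 0-order backgrounds; FIMO's exact
q-values are not reproduced (BH is used); the interventional Shapley
route is pure R and intended for verification-scale models; and no
peak calling, differential accessibility, or cross-species sequence
alignment is performed — labels and intervals are inputs.
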