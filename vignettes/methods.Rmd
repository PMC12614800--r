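---
title: "Models and methods: multi-day interneuron calcium analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multi-day interneuron calcium analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fearca` re-implements, as a tested pipeline, a population-level analysis of
multi-day single-cell calcium recordings from amygdala interneurons during
discriminative auditory fear conditioning and extinction. This vignette is
the package's own account of the models it implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The experimental structure being modelled

The paradigm spans four sessions. On the habituation day two pure tones
(the future CS+ and CS−, each 30 s of 200 ms pips at 0.9 Hz) are presented
five times each, alternating. On the conditioning day each CS+ is followed
by a 2 s foot shock (US) placed one pip period (1/0.9 s) after tone
offset, with five interleaved CS− presentations. On the two
test/extinction days the CS− is presented four times followed by twelve
CS+ presentations. Inter-trial intervals are drawn uniformly from
60–90 s after a 2 min baseline. `build_protocol()` lays out these
timelines and `validate_event_table()` enforces the invariants (durations,
pairing, per-day trial counts).

Fluorescence traces enter the pipeline as cells × samples matrices at
20 Hz, one per session, with the same cells registered across all
sessions of an animal. `preprocess_traces()` z-scores each cell over the
concatenated multi-session recording — matching an acquisition chain in
which all session movies are concatenated before cell extraction — and
mean-bins to 250 ms. Per-session z-scoring is available via a flag; the
concatenated default is an assumption, since session boundaries could in
principle be used instead.

Conventions used throughout: intervals are half-open `[onset, offset)` in
seconds; bin *b* covers `[b·w, (b+1)·w)`; constant traces z-score to zero
with a warning rather than dividing by zero.

## Event-aligned analysis

`align_to_events()` cuts per-trial snippets and subtracts, per cell and
trial, the mean over the baseline window preceding onset (30 s for CS, 5 s
for US, 2 s for immobility events). The AUC of a response
(`compute_auc()`) is the integral of the baselined trace over the event
window (30 s CS, 5 s US, 2 s immobility). Because binned traces are step
functions, the exact integral is the bin sum times the bin width; this
choice (rather than a trapezoid through the bin samples, which
under-counts a step signal's area by half a bin at each edge) makes a
rectangular response integrate to exactly height × width and keeps the
AUC exactly linear and additive over disjoint windows.

Responsiveness follows a per-trial rank-sum rule: for each presentation,
the binned baseline window is compared to the evoked window (CS: 120 vs
120 bins; US: 20 vs 8 bins) with the two-sided Wilcoxon rank-sum test,
normal approximation with tie and continuity corrections — at 120 bins per
window, exact enumeration adds nothing. A cell is *responsive* when at
least 3 presentations are significant at α = 0.01; its direction is the
majority sign of the significant trials, with exact ties broken by the
sign of the mean AUC (and logged). The per-trial test is implemented as a
vectorised row-wise statistic verified in the test suite to agree with
`stats::wilcox.test(exact = FALSE)` to 1e−12; the vectorisation is purely
a performance matter (the null-control screen tests 50,000 cell-trials).

For across-day comparisons the uneven trial counts are balanced: the
first four presentations of each CS on habituation, the four CS− and the
first four CS+ on test/extinction 1, and the last four CS+ on extinction
2 (`across_day_trial_sets()`).

Chance overlap of CS+/CS−/US responsiveness is modelled as the
independence product of an animal's marginal responsive fractions. The
original analysis displays a chance level without defining it; the
independence product is the natural null for "is multisensory overlap
enriched", but other constructions are conceivable.

## Response archetypes: PCA + K-means with template labelling

Archetype discovery (`fit_cluster_model()`) projects per-trial baselined
snippets of responsive cells onto the smallest principal subspace holding
at least 80% of variance and partitions the scores by K-means (k-means++
style multiple restarts: 50 seeded restarts, 100 iterations — the
downstream analysis needs a stable partition). The silhouette coefficient
is computed on the PCA scores with Euclidean distance, because that is
the space the clusterer operates in (the alternative — raw traces — is
left to the caller via `cluster::silhouette`). `silhouette_scan()`
reports the mean silhouette for k = 2…20. Features are *not*
re-standardised per feature: the traces are already z-scored, and
re-scaling would distort amplitude relations between trials.

The original workflow inspects, classifies and merges clusters by hand
(with k deliberately set above the silhouette optimum: 16 for US
patterns, 8 for conditioning CS patterns, 10 across days, 5 for
extinction dynamics). `merge_and_label()` makes that step reproducible:
an explicit raw→merged map (identity by default) plus automatic semantic
labelling of each merged cluster by maximal Pearson correlation of its
mean feature vector against a library of named templates.
`archetype_feature_templates()` builds those templates by passing one
noise-free cell per archetype through the *identical* generation,
preprocessing and alignment path, which guarantees the template layout
matches the feature layout. Template correlation is scale-free, so the
per-cell amplitude attenuation introduced by z-scoring does not affect
labelling.

Cross-labelling flows (`cluster_flow()`) count cells moving between two
labellings, masking flows below 5 cells for display, and
`cluster_fractions_per_animal()` prepares per-animal fractions for
Friedman-type comparisons.

## Population vector distance

The PVD between a CS and the US reference
(`us_reference_vector()`: per-cell mean of the baselined 5 s US response,
averaged over shocks) is the Euclidean distance between population
vectors. Within a presentation, the 30 s CS window is read out at the
analysis bin width (0.25 s → 120 vectors) and per-bin distances are
averaged; a `mean_vector` mode collapses the window to one vector first.
The phrase "30 s binned responses" is ambiguous between those two
readings; per-bin is the default and both are exposed.

Within conditioning, changes are normalised to the first CS/US pairing
(`100·(d_t − d_1)/d_1`; negative = convergence toward the US), with
early (pairings 1–2) and late (pairings 4–5) means. Cluster-removal
ablations (`pvd_ablation()`) recompute the change on the complement of
each named cell set. Across days, the distance of the first four CS
presentations to the conditioning US reference is normalised to the
habituation-day distance.

A numerical point that shaped the validation fixture
(`simulate_cs_us_morph()`): adding isotropic noise to a population vector
inflates every Euclidean distance (E‖v+ε‖ > ‖v‖, of order nσ²/2d), which
biases normalised changes toward zero by different amounts at different
distances. The planted-morph fixture therefore jitters the *morph
coefficient* along the CS→US line instead — the distance is exactly
linear in that noise, so recovery of the planted convergence rate is
unbiased while keeping honest trial-to-trial variability.

## Decoding

Decoding follows the population-decoder design of the original analysis:
one sample per 1 s bin of a 30 s window, features a random subsample of
37 cells per animal (the minimum population size across animals of the
emulated dataset), exactly balanced classes — each CS presentation
contributes a 30-sample block and BASELINE blocks are the 30 s windows
immediately preceding CS onsets (the natural stimulus-free epochs; where
the original placed its baseline windows is not stated). Intra-day
decoding uses one-vs-one linear SVMs with majority vote (C = 1, no
feature rescaling beyond the pipeline z-score), 10-fold stratified
cross-validation, repeated over fresh cell subsamples (100 iterations by
default). Accuracy is the confusion-matrix trace over its total;
precision, recall and F1 are reported per class. Controls: temporally
shuffled labels, responsive-only / non-responsive-only subsets, and a
random size-matched subset.

Cross-day transfer trains two-way decoders (baseline vs CS+, baseline vs
CS−) on one day and evaluates them unchanged on another day of the same
registered cells. Per-cell absolute weights (`|w| = |t(coefs)·SV|`)
index each cell's contribution; `weight_selectivity()` correlates
|w(CS+)| with |w(CS−)| across subsample iterations (Pearson by default;
Spearman via argument — the original does not state which), and
`weight_stability()` provides the successive-refit control on 90%
partitions.

## Behaviour: immobility and discrimination

Pose tables carry x, y and likelihood for eight tracked body parts.
`filter_pose()` holds the most recent confident position through
low-likelihood frames (threshold 0.9 — the source analysis filters "low
likelihood" positions without giving the cutoff), back-filling a leading
low-likelihood run from the first confident frame; hold-last was chosen
over interpolation because interpolation manufactures motion through
dropouts. Immobility requires all five trunk points (ear bases,
upper/middle spine, tail base) to stay below a displacement threshold
(default 2 px/frame, within the published per-animal calibration range
0.7–3.5) for at least 2 s. Bouts overlapping any CS are flagged and
excluded from neural alignment but retained for behavioural scoring —
immobility during the tone is exactly what the discrimination score
measures.

Immobility-aligned activity baselines each bout-onset/offset snippet to
the preceding 2 s, pools the two extinction sessions into one trace per
cell, and integrates 2 s after onset/offset. Stability across sessions is
the per-animal Spearman correlation of per-cell responses between session
pairs, tested across animals with one-sample t-tests.

The discrimination score is DS = (Imm_CS+ − Imm_CS−)/(Imm_CS+ +
Imm_CS−), computed on test/extinction 1. Which CS+ trials enter Imm_CS+
is not stated in the source; the default uses the first four CS+ against
the four CS− so the trial counts are balanced (all twelve are available
via the `trials` argument). Cluster-count/behaviour relations use
Spearman correlations.

## The synthetic-data generator

`generate_population()` plants, per cell, one archetype from each family
— US response pattern, CS+ and CS− conditioning patterns, and an
across-day pattern gating CS responses on non-conditioning days (e.g.
"Fear" → CS response only on test/extinction 1). Default mixture
proportions reproduce the reported cluster-size fractions of the emulated
dataset (out of 519 cells), and the default scale is 9 animals × 58
cells. Event drives follow the real stimulus microstructure: tones are
200 ms pips at 0.9 Hz (pip height scaled by the inverse duty cycle so the
planted amplitude is the evoked *mean* in noise-s.d. units), the US is a
2 s boxcar, "US off" responds in the 2 s after shock offset. Drives are
convolved with a peak-normalised difference-of-exponentials calcium
kernel (rise 0.1 s, decay 0.6 s — GCaMP6f-like; configurable for slower
indicators), truncated after at least five decay constants and extended
until the peak-normalised tail falls below 0.005. Inhibited archetypes
are negative drive modulations: interneurons are tonically active in
vivo, so suppression of fluorescence below baseline is the realistic
signature, and after z-scoring a negative modulation represents it
directly.

Noise is unit-variance per cell: temporally white innovations plus a
small AR(1) component (φ = 0.9 at 20 Hz, 2.25% of the variance). The
white-dominated mixture reflects that extracted single-cell traces are
photon-shot-noise limited at the frame level; the AR component adds
calcium-like slow structure. The proportion matters statistically: the
rank-sum responsiveness test assumes exchangeable bins, and a noise
floor dominated by a slow AR process at the 250 ms bin scale would
inflate the per-trial false-positive rate far above its nominal α,
destroying the null-calibration property the generator must provide.
With the default mixture the per-trial rate stays within a small factor
of α and the ≥3-of-5 family rule keeps null cells essentially never
classified responsive (exact binomial bound ≈ 9.85×10⁻⁶ at independent
trials).

State modulation: cells whose across-day archetype is listed in
`state_modulation` (defaults: "Fear inhibited" and "Extinction", both
−1, mirroring the reported immobility-suppressed classes) receive a
signed sustained drive during planted immobility bouts.
`generate_behaviour()` produces the pose side: a two-state semi-Markov
path (immobile dwells ≥ 2 s with an exponential tail), a reflected
random walk at 3–8 px/frame while mobile, sub-threshold jitter while
immobile, eight body parts riding the common trajectory, and occasional
likelihood dropouts.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: biophysical calcium dynamics and indicator
saturation, photobleaching, neuropil contamination and crosstalk between
ROIs, registration errors across days, non-stationary baselines,
correlated (population-level) noise, and behaviour–neuron feedback
beyond the planted state modulation. Recovery results on synthetic data
validate the *implementation* of each stage against ground truth; they
are not evidence about effect sizes in vivo.

## Problem sizes and determinism

The validation suite uses desk-scale problem sizes chosen to exercise
each property with comfortable statistical margin: 10,000 cells for the
null-calibration screen, 400 cells × 6 archetypes for clustering
recovery (amplitudes 3×, 2×, 1×, 0.5× noise s.d.), 58-cell populations
with 37-cell subsamples for decoding, 20 seeds × 3 convergence rates for
PVD recovery, and ~50 planted bouts for immobility detection. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

Every stochastic step is seeded: the pipeline seed spawns per-stage and
per-iteration seeds, a config fully serialises a run (`config_hash()`),
and two runs with the same config produce byte-identical exported tables.
Group comparisons throughout use the nonparametric reporting pattern
(Friedman + Dunn for repeated measures, Mann–Whitney / paired Wilcoxon
with Bonferroni correction, chi-square with Yates continuity correction
at small expected counts), with Shapiro–Wilk and Levene screening
reported alongside. Dunn's post hoc is computed in-package from the
standard rank-sum z formula, as no installed package provides it.

## Known limitations

- The shipped merge maps/templates approximate a manual
  inspect-and-merge step; on real data the published cluster semantics
  are recoverable only qualitatively.
- The chance-overlap model (independence product) is an assumption; the
  original's construction is undocumented.
- The generator's across-day archetype applies to both CS types on
  non-conditioning days; differential CS+/CS− across-day dynamics can be
  planted only via the `truth` argument.
- Trace I/O is TSV/CSV; no HDF5 container is provided.
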