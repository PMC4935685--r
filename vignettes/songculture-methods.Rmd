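---
title: "Methods: quantifying birdsong phonology, syntax, and cultural evolution"
author: "songculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying birdsong phonology, syntax, and cultural evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songculture)
```

# Overview

`songculture` implements a pipeline for comparing learned bird song across
populations, built for zebra finch (*Taeniopygia guttata*) song but applicable
to any corpus of acoustic feature contours. A male's *motif* — the stereotyped
string of *elements* (single vocal gestures) he repeats while singing — is the
unit of observation. Elements separated by inter-element gaps of at most 5 ms
are grouped into *syllables*. Each element carries a contour: one row per
0.5 ms spectrogram frame holding fundamental frequency (FF), mean frequency,
frequency change, and harmonicity.

The pipeline answers three questions:

1. **Phonology** — do elements and syllables fall into species-wide
   categories? (DTW dissimilarities, PAM clustering validated by a
   null-corrected global silhouette index, NMDS ordination, Gaussian
   mixtures with component merging.)
2. **Syntax** — does unit order within motifs carry information?
   (Transition biases, a types-per-motif permutation test, first-order
   Markov redundancy with finite-sample corrections, a syntactic
   clustering scan.)
3. **Divergence** — do populations differ? (MRPP with individual-level
   permutation, permutation chi-square with Cramér's V, spatial medians and
   neighbor-joining dendrograms.)

A fourth component, the cultural-evolution simulator, explores *why*
populations do or do not diverge: when song learning is error-prone,
improvisation continually re-spreads each population over the whole
species-specific song space and prevents the formation of local traditions.

Everything is validated end to end on synthetic data with known ground
truth, produced by the package's own generator.

# Acoustic features

The four per-frame features follow standard bioacoustic definitions:

* **Mean frequency** — the intensity-weighted mean of the spectrogram
  band frequencies.
* **Harmonicity** — the proportion of spectral intensity within ±FF/4 of
  each integer multiple of the fundamental. Windows are truncated at
  Nyquist and bands straddling a window edge are apportioned by overlap.
  A spectrally flat frame therefore scores about 0.5, a pure harmonic
  stack 1, and energy midway between harmonics 0.
* **Frequency change** — the slope of a linear regression of FF on time
  over a short window (default 5 frames, 2.5 ms), mapped through an
  arctangent onto [0, 1]: 0 falling infinitely fast, 0.5 flat, 1 rising
  infinitely fast. The arctangent scaling constant is not fixed by any
  published definition; we use `c = 0.02` ms/Hz so that ±50 Hz/ms maps to
  0.25/0.75. Frequency-change values are therefore comparable within this
  package but not across implementations.
* **Fundamental frequency** — estimated, where raw audio is used, by
  harmonic-comb scoring over a geometric candidate grid with a Viterbi
  continuity penalty on octave-scale jumps and a small monotone-in-frequency
  bonus that resolves the subharmonic ambiguity (every subharmonic of the
  true FF captures the same harmonic energy). Frames whose best comb score
  falls below a threshold are marked unvoiced. Interactive, per-element
  tuning of FF tracking — the usual practice in spectrogram GUIs — is
  deliberately replaced by this automatic procedure, so per-frame estimates
  from other trackers will differ in detail.

Contour tables, not audio, are the canonical input: the analyses operate on
measurements, and recordings are often unavailable. The audio path exists to
synthesize test fixtures and to validate supplied contours; it accepts
numeric waveforms (22.05 kHz mono; a 256-point Hamming window, 0.5 ms step,
420 Hz high-pass).

# DTW dissimilarity

Two units are compared by dynamic time warping over five features: the four
acoustic contours, each divided by its standard deviation pooled over all
frames of all units in the dataset, plus time. The time feature is the frame
position within its unit weighted by `q / L_max`, where `L_max` is the
duration of the longer of the two units and `q = 5`. Dividing by `L_max`
makes the comparison scale-free in time: doubling both units' durations
changes nothing, so a 2 ms and a 4 ms unit differ exactly as much as a 20 ms
and a 40 ms unit. Pooling the feature SDs once over the whole dataset — not
per population — keeps dissimilarities comparable across populations.

The warp path runs from the first frame pair to the last with steps down,
right, or diagonal, all with unit weight. The published description asks for
"an average of the dissimilarities along the optimal path" without fixing
the optimization target; minimizing the *mean* directly is not decomposable
by dynamic programming, so the optimal path minimizes the *accumulated*
frame distance and the reported dissimilarity is that path's sum divided by
its length in cells. The test suite verifies this definition against
exhaustive enumeration of every monotone path on short units.

Syllable-level contours are the concatenation of their elements' frames with
time measured from syllable onset in real time: within-syllable gaps remain
part of the time axis, but no frames are invented inside them, preserving
syllable rhythm without fabricating silent-frame features. Isolated unvoiced
frames are imputed by linear interpolation from neighbors; units unvoiced
throughout are rejected.

# Cluster discovery and validation

`pam_cluster()` partitions the dissimilarity matrix around medoids; the
global silhouette index (GSI) of a partition is the mean silhouette width
over all units (range −1 to 1). Because the maximum silhouette over a scan
of `k` is biased upward even on structureless data, `gsi_scan()` subtracts a
null level: reference datasets drawn as independent Gaussians whose
per-dimension SDs match an NMDS ordination of the empirical matrix (default
5 dimensions, 10 replicates), clustered and scored identically. The paper
trail for the "corrected" GSI does not define the correction; null
subtraction with a geometry-matched Gaussian reference was chosen because
the same construction is used elsewhere in the pipeline for the redundancy
null, keeping the two corrections consistent. A clear peak in the corrected
GSI indicates a clustering tendency at that `k`.

The mixture route ordinates the matrix into Euclidean space by NMDS
(`nmds_embed()`: Kruskal stress-1, 20 starts — metric start plus random
configurations — keeping the lowest-stress solution; `var_explained` is the
squared correlation between configuration and input distances). NMDS
dimensionality is deliberately exposed as a parameter with its
`var_explained` reported, since no automatic criterion is defensible for
every dataset. `gmm_merge_cluster()` then fits Gaussian mixtures with
unconstrained ("VVV") covariances for `k = 1..max_k`, selects `k` by BIC
(ties toward fewer components), and merges component pairs while their
directly estimated misclassification probability — the posterior mass of one
component's points hard-assigned to the other — exceeds 0.025. Partition
agreement between routes is quantified by the adjusted Rand index.

# Syntax statistics

Motifs are read as sequences of typed units. The transition-bias table adds
START and END pseudo-states, counts the `L + 1` transitions of each
length-`L` motif, and scores each cell by
`(p_obs − p_exp) / max(p_obs, p_exp)` in [−1, 1], with expected
probabilities `freq(a)·freq(b)` from the independence null (START and END
each occur once per motif). This surfaces position effects such as types
concentrated at motif starts or ends.

The types-per-motif test permutes units between motifs *within populations*,
preserving motif lengths, and compares the mean number of distinct types per
motif to its permutation distribution (two-sided, add-one p-value — the
add-one convention is used for every permutation p-value in the package).

First-order Markov redundancy is `1 − H1/H0`: `H0` the entropy of the type
frequencies, `H1` the conditional entropy of next type given current type,
both over within-motif transitions only (boundary pseudo-states appear in
the bias table but not in the entropy, since including them would let motif
length masquerade as syntax) and each Miller–Madow corrected for finite
samples. Redundancy 0 means sequences are as unpredictable as their type
frequencies allow; 1 means fully deterministic order.

`syntactic_redundancy_scan()` searches for the partition of units that
maximizes syntactical structure: starting from the PAM solution at each `k`,
single units are greedily reassigned (first-improvement, 5 restarts from
perturbed starts) while an objective increases. The objective is redundancy
*minus an acoustic anchoring penalty*: `lambda` (default 25) times the
fractional increase of the total unit-to-assigned-medoid dissimilarity over
the PAM optimum. The anchor is essential, not cosmetic: unconstrained
redundancy maximization is degenerate, because labeling units by their
position within the motif (alternating labels, for instance) makes any
dataset look perfectly deterministic. With the anchor, only acoustically
ambiguous units near cluster boundaries can be reassigned by syntax — the
partition is chosen "partly, but not solely" on syntactic grounds. Because
even the anchored search inflates redundancy on structureless data, each
estimate is corrected by subtracting the mean redundancy the same procedure
attains on simulated datasets: random matrices built from independent
Gaussians whose per-dimension SDs equal those of (up to) 50 NMDS dimensions
of the empirical matrix, three replicates. 99% confidence intervals
bootstrap individuals (motifs of resampled birds, labels fixed) and resample
the three null values, so both uncertainty sources are carried.

# Divergence statistics

`mrpp()` implements the multiresponse permutation procedure with group
weights `n_g / N`: the observed weighted mean within-group dissimilarity
δ is compared to its distribution under random reassignment of
*individuals* to groups (all of a bird's units move together — the bird,
not the unit, is the sampling unit; unit-level permutation is available for
sensitivity analysis and for cross-checking against conventional
implementations). The effect size is `A = 1 − δ/m_δ` and the p-value the
add-one lower tail. `type_frequency_test()` computes the Pearson chi-square
of the type × group table with analytic margins, takes its p-value from
individual-level permutations, and reports Cramér's V
(`sqrt(chi2 / (N·min(r−1, c−1)))`) as the effect size. Group structure in
ordination space is summarized by spatial medians (Weiszfeld iteration with
the Vardi–Zhang safeguard for iterates landing on data points, tolerance
1e-9) and a Saitou–Nei neighbor-joining dendrogram of the between-median
distances, serialized as newick; negative branch lengths, possible for
non-additive input, are clamped to zero with a warning. Continent-level
analyses reuse the same code path with a coarser group mapping.

# The cultural-evolution simulator

Each singer's song is a fixed-length sequence of syllables, each a point in
a bounded species-specific feature range (defaults: 5 syllables, 5
dimensions, unit hypercube — a deliberately abstract song space). Each
simulated year half the singers are replaced (one generation-equivalent per
two years). A new singer learns each syllable position by copying it exactly
from a uniformly chosen tutor of the previous year with probability
`1 − e`, or improvising — drawing uniformly from the species range — with
probability `e`, the learning-error rate. A founder population (default
100) evolves for a 50-year burn-in, splits into two daughters (default 30
each), and the daughters evolve in isolation for 200 years.

Divergence is tracked as the global silhouette index of the pooled songs
(principal-coordinates ordination of the pairwise song distances, the two
populations as the two clusters); within-population diversity as the mean
pairwise song distance. Song distance is DTW over the syllable sequences
with Euclidean syllable distance, the same mean-along-optimal-path
convention as the acoustic DTW. Where the population sizes, song
representation, and distance metric were not pinned down by any available
description, the defaults above were chosen once as a minimal model and the
conclusions are tested as *directional* properties robust to them: final
between-population GSI decreases as `e` grows, diversity is non-decreasing
in `e`, and at `e = 1` diversity converges to the ceiling of a population
improvising every syllable. That ceiling — the expected song distance
between two independent uniform songs — has no closed form because of the
minimum over warp paths, so `expected_uniform_diversity()` evaluates it by
fixed-seed Monte Carlo over independent pairs.

# The synthetic-data generator

`generate_dataset()` emits contour tables plus ground truth. Ten element
archetypes (flat, high flat, noisy flat, slide, lower slide, noisy high,
declining high, high, low, upsweep) span the two broad FF classes observed
in zebra finch song, low near 0.8 kHz and high near 3.5 kHz; their
parameters are fixtures in plausible ranges, not claims of acoustic
fidelity. An element contour is its template — log-linear FF between start
and end values — times smooth multiplicative noise (moving-average-filtered,
so contours stay continuous; white noise is available for robustness
checks); frequency change is computed from the generated FF track by the
same rolling regression the features module uses, keeping generator and
analyzer consistent. Motif lengths are uniform on 3–8 units. Inter-element
gaps are bimodal — within-syllable gaps normal around 1 ms (clipped to
[−1, 4.5] ms; negative gaps model overlapping elements), between-syllable
gaps lognormal around 40 ms — so segmentation at the 5 ms threshold recovers
the planted syllable structure essentially perfectly. Optional structure:
per-population multiplicative type-usage shifts, per-population acoustic
(log-frequency) shifts, a planted first-order transition matrix
(`symmetric_chain()` solves a circulant chain for any target redundancy,
with `analytic_redundancy()` as the closed-form oracle), and compound
syllable archetypes defined as element-template sequences.

What the generator does *not* emulate: reverberation and recording-channel
differences, introductory notes, amplitude features, within-individual
repertoire variation beyond noise, and observer segmentation error. Passing
the pipeline's tests on generated data therefore demonstrates correctness of
the computations and recoverability of planted structure under clean
conditions, not robustness to the full messiness of field recordings.

# Numerical choices and problem sizes

* Permutation p-values use the add-one convention throughout; permutation
  counts default to 10,000 in the divergence tests.
* PAM ties and mixture-order ties resolve toward smaller `k`.
* The DTW tie-break order is diagonal, vertical, horizontal; ties are
  measure-zero for continuous features.
* NMDS: 20 random starts (5 inside the GSI scan, 3 inside the redundancy
  scan where only dimension SDs are needed), iteration cap 500, stress
  floor 1e-7.
* Degenerate inputs are first-class: empty contour files warn and return
  empty lists, single-type sequences signal an error from redundancy
  (H0 = 0), groups with fewer than two units are excluded from MRPP with a
  warning, all-zero spectral frames yield NA features.
* Test and validation problem sizes were chosen at desk scale: DTW oracle
  checks enumerate paths on units of at most 6 frames; cluster-recovery
  fixtures use two populations of 8 individuals (≈70–110 units);
  calibration of permutation p-values uses 200 replicates of 500
  permutations; the simulator's directional checks use populations of 30
  over 100 years with 10 replicates per error rate; redundancy-recovery
  checks use 40 individuals (≈320 units) and 100,000 planted transitions
  for the estimator-only check.

# Known limitations

* FF tracking is intentionally simple; spectrally complex, noisy elements
  that require manual tuning in interactive tools will be estimated less
  accurately here.
* Frequency-change values depend on an arbitrary arctangent scale and are
  not comparable across software.
* The syntactic search explores single-unit moves only; partitions
  requiring coordinated reassignment of many units will not be found. Its
  `lambda` anchor trades syntactic sensitivity against acoustic fidelity
  and was fixed, not tuned per dataset.
* NMDS dimensionality is a user choice; report `var_explained` alongside
  any downstream result.
* The simulator is deliberately abstract: no age structure, dispersal,
  selective tutor choice, or genetic evolution of predispositions.
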