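# songculture

Computational comparison of learned bird song across populations, modeled on
zebra finch (*Taeniopygia guttata*) song. Many songbirds learn their songs by
imitation, and the balance between copying fidelity and improvisation decides
whether isolated populations develop local song traditions or keep
re-converging on species-wide norms. This package provides the full numerical
pipeline needed to ask that question of a song corpus, plus an agent-based
simulator that shows why high learning-error rates prevent cultural
divergence.

It is written for bioacousticians and students of cultural evolution who have
(or can simulate) *acoustic feature contours*: per-frame measurements of
fundamental frequency, mean frequency, frequency change, and harmonicity
along each song unit.

## What it computes

**Unit comparison.** Song units (elements, or syllables = elements separated
by gaps ≤ 5 ms) are compared by dynamic time warping over the four acoustic
contours plus time:

    d(a, b) = sqrt( Σ_f ((a_f − b_f)/σ_f)²  +  (q·(t_a − t_b)/L_max)² )

with feature SDs σ_f pooled over the whole dataset, q = 5, and L_max the
duration of the longer unit — so length differences count logarithmically (a
2 ms vs 4 ms pair is exactly as distant as 20 ms vs 40 ms). The dissimilarity
of two units is the mean frame distance along the optimal warp path.

**Category discovery.** Partitioning around medoids (PAM) on the
dissimilarity matrix, validated by a null-corrected global silhouette index
(GSI); independently, NMDS ordination followed by Gaussian mixtures ("VVV",
BIC-selected) with misclassification-probability merging; agreement via the
adjusted Rand index.

**Syntax.** Transition biases `(p_obs − p_exp)/max(p_obs, p_exp)` with
START/END states; a types-per-motif permutation test; first-order Markov
redundancy `1 − H1/H0` with Miller–Madow finite-sample corrections; and a
syntactic clustering scan whose search-bias is corrected with simulated null
datasets.

**Population divergence.** MRPP (effect size `A = 1 − δ/m_δ`) and a
permutation chi-square with Cramér's V, both permuting *individuals* between
groups; spatial medians and neighbor-joining dendrograms of population
centers.

**Cultural evolution.** A simulator in which each new singer copies each
syllable from a tutor with probability 1 − e and improvises it (uniform over
the species range) with probability e. Two daughter populations founded from
one ancestor diverge when e is small and stay mixed when e is large.

**Synthetic data.** A generator emitting contour tables with known ground
truth — planted unit types in two broad frequency classes, bimodal
inter-element gaps, population usage shifts, planted Markov syntax — used by
the test suite to validate every stage end to end.

## Worked example

```r
library(songculture)

# a synthetic corpus: 2 populations x 10 individuals, 10 element archetypes
spec  <- generator_spec(n_populations = 2, individuals_per_pop = 10, seed = 7)
d     <- generate_dataset(spec)
units <- unit_contours(d$motifs, level = "element")
D     <- pairwise_matrix(units, level = "element")
D
#> DTW dissimilarity matrix: 106 element-level units, 2 population(s)
#>   range [0, 6.621]

scan <- gsi_scan(D, k_range = 2:10, null_reps = 5, seed = 1)
scan
#> Null-corrected global silhouette scan (best k = 9 ):
#>   k   gsi null_gsi corrected_gsi
#>   2 0.433    0.271         0.163
#>   3 0.476    0.220         0.256
#>   ...
#>   9 0.584    0.189         0.394
#>  10 0.545    0.201         0.344

part <- pam_cluster(D, attr(scan, "best_k"))
ids   <- vapply(units, attr, character(1), "id")
truth <- d$truth$units$true_type[match(ids, d$truth$units$id)]
adjusted_rand(part$labels, truth)
#> [1] 0.838

mrpp(D, n_perm = 999, seed = 1)
#> MRPP (individual-level permutation, 999 permutations):
#>   delta = 2.8515, m_delta = 2.8538, A = 0.0008, p = 0.305
```

Reading the numbers: the corrected GSI peaks at k = 9, close to the 10
planted archetypes, and PAM recovers the planted labels well (adjusted Rand
0.84; 1 would be perfect, 0 chance). The generator planted no population
effect, and MRPP correctly finds none: within-population dissimilarity δ is
indistinguishable from its permutation expectation m_δ (effect size
A ≈ 0.001, p = 0.3).

The simulator, at a low learning-error rate, shows two isolated daughter
populations drifting apart:

```r
cfg  <- sim_config(founder_size = 60, daughter_size = 30, years = 100,
                   burn_in = 30, error_rate = 0.01, seed = 3)
run_split_experiment(cfg, sample_every = 50)
#> Split-experiment trajectory (error rate 0.01): 3 sampling points
#>  year     gsi diversity
#>     0 0.00996     0.490
#>    50 0.69003     0.271
#>   100 0.70020     0.383
```

The between-population GSI climbs from ≈ 0 (fully mixed) to 0.7
(well-separated clusters); at error rates above ~0.05 it stays near 0.

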