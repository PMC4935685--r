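#' Synthetic song generator with known ground truth
#'
#' Emits contour datasets that emulate the structure of zebra finch song —
#' motifs of 2-10 elements grouped into syllables by short gaps, two broad
#' fundamental-frequency classes (low around 0.8 kHz, high around 3.5 kHz),
#' per-population shifts in type usage, and optional planted first-order
#' syntax — together with the ground truth (true types, population effects,
#' transition matrix, analytic redundancy) needed to validate every
#' analysis stage. The templates are fixtures inspired by typical element
#' categories, not claims of acoustic fidelity.
#'
#' @name synthgen
NULL

#' Element archetype templates
#'
#' Ten element archetypes (flat, high flat, noisy flat, slide, lower slide,
#' noisy high, declining high, high, low, upsweep) with durations, start and
#' end fundamental frequency, mean frequency, and harmonicity in plausible
#' zebra finch ranges. The first five are low-FF types (around 0.5-1.3
#' kHz), the next four cover the high-FF class (2.5-4.7 kHz); `class`
#' records the broad FF category.
#'
#' @return data.frame with columns `name`, `duration_ms`, `ff_start_hz`,
#'   `ff_end_hz`, `mf_hz`, `harm`, `class`.
#' @export
element_templates <- function() {
  data.frame(
    name = c("flat", "high_flat", "noisy_flat", "slide", "lower_slide",
             "noisy_high", "declining_high", "high", "low", "upsweep"),
    duration_ms = c(90, 44, 50, 47, 51, 37, 25, 27, 24, 20),
    ff_start_hz = c(657, 1131, 953, 1256, 884, 3310, 4376, 4676, 1293, 862),
    ff_end_hz = c(582, 1040, 835, 555, 517, 2601, 2454, 4707, 1280, 1425),
    mf_hz = c(3454, 4053, 4143, 4141, 3208, 4526, 3795, 4911, 1577, 3484),
    harm = c(0.89, 0.83, 0.62, 0.68, 0.75, 0.74, 0.91, 0.98, 0.93, 0.69),
    class = c("low", "low", "low", "low", "low",
              "high", "high", "high", "low", "low"))
}

#' Generator specification
#'
#' @param n_populations number of populations.
#' @param individuals_per_pop individuals per population.
#' @param motifs_per_individual motifs recorded per individual (default 1,
#'   one exemplar motif per male).
#' @param templates element template table (see [element_templates()]).
#' @param type_usage named base usage weights over template names (default
#'   uniform).
#' @param pop_frequency_shifts optional matrix (populations x types) of
#'   multiplicative usage shifts.
#' @param pop_acoustic_shift optional numeric per population: multiplicative
#'   log-scale shift applied to FF and mean frequency (0 = no population
#'   effect on acoustic structure).
#' @param transition_matrix optional row-stochastic matrix over types
#'   planting first-order syntax; `NULL` draws types independently.
#' @param start_probs optional distribution of the first type (defaults to
#'   usage weights).
#' @param motif_len range of motif lengths in units (default `3:8`).
#' @param syllable_templates optional list of integer vectors (indices into
#'   `templates`) defining compound syllable archetypes; when supplied,
#'   motifs are sequences of these syllables and `motif_len` counts
#'   syllables.
#' @param noise list of within-type spreads: `rel_ff`, `rel_mf` (log-scale
#'   SDs), `fc`, `harm` (additive SDs), `dur` (log-scale duration jitter).
#' @param gaps list with `short_mean`, `short_sd` (within-syllable gaps,
#'   ms, normal, clipped to \[-1, 4.5\]), `long_meanlog`, `long_sdlog`
#'   (between-syllable gaps, lognormal), `p_between` (probability a
#'   junction separates syllables when no syllable templates are given).
#' @param seed RNG seed.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_populations = 2, individuals_per_pop = 10,
                           motifs_per_individual = 1,
                           templates = element_templates(),
                           type_usage = NULL, pop_frequency_shifts = NULL,
                           pop_acoustic_shift = NULL,
                           transition_matrix = NULL, start_probs = NULL,
                           motif_len = 3:8, syllable_templates = NULL,
                           noise = list(rel_ff = 0.05, rel_mf = 0.04,
                                        fc = 0.02, harm = 0.03, dur = 0.08),
                           gaps = list(short_mean = 1, short_sd = 0.8,
                                       long_meanlog = log(40),
                                       long_sdlog = 0.35, p_between = 0.6),
                           seed = 1) {
  stopf(all(templates$ff_start_hz > 300 & templates$ff_start_hz < 8000 &
              templates$ff_end_hz > 300 & templates$ff_end_hz < 8000),
        "template FF must lie within 0.3-8 kHz")
  stopf(all(templates$duration_ms >= 5 & templates$duration_ms <= 150),
        "template durations must lie within 5-150 ms")
  k_seq <- if (is.null(syllable_templates)) nrow(templates)
           else length(syllable_templates)
  if (is.null(type_usage)) type_usage <- rep(1 / k_seq, k_seq)
  stopf(length(type_usage) == k_seq, "type_usage length mismatch")
  type_usage <- type_usage / sum(type_usage)
  if (!is.null(transition_matrix)) {
    stopf(nrow(transition_matrix) == k_seq &&
            ncol(transition_matrix) == k_seq,
          "transition_matrix must be %d x %d", k_seq, k_seq)
    stopf(all(abs(rowSums(transition_matrix) - 1) < 1e-8),
          "transition_matrix rows must sum to 1")
  }
  if (is.null(pop_acoustic_shift))
    pop_acoustic_shift <- rep(0, n_populations)
  if (!is.null(pop_frequency_shifts))
    stopf(nrow(pop_frequency_shifts) == n_populations &&
            ncol(pop_frequency_shifts) == k_seq,
          "pop_frequency_shifts must be populations x types")
  stopf(all(unlist(noise) >= 0), "noise SDs must be >= 0")
  structure(list(n_populations = n_populations,
                 individuals_per_pop = individuals_per_pop,
                 motifs_per_individual = motifs_per_individual,
                 templates = templates, type_usage = type_usage,
                 pop_frequency_shifts = pop_frequency_shifts,
                 pop_acoustic_shift = pop_acoustic_shift,
                 transition_matrix = transition_matrix,
                 start_probs = start_probs, motif_len = motif_len,
                 syllable_templates = syllable_templates,
                 noise = noise, gaps = gaps, seed = seed),
            class = "generator_spec")
}

# Draw one type sequence of length L from usage weights or a Markov chain.
sample_type_sequence <- function(L, usage, P, start_probs) {
  k <- length(usage)
  if (is.null(P)) return(sample.int(k, L, replace = TRUE, prob = usage))
  s <- integer(L)
  s[1] <- sample.int(k, 1, prob = if (is.null(start_probs)) usage
                     else start_probs)
  for (i in seq_len(L - 1))
    s[i + 1] <- sample.int(k, 1, prob = P[s[i], ])
  s
}

#' Sample typed sequences from a Markov chain
#'
#' Standalone sequence sampler (no contours) for syntax-level experiments:
#' draws motif type sequences from a first-order chain with the stationary
#' distribution as the start distribution.
#'
#' @param P row-stochastic transition matrix.
#' @param n_motifs number of motifs.
#' @param motif_len motif length range (each drawn uniformly).
#' @param seed RNG seed.
#' @param types optional type names (default `t1..tk`).
#' @return list of character vectors.
#' @export
sample_markov_sequences <- function(P, n_motifs, motif_len = 3:8, seed = 1,
                                    types = NULL) {
  k <- nrow(P)
  if (is.null(types)) types <- paste0("t", seq_len(k))
  pi0 <- stationary_distribution(P)
  set.seed(derive_seed(seed, 11))
  lapply(seq_len(n_motifs), function(m) {
    L <- if (length(motif_len) == 1) motif_len else sample(motif_len, 1)
    types[sample_type_sequence(L, pi0, P, pi0)]
  })
}

# Synthesize one element's contour frames from a template row.
synth_element <- function(tpl, noise, acoustic_shift, step_ms = 0.5) {
  dur <- tpl$duration_ms * exp(rnorm(1, 0, noise$dur))
  nf <- max(3L, round(dur / step_ms))
  t <- (seq_len(nf) - 1L) * step_ms
  ff_line <- exp(seq(log(tpl$ff_start_hz), log(tpl$ff_end_hz),
                     length.out = nf))
  ff <- ff_line * exp(acoustic_shift + rnorm(1, 0, noise$rel_ff) +
                        smooth_noise(nf, noise$rel_ff / 2))
  mf <- tpl$mf_hz * exp(acoustic_shift + rnorm(1, 0, noise$rel_mf) +
                          smooth_noise(nf, noise$rel_mf / 2))
  fc <- clamp(frequency_change_contour(t, ff) +
                smooth_noise(nf, noise$fc), 0, 1)
  harm <- clamp(tpl$harm + rnorm(1, 0, noise$harm) +
                  smooth_noise(nf, noise$harm / 2), 0.02, 1)
  data.frame(t_ms = t, ff_hz = ff, mf_hz = mf, fc = fc, harm = harm)
}

short_gap <- function(g) clamp(rnorm(1, g$short_mean, g$short_sd), -1, 4.5)
long_gap <- function(g) max(6, rlnorm(1, g$long_meanlog, g$long_sdlog))

#' Generate a synthetic contour dataset
#'
#' Draws motifs per individual per population following the specification:
#' type sequences (independent or first-order Markov, with optional
#' per-population usage shifts), element contours as template plus smooth
#' correlated noise (optionally shifted per population), and inter-element
#' gaps from a bimodal short/long mixture so that syllable segmentation at
#' the 5 ms threshold recovers the planted syllable structure. Deterministic
#' under the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return list with `motifs` (list of [song_motif()]), `contours` (the
#'   canonical contour data.frame), and `truth`: `units` (data.frame `id`,
#'   `individual`, `population`, `true_type`, `class`), `syllables`
#'   (data.frame `id`, `true_type`, or `NULL`), `transition_matrix`,
#'   `redundancy` (analytic, or `NA` without planted syntax),
#'   `pop_acoustic_shift`, `usage` (per-population type-usage weights).
#' @export
generate_dataset <- function(spec) {
  set.seed(derive_seed(spec$seed, 12))
  tpl <- spec$templates
  k_seq <- length(spec$type_usage)
  pops <- paste0("pop", seq_len(spec$n_populations))
  usage_by_pop <- lapply(seq_len(spec$n_populations), function(p) {
    w <- spec$type_usage
    if (!is.null(spec$pop_frequency_shifts))
      w <- w * spec$pop_frequency_shifts[p, ]
    w / sum(w)
  })
  if (!is.null(spec$transition_matrix)) {
    pi0 <- stationary_distribution(spec$transition_matrix)
    stopf(all(pi0 > 0), "transition matrix must be irreducible")
  }
  motifs <- list()
  unit_rows <- list()
  syl_rows <- list()
  for (p in seq_len(spec$n_populations)) {
    for (iv in seq_len(spec$individuals_per_pop)) {
      indiv <- sprintf("%s_ind%02d", pops[p], iv)
      for (mm in seq_len(spec$motifs_per_individual)) {
        motif_id <- sprintf("m%d", mm)
        L <- if (length(spec$motif_len) == 1) spec$motif_len
             else sample(spec$motif_len, 1)
        seq_types <- sample_type_sequence(L, usage_by_pop[[p]],
                                          spec$transition_matrix,
                                          spec$start_probs)
        if (is.null(spec$syllable_templates)) {
          el_types <- seq_types
          junction_between <- runif(L - 1) < spec$gaps$p_between
          syl_of_el <- cumsum(c(TRUE, junction_between))
        } else {
          el_types <- unlist(spec$syllable_templates[seq_types])
          syl_lens <- lengths(spec$syllable_templates[seq_types])
          syl_of_el <- rep(seq_along(syl_lens), syl_lens)
          junction_between <- diff(syl_of_el) > 0
        }
        n_el <- length(el_types)
        elements <- vector("list", n_el)
        onset <- 0
        for (e in seq_len(n_el)) {
          frames <- synth_element(tpl[el_types[e], ], spec$noise,
                                  spec$pop_acoustic_shift[p])
          elements[[e]] <- song_element(frames, onset_ms = onset)
          gap <- if (e < n_el) {
            if (junction_between[e]) long_gap(spec$gaps)
            else short_gap(spec$gaps)
          } else 0
          onset <- onset + elements[[e]]$duration_ms + gap
        }
        motifs[[length(motifs) + 1L]] <-
          song_motif(indiv, pops[p], motif_id, elements)
        unit_rows[[length(unit_rows) + 1L]] <- data.frame(
          id = sprintf("%s:%s:e%d", indiv, motif_id, seq_len(n_el)),
          individual = indiv, population = pops[p],
          true_type = tpl$name[el_types], class = tpl$class[el_types])
        if (!is.null(spec$syllable_templates))
          syl_rows[[length(syl_rows) + 1L]] <- data.frame(
            id = sprintf("%s:%s:s%d", indiv, motif_id,
                         seq_along(seq_types)),
            individual = indiv, population = pops[p],
            true_type = seq_types)
      }
    }
  }
  truth <- list(
    units = do.call(rbind, unit_rows),
    syllables = if (length(syl_rows)) do.call(rbind, syl_rows) else NULL,
    transition_matrix = spec$transition_matrix,
    redundancy = if (is.null(spec$transition_matrix)) NA_real_
                 else analytic_redundancy(spec$transition_matrix),
    pop_acoustic_shift = spec$pop_acoustic_shift,
    usage = usage_by_pop)
  list(motifs = motifs, contours = contour_table(motifs), truth = truth)
}

#' Stationary distribution of a Markov chain
#'
#' @param P row-stochastic matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Analytic redundancy of a first-order Markov chain
#'
#' Closed-form `1 - H1 / H0` from the stationary distribution: `H0` is the
#' entropy of the stationary type frequencies, `H1` the stationary-weighted
#' mean entropy of the transition rows. The oracle counterpart of
#' [markov_redundancy()].
#'
#' @param P row-stochastic, irreducible transition matrix.
#' @return redundancy in \[0,1\].
#' @export
analytic_redundancy <- function(P) {
  P <- as.matrix(P)
  stopf(all(abs(rowSums(P) - 1) < 1e-8), "rows must sum to 1")
  k <- nrow(P)
  reach <- diag(k) + P
  for (i in seq_len(k)) reach <- sign(reach %*% (diag(k) + P))
  stopf(all(reach > 0), "chain must be irreducible")
  pi0 <- stationary_distribution(P)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h0 <- h(pi0)
  if (h0 == 0) return(0)
  h1 <- sum(pi0 * apply(P, 1, h))
  clamp(1 - h1 / h0, 0, 1)
}

#' Symmetric chain with a target redundancy
#'
#' Builds the k-state circulant chain with diagonal `1 - (k-1) b` and
#' off-diagonal `b`, solving for `b` so that [analytic_redundancy()] equals
#' `target`. Used to plant syntax of known strength.
#'
#' @param k number of states (>= 2).
#' @param target desired redundancy in (0, 1).
#' @return transition matrix.
#' @export
symmetric_chain <- function(k, target) {
  stopf(k >= 2, "k must be >= 2")
  stopf(target > 0 && target < 1, "target must lie in (0,1)")
  red_of <- function(b) {
    P <- matrix(b, k, k)
    diag(P) <- 1 - (k - 1) * b
    analytic_redundancy(P)
  }
  b <- uniroot(function(b) red_of(b) - target,
               c(1e-9, 1 / k - 1e-9), tol = 1e-12)$root
  P <- matrix(b, k, k)
  diag(P) <- 1 - (k - 1) * b
  P
}
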