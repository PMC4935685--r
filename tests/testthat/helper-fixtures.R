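# Shared fixture builders. Everything is generated in code; no data files.

# A minimal unit contour with random features and irregular frame spacing.
random_unit <- function(n, seed, id = paste0("u", seed)) {
  set.seed(seed)
  f <- data.frame(t_ms = cumsum(c(0, runif(n - 1, 0.3, 0.8))),
                  ff_hz = runif(n, 500, 4000),
                  mf_hz = runif(n, 1000, 5000),
                  fc = runif(n), harm = runif(n))
  structure(f, id = id, individual = "indA", population = "popA",
            motif_id = "m1", duration_ms = max(f$t_ms) + 0.5,
            class = c("unit_contour", "data.frame"))
}

# A constant-feature unit of given duration and frame count (equal spacing).
constant_unit <- function(duration_ms, n_frames, id,
                          ff = 1000, mf = 2000, fc = 0.5, harm = 0.8) {
  step <- duration_ms / n_frames
  f <- data.frame(t_ms = (seq_len(n_frames) - 1) * step,
                  ff_hz = ff, mf_hz = mf, fc = fc, harm = harm)
  structure(f, id = id, individual = "indA", population = "popA",
            motif_id = "m1", duration_ms = duration_ms,
            class = c("unit_contour", "data.frame"))
}

# Fixed scaling so frame distances are easy to reason about.
unit_scaling <- function(q = 5)
  structure(list(sd = c(ff_hz = 1000, mf_hz = 1000, fc = 0.2, harm = 0.2),
                 q = q),
            class = "feature_scaling")

# Build a motif from element durations and the gaps between them.
gap_motif <- function(gaps_ms, durations_ms = rep(10, length(gaps_ms) + 1),
                      individual = "indA", population = "popA",
                      motif_id = "m1") {
  onset <- 0
  els <- vector("list", length(durations_ms))
  for (i in seq_along(durations_ms)) {
    n <- max(2L, round(durations_ms[i] / 0.5))
    frames <- data.frame(t_ms = (seq_len(n) - 1) * 0.5,
                         ff_hz = 800 + 10 * i, mf_hz = 3000,
                         fc = 0.5, harm = 0.8)
    els[[i]] <- song_element(frames, onset_ms = onset)
    if (i <= length(gaps_ms))
      onset <- onset + els[[i]]$duration_ms + gaps_ms[i]
  }
  song_motif(individual, population, motif_id, els)
}

# Two tight fundamental-frequency classes (low ~0.8 kHz, high ~3.5 kHz) with
# weak within-class substructure: the species-wide two-category condition.
two_class_spec <- function(seed, individuals_per_pop = 8) {
  templates <- data.frame(
    name = c("low_a", "low_b", "high_a", "high_b"),
    duration_ms = c(60, 70, 35, 40),
    ff_start_hz = c(750, 900, 3400, 3650),
    ff_end_hz = c(680, 820, 3250, 3500),
    mf_hz = c(3500, 3600, 4500, 4600),
    harm = c(0.85, 0.8, 0.9, 0.88),
    class = c("low", "low", "high", "high"))
  generator_spec(
    n_populations = 2, individuals_per_pop = individuals_per_pop,
    templates = templates,
    noise = list(rel_ff = 0.12, rel_mf = 0.08, fc = 0.05, harm = 0.06,
                 dur = 0.1),
    seed = seed)
}

# Seven well-separated compound-syllable archetypes (planted k = 7).
seven_syllable_spec <- function(seed) {
  generator_spec(
    n_populations = 2, individuals_per_pop = 8,
    syllable_templates = list(1L, 4L, 8L, c(10L, 10L), c(6L, 7L),
                              c(2L, 8L, 3L), c(9L, 9L, 9L)),
    motif_len = 3:6,
    noise = list(rel_ff = 0.06, rel_mf = 0.05, fc = 0.03, harm = 0.04,
                 dur = 0.08),
    seed = seed)
}

# Element-level dissimilarity matrix plus aligned truth labels.
element_dissim_with_truth <- function(spec) {
  d <- generate_dataset(spec)
  u <- unit_contours(d$motifs, "element")
  D <- pairwise_matrix(u, level = "element")
  ids <- vapply(u, attr, character(1), "id")
  truth <- d$truth$units[match(ids, d$truth$units$id), ]
  list(data = d, units = u, D = D, truth = truth)
}

# Independent brute-force alignment oracle for plain feature matrices
# (used against song_distance); enumerates every monotone path.
brute_song_distance <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  local <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    local[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf; best_len <- NA
  recurse <- function(i, j, acc, len) {
    acc <- acc + local[i, j]; len <- len + 1L
    if (i == n && j == m) {
      if (acc < best) { best <<- acc; best_len <<- len }
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc, len)
    if (i < n) recurse(i + 1, j, acc, len)
    if (j < m) recurse(i, j + 1, acc, len)
  }
  recurse(1L, 1L, 0, 0L)
  best / best_len
}
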