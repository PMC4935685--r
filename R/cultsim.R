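#' Agent-based simulation of song cultural evolution
#'
#' Each singer holds a song: an ordered sequence of syllables, each a point
#' in a species-specific feature range. Every simulated year a fraction of
#' singers is replaced; each new singer builds each syllable by copying the
#' corresponding syllable of a uniformly chosen tutor from its own
#' population with probability `1 - e`, or — with probability `e`, the
#' learning-error rate — improvising it as a uniform draw from the species
#' range. A founder population is evolved to burn-in, split into two
#' daughter populations, and divergence between them is tracked over time:
#' high-fidelity learning (small `e`) lets the two isolated populations
#' drift apart culturally, while frequent improvisation keeps both spread
#' over the whole species range and prevents divergence.
#'
#' @name cultsim
NULL

#' Simulation configuration
#'
#' @param founder_size singers in the founder population (default 100).
#' @param daughter_size singers in each daughter population (default 30).
#' @param years years simulated after the split (default 200).
#' @param burn_in years the founder evolves before the split (default 50).
#' @param syllables_per_song syllables per song (default 5).
#' @param feature_dims dimensionality of syllable feature vectors (default
#'   5).
#' @param species_range 2 x feature_dims matrix of lower/upper bounds
#'   (default unit hypercube).
#' @param error_rate improvisation probability `e` in \[0,1\].
#' @param turnover_fraction fraction of singers replaced per year (default
#'   0.5, i.e. one generation-equivalent per two years).
#' @param copy_noise_sd SD of Gaussian noise added to copied syllables
#'   (default 0: copying is exact).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(founder_size = 100, daughter_size = 30, years = 200,
                       burn_in = 50, syllables_per_song = 5,
                       feature_dims = 5, species_range = NULL,
                       error_rate = 0.1, turnover_fraction = 0.5,
                       copy_noise_sd = 0, seed = 1) {
  if (is.null(species_range))
    species_range <- rbind(lo = rep(0, feature_dims),
                           hi = rep(1, feature_dims))
  stopf(error_rate >= 0 && error_rate <= 1, "error_rate must lie in [0,1]")
  stopf(founder_size >= 2 && daughter_size >= 2, "population sizes >= 2")
  stopf(years >= 1, "years must be >= 1")
  stopf(all(species_range[2, ] > species_range[1, ]),
        "species_range upper bounds must exceed lower bounds")
  structure(list(founder_size = founder_size, daughter_size = daughter_size,
                 years = years, burn_in = burn_in,
                 syllables_per_song = syllables_per_song,
                 feature_dims = feature_dims, species_range = species_range,
                 error_rate = error_rate,
                 turnover_fraction = turnover_fraction,
                 copy_noise_sd = copy_noise_sd, seed = seed),
            class = "sim_config")
}

uniform_song <- function(cfg) {
  lo <- cfg$species_range[1, ]
  hi <- cfg$species_range[2, ]
  matrix(runif(cfg$syllables_per_song * cfg$feature_dims,
               rep(lo, each = cfg$syllables_per_song),
               rep(hi, each = cfg$syllables_per_song)),
         cfg$syllables_per_song, cfg$feature_dims)
}

#' Initialize a simulated population
#'
#' @param cfg a [sim_config()].
#' @param n population size (default founder size).
#' @return object of class `sim_state`: list with `populations` (list of
#'   song lists), `year`.
#' @export
sim_init <- function(cfg, n = cfg$founder_size) {
  set.seed(derive_seed(cfg$seed, 8))
  structure(list(populations = list(replicate(n, uniform_song(cfg),
                                              simplify = FALSE)),
                 year = 0L),
            class = "sim_state")
}

#' Advance the simulation by one year
#'
#' Replaces a `turnover_fraction` of the singers in every population. Each
#' replacement learns its song syllable by syllable: with probability
#' `1 - error_rate` it copies the syllable at the same position from a
#' tutor chosen uniformly from the previous year's population; with
#' probability `error_rate` it improvises, drawing the syllable uniformly
#' from the species range. Relies on the calling context's RNG state, so a
#' fixed seed upstream gives a bit-identical trajectory.
#'
#' @param state a `sim_state`.
#' @param cfg a [sim_config()].
#' @return the advanced `sim_state`.
#' @export
step_year <- function(state, cfg) {
  state$populations <- lapply(state$populations, function(pop) {
    n <- length(pop)
    stopf(n > 0, "empty population")
    n_new <- round(cfg$turnover_fraction * n)
    if (n_new == 0) return(pop)
    replaced <- sample(n, n_new)
    tutors <- pop   # previous year's singers tutor all replacements
    lo <- cfg$species_range[1, ]
    hi <- cfg$species_range[2, ]
    for (i in replaced) {
      song <- matrix(0, cfg$syllables_per_song, cfg$feature_dims)
      for (s in seq_len(cfg$syllables_per_song)) {
        if (runif(1) < cfg$error_rate) {
          song[s, ] <- runif(cfg$feature_dims, lo, hi)
        } else {
          syl <- tutors[[sample(n, 1)]][s, ]
          if (cfg$copy_noise_sd > 0)
            syl <- clamp(syl + rnorm(cfg$feature_dims, 0, cfg$copy_noise_sd),
                         lo, hi)
          song[s, ] <- syl
        }
      }
      pop[[i]] <- song
    }
    pop
  })
  state$year <- state$year + 1L
  state
}

#' Distance between two simulated songs
#'
#' Dynamic time warping over the syllable sequences with Euclidean distance
#' between syllable feature vectors: the mean distance along the optimal
#' monotone alignment of the two sequences. Symmetric, zero iff the songs
#' are identical.
#'
#' @param s1,s2 songs (syllables x features matrices, nonempty).
#' @return nonnegative distance.
#' @export
song_distance <- function(s1, s2) {
  stopf(nrow(s1) > 0 && nrow(s2) > 0, "songs must be nonempty")
  stopf(ncol(s1) == ncol(s2), "feature dimensions differ")
  dtw_core(as.matrix(s1), as.matrix(s2))
}

# Mean pairwise song distance within a list of songs.
mean_pairwise_distance <- function(songs) {
  n <- length(songs)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + song_distance(songs[[i]], songs[[j]])
  tot / (n * (n - 1) / 2)
}

# Between-population GSI: principal-coordinates ordination of the pooled
# song distance matrix, silhouette with the two populations as clusters.
split_gsi <- function(pop1, pop2, pco_dims = 2, max_songs = 200) {
  songs <- c(pop1, pop2)
  labels <- rep(1:2, c(length(pop1), length(pop2)))
  if (length(songs) > max_songs) {
    keep <- sort(sample(length(songs), max_songs))
    songs <- songs[keep]
    labels <- labels[keep]
  }
  n <- length(songs)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- song_distance(songs[[i]], songs[[j]])
  coords <- suppressWarnings(
    cmdscale(stats::as.dist(M), k = min(pco_dims, n - 1)))
  sil <- cluster::silhouette(labels, dist = dist(coords))
  mean(sil[, "sil_width"])
}

#' Run the two-population split experiment
#'
#' Evolves a founder population for `burn_in` years, splits it into two
#' daughter populations (disjoint samples of `daughter_size` singers), then
#' evolves both for `years` years. At each sampling year the
#' between-population global silhouette index (songs ordinated by principal
#' coordinates analysis, the two populations as the two clusters) and the
#' within-population diversity (mean pairwise song distance, averaged over
#' the two populations) are recorded.
#'
#' @param cfg a [sim_config()].
#' @param sample_every record every this many years (default 10).
#' @param pco_dims principal-coordinate dimensions for the GSI ordination.
#' @return object of class `sim_trajectory`: data.frame with `year`, `gsi`,
#'   `diversity`.
#' @export
run_split_experiment <- function(cfg, sample_every = 10, pco_dims = 2) {
  state <- sim_init(cfg)
  for (y in seq_len(cfg$burn_in)) state <- step_year(state, cfg)
  founder <- state$populations[[1]]
  pick <- sample(length(founder), 2 * cfg$daughter_size)
  state$populations <- list(founder[pick[seq_len(cfg$daughter_size)]],
                            founder[pick[cfg$daughter_size +
                                           seq_len(cfg$daughter_size)]])
  state$year <- 0L
  record <- function(st) {
    data.frame(year = st$year,
               gsi = split_gsi(st$populations[[1]], st$populations[[2]],
                               pco_dims),
               diversity = mean(c(
                 mean_pairwise_distance(st$populations[[1]]),
                 mean_pairwise_distance(st$populations[[2]]))))
  }
  rows <- list(record(state))
  for (y in seq_len(cfg$years)) {
    state <- step_year(state, cfg)
    if (y %% sample_every == 0 || y == cfg$years)
      rows[[length(rows) + 1L]] <- record(state)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$year), ]
  structure(out, error_rate = cfg$error_rate,
            class = c("sim_trajectory", "data.frame"))
}

#' Sweep the split experiment over learning-error rates
#'
#' @param cfg base [sim_config()]; `error_rate` and `seed` are overridden.
#' @param error_rates vector of error rates (default
#'   `c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5)`).
#' @param replicates replicate runs per rate.
#' @param seed base seed; replicate r of rate index i runs with a seed
#'   derived from it.
#' @param ... passed to [run_split_experiment()].
#' @return data.frame with `error_rate`, `replicate`, `year`, `gsi`,
#'   `diversity`.
#' @export
simulate_error_rates <- function(cfg = sim_config(),
                                 error_rates = c(0, 0.01, 0.02, 0.05,
                                                 0.1, 0.2, 0.5),
                                 replicates = 5, seed = 1, ...) {
  rows <- list()
  for (i in seq_along(error_rates)) {
    for (r in seq_len(replicates)) {
      cfg_r <- cfg
      cfg_r$error_rate <- error_rates[i]
      cfg_r$seed <- derive_seed(seed, 20 + 10 * i + r)
      traj <- run_split_experiment(cfg_r, ...)
      rows[[length(rows) + 1L]] <- data.frame(error_rate = error_rates[i],
                                              replicate = r, traj)
    }
  }
  do.call(rbind, rows)
}

#' Expected within-population diversity under pure improvisation
#'
#' At `error_rate = 1` every syllable is an independent uniform draw from
#' the species range, so within-population diversity converges to the mean
#' [song_distance()] between two independent uniform songs. That expectation
#' has no closed form (it involves the minimum over warping paths), so it is
#' evaluated by fixed-seed Monte Carlo over independently drawn song pairs.
#'
#' @param cfg a [sim_config()].
#' @param n_pairs Monte-Carlo pairs (default 2000).
#' @param seed RNG seed.
#' @return expected mean pairwise song distance.
#' @export
expected_uniform_diversity <- function(cfg, n_pairs = 2000, seed = 1) {
  set.seed(derive_seed(seed, 9))
  mean(vapply(seq_len(n_pairs), function(i)
    song_distance(uniform_song(cfg), uniform_song(cfg)), numeric(1)))
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("Split-experiment trajectory (error rate %.3g): %d sampling points\n",
              attr(x, "error_rate"), nrow(x)))
  print.data.frame(tail(x, 3), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.sim_trajectory <- function(x, ...) {
  plot(x$year, x$gsi, type = "b", xlab = "year",
       ylab = "between-population GSI", ylim = c(-0.2, 1), ...)
  invisible(x)
}
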