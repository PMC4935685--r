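#' Dynamic-time-warping dissimilarity between song units
#'
#' Units (elements or syllables) are compared as time series of five
#' features: the four acoustic contours (fundamental frequency, mean
#' frequency, frequency change, harmonicity), each divided by its standard
#' deviation pooled over every frame of every unit in the dataset, plus time.
#' Time is the position of a frame within its unit, weighted by `q * p`
#' where `p` is the inverse duration of the longer of the two units and `q`
#' is a weighting parameter (default 5). This normalization makes overall
#' length differences count logarithmically: all else equal, 2 ms units are
#' as different from 4 ms units as 20 ms units are from 40 ms units.
#'
#' The warping path runs from the start to the end of both units with steps
#' down, right, or diagonal; the optimal path minimizes the accumulated
#' frame distance, and the dissimilarity reported is the mean frame distance
#' along that path (path sum divided by the number of cells visited).
#'
#' @name dtw
NULL

FEATURE_NAMES <- c("ff_hz", "mf_hz", "fc", "harm")

#' Extract unit contours from motifs
#'
#' Returns the per-unit feature contours the DTW functions consume. At the
#' element level each element is one unit. At the syllable level (see
#' [segment_into_syllables()]) a unit's contour is the concatenation of its
#' constituent element frames, with times measured from syllable onset in
#' real time, so within-syllable gaps remain part of the time axis but no
#' frames are invented inside them.
#'
#' Isolated missing feature values (unvoiced frames) are imputed by linear
#' interpolation from neighboring frames; units with a feature missing in
#' every frame are rejected.
#'
#' @param motifs list of [song_motif()] objects.
#' @param level `"element"` or `"syllable"`.
#' @param gap_threshold_ms syllable segmentation threshold (ms).
#' @return list of `unit_contour` objects: data.frames with columns `t_ms`,
#'   `ff_hz`, `mf_hz`, `fc`, `harm` and attributes `id`, `individual`,
#'   `population`, `motif_id`, `duration_ms`.
#' @export
unit_contours <- function(motifs, level = c("element", "syllable"),
                          gap_threshold_ms = 5) {
  level <- match.arg(level)
  out <- list()
  for (m in motifs) {
    if (level == "element") {
      for (i in seq_along(m$elements)) {
        e <- m$elements[[i]]
        out[[length(out) + 1L]] <- make_unit(
          e$frames, sprintf("%s:%s:e%d", m$individual_id, m$motif_id, i),
          m, e$duration_ms)
      }
    } else {
      syls <- segment_into_syllables(m, gap_threshold_ms)
      for (i in seq_along(syls)) {
        s <- syls[[i]]
        frames <- do.call(rbind, lapply(s$elements, function(e) {
          f <- e$frames
          f$t_ms <- f$t_ms + e$onset_ms - s$onset_ms
          f
        }))
        last <- s$elements[[length(s$elements)]]
        dur <- last$onset_ms + last$duration_ms - s$onset_ms
        out[[length(out) + 1L]] <- make_unit(
          frames, sprintf("%s:%s:s%d", m$individual_id, m$motif_id, i),
          m, dur)
      }
    }
  }
  out
}

make_unit <- function(frames, id, motif, duration_ms) {
  for (col in FEATURE_NAMES) {
    v <- frames[[col]]
    if (anyNA(v)) {
      ok <- which(is.finite(v))
      stopf(length(ok) > 0, "unit %s has no voiced frames for %s", id, col)
      frames[[col]] <- stats::approx(frames$t_ms[ok], v[ok],
                                     xout = frames$t_ms, rule = 2)$y
    }
  }
  structure(frames, id = id, individual = motif$individual_id,
            population = motif$population, motif_id = motif$motif_id,
            duration_ms = duration_ms,
            class = c("unit_contour", "data.frame"))
}

#' Pooled feature scaling for DTW
#'
#' Standard deviations of each acoustic feature pooled over all frames of
#' all units in the dataset, plus the time-weight parameter `q`. Computing
#' the SDs once over the whole dataset (rather than per population) keeps
#' dissimilarities comparable across populations and reproducible across
#' runs.
#'
#' @param units list of `unit_contour` objects (see [unit_contours()]).
#' @param q time-weight parameter (default 5).
#' @return object of class `feature_scaling`: list with `sd` (named vector
#'   over the four features) and `q`.
#' @export
feature_scaling <- function(units, q = 5) {
  stopf(q >= 0, "q must be >= 0")
  all_frames <- do.call(rbind, lapply(units, function(u) u[FEATURE_NAMES]))
  sds <- vapply(all_frames, sd, numeric(1))
  stopf(all(sds > 0), "all pooled feature SDs must be > 0 (got: %s)",
        paste(sprintf("%s=%.3g", names(sds), sds), collapse = ", "))
  structure(list(sd = sds, q = q), class = "feature_scaling")
}

#' Frame-to-frame distance
#'
#' Euclidean distance across the five normalized features:
#' `sqrt( sum_f ((a_f - b_f) / sd_f)^2 + (q * (t_a - t_b) / L_max)^2 )`,
#' where `L_max` is the duration of the longer of the two units being
#' compared.
#'
#' @param a,b named numeric vectors with entries `t_ms`, `ff_hz`, `mf_hz`,
#'   `fc`, `harm`.
#' @param scaling a [feature_scaling()].
#' @param L_max duration of the longer unit (ms, > 0).
#' @return nonnegative distance.
#' @export
frame_distance <- function(a, b, scaling, L_max) {
  stopf(L_max > 0, "L_max must be > 0")
  acc <- sum(((a[FEATURE_NAMES] - b[FEATURE_NAMES]) / scaling$sd)^2)
  tt <- (scaling$q * (a[["t_ms"]] - b[["t_ms"]]) / L_max)^2
  sqrt(acc + tt)
}

# Normalize a unit's frames into the matrix dtw_core expects.
unit_matrix <- function(u, scaling, L_max) {
  cbind(as.matrix(u[FEATURE_NAMES]) %*% diag(1 / scaling$sd),
        scaling$q * u$t_ms / L_max)
}

#' DTW dissimilarity between two units
#'
#' @param u,v `unit_contour` objects (nonempty).
#' @param scaling a [feature_scaling()].
#' @return nonnegative, symmetric dissimilarity: the mean normalized frame
#'   distance along the optimal warping path.
#' @export
dtw_distance <- function(u, v, scaling) {
  stopf(nrow(u) > 0 && nrow(v) > 0, "units must be nonempty")
  L_max <- max(attr(u, "duration_ms"), attr(v, "duration_ms"))
  dtw_core(unit_matrix(u, scaling, L_max), unit_matrix(v, scaling, L_max))
}

#' Pairwise DTW dissimilarity matrix
#'
#' Computes all pairwise [dtw_distance()] values between units and packages
#' them with unit metadata.
#'
#' @param units list of `unit_contour` objects (>= 2).
#' @param scaling a [feature_scaling()]; computed from `units` when `NULL`.
#' @param level recorded unit level (`"element"` or `"syllable"`).
#' @return object of class `song_dissim`: list with `values` (symmetric
#'   matrix with unit ids as dimnames), `meta` (data.frame `id`,
#'   `individual`, `population`, `motif_id`, `duration_ms`), `level`,
#'   `scaling`.
#' @export
pairwise_matrix <- function(units, scaling = NULL,
                            level = c("element", "syllable")) {
  level <- match.arg(level)
  n <- length(units)
  stopf(n >= 2, "need >= 2 units")
  if (is.null(scaling)) scaling <- feature_scaling(units)
  ids <- vapply(units, attr, character(1), "id")
  stopf(!anyDuplicated(ids), "unit ids must be unique")
  durs <- vapply(units, attr, numeric(1), "duration_ms")
  mats <- lapply(units, function(u)
    cbind(as.matrix(u[FEATURE_NAMES]) %*% diag(1 / scaling$sd), u$t_ms))
  D <- dtw_pairwise(mats, durs, scaling$q)
  dimnames(D) <- list(ids, ids)
  meta <- data.frame(
    id = ids,
    individual = vapply(units, attr, character(1), "individual"),
    population = vapply(units, attr, character(1), "population"),
    motif_id = vapply(units, attr, character(1), "motif_id"),
    duration_ms = durs)
  structure(list(values = D, meta = meta, level = level, scaling = scaling),
            class = "song_dissim")
}

#' Construct a song_dissim from a plain matrix
#'
#' @param values symmetric nonnegative matrix with zero diagonal.
#' @param meta optional metadata data.frame with an `id` column matching the
#'   matrix order.
#' @param level unit level label.
#' @return a `song_dissim`.
#' @export
song_dissim <- function(values, meta = NULL, level = "element") {
  values <- as.matrix(values)
  stopf(isSymmetric(unname(values), tol = 1e-8), "matrix must be symmetric")
  stopf(all(values >= 0), "dissimilarities must be >= 0")
  stopf(all(abs(diag(values)) < 1e-12), "diagonal must be zero")
  if (is.null(dimnames(values)))
    dimnames(values) <- list(paste0("u", seq_len(nrow(values))),
                             paste0("u", seq_len(nrow(values))))
  if (is.null(meta))
    meta <- data.frame(id = rownames(values),
                       individual = rownames(values),
                       population = "pop1",
                       motif_id = rownames(values),
                       duration_ms = NA_real_)
  structure(list(values = values, meta = meta, level = level,
                 scaling = NULL),
            class = "song_dissim")
}

#' @export
print.song_dissim <- function(x, ...) {
  cat(sprintf("DTW dissimilarity matrix: %d %s-level units, %d population(s)\n",
              nrow(x$values), x$level, length(unique(x$meta$population))))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.matrix.song_dissim <- function(x, ...) x$values

#' @export
as.dist.song_dissim <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' Write / read a dissimilarity matrix as CSV
#'
#' Square CSV with unit ids as header and row names.
#'
#' @param x a `song_dissim`.
#' @param path file path.
#' @rdname dissim_io
#' @export
write_dissim_csv <- function(x, path) {
  write.csv(x$values, path, row.names = TRUE)
  invisible(path)
}

#' @param level unit level for the reconstructed object.
#' @rdname dissim_io
#' @export
read_dissim_csv <- function(path, level = "element") {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  song_dissim(as.matrix(df), level = level)
}

#' Write / read a lower-triangular (PHYLIP-style) matrix
#'
#' First line holds the number of units; each following line holds a unit id
#' and its distances to all preceding units.
#'
#' @rdname dissim_io
#' @export
write_dissim_phylip <- function(x, path) {
  n <- nrow(x$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", n), con)
  for (i in seq_len(n)) {
    vals <- if (i > 1) sprintf("%.10g", x$values[i, 1:(i - 1)]) else character(0)
    writeLines(paste(c(rownames(x$values)[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname dissim_io
#' @export
read_dissim_phylip <- function(path, level = "element") {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  D <- matrix(0, n, n)
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    ids[i] <- parts[1]
    if (i > 1) {
      v <- as.numeric(parts[-1])
      D[i, 1:(i - 1)] <- v
      D[1:(i - 1), i] <- v
    }
  }
  dimnames(D) <- list(ids, ids)
  song_dissim(D, level = level)
}

# Brute-force DTW by exhaustive enumeration of all monotone warp paths.
# Independent reference used in the test-suite; exponential in frame counts,
# only feasible for tiny units.
dtw_brute_force <- function(u, v, scaling) {
  L_max <- max(attr(u, "duration_ms"), attr(v, "duration_ms"))
  A <- unit_matrix(u, scaling, L_max)
  B <- unit_matrix(v, scaling, L_max)
  n <- nrow(A); m <- nrow(B)
  local <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    local[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  best <- list(sum = Inf, len = 0L)
  recurse <- function(i, j, acc, len) {
    acc <- acc + local[i, j]
    len <- len + 1L
    if (i == n && j == m) {
      if (acc < best$sum) best <<- list(sum = acc, len = len)
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc, len)
    if (i < n) recurse(i + 1, j, acc, len)
    if (j < m) recurse(i, j + 1, acc, len)
  }
  recurse(1L, 1L, 0, 0L)
  best$sum / best$len
}
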