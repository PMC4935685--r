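#' Song data model and contour-table input/output
#'
#' A *motif* is the stereotyped sequence of song units a male repeats within a
#' song bout. At the finest grain it is segmented into *elements* (single
#' presumed vocal gestures); elements separated by short gaps are grouped into
#' *syllables*. Each element carries an acoustic feature contour: one row per
#' 0.5 ms spectrogram frame with fundamental frequency (`ff_hz`), mean
#' frequency (`mf_hz`), frequency change (`fc`, in \[0,1\], 0.5 = flat) and
#' harmonicity (`harm`, in \[0,1\]).
#'
#' The canonical interchange format is the *contour table*: delimited text,
#' UTF-8, header row, columns `individual`, `population`, `motif_id`,
#' `element_idx`, `t_ms`, `ff_hz`, `mf_hz`, `fc`, `harm`, where `t_ms` is the
#' frame time measured from motif onset. Within a motif, elements are ordered
#' by onset; consecutive onsets may overlap, so negative inter-element gaps
#' are permitted.
#'
#' @name songio
NULL

CONTOUR_COLUMNS <- c("individual", "population", "motif_id", "element_idx",
                     "t_ms", "ff_hz", "mf_hz", "fc", "harm")

#' Construct a song element
#'
#' @param frames data.frame with columns `t_ms` (time within the element,
#'   strictly increasing, starting at 0), `ff_hz`, `mf_hz`, `fc`, `harm`.
#' @param onset_ms element onset measured from motif onset (ms).
#' @param step_ms frame step (ms); used to define duration as
#'   `last t - first t + step`.
#' @return object of class `song_element`.
#' @export
song_element <- function(frames, onset_ms = 0, step_ms = 0.5) {
  stopf(is.data.frame(frames) && nrow(frames) > 0, "element needs >= 1 frame")
  need <- c("t_ms", "ff_hz", "mf_hz", "fc", "harm")
  stopf(all(need %in% names(frames)), "element frames need columns: %s",
        paste(need, collapse = ", "))
  frames <- frames[need]
  stopf(all(diff(frames$t_ms) > 0) || nrow(frames) == 1,
        "frame times must be strictly increasing")
  stopf(all(frames$ff_hz > 0), "ff_hz must be > 0")
  stopf(all(frames$mf_hz > 0), "mf_hz must be > 0")
  stopf(all(frames$fc >= 0 & frames$fc <= 1), "fc must lie in [0, 1]")
  stopf(all(frames$harm >= 0 & frames$harm <= 1), "harm must lie in [0, 1]")
  structure(
    list(frames = frames, onset_ms = onset_ms,
         duration_ms = frames$t_ms[nrow(frames)] - frames$t_ms[1] + step_ms,
         step_ms = step_ms),
    class = "song_element")
}

#' Construct a motif
#'
#' Inter-element gaps are derived from element onsets and durations:
#' `gap[i] = onset[i+1] - (onset[i] + duration[i])`. Gaps may be negative
#' (elements can overlap in time).
#'
#' @param individual_id,population,motif_id identifiers.
#' @param elements list of [song_element()] objects ordered by onset.
#' @return object of class `song_motif`.
#' @export
song_motif <- function(individual_id, population, motif_id, elements) {
  stopf(length(elements) >= 1, "motif needs >= 1 element")
  onsets <- vapply(elements, `[[`, numeric(1), "onset_ms")
  stopf(!is.unsorted(onsets), "elements must be ordered by onset")
  durs <- vapply(elements, `[[`, numeric(1), "duration_ms")
  n <- length(elements)
  gaps <- if (n > 1) onsets[-1] - (onsets[-n] + durs[-n]) else numeric(0)
  structure(
    list(individual_id = as.character(individual_id),
         population = as.character(population),
         motif_id = as.character(motif_id),
         elements = elements, gaps_ms = gaps),
    class = "song_motif")
}

#' @export
print.song_motif <- function(x, ...) {
  cat(sprintf("Motif %s (individual %s, population %s): %d elements\n",
              x$motif_id, x$individual_id, x$population, length(x$elements)))
  if (length(x$gaps_ms))
    cat("  gaps (ms):", paste(signif(x$gaps_ms, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.song_element <- function(x, ...) {
  cat(sprintf("Element: %d frames, onset %.2f ms, duration %.2f ms\n",
              nrow(x$frames), x$onset_ms, x$duration_ms))
  invisible(x)
}

# Build motif objects from a validated contour data.frame (t_ms motif-relative).
motifs_from_table <- function(df, step_ms = 0.5) {
  key <- interaction(df$individual, df$motif_id, drop = TRUE)
  out <- lapply(split(df, key), function(m) {
    els <- lapply(split(m, m$element_idx), function(e) {
      e <- e[order(e$t_ms), ]
      onset <- e$t_ms[1]
      frames <- data.frame(t_ms = e$t_ms - onset, ff_hz = e$ff_hz,
                           mf_hz = e$mf_hz, fc = e$fc, harm = e$harm)
      song_element(frames, onset_ms = onset, step_ms = step_ms)
    })
    ord <- order(vapply(els, `[[`, numeric(1), "onset_ms"))
    song_motif(m$individual[1], m$population[1], m$motif_id[1], els[ord])
  })
  names(out) <- NULL
  out
}

#' Read a contour table
#'
#' Reads a delimited contour table (see [songio]) and returns a list of
#' [song_motif()] objects. Rows violating the feature invariants (`ff_hz > 0`,
#' `mf_hz > 0`, `fc` and `harm` in \[0,1\]) or non-monotone frame times within
#' an element are reported with their line numbers.
#'
#' Files whose frame step differs from `step_ms` are resampled onto a
#' `step_ms` grid by linear interpolation (with a message).
#'
#' @param path file path.
#' @param sep field separator (`,` for CSV, `"\t"` for TSV).
#' @param step_ms canonical frame step in ms (default 0.5).
#' @return list of `song_motif` objects, grouped by individual/motif and
#'   ordered by element onset.
#' @export
read_contour_table <- function(path, sep = ",", step_ms = 0.5) {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty contour table: ", path)
    return(list())
  }
  missing_cols <- setdiff(CONTOUR_COLUMNS, names(df))
  stopf(length(missing_cols) == 0, "contour table %s lacks column(s): %s",
        path, paste(missing_cols, collapse = ", "))
  df <- df[CONTOUR_COLUMNS]
  # +1 header line -> data row i sits on file line i + 1
  bad <- which(!(df$ff_hz > 0) | !(df$mf_hz > 0) |
                 df$fc < 0 | df$fc > 1 | df$harm < 0 | df$harm > 1 |
                 !is.finite(df$t_ms))
  stopf(length(bad) == 0, "invalid feature values at line(s): %s",
        paste(bad + 1L, collapse = ", "))
  ekey <- interaction(df$individual, df$motif_id, df$element_idx, drop = TRUE)
  for (idx in split(seq_len(nrow(df)), ekey)) {
    t <- df$t_ms[idx]
    stopf(!is.unsorted(t, strictly = TRUE) || length(t) == 1,
          "non-monotone frame times within element at line(s): %s",
          paste(idx + 1L, collapse = ", "))
  }
  df <- resample_contours(df, ekey, step_ms)
  motifs_from_table(df, step_ms = step_ms)
}

# Linear-interpolation resampling of per-element contours onto a step_ms grid.
resample_contours <- function(df, ekey, step_ms) {
  steps <- unlist(lapply(split(df$t_ms, ekey), diff))
  if (length(steps) == 0 || all(abs(steps - step_ms) < 1e-9)) return(df)
  message("resampling contours to a ", step_ms, " ms frame step")
  pieces <- lapply(split(df, ekey), function(e) {
    e <- e[order(e$t_ms), ]
    if (nrow(e) == 1) return(e)
    tt <- seq(e$t_ms[1], e$t_ms[nrow(e)], by = step_ms)
    out <- e[rep(1L, length(tt)), ]
    out$t_ms <- tt
    for (col in c("ff_hz", "mf_hz", "fc", "harm"))
      out[[col]] <- stats::approx(e$t_ms, e[[col]], xout = tt)$y
    out
  })
  do.call(rbind, c(pieces, list(make.row.names = FALSE)))
}

#' Write a contour table
#'
#' Inverse of [read_contour_table()]: serializes motifs back to the canonical
#' contour-table format (frame times written motif-relative).
#'
#' @param motifs list of [song_motif()] objects.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_contour_table <- function(motifs, path, sep = ",") {
  df <- contour_table(motifs)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flatten motifs to a contour data.frame
#'
#' @param motifs list of [song_motif()] objects.
#' @return data.frame in the canonical column order (see [songio]).
#' @export
contour_table <- function(motifs) {
  pieces <- lapply(motifs, function(m) {
    el <- lapply(seq_along(m$elements), function(i) {
      e <- m$elements[[i]]
      data.frame(individual = m$individual_id, population = m$population,
                 motif_id = m$motif_id, element_idx = i,
                 t_ms = e$frames$t_ms + e$onset_ms,
                 ff_hz = e$frames$ff_hz, mf_hz = e$frames$mf_hz,
                 fc = e$frames$fc, harm = e$frames$harm)
    })
    do.call(rbind, el)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Segment a motif into syllables
#'
#' Consecutive elements separated by an inter-element gap of at most
#' `gap_threshold_ms` share a syllable; a gap strictly greater than the
#' threshold starts a new syllable. The default of 5 ms reflects the trough of
#' the bimodal inter-element gap distribution in zebra finch song; the
#' comparison is strict (`> 5` splits, `<= 5`, including negative overlap
#' gaps, joins).
#'
#' @param motif a [song_motif()].
#' @param gap_threshold_ms split threshold in ms (default 5).
#' @return list of `song_syllable` objects (fields `elements`,
#'   `internal_gaps_ms`, `onset_ms`), concatenating to the original element
#'   order.
#' @export
segment_into_syllables <- function(motif, gap_threshold_ms = 5) {
  stopf(inherits(motif, "song_motif"), "motif must be a song_motif")
  n <- length(motif$elements)
  breaks <- which(motif$gaps_ms > gap_threshold_ms)   # strict >
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    structure(
      list(elements = motif$elements[idx],
           internal_gaps_ms = if (length(idx) > 1)
             motif$gaps_ms[idx[-length(idx)]] else numeric(0),
           onset_ms = motif$elements[[idx[1]]]$onset_ms),
      class = "song_syllable")
  })
}

#' @export
print.song_syllable <- function(x, ...) {
  cat(sprintf("Syllable: %d element(s), onset %.2f ms\n",
              length(x$elements), x$onset_ms))
  invisible(x)
}

#' Inter-element gap histogram on a signed-log scale
#'
#' Collects all inter-element gaps across motifs and bins them on an
#' approximately logarithmic scale whose direction is reversed for negative
#' values: fixed 0.5 ms bins between -1 and 1 ms, doubling (log2) bin edges
#' beyond 1 ms in both directions. Birds appear to perceive temporal features
#' on a roughly logarithmic scale, which motivates the binning.
#'
#' @param motifs list of [song_motif()] objects.
#' @return object of class `gap_histogram`: data.frame with `lower`, `upper`,
#'   `count`; total count equals the number of gaps.
#' @export
gap_histogram <- function(motifs) {
  gaps <- unlist(lapply(motifs, `[[`, "gaps_ms"))
  if (length(gaps) == 0) {
    warning("no inter-element gaps present")
    return(structure(data.frame(lower = numeric(0), upper = numeric(0),
                                count = integer(0)),
                     class = c("gap_histogram", "data.frame")))
  }
  hi <- max(1, 2^ceiling(log2(max(gaps, 1))))
  lo <- -max(1, 2^ceiling(log2(max(-min(gaps, -1), 1))))
  pos <- 2^(seq(0, log2(hi)))
  neg <- -rev(2^(seq(0, log2(-lo))))
  breaks <- unique(sort(c(neg, seq(-1, 1, by = 0.5), pos)))
  counts <- hist(gaps, breaks = breaks, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  structure(data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                       count = counts),
            class = c("gap_histogram", "data.frame"))
}

#' @export
print.gap_histogram <- function(x, ...) {
  cat("Inter-element gap histogram (signed-log bins):\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
plot.gap_histogram <- function(x, ...) {
  mid <- seq_len(nrow(x))
  graphics::barplot(x$count, names.arg = sprintf("(%g,%g]", x$lower, x$upper),
                    las = 2, ylab = "count", xlab = "gap (ms)", ...)
  invisible(x)
}
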