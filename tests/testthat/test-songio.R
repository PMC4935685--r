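test_that("contour tables round-trip through write and read", {
  d <- generate_dataset(generator_spec(n_populations = 1,
                                       individuals_per_pop = 3, seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_table(d$motifs, path)
  back <- read_contour_table(path)
  expect_length(back, length(d$motifs))
  orig <- contour_table(d$motifs)
  again <- contour_table(back)
  expect_equal(again$t_ms, orig$t_ms, tolerance = 1e-8)
  expect_equal(again$ff_hz, orig$ff_hz, tolerance = 1e-8)
  expect_equal(again$harm, orig$harm, tolerance = 1e-8)
  expect_equal(vapply(back, function(m) length(m$elements), integer(1)),
               vapply(d$motifs, function(m) length(m$elements), integer(1)))
  # gap structure survives the round trip
  expect_equal(unname(unlist(lapply(back, `[[`, "gaps_ms"))),
               unname(unlist(lapply(d$motifs, `[[`, "gaps_ms"))),
               tolerance = 1e-8)
})

test_that("a written two-element fixture reads back with its frame count", {
  m <- gap_motif(gaps_ms = 2, durations_ms = c(2.5, 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_table(list(m), path)
  back <- read_contour_table(path)
  expect_length(back, 1)
  expect_length(back[[1]]$elements, 2)
  expect_equal(sum(vapply(back[[1]]$elements,
                          function(e) nrow(e$frames), integer(1))), 10)
})

test_that("malformed contour tables are rejected with line numbers", {
  d <- generate_dataset(generator_spec(n_populations = 1,
                                       individuals_per_pop = 1, seed = 22))
  df <- d$contours
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- df
  bad$harm[7] <- 1.3
  write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_contour_table(path), "line.*8")

  write.csv(df[, setdiff(names(df), "ff_hz")], path, row.names = FALSE)
  expect_error(read_contour_table(path), "ff_hz")

  bad2 <- df
  bad2$t_ms[2] <- bad2$t_ms[1] - 0.1   # non-monotone within element
  write.csv(bad2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_contour_table(path), "non-monotone")

  write.csv(df[0, ], path, row.names = FALSE)
  expect_warning(empty <- read_contour_table(path), "empty")
  expect_identical(empty, list())
})

test_that("contours on a non-canonical step are resampled to 0.5 ms", {
  m <- gap_motif(gaps_ms = numeric(0), durations_ms = 10)
  df <- contour_table(list(m))
  df <- df[seq(1, nrow(df), by = 2), ]   # 1 ms step
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_message(back <- read_contour_table(path), "resampling")
  steps <- diff(back[[1]]$elements[[1]]$frames$t_ms)
  expect_equal(unique(round(steps, 9)), 0.5)
})

test_that("syllable segmentation follows the strict 5 ms gap rule", {
  m <- gap_motif(gaps_ms = c(2, 8, 3))
  syl <- segment_into_syllables(m)
  expect_length(syl, 2)
  expect_equal(vapply(syl, function(s) length(s$elements), integer(1)),
               c(2L, 2L))

  # a gap of exactly 5 ms joins; only strictly greater splits
  expect_length(segment_into_syllables(gap_motif(5)), 1)
  expect_length(segment_into_syllables(gap_motif(5 + 1e-9)), 2)
  # overlapping elements (negative gap) share a syllable
  expect_length(segment_into_syllables(gap_motif(-1)), 1)
})

test_that("segmentation preserves order, is idempotent, and is monotone in the threshold", {
  set.seed(31)
  for (r in 1:10) {
    gaps <- runif(sample(2:8, 1), -1, 30)
    m <- gap_motif(gaps)
    syl <- segment_into_syllables(m)
    # concatenation reproduces the element order
    flat <- unlist(lapply(syl, `[[`, "elements"), recursive = FALSE)
    expect_equal(vapply(flat, `[[`, numeric(1), "onset_ms"),
                 vapply(m$elements, `[[`, numeric(1), "onset_ms"))
    # internal gaps never exceed the threshold
    expect_true(all(unlist(lapply(syl, `[[`, "internal_gaps_ms")) <= 5))
    # re-segmenting each syllable (as a motif) with the same threshold
    # changes nothing
    for (s in syl) {
      sub <- song_motif("a", "p", "m", s$elements)
      expect_length(segment_into_syllables(sub), 1)
    }
    # raising the threshold never increases the syllable count
    counts <- vapply(c(0, 2, 5, 10, 40),
                     function(th) length(segment_into_syllables(m, th)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("gap histogram conserves counts on signed-log bins", {
  m <- gap_motif(c(-1, 0.4, 2, 30))
  h <- gap_histogram(list(m))
  expect_equal(sum(h$count), 4)
  expect_gte(sum(h$count > 0), 3)
  # fixed 0.5 ms bins between -1 and 1
  inner <- h[h$lower >= -1 & h$upper <= 1, ]
  expect_true(all(abs(inner$upper - inner$lower - 0.5) < 1e-9))

  same <- gap_histogram(list(gap_motif(c(3, 3, 3))))
  expect_equal(sum(same$count > 0), 1)

  expect_warning(h0 <- gap_histogram(list(gap_motif(numeric(0)))), "no inter")
  expect_equal(nrow(h0), 0)
})

test_that("generated gaps are bimodal with a trough at the 5 ms threshold", {
  d <- generate_dataset(generator_spec(individuals_per_pop = 30, seed = 33))
  h <- gap_histogram(d$motifs)
  dens <- h$count / (h$upper - h$lower)
  short_peak <- max(dens[h$upper <= 2])
  trough <- dens[h$lower >= 4 & h$upper <= 8]
  long_peak <- max(dens[h$lower >= 16])
  expect_gt(short_peak, 2 * max(trough))
  expect_gt(long_peak, 2 * max(trough))
})
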