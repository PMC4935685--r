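test_that("frame distance follows the normalized five-feature formula", {
  sc <- unit_scaling(q = 5)
  a <- c(t_ms = 2, ff_hz = 1000, mf_hz = 2000, fc = 0.5, harm = 0.8)
  expect_identical(frame_distance(a, a, sc, L_max = 10), 0)
  # frames differing only in time by L_max / q contribute exactly 1
  b <- a; b[["t_ms"]] <- a[["t_ms"]] + 10 / sc$q
  expect_equal(frame_distance(a, b, sc, L_max = 10), 1)
  # one acoustic feature off by one pooled SD contributes exactly 1
  b2 <- a; b2[["ff_hz"]] <- a[["ff_hz"]] + sc$sd[["ff_hz"]]
  expect_equal(frame_distance(a, b2, sc, L_max = 10), 1)
  # all five terms combine in quadrature
  b3 <- a
  b3[["ff_hz"]] <- a[["ff_hz"]] + sc$sd[["ff_hz"]]
  b3[["t_ms"]] <- a[["t_ms"]] + 10 / sc$q
  expect_equal(frame_distance(a, b3, sc, L_max = 10), sqrt(2))
  expect_error(frame_distance(a, b, sc, L_max = 0), "L_max")
})

test_that("dtw distance is zero on self and symmetric", {
  sc <- unit_scaling()
  for (r in 1:10) {
    u <- random_unit(sample(3:12, 1), r)
    v <- random_unit(sample(3:12, 1), 100 + r)
    expect_identical(dtw_distance(u, u, sc), 0)
    expect_equal(dtw_distance(u, v, sc), dtw_distance(v, u, sc))
    expect_gte(dtw_distance(u, v, sc), 0)
  }
})

test_that("dtw equals exhaustive enumeration over all monotone warp paths", {
  sc <- unit_scaling()
  set.seed(17)
  for (r in 1:40) {
    u <- random_unit(sample(2:6, 1), 200 + r)
    v <- random_unit(sample(2:6, 1), 300 + r)
    expect_equal(dtw_distance(u, v, sc),
                 songculture:::dtw_brute_force(u, v, sc),
                 tolerance = 1e-9)
  }
})

test_that("length differences weigh logarithmically: 2 vs 4 ms equals 20 vs 40 ms", {
  sc <- unit_scaling()
  d_short <- dtw_distance(constant_unit(2, 5, "a"),
                          constant_unit(4, 9, "b"), sc)
  d_long <- dtw_distance(constant_unit(20, 5, "c"),
                         constant_unit(40, 9, "d"), sc)
  expect_equal(d_short, d_long, tolerance = 1e-9)
  expect_gt(d_short, 0)
  # general time-scale invariance for an arbitrary warped pair
  u <- random_unit(7, 41); v <- random_unit(5, 42)
  u10 <- u; u10$t_ms <- u$t_ms * 10
  attr(u10, "duration_ms") <- attr(u, "duration_ms") * 10
  v10 <- v; v10$t_ms <- v$t_ms * 10
  attr(v10, "duration_ms") <- attr(v, "duration_ms") * 10
  expect_equal(dtw_distance(u, v, sc), dtw_distance(u10, v10, sc),
               tolerance = 1e-9)
})

test_that("the pairwise matrix matches independent per-pair computations", {
  units <- lapply(1:12, function(i) random_unit(sample(3:10, 1), 400 + i))
  D <- pairwise_matrix(units, level = "element")
  sc <- D$scaling
  expect_true(isSymmetric(unname(D$values)))
  expect_true(all(diag(D$values) == 0))
  for (i in c(1, 4)) for (j in c(7, 12))
    expect_equal(D$values[i, j], dtw_distance(units[[i]], units[[j]], sc),
                 tolerance = 1e-12)
  # identical units give zeros
  same <- lapply(1:3, function(i) {
    u <- constant_unit(10, 8, paste0("s", i))
    u
  })
  D0 <- pairwise_matrix(same, scaling = unit_scaling(), level = "element")
  expect_true(all(D0$values == 0))
  # permuting unit order permutes rows/columns consistently
  perm <- c(3, 1, 2, 7, 12, 5, 4, 6, 9, 8, 11, 10)
  Dp <- pairwise_matrix(units[perm], scaling = sc, level = "element")
  expect_equal(unname(Dp$values), unname(D$values[perm, perm]),
               tolerance = 1e-12)
})

test_that("syllable-level contours keep real time and motif gaps", {
  m <- gap_motif(c(2, 8), durations_ms = c(5, 5, 5))
  u <- unit_contours(list(m), "syllable")
  expect_length(u, 2)   # first two elements joined by the 2 ms gap
  # time axis of the joined syllable includes the 2 ms gap
  expect_equal(max(u[[1]]$t_ms), 5 + 2 + 4.5)
  expect_equal(attr(u[[1]], "duration_ms"), 12)
  expect_equal(nrow(u[[1]]), 20)   # frames only, none inside the gap
})

test_that("dissimilarity matrices survive CSV and PHYLIP round trips", {
  units <- lapply(1:6, function(i) random_unit(5, 500 + i))
  D <- pairwise_matrix(units, level = "element")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dissim_csv(D, csv)
  back <- read_dissim_csv(csv)
  expect_equal(unname(back$values), unname(D$values), tolerance = 1e-6)
  expect_identical(rownames(back$values), rownames(D$values))
  phy <- withr::local_tempfile(fileext = ".txt")
  write_dissim_phylip(D, phy)
  back2 <- read_dissim_phylip(phy)
  expect_equal(unname(back2$values), unname(D$values), tolerance = 1e-8)
})

test_that("units with isolated unvoiced frames are imputed, fully unvoiced rejected", {
  m <- gap_motif(numeric(0), durations_ms = 6)
  m$elements[[1]]$frames$ff_hz[3] <- NA
  u <- unit_contours(list(m), "element")
  expect_false(anyNA(u[[1]]$ff_hz))
  m2 <- gap_motif(numeric(0), durations_ms = 6)
  m2$elements[[1]]$frames$ff_hz[] <- NA
  expect_error(unit_contours(list(m2), "element"), "no voiced frames")
})
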