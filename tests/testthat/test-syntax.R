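test_that("transition bias formula behaves at its anchor points", {
  # two motifs engineered so A->B is observed twice and B->A never
  seqs <- list(c("A", "B"), c("A", "B"))
  tb <- transition_bias(seqs)
  expect_true(all(tb$bias >= -1 & tb$bias <= 1))
  expect_equal(sum(tb$p_obs), 1)
  # B->A expected but never observed: bias exactly -1
  expect_equal(tb$bias[tb$from == "B" & tb$to == "A"], -1)
  # expected under independence but never observed: bias -1
  expect_equal(tb$bias[tb$from == "START" & tb$to == "END"], -1)
  # START row p_obs mass equals motifs / total transitions
  expect_equal(sum(tb$p_obs[tb$from == "START"]), 2 / 6)

  # direct arithmetic anchors of (p_obs - p_exp) / max(p_obs, p_exp)
  bias_of <- function(p_obs, p_exp)
    if (max(p_obs, p_exp) == 0) 0 else (p_obs - p_exp) / max(p_obs, p_exp)
  expect_equal(bias_of(0.2, 0.2), 0)
  expect_equal(bias_of(0.2, 0.1), 0.5)
  expect_equal(bias_of(0, 0.3), -1)

  expect_error(transition_bias(seqs, types = "A"), "not in")
})

test_that("planted start/end position biases surface in the table", {
  # slide-like type S opens motifs, flat-like type F closes them
  set.seed(61)
  seqs <- replicate(60, c("S", sample(c("X", "Y"), 3, TRUE), "F"),
                    simplify = FALSE)
  tb <- transition_bias(seqs)
  expect_gt(tb$bias[tb$from == "START" & tb$to == "S"], 0.5)
  expect_gt(tb$bias[tb$from == "F" & tb$to == "END"], 0.5)
  expect_equal(tb$bias[tb$from == "START" & tb$to == "F"], -1)
  expect_equal(tb$bias[tb$from == "S" & tb$to == "END"], -1)
})

test_that("types-per-motif permutation test detects over- and under-dispersion", {
  # every motif holds one unit of each of 5 types: more types than chance
  over <- replicate(20, sample(paste0("t", 1:5)), simplify = FALSE)
  r_over <- types_per_motif_test(over, n_perm = 400, seed = 2)
  expect_gt(r_over$observed, r_over$null_mean)
  expect_lt(r_over$p_value, 0.01)

  # strong within-motif repetition: fewer types than chance
  set.seed(62)
  under <- replicate(20, rep(sample(paste0("t", 1:5), 1), 5),
                     simplify = FALSE)
  r_under <- types_per_motif_test(under, n_perm = 400, seed = 3)
  expect_lt(r_under$observed, r_under$null_mean)
  expect_lt(r_under$p_value, 0.01)

  # single type everywhere: degenerate, p = 1
  mono <- replicate(10, rep("t1", 4), simplify = FALSE)
  r_mono <- types_per_motif_test(mono, n_perm = 100, seed = 4)
  expect_equal(r_mono$observed, 1)
  expect_equal(r_mono$null_mean, 1)
  expect_equal(r_mono$p_value, 1)

  # permutation stays within populations; singleton populations are dropped
  expect_warning(
    types_per_motif_test(over, populations = c("a", rep("b", 19)),
                         n_perm = 50, seed = 5),
    "single motif")
})

test_that("Markov redundancy hits its analytic anchors", {
  # deterministic alternation: fully predictable
  cyc <- replicate(10, rep(c("A", "B"), 10), simplify = FALSE)
  expect_equal(markov_redundancy(cyc), 1)

  # iid uniform: redundancy tends to 0
  set.seed(63)
  iid <- replicate(80, sample(paste0("t", 1:4), 30, TRUE), simplify = FALSE)
  expect_lt(markov_redundancy(iid), 0.03)

  # 3-state chain with known transition matrix: matches analytic value
  P <- matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3,
              byrow = TRUE)
  seqs <- sample_markov_sequences(P, 2000, motif_len = 15, seed = 64)
  expect_lt(abs(markov_redundancy(seqs) - analytic_redundancy(P)), 0.01)

  # invariant under relabeling of types
  relab <- lapply(seqs, function(s) c(t1 = "zz", t2 = "qq", t3 = "aa")[s])
  expect_equal(markov_redundancy(relab), markov_redundancy(seqs))

  expect_error(markov_redundancy(list(rep("A", 5))), "single type")
})

test_that("greedy syntactic search never decreases its objective", {
  set.seed(65)
  d <- generate_dataset(generator_spec(
    n_populations = 1, individuals_per_pop = 8,
    transition_matrix = symmetric_chain(4, 0.4),
    templates = element_templates()[1:4, ], seed = 66))
  u <- unit_contours(d$motifs, "element")
  D <- pairwise_matrix(u, level = "element")
  ids <- vapply(u, attr, character(1), "id")
  motifs_idx <- split(seq_along(ids),
                      sub(":e[0-9]+$", "", ids))[unique(sub(":e[0-9]+$", "", ids))]
  seq_idx <- unname(motifs_idx)
  pam0 <- pam_cluster(D, 4)$labels
  r0 <- songculture:::labelled_redundancy(as.integer(pam0), seq_idx, 4)
  fit <- songculture:::run_syntax_search(D$values, seq_idx, 4,
                                         restarts = 3, seed = 9)
  expect_gte(fit$redundancy, r0 - 1e-12)
  expect_true(all(tabulate(fit$labels, 4) > 0))
})

test_that("the redundancy scan corrects away its own bias on structureless data", {
  # iid coordinates, no syntax: corrected redundancy ~ 0 with a CI covering 0
  set.seed(67)
  n_ind <- 40; per <- 8; n <- n_ind * per
  X <- matrix(rnorm(n * 4), n)
  D <- song_dissim(as.matrix(dist(X)))
  D$meta$individual <- rep(paste0("ind", seq_len(n_ind)), each = per)
  seqs <- unname(split(D$meta$id, rep(seq_len(n_ind), each = per)))
  scan <- syntactic_redundancy_scan(D, seqs, k_range = c(2, 4),
                                    null_reps = 3, boot_reps = 100,
                                    seed = 5, restarts = 3, null_dims = 30)
  expect_true(all(scan$corrected <= scan$redundancy + 1e-12))
  expect_true(all(abs(scan$corrected) < 0.05))
  expect_true(all(scan$ci99_lo <= 0 & scan$ci99_hi >= 0))
  expect_true(all(scan$ci99_lo <= scan$corrected &
                    scan$corrected <= scan$ci99_hi))
})
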