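# Exchangeable-unit fixture: n units on 2-D Gaussian coordinates with
# individuals of `units_per_ind` units each, split over groups.
null_groups_dissim <- function(n_ind = 12, units_per_ind = 4, n_groups = 2,
                               seed = 1) {
  set.seed(seed)
  n <- n_ind * units_per_ind
  X <- matrix(rnorm(n * 2), n)
  D <- song_dissim(as.matrix(dist(X)))
  D$meta$individual <- rep(paste0("ind", seq_len(n_ind)),
                           each = units_per_ind)
  D$meta$population <- rep(rep(paste0("g", seq_len(n_groups)),
                               length.out = n_ind), each = units_per_ind)
  D
}

test_that("the MRPP effect size identity reproduces the element-level worked example", {
  expect_equal(round(mrpp_effect_size(0.2841, 0.2887), 4), 0.0159)
  # and the syllable-level companion values
  expect_equal(round(mrpp_effect_size(0.2818, 0.2879), 4), 0.0212,
               tolerance = 1e-4)
})

test_that("MRPP output always satisfies A = 1 - delta / m_delta", {
  D <- null_groups_dissim(seed = 71)
  r <- mrpp(D, n_perm = 300, seed = 1)
  expect_equal(r$A, 1 - r$delta / r$m_delta)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  # exchangeable units: tiny effect size
  expect_lt(abs(r$A), 0.05)
})

test_that("MRPP flags fully separated groups and excludes tiny ones", {
  set.seed(72)
  X <- rbind(matrix(rnorm(20 * 2), 20), matrix(rnorm(24 * 2), 24) + 20)
  D <- song_dissim(as.matrix(dist(X)))
  D$meta$individual <- rep(paste0("i", 1:11), each = 4)
  groups <- rep(c("a", "b"), c(20, 24))
  r <- mrpp(D, groups = groups, n_perm = 199, seed = 2)
  expect_lt(r$delta, r$m_delta)
  # only a permutation reproducing the original split can tie delta
  expect_lte(r$p_value, 2 / 200)
  expect_gt(r$A, 0.5)

  groups_bad <- c("solo", groups[-1])
  expect_warning(mrpp(D, groups = groups_bad, n_perm = 50, seed = 3),
                 "excluding group")
})

test_that("unit-level MRPP agrees with the vegan reference implementation", {
  D <- null_groups_dissim(seed = 73)
  groups <- D$meta$population
  ours <- mrpp(D, groups = groups, n_perm = 500, seed = 4,
               unit_of_permutation = "unit")
  ref <- vegan::mrpp(stats::as.dist(D$values), grouping = groups,
                     permutations = 500)
  expect_equal(ours$delta, ref$delta, tolerance = 1e-10)
  # permutation means agree statistically (independent shuffles)
  expect_equal(ours$m_delta, ref$E.delta, tolerance = 0.01)
  expect_equal(ours$A, 1 - ref$delta / ref$E.delta, tolerance = 0.01)
})

test_that("coarser groupings cannot beat the grouping that carries the signal", {
  # population-level signal: 4 populations with distinct centers, pooled
  # pairwise into 2 "continents"
  set.seed(74)
  centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4), 4, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(12 * 2), 12), 2, centers[i, ], `+`)))
  D <- song_dissim(as.matrix(dist(X)))
  D$meta$individual <- rep(paste0("i", 1:16), each = 3)
  pops <- rep(paste0("p", 1:4), each = 12)
  conts <- rep(c("c1", "c1", "c2", "c2"), each = 12)
  a_pop <- mrpp(D, groups = pops, n_perm = 300, seed = 5)$A
  a_cont <- mrpp(D, groups = conts, n_perm = 300, seed = 5)$A
  expect_gt(a_pop, a_cont)
})

test_that("permutation chi-square matches the analytic statistic and Cramer's V anchors", {
  # perfect association
  r1 <- type_frequency_test(rep(c("A", "B"), each = 10),
                            rep(c("g1", "g2"), each = 10),
                            n_perm = 99, seed = 6)
  expect_equal(r1$cramers_v, 1)
  expect_lt(r1$p_perm, 0.05)

  # exactly proportional table: no association at all
  types <- rep(c("A", "A", "B"), times = 4)
  groups <- rep(c("g1", "g2"), each = 6)
  r2 <- type_frequency_test(types, groups, n_perm = 99, seed = 7)
  expect_equal(r2$chi2, 0)
  expect_equal(r2$cramers_v, 0)
  expect_gt(r2$p_perm, 0.9)

  # 3 x 4 toy table against the standard Pearson computation
  set.seed(75)
  t3 <- sample(c("x", "y", "z"), 120, TRUE, prob = c(0.5, 0.3, 0.2))
  g4 <- sample(paste0("g", 1:4), 120, TRUE)
  r3 <- type_frequency_test(t3, g4, n_perm = 99, seed = 8)
  ref <- suppressWarnings(stats::chisq.test(table(t3, g4), correct = FALSE))
  expect_equal(r3$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r3$df, unname(ref$parameter))
  expect_equal(r3$cramers_v,
               sqrt(r3$chi2 / (120 * min(3 - 1, 4 - 1))), tolerance = 1e-12)
})

test_that("spatial medians minimize summed distances", {
  expect_equal(spatial_median(matrix(c(3, 7), 1)), c(3, 7))
  sq <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  expect_equal(spatial_median(sq), c(1, 1), tolerance = 1e-6)
  # 3 non-collinear points against a brute-force grid search
  pts <- rbind(c(0, 0), c(4, 0), c(1, 3))
  med <- spatial_median(pts)
  obj <- function(p) sum(sqrt(colSums((t(pts) - p)^2)))
  grid <- expand.grid(x = seq(0, 4, by = 0.01), y = seq(0, 3, by = 0.01))
  vals <- sqrt((grid$x - pts[1, 1])^2 + (grid$y - pts[1, 2])^2) +
    sqrt((grid$x - pts[2, 1])^2 + (grid$y - pts[2, 2])^2) +
    sqrt((grid$x - pts[3, 1])^2 + (grid$y - pts[3, 2])^2)
  best <- grid[which.min(vals), ]
  expect_lt(sqrt(sum((med - c(best$x, best$y))^2)), 0.02)
  expect_lte(obj(med), min(vals) + 1e-9)
})

test_that("neighbor joining reproduces additive distances exactly", {
  # 3-taxon closed form: pendant branches (1, 2, 3)
  M <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_dendrogram(M)
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  expect_equal(as.matrix(cophenetic(tr))[rownames(M), colnames(M)], M,
               tolerance = 1e-9)

  # distances from a known random 5-taxon additive tree are recovered
  set.seed(76)
  true_tree <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  M5 <- cophenetic(true_tree)
  rec <- nj_dendrogram(M5)
  expect_equal(as.matrix(cophenetic(rec))[rownames(M5), colnames(M5)],
               M5, tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(true_tree), rec), 0,
               ignore_attr = TRUE)
})

test_that("group medians feed a dendrogram end to end", {
  set.seed(77)
  centers <- matrix(c(0, 0, 6, 0, 0, 6, 8, 8), 4, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(10 * 2), 10), 2, centers[i, ], `+`)))
  ord <- list(coords = X)
  gm <- group_medians(ord, rep(paste0("p", 1:4), each = 10))
  expect_equal(dim(gm$medians), c(4, 2))
  expect_true(all(abs(gm$medians - centers) < 1))
  tr <- nj_dendrogram(gm$distances)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, paste0("p", 1:4))
  nwk <- ape::write.tree(tr)
  expect_match(nwk, "^\\(.*\\);$")
})
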