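#' Population divergence statistics
#'
#' Tests of whether song structure differs between groups (populations or
#' continents): the multiresponse permutation procedure (MRPP) on the DTW
#' dissimilarities, a permutation chi-square test with Cramer's V on type
#' usage frequencies, spatial (geometric) medians in ordination space, and
#' neighbor-joining dendrograms of the between-group median distances.
#' Because the sampling unit is the individual male (all units of a bird
#' move together), permutations shuffle individuals between groups by
#' default.
#'
#' @name divergence
NULL

# delta: weighted mean within-group dissimilarity, weights n_g / N.
mrpp_delta <- function(M, group_idx, n_total) {
  d <- 0
  for (idx in group_idx) {
    ng <- length(idx)
    d <- d + (ng / n_total) *
      (sum(M[idx, idx]) / (ng * (ng - 1)))
  }
  d
}

# Reassign groups at the individual level, preserving how many individuals
# each group holds; returns the permuted per-unit group vector.
permute_individuals <- function(unit_indiv, indiv_group) {
  new_group <- setNames(sample(indiv_group), names(indiv_group))
  as.character(new_group[unit_indiv])
}

#' Multiresponse permutation procedure
#'
#' Compares the observed weighted mean within-group dissimilarity (delta)
#' with its distribution under random reassignment of individuals to groups
#' (all of an individual's units move together, group sizes in individuals
#' preserved). The effect size is `A = 1 - delta / m_delta`, with `m_delta`
#' the mean permuted delta; `A > 0` means units are more similar within
#' groups than expected. The p-value is the add-one lower tail,
#' `p = (#{delta_perm <= delta_obs} + 1) / (n_perm + 1)`.
#'
#' @param D a `song_dissim`.
#' @param groups group label per unit; defaults to `D$meta$population`.
#' @param individuals individual label per unit; defaults to
#'   `D$meta$individual`. Used when `unit_of_permutation = "individual"`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param unit_of_permutation `"individual"` (default) or `"unit"`; the
#'   latter shuffles single units and matches conventional MRPP
#'   implementations.
#' @return object of class `mrpp_result`: `delta`, `m_delta`, `A`,
#'   `p_value`, `n_perm`, `groups_used`.
#' @export
mrpp <- function(D, groups = NULL, individuals = NULL, n_perm = 10000,
                 seed = 1, unit_of_permutation = c("individual", "unit")) {
  unit_of_permutation <- match.arg(unit_of_permutation)
  M <- D$values
  if (is.null(groups)) groups <- D$meta$population
  if (is.null(individuals)) individuals <- D$meta$individual
  groups <- as.character(groups)
  individuals <- as.character(individuals)
  stopf(length(groups) == nrow(M) && length(individuals) == nrow(M),
        "groups/individuals must have one label per unit")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 units: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    M <- M[keep, keep]
    groups <- groups[keep]
    individuals <- individuals[keep]
  }
  stopf(length(unique(groups)) >= 2, "need >= 2 groups with >= 2 units")
  n <- nrow(M)
  delta_of <- function(g) mrpp_delta(M, split(seq_len(n), g), n)
  delta <- delta_of(groups)
  indiv_group <- vapply(split(groups, individuals), `[`, character(1), 1)
  set.seed(derive_seed(seed, 6))
  perm_delta <- vapply(seq_len(n_perm), function(r) {
    g <- if (unit_of_permutation == "individual")
      permute_individuals(individuals, indiv_group) else sample(groups)
    delta_of(g)
  }, numeric(1))
  m_delta <- mean(perm_delta)
  structure(list(delta = delta, m_delta = m_delta,
                 A = 1 - delta / m_delta,
                 p_value = (sum(perm_delta <= delta) + 1) / (n_perm + 1),
                 n_perm = n_perm,
                 groups_used = sort(unique(groups)),
                 unit_of_permutation = unit_of_permutation),
            class = "mrpp_result")
}

#' MRPP effect size from delta and its permutation expectation
#'
#' `A = 1 - delta / m_delta`: the chance-corrected within-group agreement.
#'
#' @param delta observed weighted mean within-group dissimilarity.
#' @param m_delta mean of the permuted deltas.
#' @return effect size `A`.
#' @export
mrpp_effect_size <- function(delta, m_delta) 1 - delta / m_delta

#' @export
print.mrpp_result <- function(x, ...) {
  cat(sprintf("MRPP (%s-level permutation, %d permutations):\n",
              x$unit_of_permutation, x$n_perm))
  cat(sprintf("  delta = %.4f, m_delta = %.4f, A = %.4f, p = %.4g\n",
              x$delta, x$m_delta, x$A, x$p_value))
  invisible(x)
}

# Pearson chi-square and Cramer's V of a contingency table (no continuity
# correction); expected counts from analytic margins.
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expd)^2 / expd)
  v <- sqrt(chi2 / (n * min(nrow(tab) - 1, ncol(tab) - 1)))
  list(chi2 = chi2, df = (nrow(tab) - 1) * (ncol(tab) - 1), cramers_v = v,
       expected = expd)
}

#' Permutation chi-square test of type usage by group
#'
#' Pearson chi-square on the type x group contingency table (expected counts
#' from analytic margins), with the p-value taken from a permutation
#' distribution in which individuals are shuffled between groups. Cramer's V
#' (`sqrt(chi2 / (N * min(r-1, c-1)))`, in \[0,1\]) quantifies the strength
#' of association. Empty rows or columns are dropped with a warning and the
#' degrees of freedom adjusted.
#'
#' @param type_labels type per unit.
#' @param groups group per unit.
#' @param individuals individual per unit (required for individual-level
#'   permutation; defaults to unit-level labels).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return object of class `contingency_result`: `chi2`, `df`, `p_perm`,
#'   `cramers_v`, `observed`, `expected`, `perm_expected` (mean permuted
#'   cell counts).
#' @export
type_frequency_test <- function(type_labels, groups, individuals = NULL,
                                n_perm = 10000, seed = 1) {
  type_labels <- as.character(type_labels)
  groups <- as.character(groups)
  if (is.null(individuals)) individuals <- seq_along(type_labels)
  individuals <- as.character(individuals)
  stopf(length(groups) == length(type_labels), "length mismatch")
  tab <- table(type_labels, groups)
  empty_r <- rownames(tab)[rowSums(tab) == 0]
  empty_c <- colnames(tab)[colSums(tab) == 0]
  if (length(empty_r) || length(empty_c))
    warning("dropping empty row(s)/column(s): ",
            paste(c(empty_r, empty_c), collapse = ", "))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  stopf(nrow(tab) >= 2 && ncol(tab) >= 2,
        "need >= 2 types and >= 2 groups")
  obs <- chisq_stat(tab)
  indiv_group <- vapply(split(groups, individuals), `[`, character(1), 1)
  types_f <- factor(type_labels, levels = rownames(tab))
  groups_lv <- colnames(tab)
  set.seed(derive_seed(seed, 7))
  perm_counts <- matrix(0, nrow(tab), ncol(tab))
  exceed <- 0L
  for (r in seq_len(n_perm)) {
    g <- permute_individuals(individuals, indiv_group)
    ptab <- table(types_f, factor(g, levels = groups_lv))
    perm_counts <- perm_counts + ptab
    if (chisq_stat(ptab)$chi2 >= obs$chi2 - 1e-12) exceed <- exceed + 1L
  }
  structure(list(chi2 = obs$chi2, df = obs$df,
                 p_perm = (exceed + 1) / (n_perm + 1),
                 cramers_v = obs$cramers_v,
                 observed = tab, expected = obs$expected,
                 perm_expected = perm_counts / n_perm,
                 n_perm = n_perm),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Permutation chi-square: chi2 = %.3f, df = %d, permuted p = %.4g, Cramer's V = %.3f\n",
              x$chi2, x$df, x$p_perm, x$cramers_v))
  invisible(x)
}

#' Spatial (geometric) median of a point cloud
#'
#' The point minimizing the summed Euclidean distances to the group's
#' ordination coordinates, found by iteratively reweighted averaging
#' (Weiszfeld) to a tolerance of 1e-9.
#'
#' @param coords numeric matrix (points x dimensions); a single point is its
#'   own median.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return numeric vector of length `ncol(coords)`.
#' @export
spatial_median <- function(coords, tol = 1e-9, max_iter = 1000) {
  coords <- as.matrix(coords)
  stopf(nrow(coords) >= 1, "need >= 1 point")
  if (nrow(coords) == 1) return(as.numeric(coords[1, ]))
  if (nrow(coords) == 2) return(as.numeric(colMeans(coords)))
  y <- colMeans(coords)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(coords, 2, y)^2))
    on_point <- d < 1e-12
    off <- !on_point
    w <- 1 / d[off]
    t_y <- colSums(coords[off, , drop = FALSE] * w) / sum(w)
    if (any(on_point)) {
      # Vardi-Zhang safeguard when the iterate coincides with a data point
      r_vec <- colSums(sweep(coords[off, , drop = FALSE], 2, y) * w)
      r <- sqrt(sum(r_vec^2))
      eta <- sum(on_point)
      if (r <= eta) return(as.numeric(y))   # the data point is the median
      step <- min(1, eta / r)
      y_new <- (1 - step) * t_y + step * y
    } else {
      y_new <- t_y
    }
    if (sqrt(sum((y_new - y)^2)) < tol) return(as.numeric(y_new))
    y <- y_new
  }
  warning("spatial median did not converge within ", max_iter, " iterations")
  as.numeric(y)
}

#' Neighbor-joining dendrogram of group medians
#'
#' Builds a Saitou-Nei neighbor-joining tree from a symmetric matrix of
#' distances between group spatial medians; branch lengths correspond to
#' median dissimilarities, and additive input distances are reproduced
#' exactly. Negative branch lengths (possible for non-additive input) are
#' clamped to zero with a warning.
#'
#' @param M symmetric nonnegative distance matrix with group names as
#'   dimnames (>= 3 groups).
#' @return an [ape::nj()] `phylo` tree.
#' @export
nj_dendrogram <- function(M) {
  M <- as.matrix(M)
  stopf(nrow(M) >= 3, "need >= 3 groups")
  stopf(isSymmetric(unname(M), tol = 1e-8), "M must be symmetric")
  stopf(all(M >= 0), "M must be nonnegative")
  tree <- ape::nj(stats::as.dist(M))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Group medians from an ordination
#'
#' Convenience: spatial median of each group's NMDS coordinates plus the
#' Euclidean distances between medians, ready for [nj_dendrogram()].
#'
#' @param ordination a `song_nmds` (see [nmds_embed()]).
#' @param groups group label per point.
#' @return list with `medians` (groups x dims) and `distances` (symmetric
#'   matrix).
#' @export
group_medians <- function(ordination, groups) {
  coords <- ordination$coords
  groups <- as.character(groups)
  stopf(length(groups) == nrow(coords), "one group label per point required")
  med <- t(vapply(split(seq_len(nrow(coords)), groups),
                  function(idx) spatial_median(coords[idx, , drop = FALSE]),
                  numeric(ncol(coords))))
  list(medians = med, distances = as.matrix(dist(med)))
}
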