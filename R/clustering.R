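#' Cluster discovery and validation for song units
#'
#' Species-wide unit categories are sought by partitioning the DTW
#' dissimilarity matrix around medoids (PAM) and validating candidate
#' cluster numbers with a null-corrected global silhouette index (GSI). An
#' independent route ordinates the matrix into Euclidean space by non-metric
#' multidimensional scaling (NMDS) and fits Gaussian mixture models whose
#' components are then merged by estimated misclassification probability;
#' agreement between the routes is quantified by the adjusted Rand index.
#'
#' @name clustering
NULL

#' Partitioning around medoids on a dissimilarity matrix
#'
#' Runs the PAM algorithm (BUILD then SWAP until no improving swap) directly
#' on the dissimilarities, assigning each unit to its nearest medoid, and
#' attaches the global silhouette index of the solution.
#'
#' @param D a `song_dissim` (see [pairwise_matrix()]).
#' @param k number of clusters, `2 <= k < n`.
#' @return object of class `song_partition`: list with `labels` (named
#'   integer vector), `k`, `medoids` (unit ids), `gsi` (mean silhouette
#'   width), `silhouette` (per-unit widths).
#' @export
pam_cluster <- function(D, k) {
  n <- nrow(D$values)
  stopf(k >= 2 && k < n, "k must satisfy 2 <= k < n (n = %d)", n)
  fit <- cluster::pam(stats::as.dist(D$values), k = k, diss = TRUE)
  sil <- cluster::silhouette(fit$clustering, dmatrix = D$values)
  labels <- fit$clustering
  names(labels) <- rownames(D$values)
  structure(list(labels = labels, k = k, medoids = fit$medoids,
                 gsi = mean(sil[, "sil_width"]),
                 silhouette = sil[, "sil_width"]),
            class = "song_partition")
}

#' @export
print.song_partition <- function(x, ...) {
  cat(sprintf("Partition into k = %d clusters", x$k))
  if (!is.null(x$gsi)) cat(sprintf(" (GSI = %.3f)", x$gsi))
  cat("\n  sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

# Mean silhouette width of a PAM solution on a plain matrix.
pam_gsi <- function(M, k) {
  fit <- cluster::pam(stats::as.dist(M), k = k, diss = TRUE)
  mean(cluster::silhouette(fit$clustering, dmatrix = M)[, "sil_width"])
}

#' Null-corrected global silhouette scan
#'
#' For each candidate `k`, the global silhouette index (GSI, the mean
#' silhouette width over all units, range -1 to 1) of the PAM solution is
#' computed. Because GSI is biased upward on structureless data, a null
#' correction is subtracted: reference datasets are drawn as independent
#' Gaussian samples whose per-dimension standard deviations match an NMDS
#' ordination of the empirical matrix, and the mean GSI of PAM solutions on
#' their Euclidean distance matrices (same `k`) is the null level. A clear
#' peak in the corrected GSI indicates a clustering tendency at that `k`.
#'
#' @param D a `song_dissim`.
#' @param k_range candidate cluster numbers (default `2:20`, truncated to
#'   `n - 1`).
#' @param null_reps number of null datasets per `k` (default 10).
#' @param null_dim NMDS dimensionality used to calibrate the null (default 5).
#' @param seed RNG seed.
#' @return object of class `gsi_scan`: data.frame with `k`, `gsi`,
#'   `null_gsi`, `corrected_gsi`; attribute `best_k` is the `k` maximizing
#'   the corrected GSI.
#' @export
gsi_scan <- function(D, k_range = 2:20, null_reps = 10, null_dim = 5,
                     seed = 1) {
  n <- nrow(D$values)
  stopf(n >= 4, "need at least 4 units")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  stopf(length(k_range) > 0, "k_range empty after truncation to [2, n-1]")
  null_dim <- min(null_dim, n - 2)
  ord <- suppressWarnings(nmds_embed(D, d = null_dim, seed = seed, n_starts = 5))
  sds <- apply(ord$coords, 2, sd)
  set.seed(derive_seed(seed, 1))
  nulls <- lapply(seq_len(null_reps), function(r) {
    X <- matrix(rnorm(n * null_dim), n) %*% diag(sds, null_dim)
    as.matrix(dist(X))
  })
  rows <- lapply(k_range, function(k) {
    g <- pam_gsi(D$values, k)
    g0 <- mean(vapply(nulls, pam_gsi, numeric(1), k = k))
    data.frame(k = k, gsi = g, null_gsi = g0, corrected_gsi = g - g0)
  })
  out <- do.call(rbind, rows)
  structure(out, best_k = out$k[which.max(out$corrected_gsi)],
            class = c("gsi_scan", "data.frame"))
}

#' @export
print.gsi_scan <- function(x, ...) {
  cat("Null-corrected global silhouette scan (best k =",
      attr(x, "best_k"), "):\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.gsi_scan <- function(x, ...) {
  plot(x$k, x$corrected_gsi, type = "b", xlab = "k",
       ylab = "corrected GSI", ...)
  graphics::abline(v = attr(x, "best_k"), lty = 2)
  invisible(x)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal-style NMDS (monotone regression, stress-1) from multiple starts:
#' the first start is the metric (principal coordinates) configuration, the
#' rest are random; the lowest-stress solution is kept. Variance explained
#' is the squared correlation between configuration distances and the input
#' dissimilarities.
#'
#' @param D a `song_dissim`.
#' @param d embedding dimensionality (>= 1).
#' @param seed RNG seed.
#' @param n_starts number of starts (default 20).
#' @return object of class `song_nmds`: list with `coords` (n x d),
#'   `stress` (Kruskal stress-1), `var_explained`, `converged`.
#' @export
nmds_embed <- function(D, d = 2, seed = 1, n_starts = 20) {
  stopf(d >= 1, "d must be >= 1")
  n <- nrow(D$values)
  dd <- stats::as.dist(D$values)
  set.seed(derive_seed(seed, 2))
  best <- NULL
  for (s in seq_len(n_starts)) {
    y <- if (s == 1) NULL else matrix(rnorm(n * d), n)
    fit <- tryCatch({
      if (is.null(y)) vegan::monoMDS(dd, k = d, maxit = 500,
                                     smin = 1e-7, sratmax = 1 - 1e-7)
      else vegan::monoMDS(dd, y = y, k = d, maxit = 500,
                          smin = 1e-7, sratmax = 1 - 1e-7)
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
      best <- fit
  }
  stopf(!is.null(best), "NMDS failed in all starts")
  if (best$icause == 1L)   # terminated by hitting the iteration cap
    warning("NMDS did not converge; best configuration kept")
  coords <- best$points
  rownames(coords) <- rownames(D$values)
  ve <- cor(as.numeric(dist(coords)), as.numeric(dd))^2
  structure(list(coords = coords, stress = best$stress, var_explained = ve,
                 converged = best$icause != 1L),
            class = "song_nmds")
}

#' @export
print.song_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d points in %d dimension(s), stress %.4g, %.1f%% variance explained\n",
              nrow(x$coords), ncol(x$coords), x$stress,
              100 * x$var_explained))
  invisible(x)
}

#' Gaussian mixture clustering with component merging
#'
#' Fits Gaussian mixtures with unconstrained covariances ("VVV") by EM for
#' `k = 1..max_k`, selects `k` by BIC (ties toward smaller `k`), then merges
#' component pairs while their directly estimated misclassification
#' probability — the posterior mass of one component's points assigned to
#' the other — exceeds `merge_threshold`. Merging mixture components
#' recognizes that several Gaussians may jointly describe one non-Gaussian
#' cluster.
#'
#' @param X numeric matrix of ordination coordinates (n x d).
#' @param max_k maximum number of mixture components.
#' @param merge_threshold misclassification probability above which a pair
#'   of components is merged (default 0.025).
#' @return object of class `song_partition` with extra fields `k_mixture`
#'   (components before merging) and `merge_path` (sequence of merged
#'   pairs).
#' @export
gmm_merge_cluster <- function(X, max_k = 10, merge_threshold = 0.025) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopf(n > ncol(X) + 1, "need n > d + 1")
  # Mclust resolves its worker functions in the caller's environment
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(X, G = 1:max_k, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit))   # VVV can fail on degenerate data; fall back
    fit <- mclust::Mclust(X, G = 1:max_k, verbose = FALSE)
  stopf(!is.null(fit), "mixture fitting failed")
  z <- fit$z
  if (is.null(z) || fit$G == 1) z <- matrix(1, n, 1)
  merge_path <- list()
  repeat {
    G <- ncol(z)
    if (G == 1) break
    hard <- max.col(z)
    # misclassification probability between each ordered pair (i -> j):
    # expected fraction of component i's posterior mass classified as j
    q <- matrix(0, G, G)
    for (i in seq_len(G)) {
      wi <- sum(z[, i])
      if (wi > 0)
        for (j in seq_len(G)) if (j != i)
          q[i, j] <- sum(z[hard == j, i]) / wi
    }
    pairq <- pmax(q, t(q))
    worst <- which(pairq == max(pairq), arr.ind = TRUE)[1, ]
    if (pairq[worst[1], worst[2]] <= merge_threshold) break
    a <- min(worst); b <- max(worst)
    merge_path[[length(merge_path) + 1L]] <- c(a, b)
    z[, a] <- z[, a] + z[, b]
    z <- z[, -b, drop = FALSE]
  }
  labels <- max.col(z)
  names(labels) <- rownames(X)
  structure(list(labels = labels, k = ncol(z), medoids = NULL, gsi = NULL,
                 k_mixture = fit$G, merge_path = merge_path),
            class = "song_partition")
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-adjusted agreement between two labelings of the same
#' units: 0 is the chance level, 1 means identical assignments (up to
#' relabeling).
#'
#' @param p1,p2 `song_partition` objects or plain label vectors of equal
#'   length.
#' @return adjusted Rand index.
#' @export
adjusted_rand <- function(p1, p2) {
  l1 <- if (inherits(p1, "song_partition")) p1$labels else p1
  l2 <- if (inherits(p2, "song_partition")) p2$labels else p2
  stopf(length(l1) == length(l2),
        "partitions cover different unit sets (%d vs %d)",
        length(l1), length(l2))
  mclust::adjustedRandIndex(l1, l2)
}
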