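# Internal helpers shared across modules.

# Plug-in Shannon entropy (natural log) of a count vector, with optional
# Miller-Madow small-sample correction: H_hat + (m - 1) / (2 N), where m is
# the number of observed (nonzero) categories and N the total count.
entropy_counts <- function(counts, correct = TRUE) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0L) return(0)
  p <- counts / n
  h <- -sum(p * log(p))
  if (correct && n > 0) h <- h + (length(counts) - 1) / (2 * n)
  h
}

# Deterministic child seeds derived from a user seed (kept well below 2^31).
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 100000L) * 1000L + as.integer(index) %% 1000L
}

# Stop unless a condition holds, with sprintf-style message.
stopf <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Moving-average smoother used for generating smooth (autocorrelated) noise.
smooth_noise <- function(n, sd, span = 9L) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  span <- max(1L, min(span, n))
  x <- rnorm(n + span - 1L)
  k <- rep(1 / span, span)
  y <- as.numeric(stats::filter(x, k, sides = 1))[span:(n + span - 1L)]
  # restore unit variance after averaging, then scale
  y * sd * sqrt(span)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
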