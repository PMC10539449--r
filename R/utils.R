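# Internal helpers shared across the simulation and analysis pipelines.

#' @import stats
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a master seed and a label.
# Keeps results below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(master, ...) {
  label <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Run `expr` under a local RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle in degrees to (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Minimum-jerk scalar profile s(x) on x in [0, 1]: position fraction,
# with zero velocity and acceleration at both ends.
minjerk_pos <- function(x) 10 * x^3 - 15 * x^4 + 6 * x^5

# Its derivative (velocity fraction per unit normalised time); peak 1.875 at x = 0.5.
minjerk_vel <- function(x) 30 * x^2 - 60 * x^3 + 30 * x^4

# Interpolate a min-jerk point-to-point trajectory at times `t`.
# Before t0 holds p0; after t0 + T holds p1. Returns a matrix (length(t) x 3).
minjerk_path <- function(t, t0, T, p0, p1) {
  if (!length(t)) return(matrix(numeric(), 0, 3))
  x <- pmin(pmax((t - t0) / T, 0), 1)
  s <- minjerk_pos(x)
  outer(s, p1 - p0) + matrix(p0, nrow = length(t), ncol = 3, byrow = TRUE)
}

# Binary entropy in bits, 0 at p in {0, 1}.
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

# Truncated-normal sampler by rejection (bounds are loose in practice).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# Central-difference derivative with one-sided endpoints.
central_diff <- function(y, t) {
  n <- length(y)
  if (n < 3) stop("central_diff needs at least 3 samples")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  idx <- 2:(n - 1)
  d[idx] <- (y[idx + 1] - y[idx - 1]) / (t[idx + 1] - t[idx - 1])
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase (forward-backward) filtering with odd-reflection padding at both
# ends, so start-up transients decay inside the padding rather than biasing
# the signal edges.
filtfilt_refl <- function(bf, y) {
  n <- length(y)
  pad <- min(n - 1, 36)
  head_pad <- 2 * y[1] - y[(pad + 1):2]
  tail_pad <- 2 * y[n] - y[(n - 1):(n - pad)]
  yy <- c(head_pad, y, tail_pad)
  out <- signal::filtfilt(bf, yy)
  out[(pad + 1):(pad + n)]
}
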