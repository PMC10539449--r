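# Independent brute-force oracles used to cross-check pipeline stages.
# These deliberately recompute everything from definitions and stay free of
# the package's optimised code paths.

# I-DT segmentation with dispersion re-enumerated over all pairs at every
# growth step (O(n^2) per window).
oracle_idt <- function(yaw, pitch, valid, dt, dispersion_max = 3,
                       min_duration = 0.1) {
  full_disp <- function(i, j) {
    y <- yaw[i:j]; p <- pitch[i:j]
    if (j == i) return(0)
    m <- 0
    for (a in seq_along(y)) for (b in seq_along(y)) {
      d <- sqrt((y[a] - y[b])^2 + (p[a] - p[b])^2)
      if (d > m) m <- d
    }
    m
  }
  res <- list()
  runs <- rle(valid)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  for (r in which(runs$values)) {
    lo <- starts[r]; hi <- ends[r]
    i <- lo
    while (i <= hi) {
      j <- i
      while (j < hi && full_disp(i, j + 1) <= dispersion_max) j <- j + 1
      if ((j - i + 1) * dt >= min_duration - 1e-9) {
        res[[length(res) + 1]] <- c(i, j)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  res
}

# Per-sample transverse-plane angle maximum, recomputed directly.
oracle_rom <- function(hx, hz, hyaw, cx, cz) {
  best <- NA_real_
  for (i in seq_along(hx)) {
    dx <- cx[i] - hx[i]; dz <- cz[i] - hz[i]
    if (dx^2 + dz^2 < 1e-12) next
    fx <- sin(hyaw[i] * pi / 180); fz <- cos(hyaw[i] * pi / 180)
    ang <- acos(max(min((dx * fx + dz * fz) / sqrt(dx^2 + dz^2), 1), -1)) * 180 / pi
    if (is.na(best) || ang > best) best <- ang
  }
  best
}

# Exhaustive rank-count Mann-Whitney U (pairs with x > y; ties half).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
  }
  u
}

# Textbook cell-mean sums of squares for the balanced 2 (between) x 2
# (within) mixed design.
oracle_mixed_ss <- function(g1, g2) {
  k <- 2; n <- nrow(g1); N <- 2 * n
  y <- rbind(g1, g2)
  gm <- mean(y)
  gmeans <- c(mean(g1), mean(g2))
  cmeans <- colMeans(y)
  cell <- rbind(colMeans(g1), colMeans(g2))
  smeans <- rowMeans(y)
  ss_group <- k * n * sum((gmeans - gm)^2)
  ss_subj <- k * sum((smeans - rep(gmeans, each = n))^2)
  ss_cond <- N * sum((cmeans - gm)^2)
  ss_int <- n * sum((cell - outer(gmeans, rep(1, k)) -
                       outer(rep(1, 2), cmeans) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_werr <- ss_total - ss_group - ss_subj - ss_cond - ss_int
  list(group = ss_group, subj = ss_subj, cond = ss_cond, int = ss_int,
       werr = ss_werr, total = ss_total)
}

# JZS Bayes factor by quadrature over the effect-size scale directly
# (noncentral-t marginal against a Cauchy prior), independent of the
# g-mixture route the package integrates.
oracle_jzs <- function(t, n_eff, nu, r = sqrt(2) / 2) {
  alt <- suppressWarnings(stats::integrate(function(d) {
    vapply(d, function(dd) stats::dt(t, nu, ncp = dd * sqrt(n_eff)), 0) *
      stats::dcauchy(d, 0, r)
  }, -Inf, Inf, rel.tol = 1e-12)$value)
  alt / suppressWarnings(stats::dt(t, nu))
}
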