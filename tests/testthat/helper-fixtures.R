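# Fixtures and independent oracles used across the suite. Oracles are
# implemented here from first principles, independently of the package code
# paths they check.

# Logical disc mask on an nr x nc canvas (pixel-center inclusion).
disc_mask <- function(nr, nc, cy, cx, r) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# Rotated-ellipse mask (semi-axes a, b; rotation theta in radians), centered.
rotated_ellipse_mask <- function(size, a, b, theta) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size) - ctr
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  u <- cols * cos(theta) + rows * sin(theta)
  v <- -cols * sin(theta) + rows * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# Exhaustive between-class-variance maximiser over all 256 candidate levels:
# the definitional form of the Otsu criterion, computed by plain loops.
otsu_brute_force <- function(image) {
  h <- tabulate(as.vector(image) + 1L, nbins = 256L)
  n <- sum(h)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    n0 <- sum(h[1:(t + 1)])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * h[1:(t + 1)]) / n0
    mu1 <- sum(((t + 1):255) * h[(t + 2):256]) / n1
    v <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Shoelace polygon area, written independently of the package internals.
shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Two-level synthetic image: one disc of gray `fg` on background `bg`.
two_tone_disc_image <- function(size = 128, r = 30, fg = 200L, bg = 50L) {
  m <- disc_mask(size, size, (size + 1) / 2, (size + 1) / 2, r)
  img <- matrix(bg, size, size)
  img[m] <- fg
  storage.mode(img) <- "integer"
  list(image = img, mask = m)
}

# A step PSD series: monodisperse at d_lo before t_step, at d_hi after.
step_psd_series <- function(t_step_s = 300 * 60, interval_s = 285,
                            t_end_s = 600 * 60, d_lo = 3, d_hi = 1000) {
  bins <- psd_bins(60)
  times <- seq(0, t_end_s, by = interval_s)
  lo_bin <- findInterval(d_lo, bins$edges)
  hi_bin <- findInterval(d_hi, bins$edges)
  vf <- matrix(0, length(times), length(bins$centers))
  vf[times < t_step_s, lo_bin] <- 1
  vf[times >= t_step_s, hi_bin] <- 1
  size_distribution_series(times, bins$centers, vf)
}

# Series with given per-snapshot (median, smd)-defining two-bin mixtures is
# awkward; for adversarial SMD-vs-median ordering we build snapshots directly.
two_bin_series <- function(times_s, centers, w_hi) {
  vf <- cbind(1 - w_hi, w_hi)
  size_distribution_series(times_s, centers, vf)
}
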