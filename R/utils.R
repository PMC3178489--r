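# Internal helpers shared across modules.

# Run `expr` with a private RNG state seeded by `seed`, restoring the caller's
# stream afterwards so simulators never perturb the global RNG.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    stop(sprintf("`%s` = %g is outside its valid range %s%g, %g]",
                 name, x, if (strict_min) "(" else "[", min, max),
         call. = FALSE)
  }
  invisible(x)
}

# Shoelace signed area of a polygon given as x/y vectors (not closed).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# Second central moments of a polygon (area-normalised covariance matrix),
# via the standard shoelace-type moment formulas. Used for polygon-exact
# ground truth of the moment-equivalent ellipse.
polygon_covariance <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  s <- sign(a)
  a <- abs(a)
  cx <- s * sum((x + x[j]) * cross) / (6 * a)
  cy <- s * sum((y + y[j]) * cross) / (6 * a)
  ixx <- s * sum((y^2 + y * y[j] + y[j]^2) * cross) / 12      # integral y^2 dA
  iyy <- s * sum((x^2 + x * x[j] + x[j]^2) * cross) / 12      # integral x^2 dA
  ixy <- s * sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cross) / 24
  sxx <- iyy / a - cx^2
  syy <- ixx / a - cy^2
  sxy <- ixy / a - cx * cy
  list(area = a, centroid = c(cx, cy),
       cov = matrix(c(sxx, sxy, sxy, syy), 2, 2))
}

# Full major/minor axis lengths of the moment-equivalent ellipse from an
# area-normalised covariance matrix (for a filled ellipse with semi-axes a, b
# the variance along the major axis is a^2/4, hence full axis = 4*sqrt(lambda)).
axes_from_covariance <- function(cov) {
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

max_pairwise_distance <- function(x, y) {
  if (length(x) == 1L) return(0)
  ## distances only among convex hull vertices
  h <- grDevices::chull(x, y)
  d <- as.matrix(stats::dist(cbind(x[h], y[h])))
  max(d)
}
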