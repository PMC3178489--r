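#' Specify a synthetic fungal particle
#'
#' A `shape_spec` describes one synthetic particle archetype spanning the
#' morphological continuum of filamentous fungi in submerged culture: smooth
#' round pellets (`disc`), elongated smooth particles (`ellipse`),
#' rough-surfaced pellets (`rough_pellet`), elongated irregular aggregates
#' (`clump`) and dispersed filamentous growth (`mycelium`).
#'
#' For `rough_pellet` and `clump` the boundary is a harmonic perturbation of a
#' circle, `r(theta) = r0 * (1 + sum_k a_k cos(k*theta + phi_k))` with
#' `k = 2..roughness_order` and random amplitudes `a_k` (seeded) scaled so that
#' `sum |a_k| = roughness_amplitude`. This keeps the boundary star-shaped and
#' gives a generating polygon from which exact ground-truth measurements are
#' computed. Clumps additionally stretch the x axis by `elongation`.
#'
#' @param shape_class one of `"disc"`, `"ellipse"`, `"rough_pellet"`,
#'   `"clump"`, `"mycelium"`.
#' @param radius_px semi-major extent of the particle in pixels (for
#'   `mycelium`, the extent scale of the filament network).
#' @param elongation major/minor axis ratio, >= 1. Must be 1 for `disc` and
#'   `rough_pellet`.
#' @param roughness_amplitude total relative boundary perturbation, in
#'   `[0, 0.5)`. Must be 0 for `disc` and `ellipse`.
#' @param roughness_order highest angular harmonic (integer >= 2).
#' @param seed integer seed controlling the random harmonics / filament walk.
#' @return an object of class `fm_shape_spec`.
#' @seealso [render_particle()]
#' @export
shape_spec <- function(shape_class = c("disc", "ellipse", "rough_pellet",
                                       "clump", "mycelium"),
                       radius_px, elongation = 1, roughness_amplitude = 0,
                       roughness_order = 8L, seed = 1L) {
  shape_class <- match.arg(shape_class)
  stop_if_not_scalar_number(radius_px, "radius_px", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(elongation, "elongation", min = 1)
  stop_if_not_scalar_number(roughness_amplitude, "roughness_amplitude",
                            min = 0, max = 0.5 - 1e-12)
  stop_if_not_scalar_number(roughness_order, "roughness_order", min = 2)
  if (shape_class %in% c("disc", "rough_pellet") && elongation != 1) {
    stop(sprintf("shape class '%s' requires elongation = 1", shape_class),
         call. = FALSE)
  }
  if (shape_class %in% c("disc", "ellipse") && roughness_amplitude != 0) {
    stop(sprintf("shape class '%s' requires roughness_amplitude = 0",
                 shape_class), call. = FALSE)
  }
  structure(
    list(shape_class = shape_class, radius_px = radius_px,
         elongation = elongation, roughness_amplitude = roughness_amplitude,
         roughness_order = as.integer(roughness_order),
         seed = as.integer(seed)),
    class = "fm_shape_spec"
  )
}

# Random boundary harmonics for rough_pellet/clump; returns a function
# rho(theta) giving the relative radial perturbation.
roughness_profile <- function(spec) {
  if (spec$roughness_amplitude == 0) return(function(theta) rep(0, length(theta)))
  ks <- 2:spec$roughness_order
  with_seed(spec$seed, {
    a <- stats::runif(length(ks), 0.2, 1) * sample(c(-1, 1), length(ks), TRUE)
    phi <- stats::runif(length(ks), 0, 2 * pi)
    a <- a / sum(abs(a)) * spec$roughness_amplitude
    function(theta) {
      out <- numeric(length(theta))
      for (i in seq_along(ks)) out <- out + a[i] * cos(ks[i] * theta + phi[i])
      out
    }
  })
}

# Generating boundary polygon (x, y) around the origin, in pixel units.
shape_polygon <- function(spec, n_vertices = 2048L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  a <- spec$radius_px
  b <- spec$radius_px / spec$elongation
  rho <- roughness_profile(spec)(theta)
  list(x = a * (1 + rho) * cos(theta), y = b * (1 + rho) * sin(theta))
}

#' Render a synthetic particle image with analytic ground truth
#'
#' Rasterises a [shape_spec()] into an 8-bit grayscale image (one bright
#' particle on a darker background) and returns a ground-truth record of its
#' geometry: closed forms for discs and ellipses, polygon-exact values
#' (shoelace area, convex hull of the generating polygon, polygon moment
#' ellipse) for rough pellets and clumps. For `mycelium` only the projected
#' area is available; all other descriptors are `NA`, mirroring the fact that
#' dispersed mycelial growth has no measurable particle geometry.
#'
#' @param spec a [shape_spec()].
#' @param image_size side length of the square image in pixels.
#' @param scale_um_per_px physical pixel size; ground truth lengths/areas are
#'   reported in scaled units.
#' @param foreground,background gray levels (0-255) of particle and backdrop.
#' @return a list of class `fm_particle_image` with elements `image` (integer
#'   matrix, 0-255), `mask` (logical matrix), `truth` (one-row data.frame with
#'   columns shape_class, area, convex_area, perimeter, max_diameter,
#'   major_axis, minor_axis, circularity, solidity, aspect_ratio,
#'   morphology_number, seed, scale_um_per_px).
#' @export
render_particle <- function(spec, image_size = 512L, scale_um_per_px = 1,
                            foreground = 200L, background = 50L) {
  stopifnot(inherits(spec, "fm_shape_spec"))
  stop_if_not_scalar_number(image_size, "image_size", min = 16)
  stop_if_not_scalar_number(scale_um_per_px, "scale_um_per_px",
                            min = 0, strict_min = TRUE)
  image_size <- as.integer(image_size)
  extent <- spec$radius_px * (1 + spec$roughness_amplitude)
  if (spec$shape_class != "mycelium" && 2 * extent > image_size - 4) {
    stop(sprintf(paste0("particle exceeds image bounds: maximal extent ",
                        "%.1f px does not fit in a %d px image"),
                 2 * extent, image_size), call. = FALSE)
  }

  cx <- (image_size + 1) / 2
  cy <- (image_size + 1) / 2
  s <- scale_um_per_px

  if (spec$shape_class == "mycelium") {
    mask <- draw_mycelium(spec, image_size, cx, cy)
    truth <- data.frame(
      shape_class = "mycelium", area = sum(mask) * s^2,
      convex_area = NA_real_, perimeter = NA_real_, max_diameter = NA_real_,
      major_axis = NA_real_, minor_axis = NA_real_, circularity = NA_real_,
      solidity = NA_real_, aspect_ratio = NA_real_,
      morphology_number = NA_real_,
      seed = spec$seed, scale_um_per_px = s,
      stringsAsFactors = FALSE
    )
  } else {
    mask <- rasterize_shape(spec, image_size, cx, cy)
    truth <- shape_ground_truth(spec, s)
  }

  img <- matrix(as.integer(background), image_size, image_size)
  img[mask] <- as.integer(foreground)
  structure(list(image = img, mask = mask, truth = truth, spec = spec),
            class = "fm_particle_image")
}

# Inside test for star-shaped boundaries: scale to unit coordinates, compare
# polar radius with 1 + rho(theta).
rasterize_shape <- function(spec, image_size, cx, cy) {
  a <- spec$radius_px
  b <- spec$radius_px / spec$elongation
  xs <- (seq_len(image_size) - cx) / a
  ys <- (seq_len(image_size) - cy) / b
  u <- matrix(xs, image_size, image_size, byrow = TRUE)  # column -> x
  v <- matrix(ys, image_size, image_size)                # row -> y
  r <- sqrt(u^2 + v^2)
  if (spec$roughness_amplitude == 0) return(r <= 1)
  rho <- roughness_profile(spec)
  theta <- atan2(v, u)
  r <= 1 + matrix(rho(as.vector(theta)), image_size, image_size)
}

shape_ground_truth <- function(spec, s) {
  a <- spec$radius_px
  b <- spec$radius_px / spec$elongation
  if (spec$shape_class %in% c("disc", "ellipse")) {
    area <- pi * a * b
    convex_area <- area
    ## Ramanujan's ellipse perimeter approximation (exact for the disc)
    h <- ((a - b) / (a + b))^2
    perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
    major <- 2 * a
    minor <- 2 * b
    maxd <- 2 * a
  } else {
    poly <- shape_polygon(spec)
    area <- polygon_area(poly$x, poly$y)
    hidx <- grDevices::chull(poly$x, poly$y)
    convex_area <- polygon_area(poly$x[hidx], poly$y[hidx])
    perim <- polygon_perimeter(poly$x, poly$y)
    maxd <- max_pairwise_distance(poly$x, poly$y)
    axes <- axes_from_covariance(polygon_covariance(poly$x, poly$y)$cov)
    major <- axes[["major"]]
    minor <- axes[["minor"]]
  }
  sol <- min(area / convex_area, 1)
  ar <- major / minor
  circ <- min(4 * pi * area / perim^2, 1)
  mn <- morphology_number(area, sol, maxd, ar)
  data.frame(
    shape_class = spec$shape_class, area = area * s^2,
    convex_area = convex_area * s^2, perimeter = perim * s,
    max_diameter = maxd * s, major_axis = major * s, minor_axis = minor * s,
    circularity = circ, solidity = sol, aspect_ratio = ar,
    morphology_number = mn, seed = spec$seed, scale_um_per_px = s,
    stringsAsFactors = FALSE
  )
}

# Filament network as a seeded correlated random walk with side branches,
# painted at 1 px line width.
draw_mycelium <- function(spec, image_size, cx, cy) {
  mask <- matrix(FALSE, image_size, image_size)
  lim <- spec$radius_px
  paint <- function(x0, y0, x1, y1) {
    n <- max(2L, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
    xs <- round(cx + seq(x0, x1, length.out = n))
    ys <- round(cy + seq(y0, y1, length.out = n))
    ok <- xs >= 1 & xs <= image_size & ys >= 1 & ys <= image_size
    mask[cbind(ys[ok], xs[ok])] <<- TRUE
  }
  with_seed(spec$seed, {
    n_branch <- 12L
    for (br in seq_len(n_branch)) {
      x <- stats::runif(1, -lim / 4, lim / 4)
      y <- stats::runif(1, -lim / 4, lim / 4)
      ang <- stats::runif(1, 0, 2 * pi)
      step <- lim / 12
      for (k in seq_len(24L)) {
        ang <- ang + stats::rnorm(1, 0, 0.5)
        x1 <- x + step * cos(ang)
        y1 <- y + step * sin(ang)
        x1 <- max(min(x1, lim), -lim)
        y1 <- max(min(y1, lim), -lim)
        paint(x, y, x1, y1)
        x <- x1; y <- y1
      }
    }
  })
  mask
}

#' @export
print.fm_particle_image <- function(x, ...) {
  cat(sprintf("<synthetic particle: %s, %d x %d px>\n",
              x$truth$shape_class, nrow(x$image), ncol(x$image)))
  print(x$truth, row.names = FALSE)
  invisible(x)
}
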