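#' Convert an image to 8-bit grayscale
#'
#' Accepts an integer/double matrix (gray) or an H x W x C array (color, e.g.
#' as returned by [png::readPNG()]). Values already on the 0-255 integer scale
#' are returned unchanged; values in `[0, 1]` are rescaled to 0-255. Color
#' input is combined with Rec. 601 luminance weights (0.299 R + 0.587 G +
#' 0.114 B).
#'
#' @param image matrix or 3-d array of finite values.
#' @return integer matrix with values in 0-255.
#' @export
to_grayscale_8bit <- function(image) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  if (!all(is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    w <- switch(as.character(min(nc, 3L)),
                "1" = 1, "2" = c(1, 0), "3" = c(0.299, 0.587, 0.114))
    w <- w / sum(w)
    gray <- matrix(0, dim(image)[1], dim(image)[2])
    for (k in seq_along(w)) gray <- gray + w[k] * image[, , k]
    image <- gray
  }
  if (!is.matrix(image)) stop("image must be a matrix or 3-d array", call. = FALSE)
  mx <- max(image)
  if (mx <= 1) {
    out <- round(image * 255)
  } else {
    if (mx > 255) stop("gray levels above 255 are not 8-bit", call. = FALSE)
    out <- round(image)
  }
  storage.mode(out) <- "integer"
  out
}

#' Otsu threshold of an 8-bit grayscale image
#'
#' Finds the gray level maximising the between-class variance over all 256
#' candidate levels (the Otsu criterion); ties are broken toward the lowest
#' level. A threshold `t` splits pixels into classes `<= t` and `> t`.
#'
#' @param image 8-bit grayscale matrix (coerced via [to_grayscale_8bit()]).
#' @param polarity `"bright"` if the particles are the brighter class (the
#'   convention of the synthetic renderer), `"dark"` for dark particles on a
#'   bright background.
#' @return list with `threshold` (integer, 0-254), `binary` (logical matrix,
#'   TRUE = particle) and `polarity`.
#' @export
otsu_threshold <- function(image, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  image <- to_grayscale_8bit(image)
  counts <- tabulate(as.vector(image) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    stop("no threshold exists: image has fewer than 2 distinct gray levels",
         call. = FALSE)
  }
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts) / n                    # weight of class <= t
  m0 <- cumsum(counts * levels) / n           # partial mean sum
  mt <- m0[256]
  t_all <- 1:255                              # candidate thresholds t = 0..254
  w <- w0[t_all]
  mu0 <- m0[t_all] / w
  mu1 <- (mt - m0[t_all]) / (1 - w)
  sigma_b <- w * (1 - w) * (mu0 - mu1)^2
  sigma_b[!is.finite(sigma_b)] <- -Inf
  thr <- levels[which.max(sigma_b)]           # lowest maximiser
  binary <- if (polarity == "bright") image > thr else image <= thr
  list(threshold = as.integer(thr), binary = binary, polarity = polarity)
}

# Connected-component labeling on the pixel lattice via graph components.
# 8-connectivity for foreground particles (ImageJ convention),
# 4-connectivity for background when filling holes.
label_components <- function(mask, connectivity = 8L) {
  idx <- which(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(labels)
  nr <- nrow(mask)
  nc <- ncol(mask)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  id_of <- match(seq_len(nr * nc), idx)  # pixel index -> vertex id (NA if bg)
  edges <- vector("list", length(shifts))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    r2 <- r + dr; c2 <- c_ + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    nb_id <- id_of[nb]
    keep <- !is.na(nb_id)
    edges[[k]] <- cbind(which(ok)[keep], nb_id[keep])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(e) && nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connected) not reachable from the image border are
#' set to foreground. Measurements treat particles as filled silhouettes.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  holes <- bg > 0L & !(bg %in% border_labels)
  mask | holes
}

#' Extract particles from a binary image
#'
#' Labels 8-connected foreground components, removes components smaller than
#' `min_area` (in px^2) and, optionally, components touching the image border
#' (both ImageJ analyze-particles conventions). An empty result is valid and
#' indicates purely mycelial material downstream.
#'
#' @param binary logical matrix (TRUE = particle).
#' @param min_area minimum component area in pixels.
#' @param exclude_border drop components touching the border?
#' @return list of particle masks; each element is a list with `mask` (cropped
#'   logical matrix), `offset` (row/col of the crop origin) and `id`.
#' @export
extract_particles <- function(binary, min_area = 50, exclude_border = TRUE) {
  if (!is.logical(binary)) stop("`binary` must be a logical matrix", call. = FALSE)
  labels <- label_components(binary, connectivity = 8L)
  n <- max(labels)
  if (n == 0L) return(list())
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(labels == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    if (exclude_border && k %in% border) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    m[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
    out[[length(out) + 1L]] <- list(mask = m, offset = c(r0, c0),
                                    id = length(out) + 1L)
  }
  out
}

# Moore-neighbour boundary trace; returns the chain-code step counts
# (straight / diagonal) of the outer boundary.
trace_boundary_steps <- function(mask) {
  nr <- nrow(mask) + 2L
  nc <- ncol(mask) + 2L
  m <- matrix(FALSE, nr, nc)
  m[2:(nr - 1L), 2:(nc - 1L)] <- mask
  start <- which(m)[1]                       # first TRUE in column-major order
  sr <- ((start - 1L) %% nr) + 1L
  sc <- ((start - 1L) %/% nr) + 1L
  ## clockwise neighbour order starting east (dr, dc)
  nbr <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L,
                  0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L),
                ncol = 2L, byrow = TRUE)
  r <- sr; c_ <- sc
  dir <- 7L                                  # backtrack points north-ish
  n_straight <- 0L
  n_diag <- 0L
  max_steps <- 4L * sum(mask) + 8L
  first_move <- NULL
  steps <- 0L
  repeat {
    found <- FALSE
    for (i in 0:7) {
      d <- (dir + i) %% 8L
      rr <- r + nbr[d + 1L, 1L]
      cc <- c_ + nbr[d + 1L, 2L]
      if (m[rr, cc]) {
        if (d %% 2L == 0L) n_straight <- n_straight + 1L else n_diag <- n_diag + 1L
        r <- rr; c_ <- cc
        dir <- (d + 6L) %% 8L               # new search start: backtrack + 2
        if (is.null(first_move)) first_move <- d
        found <- TRUE
        break
      }
    }
    if (!found) break                        # isolated pixel
    steps <- steps + 1L
    if (r == sr && c_ == sc && steps > 1L) break
    if (steps > max_steps) break
  }
  c(straight = n_straight, diagonal = n_diag)
}

#' Measure the geometry of one particle mask
#'
#' Computes the per-particle geometric quantities underlying the shape
#' descriptors: projected area (pixel count), perimeter (Moore boundary chain
#' code with Kulpa length correction, 0.948 per straight and 1.340 per
#' diagonal step, which removes the ~5% digitisation bias of raw chain-code
#' length), convex area (hull of the boundary-pixel corner points, so that
#' `convex_area >= area` always holds), maximal Feret diameter (largest
#' pairwise distance over hull vertices) and the major/minor axes of the
#' moment-equivalent ellipse (pixel-center second moments plus the 1/12
#' per-pixel variance). Interior holes are filled before measuring. A
#' single-pixel particle is measured with degenerate conventions (perimeter 4,
#' axes 1 px, aspect ratio 1).
#'
#' @param mask logical matrix containing one connected particle.
#' @param scale_um_per_px physical pixel size; lengths scale by it, areas by
#'   its square, descriptors are unaffected.
#' @param particle_id identifier copied into the output row.
#' @param diameter `"feret"` (default; the maximal diameter of the pellet) or
#'   `"ellipse"` to use the moment-ellipse major axis as D instead.
#' @return one-row data.frame with columns `particle_id, area, perimeter,
#'   convex_area, max_diameter, major_axis, minor_axis, circularity,
#'   circularity_raw, solidity, solidity_raw, aspect_ratio, morphology_number,
#'   morphology_number_raw, scale_um_per_px`.
#' @export
measure_particle <- function(mask, scale_um_per_px = 1, particle_id = 1L,
                             diameter = c("feret", "ellipse")) {
  diameter <- match.arg(diameter)
  if (!is.logical(mask) || !any(mask)) {
    stop("`mask` must be a logical matrix with at least one TRUE pixel",
         call. = FALSE)
  }
  s <- scale_um_per_px
  mask <- fill_holes(mask)
  area_px <- sum(mask)

  ## perimeter
  if (area_px == 1L) {
    perim_px <- 4
  } else {
    st <- trace_boundary_steps(mask)
    perim_px <- 0.948 * st[["straight"]] + 1.340 * st[["diagonal"]]
    perim_px <- max(perim_px, 4)
  }

  ## convex hull of boundary-pixel corners (x = col, y = row)
  inner <- mask
  inner[] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr > 2 && nc > 2) {
    inner[2:(nr - 1), 2:(nc - 1)] <-
      mask[2:(nr - 1), 2:(nc - 1)] & mask[1:(nr - 2), 2:(nc - 1)] &
      mask[3:nr, 2:(nc - 1)] & mask[2:(nr - 1), 1:(nc - 2)] &
      mask[2:(nr - 1), 3:nc]
  }
  bnd <- which(mask & !inner, arr.ind = TRUE)
  px <- rep(bnd[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  py <- rep(bnd[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  h <- grDevices::chull(px, py)
  hull_area_px <- polygon_area(px[h], py[h])
  feret_px <- max_pairwise_distance(px[h], py[h])

  ## moment-equivalent ellipse from pixel centers (+ 1/12 pixel variance)
  pix <- which(mask, arr.ind = TRUE)
  cov <- if (area_px > 1L) {
    stats::cov(cbind(pix[, 2], pix[, 1])) * (area_px - 1) / area_px
  } else {
    matrix(0, 2, 2)
  }
  cov <- cov + diag(1 / 12, 2)
  axes <- axes_from_covariance(cov)
  major_px <- axes[["major"]]
  minor_px <- axes[["minor"]]

  d_px <- if (diameter == "feret") feret_px else major_px
  circ <- circularity(area_px, perim_px, cap = FALSE)
  sol <- area_px / hull_area_px
  ar <- aspect_ratio(major_px, minor_px)
  mn <- morphology_number(area_px, min(sol, 1), d_px, ar, clamp = FALSE)

  data.frame(
    particle_id = particle_id,
    area = area_px * s^2, perimeter = perim_px * s,
    convex_area = hull_area_px * s^2, max_diameter = feret_px * s,
    major_axis = major_px * s, minor_axis = minor_px * s,
    circularity = min(circ, 1), circularity_raw = circ,
    solidity = min(sol, 1), solidity_raw = sol,
    aspect_ratio = ar,
    morphology_number = min(max(mn, 0), 1), morphology_number_raw = mn,
    scale_um_per_px = s,
    stringsAsFactors = FALSE
  )
}

#' Shape descriptors
#'
#' `circularity()` is `4*pi*A / P^2` (1 for a perfect circle); `solidity()` is
#' `A / convex_area` (1 for a smooth convex shape; a roughness / active-surface
#' proxy); `aspect_ratio()` is major / minor axis (elongation, >= 1; the axes
#' are ordered internally). Digitisation can push circularity or solidity
#' slightly above 1 on coarse rasters; by default values are capped at 1
#' (`solidity()` warns), with the raw value available via `cap = FALSE` or the
#' `*_raw` columns of [measure_particle()].
#'
#' @param area projected area.
#' @param perimeter particle perimeter (> 0).
#' @param cap cap the result at 1?
#' @return dimensionless scalar (vectorised over inputs).
#' @name descriptors
NULL

#' @rdname descriptors
#' @export
circularity <- function(area, perimeter, cap = TRUE) {
  if (any(perimeter <= 0)) stop("perimeter must be positive", call. = FALSE)
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  val <- 4 * pi * area / perimeter^2
  if (cap) pmin(val, 1) else val
}

#' @rdname descriptors
#' @param convex_area area of the convex hull (>= area up to digitisation).
#' @export
solidity <- function(area, convex_area) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  val <- area / convex_area
  if (any(val > 1)) {
    warning("solidity > 1 (digitisation artifact); clamped to 1")
    val <- pmin(val, 1)
  }
  val
}

#' @rdname descriptors
#' @param major_axis,minor_axis moment-ellipse axes (any order; both > 0).
#' @export
aspect_ratio <- function(major_axis, minor_axis) {
  if (any(minor_axis <= 0) || any(major_axis <= 0)) {
    stop("degenerate particle: axes must be positive", call. = FALSE)
  }
  pmax(major_axis, minor_axis) / pmin(major_axis, minor_axis)
}

#' Dimensionless Morphology number
#'
#' Combines the four macro-morphological quantities of a fungal particle --
#' projected area A, solidity S, maximal diameter D and elongation E -- into
#' `MN = 2 * sqrt(A * S) / (sqrt(pi) * D * E)`.
#'
#' A perfect circle (A = pi r^2, S = 1, D = 2r, E = 1) gives MN = 1; a
#' one-dimensional line gives MN -> 0 (for an L x w rectangle, MN scales as
#' w^(3/2) as the width vanishes). All intermediate pellet/clump morphologies
#' fall in (0, 1): MN increases with area and solidity and decreases with
#' diameter and elongation, so compact smooth pellets score high and rough or
#' elongated particles score low.
#'
#' @param area projected area A (> 0).
#' @param solidity solidity S in (0, 1].
#' @param max_diameter maximal (Feret) diameter D (> 0), same length unit as
#'   `sqrt(area)`.
#' @param elongation aspect ratio E (>= 1).
#' @param clamp clamp the result into `[0, 1]` (digitisation can overshoot
#'   slightly)?
#' @return dimensionless scalar (vectorised).
#' @export
morphology_number <- function(area, solidity, max_diameter, elongation,
                              clamp = TRUE) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  if (any(solidity <= 0 | solidity > 1)) {
    stop("solidity must be in (0, 1]", call. = FALSE)
  }
  if (any(max_diameter <= 0)) stop("max_diameter must be positive", call. = FALSE)
  if (any(elongation < 1)) stop("elongation must be >= 1", call. = FALSE)
  mn <- 2 * sqrt(area * solidity) / (sqrt(pi) * max_diameter * elongation)
  if (clamp) pmin(pmax(mn, 0), 1) else mn
}

#' Summarise the particles of one sample
#'
#' Means and standard deviations of area, circularity, solidity, aspect ratio
#' and Morphology number over the measured particles of a cultivation sample.
#' An empty measurement set raises the mycelial flag: purely dispersed growth
#' has no measurable particles and no numeric summary.
#'
#' @param measurements data.frame of [measure_particle()] rows (possibly
#'   zero rows), or an empty list.
#' @return object of class `fm_morphology_summary`: list with `n_particles`,
#'   `mycelial_flag` and a `stats` data.frame (descriptor, mean, sd).
#' @export
summarize_sample <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements)) {
    measurements <- if (length(measurements)) {
      do.call(rbind, measurements)
    } else {
      data.frame()
    }
  }
  if (nrow(measurements) == 0L) {
    return(structure(list(n_particles = 0L, mycelial_flag = TRUE,
                          stats = NULL),
                     class = "fm_morphology_summary"))
  }
  vars <- c("area", "circularity", "solidity", "aspect_ratio",
            "morphology_number")
  stats_df <- data.frame(
    descriptor = vars,
    mean = vapply(vars, function(v) mean(measurements[[v]]), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(measurements[[v]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  stats_df$sd[is.na(stats_df$sd)] <- 0
  structure(list(n_particles = nrow(measurements), mycelial_flag = FALSE,
                 stats = stats_df),
            class = "fm_morphology_summary")
}

#' @export
print.fm_morphology_summary <- function(x, ...) {
  if (x$mycelial_flag) {
    cat("<morphology summary: mycelial growth, no measurable particles>\n")
  } else {
    cat(sprintf("<morphology summary: %d particles>\n", x$n_particles))
    print(x$stats, row.names = FALSE)
  }
  invisible(x)
}

#' Full image-analysis chain for one image
#'
#' Grayscale conversion, Otsu thresholding, particle extraction and
#' per-particle measurement, followed by the sample summary -- the complete
#' microscopy image-analysis stage.
#'
#' @param image matrix or array accepted by [to_grayscale_8bit()].
#' @param scale_um_per_px physical pixel size.
#' @param polarity see [otsu_threshold()].
#' @param min_area,exclude_border see [extract_particles()].
#' @param diameter see [measure_particle()].
#' @return list with `measurements` (data.frame, one row per particle),
#'   `summary` ([summarize_sample()] result) and `threshold`.
#' @export
measure_image <- function(image, scale_um_per_px = 1,
                          polarity = c("bright", "dark"),
                          min_area = 50, exclude_border = TRUE,
                          diameter = c("feret", "ellipse")) {
  diameter <- match.arg(diameter)
  ot <- otsu_threshold(image, polarity = match.arg(polarity))
  parts <- extract_particles(ot$binary, min_area = min_area,
                             exclude_border = exclude_border)
  rows <- lapply(seq_along(parts), function(i) {
    measure_particle(parts[[i]]$mask, scale_um_per_px = scale_um_per_px,
                     particle_id = i, diameter = diameter)
  })
  meas <- if (length(rows)) do.call(rbind, rows) else
    measure_particle_empty_frame()
  list(measurements = meas, summary = summarize_sample(meas),
       threshold = ot$threshold)
}

measure_particle_empty_frame <- function() {
  data.frame(particle_id = integer(0), area = numeric(0),
             perimeter = numeric(0), convex_area = numeric(0),
             max_diameter = numeric(0), major_axis = numeric(0),
             minor_axis = numeric(0), circularity = numeric(0),
             circularity_raw = numeric(0), solidity = numeric(0),
             solidity_raw = numeric(0), aspect_ratio = numeric(0),
             morphology_number = numeric(0),
             morphology_number_raw = numeric(0),
             scale_um_per_px = numeric(0), stringsAsFactors = FALSE)
}
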