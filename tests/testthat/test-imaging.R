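test_that("grayscale conversion is an identity on 8-bit input and preserves constancy", {
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  expect_identical(to_grayscale_8bit(img), matrix(as.integer(img), 8, 8))

  col <- array(0.4, dim = c(6, 6, 3))
  g <- to_grayscale_8bit(col)
  expect_true(all(g == g[1, 1]))
  expect_equal(g[1, 1], 102L)  # 0.4 of the 0-255 range

  two <- two_tone_disc_image()
  expect_equal(sort(unique(as.vector(to_grayscale_8bit(two$image)))),
               c(50L, 200L))
  expect_error(to_grayscale_8bit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("Otsu separates a two-tone image exactly and rejects constant images", {
  two <- two_tone_disc_image(fg = 200L, bg = 50L)
  ot <- otsu_threshold(two$image, polarity = "bright")
  ## every level in [50, 199] maximises the criterion on a two-level
  ## histogram; the documented tie-break picks the lowest
  expect_gte(ot$threshold, 50)
  expect_lt(ot$threshold, 200)
  expect_identical(ot$binary, two$mask)
  expect_error(otsu_threshold(matrix(7L, 10, 10)), "no threshold")
})

test_that("Otsu equals the exhaustive between-class-variance maximiser", {
  set.seed(3)
  for (i in 1:25) {
    img <- matrix(as.integer(pmin(pmax(round(c(
      rnorm(600, 60, 10), rnorm(400, 180, 10))), 0), 255)), 40, 25)
    expect_identical(otsu_threshold(img)$threshold, otsu_brute_force(img))
  }
})

test_that("Otsu threshold of the inverted image mirrors the original", {
  ## overlapping classes keep the variance maximiser unique, so inversion
  ## must mirror the threshold (within one level of grid asymmetry)
  set.seed(9)
  img <- matrix(as.integer(pmin(pmax(round(c(
    rnorm(500, 90, 20), rnorm(500, 160, 20))), 0), 255)), 50, 20)
  t1 <- otsu_threshold(img)$threshold
  t2 <- otsu_threshold(255L - img)$threshold
  expect_lte(abs(t2 - (255 - t1)), 1)
})

test_that("particle extraction follows analyze-particles semantics", {
  ## two well-separated discs
  m <- disc_mask(120, 240, 60, 60, 20) | disc_mask(120, 240, 60, 180, 20)
  expect_length(extract_particles(m), 2)

  ## disc touching the border
  mb <- disc_mask(100, 100, 50, 3, 20)
  expect_length(extract_particles(mb, exclude_border = TRUE), 0)
  expect_length(extract_particles(mb, exclude_border = FALSE), 1)

  ## 50 non-overlapping discs on a grid, 5 below min_area = 50 px^2
  img <- matrix(FALSE, 200, 400)
  k <- 0
  for (i in 1:5) for (j in 1:10) {
    k <- k + 1
    r <- if (k <= 5) 3 else 6          # r = 3 -> ~29 px^2, r = 6 -> ~113 px^2
    img <- img | disc_mask(200, 400, i * 40 - 20, j * 40 - 20, r)
  }
  expect_length(extract_particles(img, min_area = 50,
                                  exclude_border = FALSE), 45)
  expect_length(extract_particles(img, min_area = 1,
                                  exclude_border = FALSE), 50)
})

test_that("hole filling closes interior background only", {
  m <- disc_mask(80, 80, 40, 40, 25) & !disc_mask(80, 80, 40, 40, 10)
  filled <- fill_holes(m)
  expect_identical(filled, disc_mask(80, 80, 40, 40, 25))
})

test_that("measured disc and ellipse geometry converge to closed forms", {
  d <- disc_mask(440, 440, 220, 220, 200)
  md <- measure_particle(d)
  expect_lt(abs(md$area - pi * 200^2) / (pi * 200^2), 0.005)
  expect_lt(abs(md$max_diameter - 400) / 400, 0.01)
  expect_lt(abs(md$perimeter - 2 * pi * 200) / (2 * pi * 200), 0.01)
  expect_gt(md$circularity, 0.98)
  expect_gt(md$solidity, 0.98)
  expect_lt(abs(md$aspect_ratio - 1), 0.02)
  ## convex shape: hull area close to the particle area
  expect_lt(abs(md$convex_area - md$area) / md$area, 0.01)

  e <- rotated_ellipse_mask(440, 200, 100, 0)
  me <- measure_particle(e)
  expect_lt(abs(me$aspect_ratio - 2) / 2, 0.02)
  expect_lt(abs(me$major_axis - 400) / 400, 0.02)
  expect_lt(abs(me$minor_axis - 200) / 200, 0.02)
})

test_that("single-pixel particles use the documented degenerate conventions", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  r <- measure_particle(m)
  expect_equal(r$area, 1)
  expect_equal(r$perimeter, 4)
  expect_equal(r$aspect_ratio, 1)
})

test_that("descriptors reproduce their closed forms", {
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_equal(circularity(2, 6), 2 * pi / 9)
  expect_error(circularity(1, 0), "perimeter")

  expect_equal(solidity(3, 3), 1)          # any convex polygon
  expect_warning(s <- solidity(1.01, 1), "clamped")
  expect_equal(s, 1)

  expect_equal(aspect_ratio(3, 1), 3)
  expect_equal(aspect_ratio(1, 3), 3)      # axes ordered internally
  expect_error(aspect_ratio(1, 0), "degenerate")
})

test_that("plus-sign pentomino has solidity 5/7 from the exact corner hull", {
  m <- matrix(FALSE, 7, 7)
  m[4, 3:5] <- TRUE
  m[3:5, 4] <- TRUE
  r <- measure_particle(m)
  expect_equal(r$area, 5)
  expect_equal(r$convex_area, 7)
  expect_equal(r$solidity, 5 / 7)
  expect_equal(r$aspect_ratio, 1, tolerance = 1e-10)
})

test_that("Morphology number satisfies its boundary anchors and monotonicity", {
  ## perfect circle by substitution: exactly 1 for any radius
  for (r in c(0.5, 1, 37, 1e4)) {
    expect_equal(morphology_number(pi * r^2, 1, 2 * r, 1), 1)
  }
  ## line limit: L x w rectangle, w -> 0 (A = Lw, S = 1, D -> L, E = L/w)
  L <- 10
  w <- 10^(-(1:8))
  mn <- morphology_number(L * w, 1, L, L / w)
  expect_true(all(diff(mn) < 0))
  expect_lt(mn[8], 1e-10)
  ## analytic w^(3/2) scaling
  expect_equal(mn[2] / mn[1], (w[2] / w[1])^1.5, tolerance = 1e-12)
  ## 2:1 ellipse substitution
  expect_equal(morphology_number(2 * pi, 1, 4, 2), sqrt(2) / 4)
  ## monotone: up in A and S, down in D and E
  expect_gt(morphology_number(2, 0.8, 4, 2, clamp = FALSE),
            morphology_number(1, 0.8, 4, 2, clamp = FALSE))
  expect_gt(morphology_number(1, 0.9, 4, 2, clamp = FALSE),
            morphology_number(1, 0.8, 4, 2, clamp = FALSE))
  expect_lt(morphology_number(1, 0.8, 5, 2, clamp = FALSE),
            morphology_number(1, 0.8, 4, 2, clamp = FALSE))
  expect_lt(morphology_number(1, 0.8, 4, 3, clamp = FALSE),
            morphology_number(1, 0.8, 4, 2, clamp = FALSE))
  expect_error(morphology_number(-1, 1, 1, 1), "area")
})

test_that("descriptors are scale-equivariant and dimensionless", {
  m <- rotated_ellipse_mask(220, 90, 50, 0.4)
  a <- measure_particle(m, scale_um_per_px = 1)
  b <- measure_particle(m, scale_um_per_px = 2.5)
  expect_equal(b$area, a$area * 2.5^2)
  expect_equal(b$perimeter, a$perimeter * 2.5)
  expect_equal(b$max_diameter, a$max_diameter * 2.5)
  for (v in c("circularity", "solidity", "aspect_ratio", "morphology_number")) {
    expect_equal(b[[v]], a[[v]])
  }
})

test_that("descriptors are rotation invariant within digitisation tolerance", {
  ref <- measure_particle(rotated_ellipse_mask(360, 120, 60, 0))
  for (th in c(pi / 6, pi / 4, pi / 2)) {
    rot <- measure_particle(rotated_ellipse_mask(360, 120, 60, th))
    for (v in c("circularity", "solidity", "aspect_ratio",
                "morphology_number")) {
      expect_lt(abs(rot[[v]] - ref[[v]]) / ref[[v]], 0.02)
    }
  }
})

test_that("descriptor error shrinks as resolution grows", {
  radii <- c(25, 50, 100, 200, 400)
  res <- lapply(radii, function(r) {
    measure_particle(disc_mask(2 * r + 40, 2 * r + 40, r + 20, r + 20, r))
  })
  mn_err <- sapply(res, function(m) abs(m$morphology_number - 1))
  expect_true(all(diff(mn_err) <= 1e-9))      # nonincreasing under doubling
  ## raw geometric measurements within 1% of closed forms from r = 100 on
  m100 <- res[[3]]
  expect_lt(abs(m100$area - pi * 100^2) / (pi * 100^2), 0.01)
  expect_lt(abs(m100$max_diameter - 200) / 200, 0.01)
  expect_lt(abs(m100$perimeter - 2 * pi * 100) / (2 * pi * 100), 0.01)
})

test_that("sample summary handles constant, empty and mixed samples", {
  d <- measure_particle(disc_mask(110, 110, 55, 55, 40))
  s <- summarize_sample(do.call(rbind, replicate(10, d, simplify = FALSE)))
  expect_equal(s$n_particles, 10)
  expect_true(all(s$stats$sd == 0))
  expect_false(s$mycelial_flag)

  s0 <- summarize_sample(list())
  expect_true(s0$mycelial_flag)
  expect_equal(s0$n_particles, 0)

  e <- measure_particle(rotated_ellipse_mask(220, 100, 50, 0))
  mix <- summarize_sample(rbind(d, d, e, e))
  ar <- mix$stats$mean[mix$stats$descriptor == "aspect_ratio"]
  expect_lt(abs(ar - 1.5) / 1.5, 0.02)
})

test_that("measure_image runs the full chain on a rendered fixture", {
  p <- render_particle(shape_spec("disc", radius_px = 60), image_size = 160)
  res <- measure_image(p$image)
  expect_equal(nrow(res$measurements), 1)
  expect_gte(res$summary$stats$mean[
    res$summary$stats$descriptor == "circularity"], 0.95)
  ## empty image -> mycelial flag
  blank <- matrix(c(50L, 51L), 20, 20)
  res0 <- measure_image(blank, min_area = 500)
  expect_true(res0$summary$mycelial_flag)
})
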