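#' Scenario for a synthetic batch cultivation
#'
#' Parameters of a logistic-growth batch cultivation with a secreted enzyme
#' whose activity is proportional to the biomass-dry-weight integral (BDWI):
#' `x(t) = x_max / (1 + (x_max/x0 - 1) e^{-mu_max t})` and
#' `activity(t) = q_p * BDWI(t) * (1 + eps)`, with multiplicative Gaussian
#' noise of coefficient of variation `noise_cv`. Logistic growth (rather than
#' pure exponential) makes the BDWI saturate as in 72 h batch cultivations;
#' `mu_max_per_h` is the logistic's intrinsic rate.
#'
#' @param mu_max_per_h maximal specific growth rate (1/h).
#' @param x0_g_L inoculum biomass (g/L).
#' @param x_max_g_L carrying capacity (g/L); must exceed `x0_g_L`.
#' @param q_p_U_mg_h specific productivity (U/mg/h), the slope of volumetric
#'   activity (U/mL) versus BDWI (g h/L) -- the two share the volume basis,
#'   1 U/mL per g h/L = 1 U/mg/h.
#' @param noise_cv coefficient of variation of the multiplicative activity
#'   noise, in `[0, 1]`.
#' @param t_end_h cultivation length (h).
#' @param n_samples number of sampling points (>= 4).
#' @param osmolality_osmol_kg culture broth osmolality (osmol/kg).
#' @param seed integer seed.
#' @return object of class `fm_cultivation_scenario`.
#' @export
cultivation_scenario <- function(mu_max_per_h = 0.16, x0_g_L = 0.01,
                                 x_max_g_L = 4, q_p_U_mg_h = 0.5,
                                 noise_cv = 0.05, t_end_h = 72,
                                 n_samples = 25L,
                                 osmolality_osmol_kg = 0.4, seed = 1L) {
  stop_if_not_scalar_number(mu_max_per_h, "mu_max_per_h", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(x0_g_L, "x0_g_L", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(x_max_g_L, "x_max_g_L", min = x0_g_L,
                            strict_min = TRUE)
  stop_if_not_scalar_number(q_p_U_mg_h, "q_p_U_mg_h", min = 0)
  if (!is.numeric(noise_cv) || noise_cv < 0 || noise_cv > 1) {
    stop("noise_cv must be in [0, 1] (a CV above 1 is nonphysical)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(t_end_h, "t_end_h", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(n_samples, "n_samples", min = 4)
  stop_if_not_scalar_number(osmolality_osmol_kg, "osmolality_osmol_kg",
                            min = 0, strict_min = TRUE)
  structure(list(mu_max_per_h = mu_max_per_h, x0_g_L = x0_g_L,
                 x_max_g_L = x_max_g_L, q_p_U_mg_h = q_p_U_mg_h,
                 noise_cv = noise_cv, t_end_h = t_end_h,
                 n_samples = as.integer(n_samples),
                 osmolality_osmol_kg = osmolality_osmol_kg,
                 seed = as.integer(seed)),
            class = "fm_cultivation_scenario")
}

#' Logistic biomass curve and its exact time integral
#'
#' `logistic_biomass()` evaluates
#' `x(t) = x_max / (1 + (x_max/x0 - 1) e^{-mu t})`; `logistic_bdwi()` is its
#' closed-form integral from 0 to t,
#' `x_max t + (x_max/mu) * (log(1 + C e^{-mu t}) - log(1 + C))` with
#' `C = x_max/x0 - 1` -- the analytic biomass-dry-weight integral used as
#' ground truth for the trapezoidal [bdwi()].
#'
#' @param t time (h), vectorised.
#' @param mu intrinsic growth rate (1/h).
#' @param x0,x_max inoculum and carrying capacity (g/L).
#' @return g/L (`logistic_biomass`) or g h/L (`logistic_bdwi`).
#' @export
logistic_biomass <- function(t, mu, x0, x_max) {
  x_max / (1 + (x_max / x0 - 1) * exp(-mu * t))
}

#' @rdname logistic_biomass
#' @export
logistic_bdwi <- function(t, mu, x0, x_max) {
  C <- x_max / x0 - 1
  x_max * t + (x_max / mu) * (log1p(C * exp(-mu * t)) - log1p(C))
}

#' Construct a cultivation record
#'
#' Time course of biomass dry weight and volumetric enzyme activity for one
#' cultivation.
#'
#' @param times_h strictly increasing times (h), at least 3 points.
#' @param bdw_g_L biomass dry weight (g/L), nonnegative.
#' @param activity_U_mL volumetric enzyme activity (U/mL).
#' @param osmolality_osmol_kg scalar broth osmolality.
#' @param strain_label free-text label.
#' @return object of class `fm_cultivation`, a data.frame with attributes.
#' @export
cultivation_record <- function(times_h, bdw_g_L, activity_U_mL,
                               osmolality_osmol_kg = NA_real_,
                               strain_label = "synthetic") {
  if (length(times_h) < 3) stop("at least 3 time points required", call. = FALSE)
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(bdw_g_L < 0)) stop("negative biomass dry weight", call. = FALSE)
  if (length(bdw_g_L) != length(times_h) ||
      length(activity_U_mL) != length(times_h)) {
    stop("times, bdw and activity must have equal length", call. = FALSE)
  }
  structure(
    data.frame(time_h = times_h, bdw_g_L = bdw_g_L,
               activity_U_mL = activity_U_mL,
               osmolality_osmol_kg = osmolality_osmol_kg),
    strain_label = strain_label,
    class = c("fm_cultivation", "data.frame")
  )
}

#' Simulate a batch cultivation time course
#'
#' @param scenario a [cultivation_scenario()].
#' @return an [cultivation_record()] with attribute `ground_truth` (list with
#'   `mu_max`, `q_p` and the exact `bdwi` at each sample time).
#' @export
simulate_cultivation <- function(scenario) {
  stopifnot(inherits(scenario, "fm_cultivation_scenario"))
  times <- seq(0, scenario$t_end_h, length.out = scenario$n_samples)
  x <- logistic_biomass(times, scenario$mu_max_per_h, scenario$x0_g_L,
                        scenario$x_max_g_L)
  bdwi_true <- logistic_bdwi(times, scenario$mu_max_per_h, scenario$x0_g_L,
                             scenario$x_max_g_L)
  eps <- if (scenario$noise_cv > 0) {
    with_seed(scenario$seed, stats::rnorm(length(times), 0, scenario$noise_cv))
  } else {
    numeric(length(times))
  }
  activity <- scenario$q_p_U_mg_h * bdwi_true * (1 + eps)
  rec <- cultivation_record(times, x, activity,
                            osmolality_osmol_kg = scenario$osmolality_osmol_kg)
  attr(rec, "ground_truth") <- list(mu_max = scenario$mu_max_per_h,
                                    q_p = scenario$q_p_U_mg_h,
                                    bdwi = bdwi_true)
  rec
}

# Linear interpolation between the printed dose-response anchors; evaluated
# (not clamped) across the allowed osmolality range so panel parameters stay
# strictly monotone.
panel_anchor <- function(osmolality, o0, y0, o1, y1) {
  y0 + (y1 - y0) * (osmolality - o0) / (o1 - o0)
}

#' Generate an osmolality dose-response panel
#'
#' Emulates the observed dose-response of *A. niger* cultivations to culture
#' broth osmolality: biomass falls (4 to 0.2 g/L over 0.4 to 4.9 osmol/kg),
#' specific productivity rises (0.5 to 9 U/mg/h over the same range), the
#' maximal growth rate falls (0.16 to 0.02 1/h over 0.4 to 4.5 osmol/kg),
#' germination lags lengthen, and particles become smaller, rougher and more
#' elongated until growth turns purely mycelial beyond 4.2 osmol/kg. Scenario
#' parameters interpolate linearly between these anchors.
#'
#' @param osmolalities osmolalities in osmol/kg, each within `[0.2, 5.0]`.
#' @param n_particles number of particle shape specs drawn per level.
#' @param seed integer seed.
#' @return list of class `fm_panel`; one entry per osmolality with elements
#'   `osmolality`, `cultivation` (a [cultivation_scenario()]), `germination`
#'   (a [germination_scenario()]), `mycelial` (logical) and `shapes` (list of
#'   [shape_spec()], or a single mycelium spec when mycelial).
#' @export
generate_osmolality_panel <- function(osmolalities, n_particles = 30L,
                                      seed = 1L) {
  if (any(osmolalities < 0.2 | osmolalities > 5.0)) {
    stop("osmolalities must lie within [0.2, 5.0] osmol/kg", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_along(osmolalities), function(i) {
      o <- osmolalities[i]
      x_max <- panel_anchor(o, 0.4, 4, 4.9, 0.2)
      q_p <- panel_anchor(o, 0.4, 0.5, 4.9, 9)
      mu <- max(panel_anchor(o, 0.4, 0.16, 4.5, 0.02), 0.005)
      lag_mean <- panel_anchor(o, 0.35, 150, 3.6, 500)
      lag_sd <- panel_anchor(o, 0.35, 20, 3.6, 60)
      mean_elong <- max(panel_anchor(o, 0.4, 1.05, 4.9, 3), 1.02)
      mean_rough <- min(max(panel_anchor(o, 0.4, 0.03, 4.9, 0.35), 0.01), 0.45)
      mean_radius <- max(panel_anchor(o, 0.4, 60, 4.9, 25), 15)
      mycelial <- o > 4.2
      seed_i <- sample.int(2^30, 1)
      shapes <- if (mycelial) {
        list(shape_spec("mycelium", radius_px = mean_radius,
                        seed = seed_i))
      } else {
        lapply(seq_len(n_particles), function(k) {
          shape_spec(
            "clump",
            radius_px = max(stats::rnorm(1, mean_radius, mean_radius / 8), 12),
            elongation = max(stats::rnorm(1, mean_elong, 0.05 * mean_elong), 1),
            roughness_amplitude = min(max(
              stats::rnorm(1, mean_rough, 0.02), 0.005), 0.45),
            roughness_order = 8L,
            seed = seed_i + k
          )
        })
      }
      list(
        osmolality = o,
        cultivation = cultivation_scenario(
          mu_max_per_h = mu, x0_g_L = 0.01, x_max_g_L = x_max,
          q_p_U_mg_h = q_p, noise_cv = 0.05, t_end_h = 72, n_samples = 25L,
          osmolality_osmol_kg = o, seed = seed_i + 1000L
        ),
        germination = germination_scenario(
          lag_mean_min = lag_mean, lag_sd_min = lag_sd, seed = seed_i + 2000L
        ),
        mycelial = mycelial,
        shapes = shapes
      )
    })
  }) -> panel
  structure(panel, class = "fm_panel")
}
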