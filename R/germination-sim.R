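#' Scenario for a germinating spore population
#'
#' Parameters of the synthetic laser-diffraction experiment: a population of
#' conidia (around 3 um) that germinate after individually drawn lag times,
#' grow germ tubes and aggregate into pellets (around 1,000 um), sampled at
#' the instrument's 285 s measurement interval.
#'
#' Per-spore germination times follow a Gaussian truncated at zero with mean
#' `lag_mean_min` and sd `lag_sd_min` (`lag_sd_min = 0` gives step
#' germination). Spore diameters carry a 10% coefficient of variation by
#' default (`spore_cv`; the inoculum width is a free parameter of the
#' generator). After germination a particle grows a germ tube at
#' `tube_growth_rate_um_min`; the instrument records it as its length with
#' probability `orientation_prob` and as its (spore-sized) width otherwise --
#' the orientation ambiguity of laser diffraction. Once the tube reaches
#' `aggregation_length_um` the particle joins the aggregate population, whose
#' common diameter ramps deterministically from spore size to
#' `pellet_diameter_um` as the germinated fraction F grows
#' (`d = spore + (pellet - spore) * min(F / 0.9, 1)`), completing exactly when
#' 90% of the conidia have germinated -- the conventional definition of
#' germination completion.
#'
#' @param n_spores number of conidia.
#' @param spore_diameter_um mean conidium diameter (default 3 um).
#' @param pellet_diameter_um final pellet diameter (default 1,000 um).
#' @param lag_mean_min,lag_sd_min mean and sd of the lag-time distribution.
#' @param tube_growth_rate_um_min germ-tube elongation rate.
#' @param orientation_prob probability an elongated particle is recorded by
#'   its length.
#' @param sampling_interval_s time between snapshots (default 285 s).
#' @param spore_cv coefficient of variation of conidium diameters.
#' @param aggregation_length_um tube length at which a particle is recruited
#'   into an aggregate.
#' @param seed integer seed; the simulator is bit-reproducible given the seed.
#' @return object of class `fm_germination_scenario`.
#' @export
germination_scenario <- function(n_spores = 2000L, spore_diameter_um = 3,
                                 pellet_diameter_um = 1000,
                                 lag_mean_min = 300, lag_sd_min = 30,
                                 tube_growth_rate_um_min = 30,
                                 orientation_prob = 0.5,
                                 sampling_interval_s = 285,
                                 spore_cv = 0.1,
                                 aggregation_length_um = 100,
                                 seed = 1L) {
  stop_if_not_scalar_number(n_spores, "n_spores", min = 1)
  stop_if_not_scalar_number(spore_diameter_um, "spore_diameter_um",
                            min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(pellet_diameter_um, "pellet_diameter_um",
                            min = 0, strict_min = TRUE)
  if (spore_diameter_um >= pellet_diameter_um) {
    stop("spore_diameter_um must be smaller than pellet_diameter_um",
         call. = FALSE)
  }
  stop_if_not_scalar_number(lag_mean_min, "lag_mean_min", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(lag_sd_min, "lag_sd_min", min = 0)
  stop_if_not_scalar_number(tube_growth_rate_um_min, "tube_growth_rate_um_min",
                            min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(orientation_prob, "orientation_prob",
                            min = 0, max = 1)
  stop_if_not_scalar_number(sampling_interval_s, "sampling_interval_s",
                            min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(spore_cv, "spore_cv", min = 0, max = 0.5)
  stop_if_not_scalar_number(aggregation_length_um, "aggregation_length_um",
                            min = spore_diameter_um, max = pellet_diameter_um)
  structure(list(n_spores = as.integer(n_spores),
                 spore_diameter_um = spore_diameter_um,
                 pellet_diameter_um = pellet_diameter_um,
                 lag_mean_min = lag_mean_min, lag_sd_min = lag_sd_min,
                 tube_growth_rate_um_min = tube_growth_rate_um_min,
                 orientation_prob = orientation_prob,
                 sampling_interval_s = sampling_interval_s,
                 spore_cv = spore_cv,
                 aggregation_length_um = aggregation_length_um,
                 seed = as.integer(seed)),
            class = "fm_germination_scenario")
}

#' Logarithmic diameter bins of the synthetic instrument
#'
#' @param n_bins number of bins.
#' @param range_um lower/upper bin edges in um (instrument-like defaults).
#' @return list with `edges` (length `n_bins + 1`) and `centers` (geometric
#'   bin centers).
#' @export
psd_bins <- function(n_bins = 100L, range_um = c(0.5, 3000)) {
  edges <- exp(seq(log(range_um[1]), log(range_um[2]),
                   length.out = n_bins + 1L))
  list(edges = edges, centers = sqrt(edges[-1] * edges[-(n_bins + 1L)]))
}

#' Simulate a germinating-population size-distribution time series
#'
#' Generates the laser-diffraction output of a germinating conidia population
#' under a [germination_scenario()]: at each snapshot every particle is
#' recorded with a diameter determined by its state (ungerminated spore, germ
#' tube with orientation ambiguity, or aggregate on the collective ramp), the
#' per-particle volumes `d^3` are binned on logarithmic diameter bins and
#' normalised to volume fractions.
#'
#' Ground truth is attached as attribute `ground_truth`: `onset_min` (earliest
#' germination event) and `t90_min` (empirical 90th-percentile germination
#' time, the completion time under the 90% definition), plus the drawn
#' germination times.
#'
#' @param scenario a [germination_scenario()].
#' @param t_end_min series length in minutes; defaults to
#'   `lag_mean + 3 lag_sd + 60`. Must cover at least 99% of the lag
#'   distribution.
#' @param n_bins number of diameter bins.
#' @return an [size_distribution_series()] with attribute `ground_truth`.
#' @export
simulate_germination_psd <- function(scenario, t_end_min = NULL,
                                     n_bins = 100L) {
  stopifnot(inherits(scenario, "fm_germination_scenario"))
  if (is.null(t_end_min)) {
    t_end_min <- scenario$lag_mean_min + 3 * scenario$lag_sd_min + 60
  }
  stop_if_not_scalar_number(t_end_min, "t_end_min", min = 0, strict_min = TRUE)
  q99 <- scenario$lag_mean_min + stats::qnorm(0.99) * scenario$lag_sd_min
  if (t_end_min < q99) {
    stop("t_end_min too short: fewer than 99% of spores germinate",
         call. = FALSE)
  }

  bins <- psd_bins(n_bins)
  times_s <- seq(0, t_end_min * 60, by = scenario$sampling_interval_s)
  times_min <- times_s / 60
  n <- scenario$n_spores

  with_seed(scenario$seed, {
    ## truncated-at-zero Gaussian lag times
    g <- stats::rnorm(n, scenario$lag_mean_min, scenario$lag_sd_min)
    while (any(g <= 0)) {
      bad <- g <= 0
      g[bad] <- stats::rnorm(sum(bad), scenario$lag_mean_min,
                             scenario$lag_sd_min)
    }
    d0 <- stats::rnorm(n, scenario$spore_diameter_um,
                       scenario$spore_cv * scenario$spore_diameter_um)
    d0 <- pmax(d0, 0.2 * scenario$spore_diameter_um)
    record_length <- matrix(
      stats::runif(n * length(times_s)) < scenario$orientation_prob,
      n, length(times_s))

    rate <- scenario$tube_growth_rate_um_min
    l_agg <- scenario$aggregation_length_um
    t_tube <- (l_agg - d0) / rate             # per-spore tube-stage duration
    frac <- matrix(0, length(times_s), n_bins)
    for (j in seq_along(times_s)) {
      t <- times_min[j]
      f_germ <- mean(g <= t)
      d_agg <- scenario$spore_diameter_um +
        (scenario$pellet_diameter_um - scenario$spore_diameter_um) *
        min(f_germ / 0.9, 1)
      rec <- d0                               # ungerminated: spore width
      tube <- g <= t & t < g + t_tube
      if (any(tube)) {
        len <- d0[tube] + rate * (t - g[tube])
        rec[tube] <- ifelse(record_length[tube, j], len, d0[tube])
      }
      agg <- t >= g + t_tube
      rec[agg] <- d_agg
      rec <- pmin(pmax(rec, bins$edges[1] * 1.0001),
                  bins$edges[n_bins + 1L] * 0.9999)
      vol <- rec^3
      bi <- findInterval(rec, bins$edges, rightmost.closed = TRUE)
      v <- numeric(n_bins)
      sums <- rowsum(vol, bi)
      v[as.integer(rownames(sums))] <- sums
      frac[j, ] <- v / sum(v)
    }
    series <- size_distribution_series(times_s, bins$centers, frac)
    attr(series, "ground_truth") <- list(
      onset_min = min(g),
      t90_min = sort(g)[ceiling(0.9 * n)],
      germination_times_min = g
    )
    series
  })
}
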