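#' Construct a particle-size-distribution time series
#'
#' Container for timestamped volumetric particle size distributions as
#' produced by a laser-diffraction instrument: at each time stamp a vector of
#' volume fractions over logarithmically spaced diameter bins, each snapshot
#' summing to 1.
#'
#' @param times_s strictly increasing time stamps in seconds.
#' @param bin_centers_um strictly increasing positive bin-center diameters.
#' @param volume_fractions matrix, `length(times_s)` rows x
#'   `length(bin_centers_um)` columns; nonnegative, rows summing to 1 within
#'   1e-6.
#' @return object of class `fm_psd_series`.
#' @export
size_distribution_series <- function(times_s, bin_centers_um, volume_fractions) {
  volume_fractions <- as.matrix(volume_fractions)
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(bin_centers_um <= 0) || any(diff(bin_centers_um) <= 0)) {
    stop("bin centers must be positive and strictly increasing", call. = FALSE)
  }
  if (nrow(volume_fractions) != length(times_s) ||
      ncol(volume_fractions) != length(bin_centers_um)) {
    stop("volume_fractions must be times x bins", call. = FALSE)
  }
  if (any(volume_fractions < 0)) stop("negative volume fractions", call. = FALSE)
  sums <- rowSums(volume_fractions)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("every snapshot must sum to 1 (within 1e-6)", call. = FALSE)
  }
  structure(list(times_s = as.numeric(times_s),
                 bin_centers_um = as.numeric(bin_centers_um),
                 volume_fractions = volume_fractions),
            class = "fm_psd_series")
}

#' @export
print.fm_psd_series <- function(x, ...) {
  cat(sprintf("<PSD series: %d snapshots, %d bins (%.3g-%.3g um), %.1f min>\n",
              length(x$times_s), length(x$bin_centers_um),
              min(x$bin_centers_um), max(x$bin_centers_um),
              max(x$times_s) / 60))
  invisible(x)
}

#' Volume-median diameter (Dv50) of one snapshot
#'
#' Diameter at cumulative volume fraction 0.5, linearly interpolated in
#' log-diameter between bin centers (the laser-diffraction convention for
#' logarithmic bins). The cumulative value assigned to a bin center is the
#' cumulative volume below the bin plus half the bin's own volume, so a
#' monodisperse snapshot returns its bin center exactly and two equal bins
#' return their geometric midpoint.
#'
#' @param snapshot vector of volume fractions over `bin_centers_um`.
#' @param bin_centers_um positive, strictly increasing diameters.
#' @return diameter in the unit of `bin_centers_um`.
#' @export
median_diameter <- function(snapshot, bin_centers_um) {
  if (length(snapshot) != length(bin_centers_um)) {
    stop("snapshot and bin centers differ in length", call. = FALSE)
  }
  tot <- sum(snapshot)
  if (tot <= 0) stop("all-zero snapshot has no median diameter", call. = FALSE)
  v <- snapshot / tot
  pos <- which(v > 0)
  cum_mid <- cumsum(v) - v / 2
  cm <- cum_mid[pos]
  ld <- log(bin_centers_um[pos])
  if (0.5 <= cm[1]) return(exp(ld[1]))
  if (0.5 >= cm[length(cm)]) return(exp(ld[length(ld)]))
  exp(stats::approx(cm, ld, xout = 0.5)$y)
}

#' Sauter mean diameter (D[3,2]) of one snapshot
#'
#' Diameter of a sphere with the same volume-to-surface ratio as the
#' population: for volume fractions `v_i` at diameters `d_i`,
#' `D[3,2] = sum(v_i) / sum(v_i / d_i)` (identical to the number-weighted form
#' `sum(n d^3) / sum(n d^2)`).
#'
#' @inheritParams median_diameter
#' @return diameter in the unit of `bin_centers_um`.
#' @export
sauter_mean_diameter <- function(snapshot, bin_centers_um) {
  if (length(snapshot) != length(bin_centers_um)) {
    stop("snapshot and bin centers differ in length", call. = FALSE)
  }
  if (any(bin_centers_um <= 0 & snapshot > 0)) {
    stop("nonzero volume at a zero-diameter bin", call. = FALSE)
  }
  tot <- sum(snapshot)
  if (tot <= 0) stop("all-zero snapshot has no Sauter mean diameter", call. = FALSE)
  tot / sum(snapshot / bin_centers_um)
}

#' Per-snapshot Dv50 and SMD of a series
#'
#' @param series an [size_distribution_series()].
#' @return numeric vector, one value per snapshot.
#' @export
psd_medians <- function(series) {
  apply(series$volume_fractions, 1, median_diameter,
        bin_centers_um = series$bin_centers_um)
}

#' @rdname psd_medians
#' @export
psd_smd <- function(series) {
  apply(series$volume_fractions, 1, sauter_mean_diameter,
        bin_centers_um = series$bin_centers_um)
}

half_rise_time <- function(times, values) {
  level <- (values[1] + values[length(values)]) / 2
  times[which(values >= level)[1]]
}

#' Does the SMD rise later than the median? (QC check)
#'
#' During germination the Sauter mean diameter is expected to increase later
#' and more slowly than the volume median, because small particles carry more
#' weight in D[3,2]. Returns TRUE iff the SMD's half-rise time (first time the
#' statistic reaches the midpoint of its initial and final values) is at least
#' the median's half-rise time.
#'
#' @param series an [size_distribution_series()] spanning germination.
#' @return logical.
#' @export
smd_lags_median <- function(series) {
  t_med <- half_rise_time(series$times_s, psd_medians(series))
  t_smd <- half_rise_time(series$times_s, psd_smd(series))
  t_smd >= t_med
}

#' Detect germination onset (end of the lag phase)
#'
#' The lag phase ends with the abrupt increase of the volume-median diameter:
#' onset is the first time the median exceeds `jump_factor` times the baseline
#' median (median of the first `baseline_window` snapshots) and stays above for
#' `persistence` consecutive snapshots. The persistence requirement absorbs
#' the orientation-ambiguity flicker of laser diffraction (elongated particles
#' are recorded as either their length or their width) without pre-smoothing.
#'
#' @param series an [size_distribution_series()].
#' @param baseline_window number of initial snapshots defining the baseline.
#' @param jump_factor multiple of the baseline median that counts as "abrupt".
#' @param persistence number of consecutive snapshots the jump must persist.
#' @return onset time in minutes from inoculation (time zero = first snapshot).
#' @export
detect_onset <- function(series, baseline_window = 5L, jump_factor = 10,
                         persistence = 2L) {
  med <- psd_medians(series)
  n <- length(med)
  if (n < baseline_window + persistence) {
    stop("series too short for onset detection", call. = FALSE)
  }
  baseline <- stats::median(med[seq_len(baseline_window)])
  above <- med > jump_factor * baseline
  idx <- sustained_index(above, persistence)
  if (is.na(idx)) stop("no germination detected in series", call. = FALSE)
  series$times_s[idx] / 60
}

# first index i such that flag[i..(i+persistence-1)] are all TRUE
sustained_index <- function(flag, persistence) {
  n <- length(flag)
  if (persistence <= 1L) return(which(flag)[1])
  run <- stats::filter(as.numeric(flag), rep(1, persistence), sides = 1)
  hit <- which(run == persistence)[1]
  if (is.na(hit)) NA_integer_ else hit - persistence + 1L
}

#' Detect the SMD plateau (germination completion)
#'
#' The plateau value is the median SMD over the final `plateau_quantile`
#' fraction of snapshots; the series must have stabilised there (the total SMD
#' change over the final segment, from an OLS slope, must be within
#' `plateau_tolerance` of the plateau value, otherwise the series ended before
#' the plateau). The plateau time is the first time the SMD reaches
#' `(1 - plateau_tolerance)` of the plateau value and stays there for
#' `persistence` consecutive snapshots.
#'
#' @param series an [size_distribution_series()].
#' @param plateau_quantile final fraction of snapshots defining the plateau.
#' @param plateau_tolerance relative tolerance on "near constant".
#' @param persistence consecutive snapshots required above the threshold.
#' @return plateau time in minutes from inoculation.
#' @export
detect_plateau <- function(series, plateau_quantile = 0.05,
                           plateau_tolerance = 0.05, persistence = 2L) {
  smd <- psd_smd(series)
  t <- series$times_s
  n <- length(smd)
  k <- max(3L, ceiling(plateau_quantile * n))
  tail_idx <- (n - k + 1L):n
  plateau_value <- stats::median(smd[tail_idx])
  ## stabilisation check over the final segment (twice the plateau window)
  k2 <- max(persistence + 1L, ceiling(2 * plateau_quantile * n))
  seg <- (n - min(k2, n - 1L)):n
  slope <- stats::coef(stats::lm(smd[seg] ~ t[seg]))[2]
  change <- abs(slope) * (t[n] - t[seg[1]])
  if (!is.finite(change) || change > plateau_tolerance * plateau_value) {
    stop("series ended before plateau", call. = FALSE)
  }
  above <- smd >= (1 - plateau_tolerance) * plateau_value
  idx <- sustained_index(above, persistence)
  if (is.na(idx)) stop("series ended before plateau", call. = FALSE)
  t[idx] / 60
}

#' Lag phase and germination time of a size-distribution series
#'
#' Assembles the laser-diffraction germination readout: the lag phase is the
#' time from inoculation (t = 0, the first snapshot) to the abrupt increase of
#' the volume-median diameter, and the germination time is the interval from
#' that onset until the Sauter mean diameter reaches a near-constant value --
#' the time the spore population needs to germinate.
#'
#' @inheritParams detect_onset
#' @inheritParams detect_plateau
#' @return object of class `fm_germination`: list with `lag_phase_min`,
#'   `germination_time_min`, `onset_time_min`, `plateau_time_min`,
#'   `baseline_median_um`, `plateau_median_um` and `detection_params`.
#' @export
germination_summary <- function(series, baseline_window = 5L, jump_factor = 10,
                                persistence = 2L, plateau_quantile = 0.05,
                                plateau_tolerance = 0.05) {
  onset <- detect_onset(series, baseline_window = baseline_window,
                        jump_factor = jump_factor, persistence = persistence)
  plateau <- detect_plateau(series, plateau_quantile = plateau_quantile,
                            plateau_tolerance = plateau_tolerance,
                            persistence = persistence)
  if (plateau < onset) {
    warning("plateau detected before onset; clamping germination time to 0")
    plateau <- onset
  }
  med <- psd_medians(series)
  n <- length(med)
  k <- max(3L, ceiling(plateau_quantile * n))
  structure(list(
    lag_phase_min = onset,
    germination_time_min = plateau - onset,
    onset_time_min = onset,
    plateau_time_min = plateau,
    baseline_median_um = stats::median(med[seq_len(baseline_window)]),
    plateau_median_um = stats::median(med[(n - k + 1L):n]),
    detection_params = list(baseline_window = baseline_window,
                            jump_factor = jump_factor,
                            persistence = persistence,
                            plateau_quantile = plateau_quantile,
                            plateau_tolerance = plateau_tolerance)
  ), class = "fm_germination")
}

#' @export
print.fm_germination <- function(x, ...) {
  cat(sprintf(paste0("<germination estimate: lag phase %.1f min, ",
                     "germination time %.1f min>\n"),
              x$lag_phase_min, x$germination_time_min))
  cat(sprintf("  median %.3g -> %.3g um; plateau at %.1f min\n",
              x$baseline_median_um, x$plateau_median_um, x$plateau_time_min))
  invisible(x)
}
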