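#' Biomass dry weight integral (BDWI)
#'
#' Cumulative time integral of the biomass dry weight, evaluated by the
#' trapezoidal rule at each sample time; `BDWI(t0) = 0`. The BDWI (g h/L)
#' measures the biomass-time a cultivation has accumulated and is the
#' denominator basis of the specific productivity.
#'
#' @param record an [cultivation_record()] (or data.frame with `time_h` and
#'   `bdw_g_L`).
#' @return numeric vector of BDWI values (g h/L), one per sample time,
#'   nondecreasing for nonnegative biomass.
#' @export
bdwi <- function(record) {
  t <- record$time_h
  x <- record$bdw_g_L
  if (is.null(t) || is.null(x)) {
    stop("record must have time_h and bdw_g_L", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  c(0, cumsum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2))
}

#' Specific productivity from a cultivation record
#'
#' Ordinary least-squares slope of volumetric enzyme activity (U/mL) over the
#' BDWI (g h/L): the approximately linear relationship whose slope is the
#' specific productivity. Because activity and BDWI share the volume basis,
#' the slope unit 1 U/mL per g h/L equals 1 U/mg/h, so no numeric conversion
#' factor applies.
#'
#' @param record an [cultivation_record()].
#' @param intercept fit a free intercept (default) or force the line through
#'   the origin.
#' @return list with `specific_productivity_U_mg_h`, `slope_r2`, `intercept`
#'   and `n_points`.
#' @export
specific_productivity <- function(record, intercept = TRUE) {
  b <- bdwi(record)
  y <- record$activity_U_mL
  if (length(unique(b)) < 2 || stats::sd(b) == 0) {
    stop("degenerate regressor: all BDWI values identical", call. = FALSE)
  }
  if (length(b) < 3) stop("at least 3 points required", call. = FALSE)
  fit <- if (intercept) stats::lm(y ~ b) else stats::lm(y ~ b - 1)
  slope <- unname(stats::coef(fit)[if (intercept) 2L else 1L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(specific_productivity_U_mg_h = slope,
       slope_r2 = r2,
       intercept = if (intercept) unname(stats::coef(fit)[1L]) else 0,
       n_points = length(b))
}

#' Maximal specific growth rate
#'
#' Maximum over all sliding windows of the log-linear regression slope of
#' `ln(BDW)` versus time -- the steepest sustained exponential phase of the
#' growth curve. Exact on noiseless exponential data; on a logistic curve it
#' recovers the intrinsic rate when sampling covers the early phase.
#'
#' @param record an [cultivation_record()].
#' @param window number of consecutive points per regression window (>= 3).
#' @return rate in 1/h.
#' @export
mu_max <- function(record, window = 4L) {
  t <- record$time_h
  x <- record$bdw_g_L
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 points", call. = FALSE)
  n <- length(t)
  best <- -Inf
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    if (any(x[idx] <= 0)) next
    sl <- stats::coef(stats::lm(log(x[idx]) ~ t[idx]))[2]
    if (is.finite(sl) && sl > best) best <- sl
  }
  if (!is.finite(best)) {
    stop("no window with strictly positive biomass", call. = FALSE)
  }
  unname(best)
}

#' Fold and percent change
#'
#' `fold_change(before, after)` returns `after / before`;
#' `percent_change()` returns `100 * (after - before) / before`.
#'
#' @param before baseline value (> 0).
#' @param after new value.
#' @return dimensionless fold change / percent.
#' @export
fold_change <- function(before, after) {
  if (any(before <= 0)) stop("baseline must be positive", call. = FALSE)
  after / before
}

#' @rdname fold_change
#' @export
percent_change <- function(before, after) {
  if (any(before <= 0)) stop("baseline must be positive", call. = FALSE)
  100 * (after - before) / before
}

#' Fit the exponential correlation y = a * exp(b * x)
#'
#' Nonlinear least squares on the original scale, initialised from the
#' log-linear regression of `ln(y)` on `x`. The coefficient of determination
#' is computed on the original scale (`1 - SSres/SStot`); the log-scale R^2
#' and the log-linear coefficient estimates are retained alongside. Used to
#' correlate the Morphology number with specific productivity, where a
#' negative `b` expresses that smaller (more mycelial) Morphology numbers go
#' with higher productivity.
#'
#' @param x predictor (e.g. Morphology numbers).
#' @param y positive response (e.g. specific productivities, U/mg/h).
#' @return object of class `fm_expfit`: list with `a`, `b`, `r2`, `r2_log`,
#'   `a_loglin`, `b_loglin`, `n_points`.
#' @export
fit_exponential <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("insufficient points: need at least 3", call. = FALSE)
  if (any(y <= 0)) {
    stop("nonpositive y: log-initialisation undefined", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("singular design: all x identical", call. = FALSE)

  loglin <- stats::lm(log(y) ~ x)
  a0 <- exp(unname(stats::coef(loglin)[1]))
  b0 <- unname(stats::coef(loglin)[2])
  r2_log <- suppressWarnings(summary(loglin)$r.squared)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    a <- a0; b <- b0
    yhat <- a0 * exp(b0 * x)
  } else {
    cf <- stats::coef(fit)
    a <- unname(cf["a"]); b <- unname(cf["b"])
    yhat <- stats::fitted(fit)
  }
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(a = a, b = b, r2 = r2, r2_log = r2_log,
                 a_loglin = a0, b_loglin = b0, n_points = length(x)),
            class = "fm_expfit")
}

#' @export
print.fm_expfit <- function(x, ...) {
  cat(sprintf("<exponential fit: y = %.4g * exp(%.4g x), R2 = %.3f, n = %d>\n",
              x$a, x$b, if (is.na(x$r2)) NA else x$r2, x$n_points))
  invisible(x)
}

#' Correlate Morphology number with specific productivity across cultivations
#'
#' Joins the per-cultivation mean Morphology number with the corresponding
#' specific productivity and fits the exponential correlation
#' `q_p = a * exp(b * MN)`. Mycelial-flagged cultivations carry no Morphology
#' number and are excluded (their count is reported via a message).
#'
#' @param panel data.frame with columns `morphology_number` (per-cultivation
#'   mean; `NA` for mycelial cultivations), `specific_productivity` and
#'   optionally `mycelial` (logical).
#' @return list with `fit` (an [fit_exponential()] result) and `scatter` (the
#'   data.frame actually fitted).
#' @export
correlate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  myc <- if (!is.null(panel$mycelial)) panel$mycelial else
    !is.finite(panel$morphology_number)
  n_excl <- sum(myc | !is.finite(panel$morphology_number))
  if (n_excl > 0) {
    message(sprintf("excluding %d mycelial cultivation(s) without a Morphology number",
                    n_excl))
  }
  keep <- !myc & is.finite(panel$morphology_number) &
    is.finite(panel$specific_productivity)
  scatter <- panel[keep, , drop = FALSE]
  if (nrow(scatter) < 3) {
    stop("insufficient points: need at least 3 cultivations", call. = FALSE)
  }
  fit <- fit_exponential(scatter$morphology_number,
                         scatter$specific_productivity)
  list(fit = fit, scatter = scatter)
}

#' Cultivation-performance summary
#'
#' Bundles the performance metrics of one cultivation: the BDWI curve, the
#' specific productivity (slope of activity vs BDWI), its R^2, the maximal
#' growth rate and the final volumetric activity.
#'
#' @inheritParams specific_productivity
#' @param window window for [mu_max()].
#' @return object of class `fm_productivity`.
#' @export
productivity_result <- function(record, intercept = TRUE, window = 4L) {
  sp <- specific_productivity(record, intercept = intercept)
  structure(list(
    bdwi_curve = data.frame(time_h = record$time_h, bdwi_g_h_L = bdwi(record)),
    specific_productivity_U_mg_h = sp$specific_productivity_U_mg_h,
    slope_r2 = sp$slope_r2,
    mu_max_per_h = mu_max(record, window = window),
    final_activity_U_mL = record$activity_U_mL[nrow(record)]
  ), class = "fm_productivity")
}

#' @export
print.fm_productivity <- function(x, ...) {
  cat(sprintf(paste0("<productivity: q_p = %.3g U/mg/h (R2 = %.3f), ",
                     "mu_max = %.3g 1/h, final activity %.3g U/mL>\n"),
              x$specific_productivity_U_mg_h, x$slope_r2, x$mu_max_per_h,
              x$final_activity_U_mL))
  invisible(x)
}
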