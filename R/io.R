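# Readers and writers for the pipeline's plain-text formats. All CSV output
# uses a header row, '.' as decimal separator and RFC-4180 quoting; readers of
# cultivation tables additionally accept comma decimals (German-locale
# exports) and ';' separators.

#' Read and write 8-bit grayscale images
#'
#' `write_image()` writes an integer 0-255 matrix as 8-bit grayscale PNG or
#' TIFF (chosen by extension); `read_image()` reads either format and returns
#' an 8-bit matrix via [to_grayscale_8bit()].
#'
#' @param image integer matrix with values 0-255.
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image()`: integer matrix 0-255.
#' @export
write_image <- function(image, path) {
  img <- to_grayscale_8bit(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, target = path),
         tif = ,
         tiff = tiff::writeTIFF(img, where = path, bits.per.sample = 8L),
         stop("unsupported image extension: ", ext, call. = FALSE))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image extension: ", ext, call. = FALSE))
  to_grayscale_8bit(img)
}

particle_csv_columns <- c(
  "particle_id", "area", "perimeter", "convex_area", "max_diameter",
  "major_axis", "minor_axis", "circularity", "circularity_raw", "solidity",
  "solidity_raw", "aspect_ratio", "morphology_number",
  "morphology_number_raw", "scale_um_per_px"
)

#' Read and write per-particle measurement tables
#'
#' The CSV column set and order is the stable contract of
#' [measure_particle()]: particle_id, area, perimeter, convex_area,
#' max_diameter, major_axis, minor_axis, circularity, circularity_raw,
#' solidity, solidity_raw, aspect_ratio, morphology_number,
#' morphology_number_raw, scale_um_per_px.
#'
#' @param measurements data.frame of measurement rows.
#' @param path CSV file path.
#' @export
write_particle_csv <- function(measurements, path) {
  missing_cols <- setdiff(particle_csv_columns, names(measurements))
  if (length(missing_cols)) {
    stop("missing measurement columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(measurements[, particle_csv_columns], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_particle_csv
#' @export
read_particle_csv <- function(path) {
  utils::read.csv(path)
}

#' Read and write PSD time-series CSV
#'
#' Column 1 is `time_s`; the remaining columns are one per diameter bin,
#' labeled `um_<center>` with the geometric bin center in micrometers.
#'
#' @param series an [size_distribution_series()].
#' @param path CSV file path.
#' @export
write_psd_csv <- function(series, path) {
  stopifnot(inherits(series, "fm_psd_series"))
  df <- data.frame(time_s = series$times_s, series$volume_fractions)
  names(df) <- c("time_s", sprintf("um_%.10g", series$bin_centers_um))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psd_csv
#' @export
read_psd_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s" || ncol(df) < 2) {
    stop("malformed PSD CSV (", path, "): first column must be time_s",
         call. = FALSE)
  }
  centers <- as.numeric(sub("^um_", "", names(df)[-1]))
  if (any(is.na(centers))) {
    stop("malformed PSD CSV (", path, "): bin columns must be labeled um_<center>",
         call. = FALSE)
  }
  size_distribution_series(df$time_s, centers, as.matrix(df[, -1]))
}

#' Read and write cultivation records
#'
#' CSV with columns `time_h, bdw_g_L, activity_U_mL, osmolality_osmol_kg`.
#' The reader normalises comma decimal separators (e.g. `88,8`) and accepts
#' `;`-separated files; the writer always emits dot decimals and commas.
#'
#' @param record an [cultivation_record()].
#' @param path CSV file path.
#' @export
write_cultivation_csv <- function(record, path) {
  utils::write.csv(
    record[, c("time_h", "bdw_g_L", "activity_U_mL", "osmolality_osmol_kg")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cultivation_csv
#' @export
read_cultivation_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(";", header, fixed = TRUE)) ";" else ","
  df <- utils::read.csv(path, sep = sep, colClasses = "character")
  need <- c("time_h", "bdw_g_L", "activity_U_mL")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("malformed cultivation CSV (", path, "): missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  to_num <- function(v, col) {
    out <- suppressWarnings(as.numeric(gsub(",", ".", v, fixed = TRUE)))
    bad <- which(is.na(out) & !is.na(v) & nzchar(v))
    if (length(bad)) {
      stop(sprintf("malformed cultivation CSV (%s): column %s, row %d: '%s'",
                   path, col, bad[1], v[bad[1]]), call. = FALSE)
    }
    out
  }
  osmo <- if ("osmolality_osmol_kg" %in% names(df)) {
    to_num(df$osmolality_osmol_kg, "osmolality_osmol_kg")
  } else {
    NA_real_
  }
  cultivation_record(to_num(df$time_h, "time_h"),
                     to_num(df$bdw_g_L, "bdw_g_L"),
                     to_num(df$activity_U_mL, "activity_U_mL"),
                     osmolality_osmol_kg = osmo[1])
}

#' Write a germination estimate
#'
#' One-row CSV of the estimate plus a JSON sidecar (`<path>.params.json`) of
#' the detection parameters used.
#'
#' @param estimate an [germination_summary()] result.
#' @param path CSV file path.
#' @export
write_germination_csv <- function(estimate, path) {
  stopifnot(inherits(estimate, "fm_germination"))
  df <- data.frame(
    lag_phase_min = estimate$lag_phase_min,
    germination_time_min = estimate$germination_time_min,
    onset_time_min = estimate$onset_time_min,
    plateau_time_min = estimate$plateau_time_min,
    baseline_median_um = estimate$baseline_median_um,
    plateau_median_um = estimate$plateau_median_um
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(estimate$detection_params,
                       paste0(path, ".params.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Pipeline configuration with documented defaults
#'
#' Central record of every tunable of the analysis chain, with the package's
#' documented defaults: pixel scale 1 um/px; bright particles; min_area 50
#' px^2 with border exclusion (ImageJ analyze-particles conventions); onset
#' detection at a 10x median jump over a 5-snapshot baseline sustained for 2
#' snapshots; plateau at 95% of the final-5% SMD level; Feret diameter as D;
#' free-intercept productivity regression. Unknown keys are errors.
#'
#' @param ... overrides of the defaults, by name.
#' @return object of class `fm_config` (a named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    scale_um_per_px = 1,
    polarity = "bright",
    min_area = 50,
    exclude_border = TRUE,
    diameter = "feret",
    baseline_window = 5L,
    jump_factor = 10,
    persistence = 2L,
    plateau_quantile = 0.05,
    plateau_tolerance = 0.05,
    intercept = TRUE,
    mu_window = 4L,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "fm_config")
}
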