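#' Run the full synthetic osmolality study
#'
#' End-to-end pipeline on a generated osmolality panel: for each osmolality
#' level and replicate it simulates a cultivation and computes the performance
#' metrics; renders and measures the level's particle images through the full
#' image-analysis chain (grayscale, Otsu, extraction, measurement, summary);
#' simulates the laser-diffraction germination experiment and detects lag
#' phase and germination time; and finally fits the exponential correlation of
#' Morphology number versus specific productivity. Mycelial levels enter the
#' tables flagged and are excluded from the correlation.
#'
#' @param osmolalities osmolality levels (osmol/kg) within `[0.2, 5.0]`.
#' @param n_replicates cultivations per level.
#' @param n_particles particle images rendered and measured per cultivation.
#' @param image_size image side length in pixels.
#' @param seed master seed; all randomness derives from it.
#' @param config an [pipeline_config()].
#' @param germination also run the germination simulations?
#' @param output_dir if non-NULL, write the result tables, the correlation
#'   JSON and an echo of the configuration into this directory.
#' @return list of class `fm_study` with `cultivations` (one row per
#'   cultivation: osmolality, replicate, morphology number mean/sd, q_p,
#'   mu_max, mycelial flag), `germination` (one row per level), `fit` and
#'   `scatter`.
#' @export
run_osmolality_study <- function(osmolalities = c(0.4, 1.0, 1.6, 2.2, 2.8, 3.4),
                                 n_replicates = 3L, n_particles = 10L,
                                 image_size = 256L, seed = 1L,
                                 config = pipeline_config(),
                                 germination = TRUE,
                                 output_dir = NULL) {
  stopifnot(inherits(config, "fm_config"))
  rows <- list()
  germ_rows <- list()

  for (rep_i in seq_len(n_replicates)) {
    panel <- generate_osmolality_panel(osmolalities, n_particles = n_particles,
                                       seed = seed + 7919L * rep_i)
    for (lvl in panel) {
      record <- simulate_cultivation(lvl$cultivation)
      prod <- productivity_result(record, intercept = config$intercept,
                                  window = config$mu_window)
      if (lvl$mycelial) {
        mn_mean <- NA_real_
        mn_sd <- NA_real_
        n_meas <- 0L
      } else {
        meas <- lapply(lvl$shapes, function(sp) {
          img <- render_particle(sp, image_size = image_size,
                                 scale_um_per_px = config$scale_um_per_px)
          res <- measure_image(img$image,
                               scale_um_per_px = config$scale_um_per_px,
                               polarity = config$polarity,
                               min_area = config$min_area,
                               exclude_border = config$exclude_border,
                               diameter = config$diameter)
          res$measurements
        })
        summ <- summarize_sample(do.call(rbind, meas))
        st <- summ$stats
        mn_mean <- st$mean[st$descriptor == "morphology_number"]
        mn_sd <- st$sd[st$descriptor == "morphology_number"]
        n_meas <- summ$n_particles
      }
      rows[[length(rows) + 1L]] <- data.frame(
        osmolality_osmol_kg = lvl$osmolality, replicate = rep_i,
        morphology_number = mn_mean, morphology_number_sd = mn_sd,
        n_particles = n_meas,
        specific_productivity = prod$specific_productivity_U_mg_h,
        slope_r2 = prod$slope_r2, mu_max_per_h = prod$mu_max_per_h,
        final_activity_U_mL = prod$final_activity_U_mL,
        mycelial = lvl$mycelial
      )
      if (germination && rep_i == 1L) {
        series <- simulate_germination_psd(lvl$germination)
        est <- germination_summary(
          series, baseline_window = config$baseline_window,
          jump_factor = config$jump_factor, persistence = config$persistence,
          plateau_quantile = config$plateau_quantile,
          plateau_tolerance = config$plateau_tolerance)
        germ_rows[[length(germ_rows) + 1L]] <- data.frame(
          osmolality_osmol_kg = lvl$osmolality,
          lag_phase_min = est$lag_phase_min,
          germination_time_min = est$germination_time_min
        )
      }
    }
  }

  cultivations <- do.call(rbind, rows)
  germ <- if (length(germ_rows)) do.call(rbind, germ_rows) else NULL
  corr <- correlate_panel(cultivations)
  study <- structure(list(cultivations = cultivations, germination = germ,
                          fit = corr$fit, scatter = corr$scatter,
                          config = config, seed = seed),
                     class = "fm_study")
  if (!is.null(output_dir)) write_study(study, output_dir)
  study
}

write_study <- function(study, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cultivations,
                   file.path(output_dir, "cultivations.csv"),
                   row.names = FALSE)
  if (!is.null(study$germination)) {
    utils::write.csv(study$germination,
                     file.path(output_dir, "germination.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(study$scatter, file.path(output_dir, "scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(a = study$fit$a, b = study$fit$b, r2 = study$fit$r2,
         n_points = study$fit$n_points),
    file.path(output_dir, "correlation_fit.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(c(unclass(study$config), list(seed = study$seed)),
                       file.path(output_dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(output_dir)
}

#' @export
print.fm_study <- function(x, ...) {
  cat(sprintf("<osmolality study: %d cultivations over %d levels>\n",
              nrow(x$cultivations),
              length(unique(x$cultivations$osmolality_osmol_kg))))
  print(x$fit)
  invisible(x)
}
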