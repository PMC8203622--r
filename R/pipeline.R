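#' Pipeline configuration
#'
#' A validated flat list of every tunable the end-to-end pipeline uses.
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @details Defaults: `seed = 1`; `n_images_per_class = 10` synthetic
#'   specimens per docking class; image truth `membrane_thickness_nm = 4`,
#'   `interface_thickening_nm = 0.6`, `noise_sigma = 0.05`; peak detection
#'   `smoothing_sigma_px = 1`, `min_separation_nm = 1`,
#'   `min_prominence_frac = 0.1`; `classification_threshold = 0.6`;
#'   `profile_width_px = 11`; frame stage `frame_distances_nm =
#'   c(0.4, 1.5, 4.7)` with `frame_noise_nm = 0.05`; relaxation stage
#'   `relax_n_replicas = 100`, `relax_taus_ns = c(tilt = 0.05, area = 0.15,
#'   thickness = 0.40)`, `relax_noise_sigma = 0.05`, `relax_dt_ns = 0.001`,
#'   `relax_duration_ns = 1`, `n_bootstrap = 1000`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_images_per_class = 10L,
    membrane_thickness_nm = 4.0,
    interface_thickening_nm = 0.6,
    noise_sigma = 0.05,
    smoothing_sigma_px = 1,
    min_separation_nm = 1,
    min_prominence_frac = 0.1,
    classification_threshold = 0.6,
    profile_width_px = 11L,
    frame_distances_nm = c(0.4, 1.5, 4.7),
    frame_noise_nm = 0.05,
    relax_n_replicas = 100L,
    relax_taus_ns = c(tilt = 0.05, area = 0.15, thickness = 0.40),
    relax_noise_sigma = 0.05,
    relax_dt_ns = 0.001,
    relax_duration_ns = 1,
    n_bootstrap = 1000L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown configuration key(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    defaults[names(over)] <- over
  }
  structure(defaults, class = "pipeline_config")
}

#' Measure a synthetic specimen with the imaging stage
#'
#' Applies the measurement chain to one generated image bundle: a radial
#' profile around the vesicle centre for free specimens, or a line scan
#' across the contact zone for docked pairs, followed by peak detection
#' and per-membrane thickness assignment.
#'
#' @param bundle result of [generate_vesicle_pair_image()].
#' @param config a [pipeline_config()] (peak/profile settings are taken
#'   from it).
#' @return A `thickness_measurement` data.frame (see
#'   [measure_thickness()]).
#' @export
measure_synthetic_image <- function(bundle, config = pipeline_config()) {
  tr <- bundle$truth
  if (tr$docking_type == "free") {
    r_max <- tr$radii_nm[1] + 4 * tr$thickness_free_nm
    prof <- radial_profile(bundle$density, tr$centers_nm[1, ], r_max,
                           bin_width_px = 1)
    measure_thickness(prof, "free",
                      smoothing_sigma_px = config$smoothing_sigma_px,
                      min_separation_nm = config$min_separation_nm,
                      min_prominence_frac = config$min_prominence_frac)
  } else {
    seg <- tr$segments$interface
    prof <- line_profile(bundle$density, seg$start, seg$end,
                         width_px = config$profile_width_px)
    measure_thickness(prof, "interface",
                      smoothing_sigma_px = config$smoothing_sigma_px,
                      min_separation_nm = config$min_separation_nm,
                      min_prominence_frac = config$min_prominence_frac)
  }
}

#' Run the full synthetic pipeline
#'
#' Executes generate - measure - classify - stats - metrics - fit - order
#' on synthetic data and writes CSV/JSON artifacts plus a reproducibility
#' log to `out_dir`. The same config and seed reproduce the bundle
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return (invisibly) a list with `thickness` (per-image measurements),
#'   `docking` (classification calls vs truth), `stats` (tight-vs-free
#'   group test), `metrics` (per-distance double-bilayer observables),
#'   `fits` (per-replica relaxation fits), `ordering` (tau ordering).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config", call. = FALSE)
  seeds <- substream_seeds(config$seed, 5L)

  ## --- imaging stage ------------------------------------------------------
  n_img <- config$n_images_per_class
  img_seeds <- substream_seeds(seeds[1], 3L * n_img)
  types <- rep(c("free", "loose", "tight"), each = n_img)
  thickness_rows <- list(); docking_rows <- list()
  for (i in seq_along(types)) {
    ty <- types[i]
    sp <- vesicle_image_spec(
      docking_type = ty,
      membrane_thickness_nm = config$membrane_thickness_nm,
      interface_thickening_nm = if (ty == "tight") config$interface_thickening_nm else NULL,
      noise_sigma = config$noise_sigma,
      seed = img_seeds[i])
    bundle <- generate_vesicle_pair_image(sp)
    tm <- measure_synthetic_image(bundle, config)
    tm$image_id <- i; tm$docking_type <- ty
    tm$true_thickness_nm <- if (ty == "free") bundle$truth$thickness_free_nm
                            else bundle$truth$thickness_interface_nm
    thickness_rows[[i]] <- as.data.frame(tm)
    if (ty != "free") {
      call <- classify_interface(bundle$protein,
                                 c(bundle$truth$segments$interface,
                                   width_px = config$profile_width_px),
                                 c(bundle$truth$segments$free,
                                   width_px = config$profile_width_px),
                                 threshold = config$classification_threshold)
      docking_rows[[i]] <- data.frame(image_id = i, true_label = ty,
                                      called_label = call$label,
                                      interface_ratio = call$interface_ratio,
                                      threshold = call$threshold)
    }
  }
  thickness <- do.call(rbind, thickness_rows)
  docking <- do.call(rbind, docking_rows)

  tight_int <- thickness$thickness_nm[thickness$docking_type == "tight" &
                                        thickness$resolved]
  free_th <- thickness$thickness_nm[thickness$docking_type == "free" &
                                      thickness$resolved]
  stats_res <- if (length(tight_int) >= 2L && length(free_th) >= 2L)
    compare_groups(tight_int, free_th, test = "t", alternative = "greater",
                   paired = FALSE) else NULL

  ## --- trajectory-metrics stage ------------------------------------------
  frame_seeds <- substream_seeds(seeds[2], length(config$frame_distances_nm))
  metrics <- do.call(rbind, lapply(seq_along(config$frame_distances_nm), function(j) {
    d <- config$frame_distances_nm[j]
    fr <- generate_bilayer_frame(bilayer_frame_spec(
      n_membranes = 2L, intermembrane_distance_nm = d,
      positional_noise_nm = config$frame_noise_nm, seed = frame_seeds[j]))
    mm <- membrane_metrics(fr, n_membranes = 2L)
    mm$requested_distance_nm <- d
    mm
  }))

  ## --- relaxation stage ---------------------------------------------------
  taus <- config$relax_taus_ns
  ens <- generate_relaxation_ensemble(relaxation_ensemble_spec(
    observables = lapply(as.list(taus), function(tau)
      c(x0 = 0, x_inf = 1, tau_ns = unname(tau))),
    dt_ns = config$relax_dt_ns, duration_ns = config$relax_duration_ns,
    noise_sigma = config$relax_noise_sigma,
    n_replicas = config$relax_n_replicas, seed = seeds[3]))
  fits <- fit_ensemble(ens)
  ordering <- tau_ordering(fits, n_bootstrap = config$n_bootstrap,
                           seed = seeds[4])

  bundle <- list(thickness = thickness, docking = docking, stats = stats_res,
                 metrics = metrics, fits = fits, ordering = ordering)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(thickness, file.path(out_dir, "thickness.csv"), row.names = FALSE)
    write.csv(docking, file.path(out_dir, "docking.csv"), row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      median_tau_ns = as.list(ordering$median_tau_ns),
      support = as.list(ordering$support),
      ordering = ordering$ordering, declared = ordering$declared),
      file.path(out_dir, "ordering.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(stats_res))
      jsonlite::write_json(list(test = stats_res$test,
                                statistic = stats_res$statistic,
                                p_value = stats_res$p_value,
                                n = as.list(stats_res$n)),
                           file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(package = "memdock",
                              version = as.character(utils::packageVersion("memdock")),
                              config = unclass(config),
                              timestamp = format(Sys.time(), tz = "UTC")),
                         file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}
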