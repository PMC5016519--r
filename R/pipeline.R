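#' Pipeline configuration
#'
#' The pipeline is driven by one nested configuration (a YAML file or an R
#' list). Every omitted key resolves to the protocol's default — 1 um / 100
#' nm density windows, a 1-160 nm radius sweep read at the 50 nm plateau,
#' Ripley grid 10-800 nm with m = 500 test points, Neyman-Scott offspring
#' mean 5 and sigma 8 nm, and a 5 x 5 um^2 analysis region. Unknown keys are
#' rejected by name, and every stochastic stage derives its seed from the
#' single top-level `seed`.
#'
#' Sample and reference entries are either files
#' (`list(path = ..., dialect = ...)`) or simulation requests
#' (`list(simulate = "csr" | "neyman_scott" | "double_membrane" |
#' "vesicle_field" | "blinking_scene", ...params)`).
#'
#' @param config Path to a YAML file, or a nested list.
#' @return An `analysis_config` list with all defaults resolved.
#' @examples
#' cfg <- validate_config(list(seed = 7))
#' cfg$ripley$m
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) abort("config must be a file path or a list")
  defaults <- list(
    seed = 1L,
    output_dir = NULL,
    region = list(x_min = 0, x_max = 5000, y_min = 0, y_max = 5000),
    samples = list(),
    reference = NULL,
    density = list(diameter = 1000, step = 100),
    calibration = list(radius_min = 1, radius_max = 160, plateau_radius = 50,
                       min_track_length = 3),
    ripley = list(d_min = 10, d_max = 800, d_step = 10, m = 500,
                  edge = "none", n_null_replicates = 5),
    simulation = list(offspring_mean = 5, offspring_sigma = 8, n_frames = 20000)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (grp in c("region", "density", "calibration", "ripley", "simulation")) {
    extra <- setdiff(names(config[[grp]]), names(defaults[[grp]]))
    if (length(extra)) {
      abort(sprintf("unknown key(s) in `%s`: %s", grp, paste(extra, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  # samples is an unnamed list of entries; modifyList cannot merge those
  if (!is.null(config$samples)) cfg$samples <- config$samples
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed < 0 ||
      cfg$seed != as.integer(cfg$seed)) {
    abort("`seed` must be a single non-negative integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$ripley$edge %in% c("none", "guard")) {
    abort("`ripley$edge` must be \"none\" or \"guard\"")
  }
  do.call(region, cfg$region)  # validates extents
  structure(cfg, class = "analysis_config")
}

#' @rdname validate_config
#' @param path Where to write the YAML representation.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_input <- function(entry, region, sim_defaults, seed) {
  if (!is.null(entry$path)) {
    tbl <- read_localizations(entry$path, dialect = entry$dialect %||% "generic_csv")
    return(crop_region(tbl, region))
  }
  if (is.null(entry$simulate)) abort("input entry needs `path` or `simulate`")
  kind <- entry$simulate
  sd <- sim_defaults
  switch(kind,
    csr = simulate_csr(entry$intensity %||% 1000, region, seed = seed,
                       n_frames = sd$n_frames),
    neyman_scott = simulate_neyman_scott(
      neyman_scott_params(loc_intensity = entry$loc_intensity %||% 1000,
                          offspring_mean = entry$offspring_mean %||% sd$offspring_mean,
                          offspring_sigma = entry$offspring_sigma %||% sd$offspring_sigma),
      region, seed = seed, n_frames = sd$n_frames)$locs,
    double_membrane = simulate_double_membrane(entry$single_intensity %||% 500,
                                               region, seed = seed,
                                               n_frames = sd$n_frames),
    vesicle_field = simulate_vesicle_field(
      entry$background_intensity %||% 500, entry$vesicle_count %||% 10,
      entry$vesicle_radius %||% 100, entry$vesicle_loc_count %||% 100,
      region, seed = seed, n_frames = sd$n_frames),
    blinking_scene = simulate_blinking_scene(
      entry$fluorophore_density %||% 2,
      blink_mean = entry$blink_mean %||% sd$offspring_mean,
      precision_sigma = entry$precision_sigma %||% sd$offspring_sigma,
      n_frames = sd$n_frames, region = region, seed = seed)$locs,
    abort(sprintf("unknown simulation kind: %s", kind))
  )
}

#' Run the full quantitative pipeline
#'
#' Orchestrates the analysis end to end: load or simulate the sample
#' localization tables and the diluted reference, map sliding-window
#' densities, calibrate blinking (conversion factor and precision), convert
#' the median localization density to a detected molecular density, compute
#' Ripley envelopes for the samples and for matched Poisson and Neyman-Scott
#' nulls, and flag excursions of the observed curve beyond the null bands.
#' When `output_dir` is set, per-stage CSVs and a JSON manifest (seeds,
#' package version, config hash) are written; the manifest plus the config
#' reproduce the bundle exactly.
#'
#' Any stage failure aborts with the stage name; outputs written so far stay
#' on disk next to a `FAILED` marker naming the stage.
#'
#' @param config An `analysis_config` from [validate_config()] (or anything
#'   it accepts).
#' @return A report bundle (list) with elements `density`, `calibration`,
#'   `molecular_density`, `ripley` (curves, observed/null envelopes,
#'   comparison, peak) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name) {
    if (!is.null(out_dir)) {
      readr::write_csv(tibble::as_tibble(obj), file.path(out_dir, paste0(name, ".csv")),
                       progress = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  reg <- do.call(region, config$region)
  log <- list()

  samples <- stage("input", {
    if (length(config$samples) == 0) abort("config lists no samples")
    purrr::imap(config$samples, function(entry, i) {
      resolve_input(entry, reg, config$simulation, seed = config$seed + 17L * i)
    })
  })
  log$n_localizations <- purrr::map_int(samples, nrow)
  inform(sprintf("pipeline: %d sample table(s), %s localizations",
                 length(samples), paste(log$n_localizations, collapse = ", ")))

  dens <- stage("density", {
    maps <- purrr::map(samples, sliding_window_density, region = reg,
                       diameter = config$density$diameter, step = config$density$step)
    summaries <- purrr::imap_dfr(maps, function(m, i) {
      dplyr::mutate(summarize_density(m, seed = config$seed + i), sample = i,
                    .before = 1)
    })
    emit(summaries, "density_summary")
    list(maps = maps, summaries = summaries)
  })

  calibration <- NULL
  if (!is.null(config$reference)) {
    calibration <- stage("calibration", {
      ref <- resolve_input(config$reference, reg, config$simulation,
                           seed = config$seed + 9973L)
      cal <- calibrate_blinking(
        ref, radii = seq(config$calibration$radius_min, config$calibration$radius_max),
        plateau_radius = config$calibration$plateau_radius,
        min_track_length = config$calibration$min_track_length)
      emit(cal$curve, "calibration_curve")
      emit(glance(cal), "calibration")
      cal
    })
    log$n_tracks_plateau <- calibration$curve$n_tracks[
      calibration$curve$radius == calibration$plateau_radius]
  }

  mdens <- NULL
  if (!is.null(calibration)) {
    mdens <- stage("molecular_density", {
      md <- molecular_density(median(dens$summaries$median),
                              calibration$conversion_factor,
                              density_se = median(dens$summaries$median_se),
                              conversion_se = calibration$conversion_se)
      emit(md, "molecular_density")
      md
    })
  }

  rip <- stage("ripley", {
    rp <- config$ripley
    grid <- seq(rp$d_min, rp$d_max, by = rp$d_step)
    curves <- purrr::imap(samples, function(s, i) {
      ripley_h(s, reg, distances = grid, m = min(rp$m, nrow(s)),
               seed = config$seed + 31L * i, edge = rp$edge)
    })
    intensity <- mean(purrr::map_dbl(samples, nrow)) / (region_area(reg) / 1e6)
    null_seeds <- config$seed + 101L * seq_len(rp$n_null_replicates)
    csr_env <- ripley_envelope(purrr::map(null_seeds, function(s) {
      ripley_h(simulate_csr(intensity, reg, seed = s), reg, distances = grid,
               m = rp$m, seed = s, edge = rp$edge)
    }))
    ns_env <- ripley_envelope(purrr::map(null_seeds, function(s) {
      sim <- simulate_neyman_scott(
        neyman_scott_params(loc_intensity = intensity,
                            offspring_mean = config$simulation$offspring_mean,
                            offspring_sigma = config$simulation$offspring_sigma),
        reg, seed = s + 1L)
      ripley_h(sim$locs, reg, distances = grid, m = min(rp$m, nrow(sim$locs)),
               seed = s, edge = rp$edge)
    }))
    observed <- if (length(curves) >= 2) {
      ripley_envelope(curves)
    } else {
      # single region: degenerate envelope (no replicate spread)
      structure(tibble::tibble(d = grid, mean_h = curves[[1]]$h,
                               lower = curves[[1]]$h, upper = curves[[1]]$h),
                class = c("ripley_envelope", "tbl_df", "tbl", "data.frame"),
                r = 1L, level = NA_real_)
    }
    comparison <- compare_to_nulls(observed, csr_env, ns_env)
    purrr::iwalk(curves, function(cv, i) emit(tidy(cv), sprintf("ripley_curve_%d", i)))
    emit(tidy(observed), "ripley_observed")
    emit(tidy(csr_env), "ripley_csr_null")
    emit(tidy(ns_env), "ripley_neyman_scott_null")
    if (!is.null(comparison$excursions)) emit(comparison$excursions, "ripley_excursions")
    list(curves = curves, observed = observed, csr = csr_env, ns = ns_env,
         comparison = comparison, peak = peak_distance(observed))
  })

  manifest <- list(
    package = "stormquant",
    version = as.character(utils::packageVersion("stormquant")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    # hash identifies the analysis, not where its outputs land
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "output_dir")]),
    log = log
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(density = dens$summaries, density_maps = dens$maps,
                 calibration = calibration, molecular_density = mdens,
                 ripley = rip, manifest = manifest))
}
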