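# End-to-end pipeline: simulate -> calibrate -> bisect -> estimate -> stats,
# driven by a single YAML-serialisable configuration with a master seed.

#' Default run configuration
#'
#' Every pipeline parameter with its default. Override entries via
#' `modifyList()` semantics in [run_pipeline()] or a YAML file read by
#' [read_config()].
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    master_seed = 1L,
    cohort = list(
      n_cells = 12L,
      positions = c("beginning", "middle", "end"),
      enrichment = list(beginning = 0.5, middle = 0.6, end = 0.7),
      protein_tracks_mrna = TRUE),
    scene = list(
      image_shape = c(96L, 96L),
      cell_axes = c(28, 14),
      n_spots = 40L,
      unit_amplitude = 100,
      unit_sigma = 1.5,
      background = 10,
      read_noise_sd = 0,
      poisson_noise = FALSE,
      border_margin_sigma = 3,
      # keep spots at least ~1 PSF FWHM apart so the calibration stage can
      # find isolated candidates
      min_spot_separation = 3),
    calibrate = list(
      n_images = 6L,
      min_separation_px = 3,
      k_sigma = 5,
      window_px = 5L,
      size_bounds = c(0.8, 3.0),
      trim_step = 0.02,
      unimodality_threshold = 0.555,
      min_support = 10L),
    estimate = list(
      estimator = "simulated",
      n_reps = 5L,
      jitter_px = 1,
      stop_tol = 1e-4),
    stats = list(
      alpha = 0.05,
      paired = FALSE,
      levels = c(0.50, 0.99))),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults, so the
#' round trip config -> file -> config is lossless.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

# Keys holding open maps (user-defined keys allowed, replaced wholesale).
OPEN_CONFIG_KEYS <- c("enrichment")

merge_config <- function(base, user, prefix = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", prefix, key)
    if (key %in% OPEN_CONFIG_KEYS)
      base[[key]] <- as.list(user[[key]])
    else if (is.list(base[[key]]) && !is.null(names(base[[key]])))
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]),
                                  paste0(prefix, key, "."))
    else
      base[[key]] <- user[[key]]
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (cfg$estimate$n_reps < 1L) stop("estimate.n_reps must be >= 1")
  if (cfg$cohort$n_cells < 1L) stop("cohort.n_cells must be >= 1")
  if (!cfg$estimate$estimator %in% c("linear", "simulated"))
    stop("estimate.estimator must be \"linear\" or \"simulated\"")
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    stop("stats.alpha must be in (0, 1)")
  invisible(cfg)
}

#' Run the full quantification pipeline on a synthetic cohort
#'
#' Simulates a stream cohort, calibrates the mRNA unit from the first few
#' images, bisects each cell about its nucleus, estimates per-half unit
#' counts (linear and, when requested, simulated), and computes the
#' polarity statistics. All artifacts are written under `out_dir`:
#' per-cell TIFFs/GeoJSON/ground truth, `unit.json`, `records.csv`,
#' `stats.json` and a `manifest.json` with the seed, the configuration and
#' file hashes. Fully deterministic given `master_seed`.
#'
#' @param config a `run_config` list, a YAML path, or `NULL` for defaults.
#' @param out_dir output directory.
#' @param write_images logical; write the per-cell TIFF/GeoJSON artifacts
#'   (disable to keep only the tabular outputs).
#' @return Invisibly, a list with `records` (data frame), `unit`,
#'   `comparison`, `by_position`, `correlation`, `config`.
#' @export
run_pipeline <- function(config = NULL, out_dir, write_images = TRUE) {
  cfg <- if (is.null(config)) default_config()
         else if (is.character(config)) read_config(config)
         else merge_config(default_config(), unclass(config))
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  base <- do.call(scene_params, c(cfg$scene, list(seed = cfg$master_seed)))
  cohort <- make_stream_cohort(
    cfg$cohort$n_cells, cfg$cohort$positions, cfg$cohort$enrichment,
    base, protein_tracks_mrna = isTRUE(cfg$cohort$protein_tracks_mrna))
  message("simulate: n_cells=", length(cohort),
          " positions=", paste(cfg$cohort$positions, collapse = ","))

  if (write_images) {
    scene_dir <- file.path(out_dir, "scenes")
    for (i in seq_along(cohort))
      write_scene(cohort[[i]], scene_dir, sprintf("cell_%03d", i))
  }

  cal_idx <- seq_len(min(cfg$calibrate$n_images, length(cohort)))
  unit <- calibrate_unit(
    lapply(cal_idx, function(i) cohort[[i]]$mrna),
    cell_masks = lapply(cal_idx, function(i) cohort[[i]]$scene$cell_mask),
    min_separation_px = cfg$calibrate$min_separation_px,
    k_sigma = cfg$calibrate$k_sigma,
    window_px = cfg$calibrate$window_px,
    size_bounds = cfg$calibrate$size_bounds,
    trim_step = cfg$calibrate$trim_step,
    unimodality_threshold = cfg$calibrate$unimodality_threshold,
    min_support = cfg$calibrate$min_support)
  message("calibrate: A=", signif(unit$amplitude, 4),
          " sigma=", signif(unit$sigma, 4),
          " n_support=", unit$n_support)
  jsonlite::write_json(unclass(unit)[c("amplitude", "sigma",
                                       "integrated_intensity", "n_support",
                                       "trim_fraction_applied")],
                       file.path(out_dir, "unit.json"),
                       auto_unbox = TRUE, digits = NA)

  simulated <- cfg$estimate$estimator == "simulated"
  records <- cohort_records(cohort, unit = unit, simulated = simulated,
                            n_reps = cfg$estimate$n_reps,
                            master_seed = cfg$master_seed + 1L,
                            jitter_px = cfg$estimate$jitter_px)
  message("estimate: estimator=", cfg$estimate$estimator,
          " n_reps=", cfg$estimate$n_reps)
  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)

  est <- cfg$estimate$estimator
  comparison <- compare_anterior_posterior(records, est,
                                           paired = cfg$stats$paired)
  by_position <- compare_by_stream_position(records, est,
                                            paired = cfg$stats$paired)
  correlation <- mrna_protein_correlation(records)
  stats_out <- list(
    overall = list(medians = as.list(comparison$medians),
                   t_statistic = comparison$t_statistic,
                   p_value = comparison$p_value,
                   significant = isTRUE(comparison$p_value <
                                          cfg$stats$alpha)),
    by_position = lapply(by_position, function(cmp) list(
      medians = as.list(cmp$medians),
      mean_mrna_posterior_fraction = cmp$mean_mrna_posterior_fraction,
      t_statistic = cmp$t_statistic, p_value = cmp$p_value)),
    correlation = correlation)
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  message("stats: overall p=", format.pval(comparison$p_value))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("fishpol")),
    master_seed = cfg$master_seed,
    config = unclass(cfg),
    files = as.list(tools::md5sum(files)))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(records = records, unit = unit, comparison = comparison,
                 by_position = by_position, correlation = correlation,
                 config = cfg))
}
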