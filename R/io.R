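#' Read an organelle-fraction time course from CSV
#'
#' Expects columns `time_min`, `organelle`, `mean`, `sd`, `n`. Organelle
#' names are normalized to the canonical compartment labels
#' ([normalize_organelle()]). Duplicate (time, organelle) pairs, negative
#' standard deviations and missing columns are rejected with descriptive
#' errors.
#'
#' @param path CSV file path.
#' @return Validated tibble with the five columns above.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tc <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_min", "organelle", "mean", "sd", "n")
  miss <- setdiff(need, names(tc))
  if (length(miss) > 0) {
    abort(paste0("Time-course CSV ", path, " is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tc <- dplyr::select(tc, dplyr::all_of(need))
  tc$organelle <- normalize_organelle(tc$organelle)
  if (any(is.na(tc$time_min)) || any(tc$time_min < 0)) {
    abort("time_min must be non-negative and complete.")
  }
  bad_sd <- which(is.na(tc$sd) | tc$sd < 0)
  if (length(bad_sd) > 0) {
    abort(paste0("Negative or missing sd at data line(s): ",
                 paste(bad_sd + 1, collapse = ", ")))
  }
  dup <- which(duplicated(tc[c("time_min", "organelle")]))
  if (length(dup) > 0) {
    abort(paste0("Duplicate (time_min, organelle) at data line(s): ",
                 paste(dup + 1, collapse = ", ")))
  }
  tc
}

#' Write a time course to CSV
#'
#' @param timecourse Tibble with columns `time_min`, `organelle`, `mean`,
#'   `sd`, `n`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(timecourse, path) {
  need <- c("time_min", "organelle", "mean", "sd", "n")
  if (!all(need %in% names(timecourse))) {
    abort(paste0("timecourse must have columns: ",
                 paste(need, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(tibble::as_tibble(timecourse),
                                 dplyr::all_of(need)), path)
  invisible(path)
}

#' Write a lipid channel and probability maps as multi-page TIFF
#'
#' Page order: the lipid channel first, then one probability map per
#' organelle in alphabetical order of the organelle names (TIFF stores no
#' channel names, so the order is the contract; [read_organelle_tiff()]
#' restores names from the sorted organelle list).
#'
#' @param lipid Numeric matrix.
#' @param prob_maps Named list of probability maps.
#' @param path Output TIFF path.
#' @param scale Intensities are divided by `scale` before writing (TIFF
#'   float pages written as 32-bit); default scales lipid by its max.
#' @return `path`, invisibly.
#' @export
write_organelle_tiff <- function(lipid, prob_maps, path, scale = NULL) {
  check_prob_maps(prob_maps)
  if (is.null(scale)) scale <- max(max(lipid), 1)
  pages <- c(list(lipid / scale), prob_maps[sort(names(prob_maps))])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page organelle TIFF
#'
#' @param path TIFF path written by [write_organelle_tiff()].
#' @param organelles Character vector of organelle names (sorted
#'   alphabetically to match page order).
#' @param scale Factor to multiply the lipid page by (undo the write-side
#'   scaling).
#' @return List with `lipid` (matrix) and `prob_maps` (named list).
#' @export
read_organelle_tiff <- function(path, organelles, scale = 1) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(organelles) + 1) {
    abort(paste0("Expected ", length(organelles) + 1, " pages, found ",
                 length(pages), "."))
  }
  list(
    lipid = pages[[1]] * scale,
    prob_maps = setNames(pages[-1], sort(organelles))
  )
}

#' Write a fitted model to JSON
#'
#' Serializes point estimates, Monte Carlo samples and summaries so that a
#' comparison between conditions can be computed later without refitting.
#'
#' @param fit A `flux_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "flux_fit"))
  payload <- list(
    preset = fit$model$preset,
    point_estimate = as.list(fit$point_estimate),
    objective = fit$objective,
    x0 = as.list(fit$x0),
    content_decay_rate = fit$content_decay_rate,
    n_starts = fit$n_starts,
    seed = fit$seed,
    mc_samples = if (!is.null(fit$mc_samples)) {
      as.data.frame(fit$mc_samples)
    },
    mc_summary = fit$mc_summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' Restores the parts of a [write_fit_json()] file needed for comparisons
#' ([fold_change()], [quasi_equilibrium()]): point estimate, MC samples and
#' summaries. The fitted data themselves are not stored.
#'
#' @param path JSON path.
#' @return A `flux_fit` (without `data`).
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(
    point_estimate = unlist(p$point_estimate),
    objective = p$objective,
    model = flux_model(p$preset),
    x0 = unlist(p$x0),
    content_decay_rate = p$content_decay_rate,
    n_starts = p$n_starts,
    seed = p$seed,
    mc_samples = if (!is.null(p$mc_samples)) as.matrix(p$mc_samples),
    mc_summary = if (!is.null(p$mc_summary)) tibble::as_tibble(p$mc_summary)
  )
  structure(fit, class = "flux_fit")
}

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected;
#' the object round-trips losslessly through [write_config()] /
#' [read_config()].
#'
#' @param preset Model preset id (see [flux_model()]).
#' @param threshold Probability-map cutoff for masks.
#' @param n_mc Monte Carlo runs for uncertainty.
#' @param n_starts Multi-starts for the point fit.
#' @param seed Master seed; all pipeline randomness flows from it.
#' @param out_dir Output directory.
#' @param timecourse_csv,ms_csv Optional paths to real input tables; when
#'   `NULL` the synthetic block is used.
#' @param synthetic Named list of generator settings (`rates`, `noise_sd`,
#'   `n_fields`, `timepoints`, `k_met`, `content_decay_rate`,
#'   `loading_frac`); defaults fill anything unset.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "1a", threshold = 0.5, n_mc = 100,
                            n_starts = 20, seed = 1, out_dir = ".",
                            timecourse_csv = NULL, ms_csv = NULL,
                            synthetic = list()) {
  known_syn <- c("rates", "noise_sd", "n_fields", "timepoints", "k_met",
                 "content_decay_rate", "loading_frac")
  unknown <- setdiff(names(synthetic), known_syn)
  if (length(unknown) > 0) {
    abort(paste0("Unknown synthetic config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  flux_model(preset)  # validates the preset
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1).")
  if (n_mc < 2) abort("n_mc must be >= 2.")
  structure(
    list(
      preset = preset, threshold = threshold, n_mc = n_mc,
      n_starts = n_starts, seed = as.integer(seed), out_dir = out_dir,
      timecourse_csv = timecourse_csv, ms_csv = ms_csv,
      synthetic = synthetic
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preset", "threshold", "n_mc", "n_starts", "seed", "out_dir",
             "timecourse_csv", "ms_csv", "synthetic")
  unknown <- setdiff(names(p), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  syn <- if (is.null(p$synthetic)) list() else as.list(p$synthetic)
  if (!is.null(syn$rates)) syn$rates <- unlist(syn$rates)
  if (!is.null(syn$timepoints)) syn$timepoints <- as.numeric(syn$timepoints)
  do.call(pipeline_config, c(
    p[setdiff(intersect(known, names(p)), "synthetic")],
    list(synthetic = syn)
  ))
}
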