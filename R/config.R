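#' Read a pipeline configuration file
#'
#' JSON configuration holding any of `params` (fields of
#' [kinetics_params()]), `design` (`trials` as a list of
#' `{name, treatment_tanks, control_tanks}`, plus any other
#' [study_design()] field), `settings` (fields of [sampler_settings()]),
#' `analysis` (fields of [analysis_config()] other than `settings`) and
#' `seed`. Missing entries fall back to package defaults.
#'
#' @param path Path to a JSON file.
#' @return List with elements `params`, `design`, `settings`, `analysis`
#'   (an [analysis_config()]) and `seed`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(kinetics_params, as.list(cfg$params))
  design_args <- as.list(cfg$design)
  if (!is.null(design_args$trials)) {
    tr <- design_args$trials
    design_args$trials <- lapply(seq_len(nrow(tr)), function(i)
      trial_spec(tr$name[i], tr$treatment_tanks[i], tr$control_tanks[i]))
  }
  design <- do.call(study_design, design_args)
  settings <- do.call(sampler_settings, as.list(cfg$settings))
  analysis_args <- as.list(cfg$analysis)
  analysis_args$settings <- settings
  analysis <- do.call(analysis_config, analysis_args)
  list(params = params, design = design, settings = settings,
       analysis = analysis,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Write the default configuration as a JSON template
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  p <- kinetics_params()
  d <- study_design()
  s <- sampler_settings()
  cfg <- list(
    params = unclass(p),
    design = list(
      trials = data.frame(
        name = vapply(d$trials, `[[`, "", "name"),
        treatment_tanks = vapply(d$trials, `[[`, 0L, "treatment_tanks"),
        control_tanks = vapply(d$trials, `[[`, 0L, "control_tanks")),
      fish_per_tank = d$fish_per_tank,
      sampling_times = d$sampling_times,
      first_window = d$first_window,
      second_window = d$second_window,
      min_resample_gap = d$min_resample_gap),
    settings = unclass(s),
    analysis = list(plasma_window = c(0, 12), mucus_window = c(0, 84),
                    grid_step = 0.1, pairing = "shuffle", pairing_seed = 1,
                    align = "per_draw"),
    seed = 1)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
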