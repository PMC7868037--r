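#' Default pipeline configuration
#'
#' Bundles every tunable of the full analysis: sampler settings, constraint
#' windows per matrix, positivity/curve grid step, draw-pairing rule and the
#' control-alignment rule for exceedance.
#'
#' @param settings A [sampler_settings()].
#' @param plasma_window,mucus_window Analysis windows (h).
#' @param grid_step Grid spacing for positivity checks and curve exports (h).
#' @param pairing Draw-pairing rule, `"shuffle"` or `"index"`.
#' @param pairing_seed Seed for the pairing shuffle.
#' @param align Exceedance control alignment, `"per_draw"` or
#'   `"posterior_mean"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(settings = sampler_settings(),
                            plasma_window = c(0, 12),
                            mucus_window = c(0, 84),
                            grid_step = 0.1,
                            pairing = "shuffle",
                            pairing_seed = 1L,
                            align = "per_draw") {
  stopifnot(inherits(settings, "sampler_settings"))
  structure(list(settings = settings, plasma_window = plasma_window,
                 mucus_window = mucus_window, grid_step = grid_step,
                 pairing = pairing, pairing_seed = as.integer(pairing_seed),
                 align = align),
            class = "analysis_config")
}

# run one stage with context added to any failure
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full multi-tissue analysis pipeline
#'
#' Executes the complete workflow on a validated measurement table holding
#' both trials, both matrices and both arms: six model fits (treatment fits
#' for ACTH-plasma, ACTH-mucus, cortisol-plasma, cortisol-mucus, plus
#' pooled-control fits per matrix), constraint filtering with the
#' matrix-specific windows (plasma 0--12 h, mucus 0--84 h), derived-parameter
#' computation and 90% CI summaries, four treatment-vs-pooled-control
#' proportional curves, and four exceedance results against the time-0 mean
#' and temporally aligned control curves.
#'
#' @param table A validated measurement table.
#' @param config An [analysis_config()].
#' @return An `analysis_report`: list with `fits` (named `posterior_draws`),
#'   `derived` (named data.frames), `summaries` (long data.frame: group,
#'   quantity, mean, ci_low, ci_high, n_draws), `curves` (named
#'   `proportional_curve`s), `exceedance` (data.frame), `baselines`, and
#'   `log` (character lines recording retained-draw counts and exclusions).
#' @export
run_full_analysis <- function(table, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  validate_measurements(table)
  for (need in list(c("trial", "ACTH"), c("trial", "cortisol"),
                    c("matrix", "plasma"), c("matrix", "mucus"),
                    c("arm", "treatment"), c("arm", "control")))
    if (!any(table[[need[1]]] == need[2]))
      stop("run_full_analysis: table has no ", need[1], " = ", need[2], " rows")

  windows <- list(plasma = config$plasma_window, mucus = config$mucus_window)
  groups <- list(
    ACTH_plasma = list(trial = "ACTH", matrix = "plasma"),
    ACTH_mucus = list(trial = "ACTH", matrix = "mucus"),
    cortisol_plasma = list(trial = "cortisol", matrix = "plasma"),
    cortisol_mucus = list(trial = "cortisol", matrix = "mucus"))

  fits <- list(); derived <- list(); baselines <- list()
  logs <- character()
  summaries <- list()

  fit_one <- function(name, sub, window) {
    pd <- .stage(paste0("fit:", name), fit_cubic(sub, config$settings))
    pd <- .stage(paste0("filter:", name),
                 constraint_filter(pd, window, config$grid_step))
    logs <<- c(logs, sprintf("%s: n_obs=%d max_rhat=%.4f retained=%d/%d",
                             name, pd$n_obs, max(pd$rhat),
                             pd$filter_info$n_retained, pd$filter_info$n_total))
    pd
  }

  for (name in names(groups)) {
    g <- groups[[name]]
    sub <- .stage(paste0("subset:", name),
                  subset_for_model(table, g$trial, g$matrix, "treatment",
                                   plasma_cutoff = config$plasma_window[2]))
    fits[[name]] <- fit_one(name, sub, windows[[g$matrix]])
    derived[[name]] <- .stage(paste0("derive:", name),
                              derive_all(fits[[name]]))
    baselines[[name]] <- .stage(paste0("baseline:", name),
                                baseline_summary(sub, time = 0))
    s <- summarize_derived(derived[[name]])
    s <- cbind(group = name, s)
    summaries[[name]] <- s
  }
  for (mx in c("plasma", "mucus")) {
    name <- paste0("control_", mx)
    sub <- .stage(paste0("subset:", name),
                  subset_for_model(table, matrix = mx, arm = "control",
                                   pool_controls = TRUE,
                                   plasma_cutoff = config$plasma_window[2]))
    fits[[name]] <- fit_one(name, sub, windows[[mx]])
    derived[[name]] <- .stage(paste0("derive:", name),
                              derive_all(fits[[name]]))
    summaries[[name]] <- cbind(group = name, summarize_derived(derived[[name]]))
  }

  curves <- list(); exc <- list()
  for (name in names(groups)) {
    g <- groups[[name]]
    ctrl <- fits[[paste0("control_", g$matrix)]]
    w <- windows[[g$matrix]]
    grid <- seq(w[1], w[2], by = config$grid_step)
    curves[[name]] <- .stage(paste0("ratio:", name),
      proportional_curve(fits[[name]], ctrl, grid,
                         pairing = config$pairing,
                         pairing_seed = config$pairing_seed))
    logs <- c(logs, sprintf("ratio %s: n_pairs=%d excluded_points=%d", name,
                            attr(curves[[name]], "n_pairs"),
                            attr(curves[[name]], "n_excluded")))
    e <- .stage(paste0("exceedance:", name),
      exceedance(derived[[name]], baselines[[name]]$mean, ctrl,
                 pairing = config$pairing,
                 pairing_seed = config$pairing_seed, align = config$align))
    exc[[name]] <- data.frame(group = name, p_above_t0 = e$p_above_t0,
                              p_above_control = e$p_above_control,
                              n_draws = e$n_draws, n_pairs = e$n_pairs)
  }

  out <- list(fits = fits, derived = derived,
              summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
              curves = curves,
              exceedance = do.call(rbind, c(exc, make.row.names = FALSE)),
              baselines = baselines, config = config, log = logs)
  class(out) <- "analysis_report"
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Multi-tissue cortisol kinetics analysis report\n")
  cat(length(x$fits), "model fits,", length(x$curves),
      "treatment-vs-control comparisons\n\n")
  s <- x$summaries
  s$mean <- round(s$mean, 2); s$ci_low <- round(s$ci_low, 2)
  s$ci_high <- round(s$ci_high, 2)
  print(s, row.names = FALSE)
  cat("\nExceedance probabilities (cort_max above threshold):\n")
  e <- x$exceedance
  e$p_above_t0 <- round(e$p_above_t0, 3)
  e$p_above_control <- round(e$p_above_control, 3)
  print(e, row.names = FALSE)
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits `summary.csv` (group x quantity: mean, ci_low, ci_high, n_draws),
#' `exceedance.csv`, one `curve_<group>.csv` per proportional curve, one
#' `draws_<group>.csv` per fit (via [export_draws()]), and `pipeline.log`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summaries, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$exceedance, file.path(dir, "exceedance.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(report$curves))
    utils::write.csv(report$curves[[nm]], file.path(dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  for (nm in names(report$fits))
    export_draws(report$fits[[nm]], file.path(dir, paste0("draws_", nm, ".csv")))
  writeLines(report$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
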