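#' Simulate a complete study dataset
#'
#' Generates a tidy measurement table with the structure the analysis
#' expects: one plasma row and one mucus row for every (fish, sampling
#' event). Within each tank a seeded permutation of the fish is assigned
#' round-robin to the early-window sampling times in increasing order; the
#' same rank order is reused for the late-window times, which guarantees the
#' minimum resampling gap by construction (earliest late time minus latest
#' early time is at least the gap in the default design, and the assignment
#' is checked explicitly).
#'
#' Observed concentrations are
#' `true_curve(...) * fish_multiplier * assay_noise`, where the fish
#' multiplier is lognormal with log-sd `fish_sd_log` and the assay noise is
#' lognormal with coefficient of variation `cv_plasma`/`cv_mucus`; both are
#' mean-1 (log-mean `-sdlog^2/2`) so noise does not bias the curve.
#' Multiplicative noise keeps every concentration strictly positive.
#'
#' The caller's RNG state is saved and restored, so the same
#' `(design, params, seed)` triple always yields an identical table.
#'
#' @param design A [study_design()].
#' @param params A [kinetics_params()].
#' @param seed Integer seed controlling fish assignment and noise.
#' @return A validated measurement table (`data.frame`) with columns
#'   `fish_id`, `tank_id`, `trial`, `arm`, `matrix`, `time_h`,
#'   `cortisol_ng_ml`.
#' @export
#' @examples
#' tab <- simulate_study(acth_design(), kinetics_params(), seed = 1)
#' nrow(tab)  # 20 fish x 2 sampling events x 2 matrices = 80 rows
simulate_study <- function(design = study_design(), params = kinetics_params(),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(params, "kinetics_params"))
  wt <- .window_times(design)
  n_events <- length(wt$first) + length(wt$second)
  if (length(wt$first) != design$fish_per_tank ||
      length(wt$second) != design$fish_per_tank)
    stop("simulate_study: design needs exactly fish_per_tank (",
         design$fish_per_tank, ") sampling times per window to sample one ",
         "fish per tank per event twice; got ", length(wt$first), " early and ",
         length(wt$second), " late times for ", n_events, " events")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  t1 <- sort(wt$first); t2 <- sort(wt$second)
  rows <- list()
  for (trial in design$trials) {
    n_tanks <- trial$treatment_tanks + trial$control_tanks
    arms <- rep(c("treatment", "control"),
                c(trial$treatment_tanks, trial$control_tanks))
    for (k in seq_len(n_tanks)) {
      tank_id <- sprintf("%s_tank%d", trial$name, k)
      fish <- sprintf("%s_t%d_f%d", trial$name, k, seq_len(design$fish_per_tank))
      perm <- sample(design$fish_per_tank)
      # per-fish lognormal multiplier, mean 1
      fmult <- stats::rlnorm(design$fish_per_tank,
                             meanlog = -params$fish_sd_log^2 / 2,
                             sdlog = params$fish_sd_log)
      sched <- data.frame(fish = fish[perm],
                          fmult = fmult[perm],
                          first = t1, second = t2)
      if (any(sched$second - sched$first < design$min_resample_gap))
        stop("simulate_study: rank assignment violates the minimum resample gap")
      for (i in seq_len(nrow(sched))) {
        for (tm in c(sched$first[i], sched$second[i])) {
          for (mx in c("plasma", "mucus")) {
            cv <- if (mx == "plasma") params$cv_plasma else params$cv_mucus
            mu <- true_curve(params, mx, arms[k], tm) * sched$fmult[i]
            if (cv > 0) {
              sdl <- sqrt(log1p(cv^2))
              mu <- mu * stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)
            }
            rows[[length(rows) + 1L]] <- data.frame(
              fish_id = sched$fish[i], tank_id = tank_id, trial = trial$name,
              arm = arms[k], matrix = mx, time_h = tm, cortisol_ng_ml = mu)
          }
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$trial, tab$tank_id, tab$time_h, tab$fish_id, tab$matrix)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  validate_measurements(tab, design)
  tab
}
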