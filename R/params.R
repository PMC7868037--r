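#' Kinetic parameters for the two-compartment cortisol simulator
#'
#' Ground-truth parameters of the simulated stress response. Plasma cortisol
#' is modelled as a baseline plus a handling-stress spike that decays
#' exponentially from the moment of injection, plus (treatment arm only) a
#' Bateman pulse with first-order absorption and elimination. Mucus cortisol
#' follows plasma through a first-order transfer compartment with its own
#' elimination rate, capturing the delayed, attenuated response of epidermal
#' mucus relative to blood.
#'
#' Defaults are chosen so that the noiseless treatment curves place the
#' plasma peak near 12 h and the mucus peak near 62 h post-injection, with
#' peak concentrations of roughly 470 ng/ml (plasma) and 21 ng/ml (mucus) --
#' magnitudes typical of an ACTH challenge in a large flatfish. Assay CVs
#' default to the intra-assay values reported for commercial cortisol ELISA
#' kits on plasma and mucus matrices (10.95% and 12.66%).
#'
#' @param baseline_plasma Resting plasma cortisol, ng/ml.
#' @param baseline_mucus Resting mucus cortisol, ng/ml.
#' @param handling_amp Amplitude of the handling-stress plasma spike at
#'   injection, ng/ml (applies to both arms).
#' @param handling_decay First-order decay rate of the handling spike, 1/h.
#' @param pulse_amp Dose-scale amplitude of the treatment plasma pulse, ng/ml.
#' @param k_abs First-order absorption rate of the pulse, 1/h.
#' @param k_elim First-order plasma elimination rate, 1/h. Must differ from
#'   `k_abs` (the Bateman form is degenerate at equality).
#' @param k_transfer Plasma-to-mucus transfer rate, 1/h.
#' @param k_mucus Mucus elimination rate, 1/h.
#' @param fish_sd_log Between-fish lognormal multiplier sd (log scale,
#'   dimensionless).
#' @param cv_plasma,cv_mucus Assay coefficients of variation (fractions in
#'   `[0, 1)`), applied as multiplicative lognormal noise.
#'
#' @return An object of class `kinetics_params` (a validated named list).
#' @seealso [true_curve()], [simulate_study()], [true_peak()]
#' @export
#' @examples
#' p <- kinetics_params()
#' true_curve(p, "plasma", "treatment", c(0, 12, 24))
kinetics_params <- function(baseline_plasma = 50,
                            baseline_mucus = 5,
                            handling_amp = 180,
                            handling_decay = 0.25,
                            pulse_amp = 750,
                            k_abs = 0.125,
                            k_elim = 0.05,
                            k_transfer = 0.0013,
                            k_mucus = 0.0045,
                            fish_sd_log = 0.3,
                            cv_plasma = 0.1095,
                            cv_mucus = 0.1266) {
  p <- list(baseline_plasma = baseline_plasma, baseline_mucus = baseline_mucus,
            handling_amp = handling_amp, handling_decay = handling_decay,
            pulse_amp = pulse_amp, k_abs = k_abs, k_elim = k_elim,
            k_transfer = k_transfer, k_mucus = k_mucus,
            fish_sd_log = fish_sd_log,
            cv_plasma = cv_plasma, cv_mucus = cv_mucus)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("kinetics_params: '", nm, "' must be a single finite number")
  }
  rates <- c("handling_decay", "k_abs", "k_elim", "k_transfer", "k_mucus")
  for (nm in rates)
    if (p[[nm]] <= 0) stop("kinetics_params: rate '", nm, "' must be > 0")
  if (p$k_abs == p$k_elim)
    stop("kinetics_params: k_abs must differ from k_elim (degenerate Bateman form)")
  amps <- c("baseline_plasma", "baseline_mucus", "handling_amp", "pulse_amp")
  for (nm in amps)
    if (p[[nm]] < 0) stop("kinetics_params: '", nm, "' must be >= 0")
  if (p$baseline_plasma <= 0 || p$baseline_mucus <= 0)
    stop("kinetics_params: baselines must be > 0 (concentrations are strictly positive)")
  if (p$fish_sd_log < 0)
    stop("kinetics_params: fish_sd_log must be >= 0")
  for (nm in c("cv_plasma", "cv_mucus"))
    if (p[[nm]] < 0 || p[[nm]] >= 1)
      stop("kinetics_params: '", nm, "' must lie in [0, 1)")
  structure(p, class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Two-compartment cortisol kinetics parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Specify one injection trial of the study design
#'
#' @param name Trial label, `"ACTH"` or `"cortisol"`.
#' @param treatment_tanks,control_tanks Number of tanks assigned to each arm.
#' @return A `trial_spec` list.
#' @export
trial_spec <- function(name, treatment_tanks, control_tanks) {
  name <- match.arg(name, c("ACTH", "cortisol"))
  stopifnot(treatment_tanks >= 0, control_tanks >= 0,
            treatment_tanks + control_tanks >= 1)
  structure(list(name = name,
                 treatment_tanks = as.integer(treatment_tanks),
                 control_tanks = as.integer(control_tanks)),
            class = "trial_spec")
}

#' Tank-based repeated-sampling study design
#'
#' Describes the experimental layout the simulator reproduces: tanks of fish
#' randomised to treatment or control at the tank level, a fixed set of
#' post-injection sampling times, one fish sampled per tank per sampling
#' event, and each fish sampled exactly twice -- once in an early window and
#' once in a late window, separated by at least `min_resample_gap` hours for
#' recovery.
#'
#' The default reproduces a two-trial design: an ACTH trial with 3 treatment
#' tanks and 1 control tank, and a cortisol-injection trial with 2 treatment
#' and 2 control tanks, 5 fish per tank, sampled at 0, 2, 4, 8, 12, 24, 36,
#' 48, 72 and 84 hours post-injection.
#'
#' @param trials List of [trial_spec()] objects.
#' @param fish_per_tank Fish per tank.
#' @param sampling_times Strictly increasing, non-negative sampling times (h).
#' @param first_window,second_window Two-element numeric ranges (h) splitting
#'   the sampling times into the early and late sampling events.
#' @param min_resample_gap Minimum hours between the two samplings of a fish.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design()                # both trials
#' acth_design()                 # ACTH trial only
study_design <- function(trials = list(trial_spec("ACTH", 3, 1),
                                       trial_spec("cortisol", 2, 2)),
                         fish_per_tank = 5,
                         sampling_times = c(0, 2, 4, 8, 12, 24, 36, 48, 72, 84),
                         first_window = c(0, 12),
                         second_window = c(24, 84),
                         min_resample_gap = 24) {
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "trial_spec")))
    stop("study_design: 'trials' must be a non-empty list of trial_spec objects")
  if (anyDuplicated(vapply(trials, `[[`, "", "name")))
    stop("study_design: duplicated trial names")
  if (any(sampling_times < 0) || is.unsorted(sampling_times, strictly = TRUE))
    stop("study_design: sampling_times must be non-negative and strictly increasing")
  stopifnot(length(first_window) == 2, length(second_window) == 2,
            first_window[1] <= first_window[2],
            second_window[1] <= second_window[2],
            fish_per_tank >= 1, min_resample_gap >= 0)
  in1 <- sampling_times >= first_window[1] & sampling_times <= first_window[2]
  in2 <- sampling_times >= second_window[1] & sampling_times <= second_window[2]
  if (any(in1 & in2)) stop("study_design: sampling windows overlap")
  if (!all(in1 | in2))
    stop("study_design: every sampling time must fall in one of the two windows")
  structure(list(trials = trials,
                 fish_per_tank = as.integer(fish_per_tank),
                 sampling_times = as.numeric(sampling_times),
                 first_window = as.numeric(first_window),
                 second_window = as.numeric(second_window),
                 min_resample_gap = as.numeric(min_resample_gap)),
            class = "study_design")
}

#' @rdname study_design
#' @export
acth_design <- function() study_design(trials = list(trial_spec("ACTH", 3, 1)))

#' @rdname study_design
#' @export
cortisol_design <- function() study_design(trials = list(trial_spec("cortisol", 2, 2)))

# sampling times falling in each window
.window_times <- function(design) {
  st <- design$sampling_times
  list(first = st[st >= design$first_window[1] & st <= design$first_window[2]],
       second = st[st >= design$second_window[1] & st <= design$second_window[2]])
}

#' Default analysis window for a matrix
#'
#' Plasma analyses are restricted to the first sampling window (0--12 h) to
#' avoid confounding by repeat sampling; mucus analyses span the full
#' experimental timeframe (0--84 h).
#'
#' @param matrix `"plasma"` or `"mucus"`.
#' @param design A [study_design()]; defaults to the standard design.
#' @return Numeric length-2 window in hours.
#' @export
matrix_window <- function(matrix = c("plasma", "mucus"), design = study_design()) {
  matrix <- match.arg(matrix)
  if (matrix == "plasma") design$first_window
  else c(min(design$sampling_times), max(design$sampling_times))
}
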