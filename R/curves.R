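# Closed-form convolution kernel: int_0^t exp(-a s) exp(-km (t - s)) ds.
# Uses the t*exp(-a t) limit when the two rates coincide to within 1e-8.
.conv_exp <- function(a, km, t) {
  if (abs(km - a) < 1e-8) t * exp(-a * t)
  else (exp(-a * t) - exp(-km * t)) / (km - a)
}

# Plasma excess over baseline: handling spike + (treatment) Bateman pulse.
.plasma_excess <- function(params, arm, t) {
  ex <- params$handling_amp * exp(-params$handling_decay * t)
  if (arm == "treatment") {
    ka <- params$k_abs; ke <- params$k_elim
    ex <- ex + params$pulse_amp * (ka / (ka - ke)) *
      (exp(-ke * t) - exp(-ka * t))
  }
  ex
}

#' Ground-truth cortisol concentration curve
#'
#' Evaluates the simulator's noiseless concentration at time `t`
#' post-injection. Plasma is a baseline plus an exponentially decaying
#' handling-stress spike plus, in the treatment arm, a Bateman
#' (difference-of-exponentials) pulse. Mucus solves
#' \deqn{dC_m/dt = k_{transfer}(C_p(t) - baseline_p) - k_{mucus}(C_m - baseline_m)}
#' in closed form (a sum of two-exponential convolutions; coincident rates
#' are handled by their analytic limit, switch tolerance 1e-8 on the rate
#' difference).
#'
#' @param params A [kinetics_params()] object.
#' @param matrix `"plasma"` or `"mucus"`.
#' @param arm `"treatment"` or `"control"`.
#' @param t Numeric vector of times, hours, all `>= 0`.
#' @return Numeric vector of concentrations (ng/ml), strictly positive.
#' @export
#' @examples
#' p <- kinetics_params()
#' true_curve(p, "mucus", "treatment", seq(0, 84, by = 12))
true_curve <- function(params, matrix = c("plasma", "mucus"),
                       arm = c("treatment", "control"), t) {
  stopifnot(inherits(params, "kinetics_params"))
  matrix <- match.arg(matrix)
  arm <- match.arg(arm)
  if (any(t < 0)) stop("true_curve: t must be >= 0")
  if (params$k_abs == params$k_elim)
    stop("true_curve: k_abs equals k_elim (degenerate Bateman form)")
  if (matrix == "plasma")
    return(params$baseline_plasma + .plasma_excess(params, arm, t))
  # mucus: convolution of the plasma excess with exp(-k_mucus u)
  km <- params$k_mucus
  resp <- params$handling_amp * .conv_exp(params$handling_decay, km, t)
  if (arm == "treatment") {
    ka <- params$k_abs; ke <- params$k_elim
    amp <- params$pulse_amp * (ka / (ka - ke))
    resp <- resp + amp * (.conv_exp(ke, km, t) - .conv_exp(ka, km, t))
  }
  params$baseline_mucus + params$k_transfer * resp
}

#' Ground-truth peak of the treatment curve
#'
#' Locates the maximum of [true_curve()] for the treatment arm over the
#' matrix's analysis window by dense grid search (step `<= 0.01` h) refined
#' with [stats::optimize()]. If the curve is monotone on the window the
#' window endpoint is returned with `at_boundary = TRUE`.
#'
#' @inheritParams true_curve
#' @param window Numeric length-2 search window in hours; defaults to
#'   [matrix_window()] for the matrix.
#' @param step Grid step in hours (upper bound 0.01 enforced).
#' @return List with `t_peak` (h), `c_peak` (ng/ml) and `at_boundary`.
#' @export
true_peak <- function(params, matrix = c("plasma", "mucus"),
                      window = NULL, step = 0.01) {
  matrix <- match.arg(matrix)
  if (is.null(window)) window <- matrix_window(matrix)
  stopifnot(length(window) == 2, window[1] < window[2], step > 0)
  step <- min(step, 0.01)
  grid <- seq(window[1], window[2], by = step)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  vals <- true_curve(params, matrix, "treatment", grid)
  i <- which.max(vals)
  if (i == 1L || i == length(grid)) {
    return(list(t_peak = grid[i], c_peak = vals[i], at_boundary = TRUE))
  }
  opt <- stats::optimize(function(x) true_curve(params, matrix, "treatment", x),
                         lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = 1e-8)
  list(t_peak = opt$maximum, c_peak = opt$objective, at_boundary = FALSE)
}
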