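# Vectorised critical points for an n x 4 coefficient matrix.
# Returns data.frame(t_max, t_min) with NA where the extremum is absent.
.critical_points_matrix <- function(B) {
  b1 <- B[, 2]; b2 <- B[, 3]; b3 <- B[, 4]
  n <- nrow(B)
  t_max <- rep(NA_real_, n)
  t_min <- rep(NA_real_, n)
  cubic <- b3 != 0
  # degenerate cubic term: quadratic curve, single critical point -b1/(2 b2)
  quad <- !cubic & b2 != 0
  if (any(quad)) {
    t0 <- -b1[quad] / (2 * b2[quad])
    is_max <- b2[quad] < 0
    t_max[quad][is_max] <- t0[is_max]
    t_min[quad][!is_max] <- t0[!is_max]
  }
  if (any(cubic)) {
    disc <- 4 * b2[cubic]^2 - 12 * b3[cubic] * b1[cubic]
    ok <- disc > 0                       # disc <= 0: no strict interior extremum
    idx <- which(cubic)[ok]
    if (length(idx)) {
      sq <- sqrt(disc[ok])
      r1 <- (-2 * b2[idx] + sq) / (6 * b3[idx])
      r2 <- (-2 * b2[idx] - sq) / (6 * b3[idx])
      # classify by the second derivative 6 b3 t + 2 b2
      f2r1 <- 6 * b3[idx] * r1 + 2 * b2[idx]
      t_max[idx] <- ifelse(f2r1 < 0, r1, r2)
      t_min[idx] <- ifelse(f2r1 < 0, r2, r1)
    }
  }
  data.frame(t_max = t_max, t_min = t_min)
}

#' Critical points of a cubic curve
#'
#' Solves `3 b3 t^2 + 2 b2 t + b1 = 0` by the quadratic formula and
#' classifies each root by the sign of the second derivative
#' `6 b3 t + 2 b2` (negative: local maximum). Absence of an extremum --
#' negative discriminant, or a degenerate polynomial with no interior
#' extremum -- is a value (`NA`), not an error.
#'
#' @param coeffs Numeric vector `c(b0, b1, b2, b3)`.
#' @return List with `t_max` and `t_min` (hours; `NA` when absent).
#' @export
#' @examples
#' critical_points(c(0, 12, -9, 2))  # t_max = 1, t_min = 2
critical_points <- function(coeffs) {
  B <- .coef_matrix(coeffs)
  cp <- .critical_points_matrix(B)
  list(t_max = cp$t_max[1], t_min = cp$t_min[1])
}

#' A-priori constraint filter for posterior draws
#'
#' Flags each posterior draw as retained or removed according to the two
#' kinetic plausibility constraints: (i) the cubic has a local maximum at
#' time `t > 0`, and (ii) the fitted concentration is strictly positive at
#' every grid point spanning the sampling window. Draws are never deleted;
#' the mask is recorded on the object so removed draws remain inspectable.
#'
#' @param pd A `posterior_draws` object from [fit_cubic()].
#' @param window Numeric length-2 sampling window in hours, e.g. `c(0, 12)`
#'   for plasma or `c(0, 84)` for mucus (see [matrix_window()]).
#' @param grid_step Spacing of the positivity grid (h).
#' @return `pd` with `retained` (logical per draw) and `filter_info` set.
#' @export
constraint_filter <- function(pd, window, grid_step = 0.1) {
  stopifnot(inherits(pd, "posterior_draws"),
            length(window) == 2, window[1] < window[2], grid_step > 0)
  B <- .coef_matrix(pd)
  cp <- .critical_points_matrix(B)
  grid <- seq(window[1], window[2], by = grid_step)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  vals <- predict_curve(B, grid)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  positive <- rowSums(vals <= 0) == 0L
  pd$retained <- !is.na(cp$t_max) & cp$t_max > 0 & positive
  pd$filter_info <- list(window = window, grid_step = grid_step,
                         n_total = nrow(B), n_retained = sum(pd$retained))
  pd
}

#' Derived kinetic quantities per retained draw
#'
#' For every retained draw, computes the time of the local maximum
#' (`t_max`), the time of the local minimum (`t_min`), the curve value at
#' the maximum (`cort_max`), the distribution time (defined as `t_max`) and
#' the elimination time (`t_min - t_max`). Draws whose cubic coefficient is
#' negative have the minimum before the maximum; they satisfy constraint
#' (i) and are retained, but their elimination time is undefined under the
#' min-after-max convention and is reported as `NA` with `elim_flagged`.
#'
#' @param pd A `posterior_draws` object already passed through
#'   [constraint_filter()].
#' @return data.frame with one row per retained draw: `draw` (row index in
#'   `pd$draws`), `chain`, `t_max`, `t_min`, `cort_max`,
#'   `distribution_time`, `elimination_time`, `elim_flagged`.
#' @export
derive_all <- function(pd) {
  stopifnot(inherits(pd, "posterior_draws"))
  if (is.null(pd$retained))
    stop("derive_all: run constraint_filter() first (retained mask not set)")
  if (!any(pd$retained))
    stop("derive_all: no retained draws; all posterior draws violated the ",
         "a-priori constraints")
  keep <- which(pd$retained)
  B <- .coef_matrix(pd)[keep, , drop = FALSE]
  cp <- .critical_points_matrix(B)
  cort_max <- B[, 1] + B[, 2] * cp$t_max + B[, 3] * cp$t_max^2 +
    B[, 4] * cp$t_max^3
  elim <- cp$t_min - cp$t_max
  flagged <- is.na(elim) | elim <= 0
  elim[flagged] <- NA_real_
  data.frame(draw = keep, chain = pd$draws$chain[keep],
             t_max = cp$t_max, t_min = cp$t_min, cort_max = cort_max,
             distribution_time = cp$t_max, elimination_time = elim,
             elim_flagged = flagged)
}

#' Posterior summary of derived kinetic quantities
#'
#' Mean and equal-tailed 90% credible interval (5th and 95th percentiles,
#' linear interpolation between order statistics, R quantile type 7) per
#' derived quantity, plus the retained-draw count. Undefined elimination
#' times (flagged draws) are dropped from that quantity's summary, with the
#' contributing draw count reported per row.
#'
#' @param derived data.frame from [derive_all()].
#' @param level Credible level (default 0.90).
#' @return data.frame with columns `quantity`, `mean`, `ci_low`, `ci_high`,
#'   `n_draws`.
#' @export
summarize_derived <- function(derived, level = 0.90) {
  stopifnot(is.data.frame(derived), nrow(derived) >= 1,
            level > 0, level < 1)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  quantities <- c("t_max", "t_min", "cort_max", "distribution_time",
                  "elimination_time")
  rows <- lapply(quantities, function(qn) {
    v <- derived[[qn]]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(quantity = qn, mean = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n_draws = 0L))
    ci <- stats::quantile(v, qs, names = FALSE, type = 7)
    data.frame(quantity = qn, mean = mean(v), ci_low = ci[1], ci_high = ci[2],
               n_draws = length(v))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(is.na(out$ci_low) | out$ci_low <= out$ci_high))
  out
}
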