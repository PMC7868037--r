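# Pair retained draw indices of two posteriors. "shuffle" permutes both
# retained sets with a seeded RNG before index pairing; both are truncated
# to the shorter length. Treatment and control were fit independently, so
# no natural pairing exists; a seeded shuffle keeps the Monte Carlo error
# of per-pair statistics unbiased and reproducible.
.pair_draws <- function(treat, control, pairing, pairing_seed) {
  if (is.null(treat$retained) || is.null(control$retained))
    stop("both posteriors must be constraint-filtered before pairing")
  ti <- which(treat$retained)
  ci <- which(control$retained)
  if (!length(ti) || !length(ci))
    stop("zero retained draws in ", if (!length(ti)) "treatment" else "control",
         " posterior")
  if (pairing == "shuffle") {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(pairing_seed))
    ti <- ti[sample(length(ti))]
    ci <- ci[sample(length(ci))]
  }
  n <- min(length(ti), length(ci))
  list(treat = ti[seq_len(n)], control = ci[seq_len(n)], n = n)
}

#' Treatment/control proportional curve
#'
#' Divides each treatment posterior curve by a paired control posterior
#' curve on a time grid and summarises the per-pair ratio curves pointwise
#' by their mean and 5th/95th percentiles, yielding the proportional curve
#' with its 90% credible band. A ratio of 1 means the treatment response is
#' indistinguishable from handling alone.
#'
#' Grid points where a pair's control curve is not strictly positive are
#' excluded for that pair (control posteriors are constraint-filtered, so
#' this can only occur outside the filter window); exclusions are counted
#' in the `n_excluded` attribute.
#'
#' @param treat,control Constraint-filtered `posterior_draws` objects.
#' @param grid Numeric time grid (h) within the shared window.
#' @param pairing `"shuffle"` (default, seeded) or `"index"` (pair by
#'   position, useful for exact identities).
#' @param pairing_seed Seed for the shuffle.
#' @return data.frame of class `proportional_curve` with columns `time_h`,
#'   `mean_ratio`, `band_low`, `band_high`; attributes `n_pairs`,
#'   `n_excluded`.
#' @export
proportional_curve <- function(treat, control, grid,
                               pairing = c("shuffle", "index"),
                               pairing_seed = 1L) {
  pairing <- match.arg(pairing)
  pr <- .pair_draws(treat, control, pairing, pairing_seed)
  Bt <- .coef_matrix(treat)[pr$treat, , drop = FALSE]
  Bc <- .coef_matrix(control)[pr$control, , drop = FALSE]
  num <- predict_curve(Bt, grid)
  den <- predict_curve(Bc, grid)
  if (is.null(dim(num))) { num <- matrix(num, 1); den <- matrix(den, 1) }
  bad <- den <= 0
  den[bad] <- NA_real_
  ratio <- num / den
  out <- data.frame(
    time_h = grid,
    mean_ratio = colMeans(ratio, na.rm = TRUE),
    band_low = apply(ratio, 2, stats::quantile, probs = 0.05,
                     na.rm = TRUE, names = FALSE, type = 7),
    band_high = apply(ratio, 2, stats::quantile, probs = 0.95,
                      na.rm = TRUE, names = FALSE, type = 7))
  stopifnot(all(out$band_low <= out$band_high, na.rm = TRUE))
  attr(out, "n_pairs") <- pr$n
  attr(out, "n_excluded") <- sum(bad)
  class(out) <- c("proportional_curve", "data.frame")
  out
}

#' @export
plot.proportional_curve <- function(x, ...) {
  graphics::plot(x$time_h, x$mean_ratio, type = "n",
                 ylim = range(c(x$band_low, x$band_high), na.rm = TRUE),
                 xlab = "time post-injection (h)",
                 ylab = "treatment / control ratio", ...)
  graphics::polygon(c(x$time_h, rev(x$time_h)),
                    c(x$band_low, rev(x$band_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$time_h, x$mean_ratio, lwd = 2)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Exceedance probabilities for the peak concentration
#'
#' Significance of `cort_max` relative to two baseline thresholds: the mean
#' time-0 concentration of the matching subset, and temporally aligned
#' modelled control values. The first is the proportion of retained draws
#' whose `cort_max` exceeds `t0_mean`; the second pairs each retained
#' treatment draw with a retained control draw and counts the proportion of
#' pairs where `cort_max` exceeds the control cubic evaluated at that
#' treatment draw's own `t_max` (`align = "per_draw"`), or at the posterior
#' mean `t_max` (`align = "posterior_mean"`).
#'
#' @param derived data.frame from [derive_all()] on the treatment posterior.
#' @param t0_mean Mean time-0 concentration (ng/ml), from
#'   [baseline_summary()].
#' @param control Constraint-filtered control `posterior_draws`.
#' @param pairing,pairing_seed See [proportional_curve()].
#' @param align Control-curve alignment rule (see above).
#' @return List with `p_above_t0`, `p_above_control`, `n_draws`, `n_pairs`.
#' @export
exceedance <- function(derived, t0_mean, control,
                       pairing = c("shuffle", "index"), pairing_seed = 1L,
                       align = c("per_draw", "posterior_mean")) {
  pairing <- match.arg(pairing)
  align <- match.arg(align)
  stopifnot(is.data.frame(derived), is.numeric(t0_mean), length(t0_mean) == 1)
  if (!nrow(derived)) stop("exceedance: empty derived-draw set")
  p_t0 <- mean(derived$cort_max > t0_mean)

  if (is.null(control$retained))
    stop("exceedance: control posterior must be constraint-filtered")
  ci <- which(control$retained)
  if (!length(ci)) stop("exceedance: zero retained control draws")
  if (pairing == "shuffle") {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(as.integer(pairing_seed))
    ti <- sample(nrow(derived))
    ci <- ci[sample(length(ci))]
  } else {
    ti <- seq_len(nrow(derived))
  }
  n <- min(length(ti), length(ci))
  ti <- ti[seq_len(n)]; ci <- ci[seq_len(n)]
  Bc <- .coef_matrix(control)[ci, , drop = FALSE]
  tm <- if (align == "per_draw") derived$t_max[ti] else
    rep(mean(derived$t_max), n)
  ctrl_val <- Bc[, 1] + Bc[, 2] * tm + Bc[, 3] * tm^2 + Bc[, 4] * tm^3
  p_ctrl <- mean(derived$cort_max[ti] > ctrl_val)
  list(p_above_t0 = p_t0, p_above_control = p_ctrl,
       n_draws = nrow(derived), n_pairs = n)
}
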