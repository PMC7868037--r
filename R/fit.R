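#' MCMC sampler settings
#'
#' Defaults follow the study's reported sampler configuration: three chains
#' of 100 000 iterations each, thinned to every third sample, with the first
#' 100 post-thinning draws of each chain discarded as burn-in.
#'
#' @param chains Number of chains (>= 2, needed for the Gelman--Rubin
#'   diagnostic).
#' @param iterations Iterations per chain before thinning.
#' @param thin Keep every `thin`-th iteration.
#' @param burnin_draws Post-thinning draws discarded per chain.
#' @param seed Integer seed; chain `c` uses stream `seed + 7919 * (c - 1)`.
#' @return A `sampler_settings` list.
#' @export
sampler_settings <- function(chains = 3, iterations = 100000, thin = 3,
                             burnin_draws = 100, seed = 1L) {
  stopifnot(chains >= 2, iterations >= 1, thin >= 1)
  kept <- floor(iterations / thin)
  if (kept <= burnin_draws)
    stop("sampler_settings: iterations/thin must exceed burnin_draws")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin),
                 burnin_draws = as.integer(burnin_draws),
                 seed = as.integer(seed)),
            class = "sampler_settings")
}

#' Priors for the cubic regression
#'
#' "Uninformed" priors in the common JAGS idiom: independent Normal(0, 1e6)
#' on each polynomial coefficient (on the raw-hours basis) and Uniform(0,
#' `sigma_max`) on the residual sd, which keeps the posterior proper while
#' contributing essentially no information at the data's scale.
#'
#' @param coef_sd Prior sd of each coefficient (default 1e3, variance 1e6).
#' @param sigma_max Upper bound of the uniform prior on sigma (ng/ml).
#' @return A `cubic_priors` list.
#' @export
cubic_priors <- function(coef_sd = 1e3, sigma_max = 1e4) {
  stopifnot(coef_sd > 0, sigma_max > 0)
  structure(list(coef_sd = coef_sd, sigma_max = sigma_max),
            class = "cubic_priors")
}

# Gibbs sampler for one chain on the scaled basis. X, y fixed; returns a
# (kept x 5) matrix of (b0..b3 scaled, sigma) draws after thinning.
.gibbs_chain <- function(X, y, XtX, Xty, prior_prec, sigma_max,
                         iterations, thin, chain_seed, init_beta, init_sd) {
  set.seed(chain_seed)
  n <- length(y)
  p <- ncol(X)
  # overdispersed start: jitter around the least-squares solution
  beta <- init_beta + stats::rnorm(p, 0, pmax(abs(init_beta), init_sd)) * 0.5
  tau <- 1 / (init_sd * stats::runif(1, 0.5, 2))^2
  kept <- floor(iterations / thin)
  out <- matrix(NA_real_, kept, p + 1L)
  k <- 0L
  shape <- (n - 1) / 2        # uniform-on-sigma prior: p(tau) ~ tau^(-3/2)
  tau_min <- 1 / sigma_max^2
  for (i in seq_len(iterations)) {
    A <- tau * XtX + prior_prec
    ch <- chol(A)
    m <- backsolve(ch, forwardsolve(t(ch), tau * Xty))
    beta <- m + backsolve(ch, stats::rnorm(p))
    r <- y - X %*% beta
    ss <- sum(r * r)
    repeat {
      tau <- stats::rgamma(1, shape, ss / 2)
      if (tau >= tau_min) break   # reject sigma > sigma_max (vanishingly rare)
    }
    if (i %% thin == 0L) {
      k <- k + 1L
      out[k, ] <- c(beta, 1 / sqrt(tau))
    }
  }
  out
}

#' Fit the Bayesian cubic time-course model
#'
#' Models concentration as `Normal(b0 + b1*t + b2*t^2 + b3*t^3, sigma^2)`
#' with independent observations, and samples the posterior by a conjugate
#' Gibbs sampler (coefficient block: multivariate normal; precision:
#' gamma, with the uniform-on-sigma prior handled exactly by its induced
#' `Gamma((n-1)/2, SS/2)` conditional truncated at `sigma_max`). Time is
#' internally rescaled by a factor of 10 for numerical conditioning of the
#' cubic design matrix; priors are applied on the raw-hours basis and draws
#' are returned on it.
#'
#' @param data A measurement-table subset (needs `time_h` and
#'   `cortisol_ng_ml`), or any data.frame with those columns; at least 5
#'   observations spanning at least 4 distinct times.
#' @param settings A [sampler_settings()].
#' @param priors A [cubic_priors()].
#' @return An object of class `posterior_draws`: list with `draws` (a
#'   data.frame `chain, index, b0, b1, b2, b3, sigma` of post-thinning,
#'   post-burn-in draws), `rhat` (per-parameter Gelman--Rubin statistic,
#'   computed before any constraint filtering), `retained` (set later by
#'   [constraint_filter()]), `settings`, `n_obs`.
#' @export
#' @examples
#' tab <- simulate_study(acth_design(), kinetics_params(), seed = 1)
#' sub <- subset_for_model(tab, "ACTH", "plasma", "treatment")
#' fit <- fit_cubic(sub, sampler_settings(iterations = 3000, thin = 1))
#' fit$rhat
fit_cubic <- function(data, settings = sampler_settings(),
                      priors = cubic_priors()) {
  stopifnot(inherits(settings, "sampler_settings"),
            inherits(priors, "cubic_priors"))
  if (!all(c("time_h", "cortisol_ng_ml") %in% names(data)))
    stop("fit_cubic: data needs columns time_h and cortisol_ng_ml")
  t_raw <- data$time_h
  y <- data$cortisol_ng_ml
  if (any(!is.finite(t_raw)) || any(!is.finite(y)))
    stop("fit_cubic: non-finite values in data")
  if (length(y) < 5)
    stop("fit_cubic: need at least 5 observations")
  if (length(unique(t_raw)) < 4)
    stop("fit_cubic: need at least 4 distinct times (cubic unidentifiable)")

  s <- 10                                  # internal time scale, hours -> decahours
  ts <- t_raw / s
  X <- cbind(1, ts, ts^2, ts^3)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  # Normal(0, coef_sd^2) on raw coefficients maps to sd coef_sd * s^j on the
  # scaled basis (beta_scaled_j = beta_raw_j * s^j).
  prior_prec <- diag(1 / (priors$coef_sd * s^(0:3))^2)
  qrX <- qr(X)
  ols <- qr.coef(qrX, y)
  init_sd <- sqrt(sum(qr.resid(qrX, y)^2) / max(length(y) - 4, 1))
  if (init_sd == 0) init_sd <- max(abs(y)) * 1e-3 + 1e-6

  per_chain <- vector("list", settings$chains)
  for (cc in seq_len(settings$chains)) {
    m <- .gibbs_chain(X, y, XtX, Xty, prior_prec, priors$sigma_max,
                      settings$iterations, settings$thin,
                      chain_seed = settings$seed + 7919L * (cc - 1L),
                      init_beta = ols, init_sd = init_sd)
    per_chain[[cc]] <- m[-seq_len(settings$burnin_draws), , drop = FALSE]
  }
  kept <- nrow(per_chain[[1]])
  draws <- do.call(rbind, per_chain)
  # back to raw-hours basis
  draws[, 2] <- draws[, 2] / s
  draws[, 3] <- draws[, 3] / s^2
  draws[, 4] <- draws[, 4] / s^3
  colnames(draws) <- c("b0", "b1", "b2", "b3", "sigma")
  chain <- rep(seq_len(settings$chains), each = kept)
  rhat <- gelman_rubin(draws, chain)
  out <- list(draws = data.frame(chain = chain,
                                 index = rep(seq_len(kept), settings$chains),
                                 draws),
              rhat = rhat, retained = NULL, filter_info = NULL,
              settings = settings, priors = priors,
              n_obs = length(y))
  class(out) <- "posterior_draws"
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws for the cubic time-course model\n")
  cat("  chains:", x$settings$chains, " draws/chain:",
      nrow(x$draws) / x$settings$chains, " n_obs:", x$n_obs, "\n")
  cat("  max Rhat:", round(max(x$rhat), 4), "\n")
  if (!is.null(x$retained))
    cat("  retained after constraint filter:", sum(x$retained), "/",
        length(x$retained), "\n")
  invisible(x)
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classic (non-split) Rhat: with `m` chains of `n` draws,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Chains with zero
#' within-chain variance are degenerate; their Rhat is reported as 1 and
#' flagged via the `"degenerate"` attribute.
#'
#' @param draws Numeric matrix (draws in rows, parameters in columns) or
#'   vector of stacked draws.
#' @param chain Integer/factor vector assigning each row to a chain; at
#'   least 2 chains with at least 10 draws each.
#' @return Named numeric vector of Rhat values (attribute `degenerate`
#'   marks zero-variance parameters).
#' @export
gelman_rubin <- function(draws, chain) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  chain <- as.integer(factor(chain))
  stopifnot(nrow(draws) == length(chain))
  m <- max(chain)
  if (m < 2) stop("gelman_rubin: need at least 2 chains")
  n <- tabulate(chain)
  if (any(n < 10)) stop("gelman_rubin: need at least 10 draws per chain")
  if (length(unique(n)) != 1)
    stop("gelman_rubin: chains must have equal length")
  n <- n[1]
  rhat <- numeric(ncol(draws))
  degen <- logical(ncol(draws))
  for (j in seq_len(ncol(draws))) {
    by_chain <- split(draws[, j], chain)
    W <- mean(vapply(by_chain, stats::var, 0))
    mns <- vapply(by_chain, mean, 0)
    B <- n * stats::var(mns)
    if (W == 0) {                          # constant chains
      rhat[j] <- 1
      degen[j] <- TRUE
    } else {
      rhat[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(rhat) <- colnames(draws)
  attr(rhat, "degenerate") <- degen
  rhat
}

#' Evaluate cubic curves on a time grid
#'
#' @param coeffs Numeric vector `c(b0, b1, b2, b3)`, a matrix/data.frame of
#'   draws with those columns, or a `posterior_draws` object.
#' @param grid Numeric vector of times (h).
#' @return For a single coefficient vector, a numeric vector; otherwise a
#'   matrix with one row per draw and one column per grid point.
#' @export
predict_curve <- function(coeffs, grid) {
  B <- .coef_matrix(coeffs)
  P <- t(vapply(grid, function(g) c(1, g, g^2, g^3), numeric(4)))
  out <- B %*% t(P)
  if (nrow(out) == 1L) drop(out) else out
}

# normalise the various coefficient representations to an n x 4 matrix
.coef_matrix <- function(coeffs) {
  if (inherits(coeffs, "posterior_draws"))
    return(as.matrix(coeffs$draws[, c("b0", "b1", "b2", "b3")]))
  if (is.data.frame(coeffs))
    return(as.matrix(coeffs[, c("b0", "b1", "b2", "b3")]))
  if (is.matrix(coeffs)) {
    if (!is.null(colnames(coeffs)) && all(c("b0", "b1", "b2", "b3") %in% colnames(coeffs)))
      return(coeffs[, c("b0", "b1", "b2", "b3"), drop = FALSE])
    stopifnot(ncol(coeffs) == 4)
    return(coeffs)
  }
  stopifnot(is.numeric(coeffs), length(coeffs) >= 4)
  matrix(coeffs[1:4], nrow = 1)
}

#' Export posterior draws as CSV
#'
#' One row per draw: chain, index, b0..b3, sigma, and the retained flag if
#' the constraint filter has been applied.
#'
#' @param pd A `posterior_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_draws <- function(pd, path) {
  stopifnot(inherits(pd, "posterior_draws"))
  out <- pd$draws
  if (!is.null(pd$retained)) out$retained <- pd$retained
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
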