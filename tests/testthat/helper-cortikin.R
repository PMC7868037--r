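# shared fixtures and oracles

# fast sampler settings for unit tests
quick_settings <- function(seed = 1, iterations = 1500, thin = 1,
                           burnin_draws = 100, chains = 3) {
  sampler_settings(chains = chains, iterations = iterations, thin = thin,
                   burnin_draws = burnin_draws, seed = seed)
}

# wrap a coefficient matrix as a minimal posterior_draws object so the
# filtering/derivation/comparison operations can be exercised on hand-made
# cubics without running the sampler
fake_pd <- function(B, sigma = 1) {
  B <- matrix(B, ncol = 4)
  colnames(B) <- c("b0", "b1", "b2", "b3")
  n <- nrow(B)
  chains <- if (n >= 2) rep(1:2, length.out = n) else 1L
  out <- list(draws = data.frame(chain = sort(chains),
                                 index = seq_len(n), B, sigma = sigma),
              rhat = stats::setNames(rep(1, 5), c("b0", "b1", "b2", "b3", "sigma")),
              retained = NULL, filter_info = NULL,
              settings = NULL, n_obs = NA_integer_)
  class(out) <- "posterior_draws"
  out
}

# simulate observations from a known cubic at the study's plasma design
# times (3 fish per time at 0, 2, 4, 8, 12 h)
cubic_dataset <- function(beta, sigma, times = rep(c(0, 2, 4, 8, 12), each = 3),
                          seed = 1) {
  set.seed(seed)
  mu <- beta[1] + beta[2] * times + beta[3] * times^2 + beta[4] * times^3
  data.frame(time_h = times, cortisol_ng_ml = mu + rnorm(length(times), 0, sigma))
}

# brute-force argmax/argmin of a cubic by dense grid search
grid_extrema <- function(beta, window, step = 0.01) {
  g <- seq(window[1], window[2], by = step)
  v <- beta[1] + beta[2] * g + beta[3] * g^2 + beta[4] * g^3
  list(t_max = g[which.max(v)], c_max = max(v), t_min = g[which.min(v)])
}

# fixed-step RK4 integration of the plasma->mucus transfer ODE
rk4_mucus <- function(params, arm, t_end, h = 1e-3) {
  f <- function(t, cm) {
    cp_excess <- true_curve(params, "plasma", arm, t) - params$baseline_plasma
    params$k_transfer * cp_excess - params$k_mucus * (cm - params$baseline_mucus)
  }
  n <- ceiling(t_end / h)
  cm <- params$baseline_mucus
  t <- 0
  for (i in seq_len(n)) {
    hh <- min(h, t_end - t)
    k1 <- f(t, cm)
    k2 <- f(t + hh / 2, cm + hh / 2 * k1)
    k3 <- f(t + hh / 2, cm + hh / 2 * k2)
    k4 <- f(t + hh, cm + hh * k3)
    cm <- cm + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
    if (t >= t_end) break
  }
  cm
}
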