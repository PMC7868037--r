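test_that("true_curve reduces to baseline with no stimulus", {
  p <- kinetics_params(handling_amp = 0, pulse_amp = 0)
  t <- c(0, 1, 7.5, 36, 84)
  expect_equal(true_curve(p, "plasma", "treatment", t),
               rep(p$baseline_plasma, length(t)))
  expect_equal(true_curve(p, "mucus", "treatment", t),
               rep(p$baseline_mucus, length(t)))
  expect_equal(true_curve(p, "plasma", "control", t),
               rep(p$baseline_plasma, length(t)))
})

test_that("plasma treatment pulse peaks at the Bateman closed-form time", {
  p <- kinetics_params(handling_amp = 0)
  ka <- p$k_abs; ke <- p$k_elim
  t_bateman <- log(ka / ke) / (ka - ke)
  pk <- true_peak(p, "plasma", window = c(0, 40))
  expect_false(pk$at_boundary)
  expect_equal(pk$t_peak, t_bateman, tolerance = 0.01)
})

test_that("closed-form mucus curve matches RK4 integration of the ODE", {
  p <- kinetics_params(k_transfer = 0.05, k_mucus = 0.04)
  for (arm in c("treatment", "control")) {
    for (t_end in c(2, 12, 48)) {
      closed <- true_curve(p, "mucus", arm, t_end)
      oracle <- rk4_mucus(p, arm, t_end, h = 1e-3)
      expect_equal(closed, oracle, tolerance = 1e-6)
    }
  }
})

test_that("coincident transfer/elimination rates use the analytic limit", {
  # k_mucus equal to k_elim hits the t*exp(-a t) branch
  p <- kinetics_params(k_transfer = 0.02, k_mucus = 0.05)
  expect_equal(true_curve(p, "mucus", "treatment", 24),
               rk4_mucus(p, "treatment", 24, h = 1e-3), tolerance = 1e-6)
})

test_that("degenerate Bateman form is rejected", {
  expect_error(kinetics_params(k_abs = 0.05, k_elim = 0.05), "degenerate")
})

test_that("ACTH-trial simulation has the stated combinatorial structure", {
  tab <- simulate_study(acth_design(), kinetics_params(), seed = 1)
  expect_equal(nrow(tab), 80)                       # 40 events x 2 matrices
  expect_equal(length(unique(tab$fish_id)), 20)
  events <- unique(tab[, c("fish_id", "time_h")])
  expect_equal(nrow(events), 40)
  # each fish sampled exactly twice, once per window, gap >= 24 h
  by_fish <- split(events$time_h, events$fish_id)
  expect_true(all(vapply(by_fish, length, 0L) == 2L))
  expect_true(all(vapply(by_fish, function(t) min(t) <= 12 && max(t) >= 24, TRUE)))
  expect_true(all(vapply(by_fish, function(t) diff(range(t)) >= 24, TRUE)))
  # one fish per tank per sampling event
  per_event <- table(tab$tank_id[tab$matrix == "plasma"],
                     tab$time_h[tab$matrix == "plasma"])
  expect_true(all(per_event == 1))
  # arms follow the tank assignment: 3 treatment tanks, 1 control
  arms <- unique(tab[, c("tank_id", "arm")])
  expect_equal(sum(arms$arm == "treatment"), 3)
  expect_equal(sum(arms$arm == "control"), 1)
})

test_that("noiseless simulation reproduces true_curve exactly", {
  p <- kinetics_params(fish_sd_log = 0, cv_plasma = 0, cv_mucus = 0)
  tab <- simulate_study(acth_design(), p, seed = 7)
  expected <- mapply(function(mx, arm, t) true_curve(p, mx, arm, t),
                     tab$matrix, tab$arm, tab$time_h)
  expect_equal(max(abs(tab$cortisol_ng_ml - expected)), 0)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  a <- simulate_study(study_design(), kinetics_params(), seed = 11)
  b <- simulate_study(study_design(), kinetics_params(), seed = 11)
  c <- simulate_study(study_design(), kinetics_params(), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$cortisol_ng_ml, c$cortisol_ng_ml))
  # schedule structure is seed-independent, only assignments/noise change
  expect_identical(dim(a), dim(c))
})

test_that("simulated concentrations are strictly positive across random params", {
  set.seed(42)
  for (i in 1:20) {
    p <- kinetics_params(
      baseline_plasma = runif(1, 10, 300), baseline_mucus = runif(1, 0.5, 20),
      handling_amp = runif(1, 0, 400), handling_decay = runif(1, 0.05, 1),
      pulse_amp = runif(1, 0, 1500), k_abs = runif(1, 0.08, 0.5),
      k_elim = runif(1, 0.01, 0.07), k_transfer = runif(1, 5e-4, 0.05),
      k_mucus = runif(1, 1e-3, 0.05), fish_sd_log = runif(1, 0, 0.6),
      cv_plasma = runif(1, 0, 0.3), cv_mucus = runif(1, 0, 0.3))
    tab <- simulate_study(acth_design(), p, seed = i)
    expect_true(all(tab$cortisol_ng_ml > 0))
  }
})

test_that("mucus ground-truth peak lags plasma peak for slow transfer", {
  set.seed(99)
  for (i in 1:100) {
    ke <- runif(1, 0.03, 0.12)
    p <- kinetics_params(
      handling_amp = runif(1, 0, 300), handling_decay = runif(1, 0.1, 0.6),
      pulse_amp = runif(1, 100, 1500), k_abs = ke + runif(1, 0.02, 0.3),
      k_elim = ke, k_transfer = runif(1, 1e-4, 0.9) * ke,
      k_mucus = runif(1, 1e-3, 0.9) * ke)
    # grid search for the underlying peaks, unconstrained by windows
    g <- seq(0, 300, by = 0.05)
    tp <- g[which.max(true_curve(p, "plasma", "treatment", g))]
    tm <- g[which.max(true_curve(p, "mucus", "treatment", g))]
    expect_gt(tm, tp)
  }
})

test_that("control-like curve (no pulse) peaks at injection", {
  p <- kinetics_params(pulse_amp = 0)
  pk <- true_peak(p, "plasma")
  expect_true(pk$at_boundary)
  expect_equal(pk$t_peak, 0)
  expect_equal(pk$c_peak, p$baseline_plasma + p$handling_amp)
})

test_that("default curves hit the intended study-scale timings", {
  p <- kinetics_params()
  plasma <- true_peak(p, "plasma", window = c(0, 12))
  mucus <- true_peak(p, "mucus")
  expect_gt(plasma$t_peak, 10)   # plasma peak near the 12 h window edge
  expect_gt(mucus$t_peak, 55)    # mucus peak near 62 h
  expect_lt(mucus$t_peak, 70)
  expect_gt(mucus$t_peak - plasma$t_peak, 45)  # ~50 h delay between matrices
})

test_that("designs that cannot honour the schedule are refused", {
  expect_error(
    simulate_study(study_design(trials = list(trial_spec("ACTH", 1, 1)),
                                fish_per_tank = 3),
                   kinetics_params(), seed = 1),
    "fish_per_tank")
  expect_error(study_design(sampling_times = c(0, 2, 2, 8)), "increasing")
  expect_error(study_design(first_window = c(0, 30)), "overlap")
})
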