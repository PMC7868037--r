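retained_pd <- function(B, window = c(0, 12)) {
  constraint_filter(fake_pd(B), window)
}

random_retained <- function(n, seed) {
  set.seed(seed)
  B <- cbind(runif(6 * n, 100, 300), runif(6 * n, 5, 40),
             runif(6 * n, -6, -1), runif(6 * n, 0.05, 0.3))
  pd <- retained_pd(B)
  keep <- which(pd$retained)
  stopifnot(length(keep) >= n)
  retained_pd(B[keep[seq_len(n)], , drop = FALSE])
}

test_that("identical posteriors give the 1:1 proportional curve exactly", {
  pd <- random_retained(50, seed = 40)
  grid <- seq(0, 12, 0.5)
  pc <- proportional_curve(pd, pd, grid, pairing = "index")
  expect_equal(pc$mean_ratio, rep(1, length(grid)))
  expect_equal(pc$band_low, rep(1, length(grid)))
  expect_equal(pc$band_high, rep(1, length(grid)))
  expect_equal(attr(pc, "n_pairs"), 50)
})

test_that("scaling every treatment draw doubles the ratio everywhere", {
  pd <- random_retained(50, seed = 41)
  B2 <- as.matrix(pd$draws[, c("b0", "b1", "b2", "b3")]) * 2
  treat <- retained_pd(B2)
  pc <- proportional_curve(treat, pd, seq(0, 12, 0.5), pairing = "index")
  expect_equal(pc$mean_ratio, rep(2, nrow(pc)))
})

test_that("pointwise summaries match direct enumeration over pairs", {
  treat <- random_retained(100, seed = 42)
  ctrl <- random_retained(100, seed = 43)
  grid <- seq(0, 12, 1)
  pc <- proportional_curve(treat, ctrl, grid, pairing = "index")
  # brute-force oracle: loop over pairs and grid points
  Bt <- as.matrix(treat$draws[, c("b0", "b1", "b2", "b3")])
  Bc <- as.matrix(ctrl$draws[, c("b0", "b1", "b2", "b3")])
  ratios <- matrix(NA_real_, 100, length(grid))
  for (i in 1:100) for (k in seq_along(grid)) {
    g <- grid[k]
    num <- sum(Bt[i, ] * g^(0:3))
    den <- sum(Bc[i, ] * g^(0:3))
    ratios[i, k] <- num / den
  }
  expect_equal(pc$mean_ratio, colMeans(ratios))
  expect_equal(pc$band_low, apply(ratios, 2, quantile, 0.05, names = FALSE))
  expect_equal(pc$band_high, apply(ratios, 2, quantile, 0.95, names = FALSE))
  expect_true(all(pc$band_low <= pc$band_high))

  # shuffle pairing is seed-deterministic
  p1 <- proportional_curve(treat, ctrl, grid, pairing = "shuffle", pairing_seed = 5)
  p2 <- proportional_curve(treat, ctrl, grid, pairing = "shuffle", pairing_seed = 5)
  expect_identical(p1, p2)
})

test_that("exceedance proportions match a brute-force recount", {
  treat <- random_retained(80, seed = 44)
  ctrl <- random_retained(80, seed = 45)
  dd <- derive_all(treat)
  thresh <- median(dd$cort_max)
  ex <- exceedance(dd, thresh, ctrl, pairing = "index")
  # recount from the exported draw tables (file-level oracle)
  f <- withr::local_tempfile(fileext = ".csv")
  export_draws(ctrl, f)
  ctrl_tab <- read.csv(f)
  ctrl_tab <- ctrl_tab[ctrl_tab$retained, ]
  n <- min(nrow(dd), nrow(ctrl_tab))
  ctrl_at_tmax <- vapply(seq_len(n), function(i)
    sum(unlist(ctrl_tab[i, c("b0", "b1", "b2", "b3")]) * dd$t_max[i]^(0:3)), 0)
  expect_equal(ex$p_above_control, mean(dd$cort_max[seq_len(n)] > ctrl_at_tmax))
  expect_equal(ex$p_above_t0, mean(dd$cort_max > thresh))
  # median threshold: exceedance 0.5 up to the 1/N tie convention
  expect_lt(abs(ex$p_above_t0 - 0.5), 1 / nrow(dd) + 1e-12)

  ex_low <- exceedance(dd, min(dd$cort_max) - 1, ctrl, pairing = "index")
  expect_equal(ex_low$p_above_t0, 1)
  expect_error(exceedance(dd[0, ], 1, ctrl), "empty")
})

test_that("run_full_analysis executes six fits and four comparisons", {
  tab <- simulate_study(study_design(), kinetics_params(), seed = 50)
  cfg <- analysis_config(settings = quick_settings(seed = 51, iterations = 800),
                         grid_step = 0.5)
  rep1 <- run_full_analysis(tab, cfg)
  expect_length(rep1$fits, 6)
  expect_named(rep1$fits, c("ACTH_plasma", "ACTH_mucus", "cortisol_plasma",
                            "cortisol_mucus", "control_plasma", "control_mucus"))
  expect_length(rep1$curves, 4)
  expect_equal(nrow(rep1$exceedance), 4)
  expect_true(all(rep1$exceedance$p_above_t0 >= 0 &
                    rep1$exceedance$p_above_t0 <= 1))
  expect_equal(nrow(rep1$summaries), 6 * 5)  # 6 groups x 5 quantities

  # identical config and seeds give identical reports
  rep2 <- run_full_analysis(tab, cfg)
  expect_identical(rep1$summaries, rep2$summaries)
  expect_identical(rep1$exceedance, rep2$exceedance)

  # report files land on disk
  d <- withr::local_tempdir()
  write_report(rep1, d)
  expect_true(all(file.exists(file.path(d, c("summary.csv", "exceedance.csv",
                                             "curve_ACTH_mucus.csv",
                                             "draws_control_plasma.csv",
                                             "pipeline.log")))))

  # missing strata abort with the stage/arm named
  expect_error(run_full_analysis(tab[tab$arm == "treatment", ], cfg),
               "control")
})
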