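# midpoint Riemann sum on a dense uniform grid (knot-agnostic)
riemann_auc <- function(centers, values, window, n = 2e6) {
  h <- (window[2] - window[1]) / n
  x <- seq(window[1] + h / 2, window[2] - h / 2, length.out = n)
  sum(stats::approx(centers, values, xout = x, ties = "ordered")$y) * h
}

test_that("AUC of constant traces is level times window length", {
  centers <- seq(0.5, 30.5, by = 1)
  expect_equal(auc_trace(centers, rep(1, length(centers)), c(1, 30)), 29)
  expect_equal(auc_trace(centers, rep(0.5, length(centers)), c(1, 30)), 14.5)
})

test_that("trapezoid AUC matches a fine-grid Riemann oracle", {
  set.seed(21)
  for (i in 1:10) {
    centers <- sort(c(0.25, stats::runif(23, 0, 32), 31.5))
    values <- stats::runif(25, 0, 1.5)
    got <- auc_trace(centers, values, c(1, 30))
    expect_equal(got, riemann_auc(centers, values, c(1, 30)), tolerance = 1e-9)
  }
})

test_that("AUC rejects unusable windows", {
  expect_error(auc_trace(c(2, 3), c(1, 1), c(1, 30)), "outside trace support")
  expect_error(auc_trace(5, values = 1, window = c(1, 30)), "at least 2 bins")
})

test_that("magnitude identities: paralysis 100, no effect 0, level s gives 100(1-s)", {
  centers <- seq(0.5, 30.5, by = 1)
  n <- length(centers)
  expect_equal(magnitude_percent(centers, rep(0, n)), 100)
  expect_equal(magnitude_percent(centers, rep(1, n)), 0)
  expect_equal(magnitude_percent(centers, rep(0.5, n)), 50)
  for (s in c(0.1, 0.25, 0.33, 0.9, 1.2)) {
    expect_equal(magnitude_percent(centers, rep(s, n)), 100 * (1 - s))
  }
})

test_that("hyperlocomotion gives negative magnitude, not clamped", {
  centers <- seq(0.5, 30.5, by = 1)
  expect_lt(magnitude_percent(centers, rep(1.4, length(centers))), 0)
})

test_that("a half-window step response yields 50 percent magnitude", {
  # speed 1 over [1, 15.5], 0 over [15.5, 30]; sharp shoulder bins
  centers <- c(seq(0.5, 15.4999, by = 0.5), 15.5, 15.5001, seq(16, 30.5, by = 0.5))
  values <- ifelse(centers <= 15.5, 1, 0)
  expect_equal(magnitude_percent(centers, values), 50, tolerance = 1e-3)
  expect_equal(
    magnitude_percent(centers, values),
    100 * (29 - riemann_auc(centers, values, c(1, 30))) / 29,
    tolerance = 1e-6
  )
})

test_that("magnitude is invariant under bin-width refinement of linear traces", {
  f <- function(t) 1 - 0.02 * t # piecewise-linear (in fact linear)
  coarse <- seq(0.5, 30.5, by = 2)
  fine <- seq(0.25, 30.75, by = 0.25)
  expect_equal(
    magnitude_percent(coarse, f(coarse)),
    magnitude_percent(fine, f(fine)),
    tolerance = 1e-12
  )
})

test_that("time to maximum effect finds the smoothed minimum, ties earliest", {
  centers <- 1:30 # width-1 bins centered on whole minutes
  v_shape <- abs(centers - 10) / 10 + 0.2
  expect_equal(time_to_max_effect(centers, v_shape, smooth_k = 1), 10)
  expect_equal(time_to_max_effect(centers, v_shape, smooth_k = 3), 10)
  monotone <- 1 - centers / 40
  expect_equal(time_to_max_effect(centers, monotone), 30) # window end
  flat <- rep(0.5, length(centers))
  expect_equal(time_to_max_effect(centers, flat), 1) # earliest eligible bin
})

test_that("smoothed argmin matches an independent rolling-mean oracle", {
  set.seed(33)
  centers <- seq(0.5, 30.5, by = 1)
  for (k in c(1, 3, 5)) {
    for (rep in 1:10) {
      v <- stats::runif(length(centers))
      oracle_sm <- vapply(seq_along(v), function(i) {
        lo <- max(1, i - (k - 1) / 2)
        hi <- min(length(v), i + (k - 1) / 2)
        mean(v[lo:hi])
      }, numeric(1))
      ok <- centers >= 1 & centers <= 30
      expected <- centers[ok][which.min(oracle_sm[ok])]
      expect_equal(time_to_max_effect(centers, v, c(1, 30), k), expected)
    }
  }
})

test_that("set-time-point speed is the covering bin's mean", {
  centers <- seq(0.5, 29.5, by = 1)
  values <- seq_along(centers) / 10
  # t_set = 10 lies in the [10, 11) bin, center 10.5
  expect_equal(set_timepoint_speed(centers, values, t_set = 10), values[11])
  expect_equal(set_timepoint_speed(centers, rep(0.3, 30), t_set = 10), 0.3)
  # value 0.2 sitting in a [9.5, 10.5) bin is returned for t_set = 10
  shifted <- centers + 0.5
  v2 <- ifelse(shifted == 10, 0.2, 1)
  expect_equal(set_timepoint_speed(shifted, v2, t_set = 10), 0.2)
  expect_error(set_timepoint_speed(centers, values, t_set = 45), "no bin covers")
})

test_that("instant full paralysis reads 0 at the set time point", {
  cfg <- quiet_cfg(
    dt = 5, duration_baseline = 10, duration_post = 35,
    wells_per_group = 1, n_experiments = 1, seed = 1
  )
  g <- genotype_params("step", Emax = 1, tau_min = 0, tau_max = 0, recovery_tau = Inf)
  tr <- simulate_trace(g, list(treatment_event(10, "fentanyl", 1e6)), cfg, v0 = 0.4)
  tab <- tibble::tibble(
    time_s = tr$time_s, experiment_id = "E01", well_id = "W01",
    animal_id = "A1", speed_mm_s = tr$speed_mm_s
  )
  b <- baseline_normalize(bin_well_means(tab, 60, 10))
  expect_equal(set_timepoint_speed(b$bin_center_min, b$mean_speed, 10), 0)
  expect_equal(magnitude_percent(b$bin_center_min, b$mean_speed), 100)
})

test_that("noiseless pipeline recovers the programmed effect magnitude", {
  cfg <- quiet_cfg(
    dt = 2, duration_baseline = 10, duration_post = 35,
    wells_per_group = 1, n_experiments = 1, seed = 1
  )
  run_tau <- function(tau) {
    g <- genotype_params("probe",
      Emax = 0.9, EC50 = 20, hill_h = 2,
      tau_min = tau, tau_max = tau, recovery_tau = Inf
    )
    tr <- simulate_trace(g, list(treatment_event(10, "fentanyl", 40)), cfg, v0 = 0.3)
    tab <- tibble::tibble(
      time_s = tr$time_s, experiment_id = "E01", well_id = "W01",
      animal_id = "A1", speed_mm_s = tr$speed_mm_s
    )
    b <- baseline_normalize(bin_well_means(tab, 60, 10))
    magnitude_percent(b$bin_center_min, b$mean_speed)
  }
  # instant onset: magnitude equals 100 * E(40) = 72 exactly
  expect_equal(run_tau(0), 72, tolerance = 1e-10)
  # slower onset erodes magnitude; eroded magnitude grows back as tau -> 0
  mags <- vapply(c(4, 2, 1, 0.25), run_tau, numeric(1))
  expect_true(all(mags < 72))
  expect_true(all(diff(mags) > 0))
})

test_that("response_metrics summarises wells and requires normalized input", {
  cfg <- quiet_cfg(
    dt = 5, duration_baseline = 10, duration_post = 35,
    wells_per_group = 2, n_experiments = 1, seed = 4
  )
  d <- mini_design(cfg)
  tab <- simulate_experiment(d, cfg)
  b <- bin_well_means(tab, 60, 10, well_metadata(d))
  expect_error(response_metrics(b), "normalized")
  m <- response_metrics(baseline_normalize(b))
  expect_equal(nrow(m), 2L)
  expect_true(all(c(
    "magnitude_pct", "t_max_effect_min", "set_point_speed",
    "recovery_half_time_min"
  ) %in% names(m)))
  # both wells identical under noise-off generation
  expect_equal(m$magnitude_pct[1], m$magnitude_pct[2])
})
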