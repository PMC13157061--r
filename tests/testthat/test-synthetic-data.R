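test_that("dose_effect follows the Hill/Emax form", {
  g <- genotype_params("x", Emax = 0.9, EC50 = 20, hill_h = 2)
  expect_equal(dose_effect(0, g), 0)
  # half-maximum identity at d = EC50
  expect_equal(dose_effect(20, g), 0.45)
  # direct evaluation: 0.9 * 40^2 / (40^2 + 20^2) = 0.9 * 1600/2000
  expect_equal(dose_effect(40, g), 0.9 * 1600 / 2000)
  expect_equal(dose_effect(40, g), 0.72)
  expect_error(dose_effect(-1, g), "dose")
})

test_that("dose_effect is monotone, bounded by Emax, and saturates", {
  for (h in c(0.5, 1, 2, 4)) {
    g <- genotype_params("x", Emax = 0.8, EC50 = 15, hill_h = h)
    d <- seq(0, 500, by = 0.5)
    e <- dose_effect(d, g)
    expect_true(all(diff(e) >= 0))
    expect_true(all(e >= 0 & e <= g$Emax))
    expect_equal(dose_effect(1e9, g), 0.8, tolerance = 5e-4)
  }
})

test_that("onset_tau interpolates between its bounds", {
  g <- genotype_params("x", tau_min = 2, tau_max = 12, EC50_tau = 40)
  expect_equal(onset_tau(0, g), 12)
  expect_equal(onset_tau(1e12, g), 2, tolerance = 1e-9)
  expect_equal(onset_tau(40, g), (2 + 12) / 2)
  d <- seq(0, 200, by = 1)
  expect_true(all(diff(onset_tau(d, g)) <= 0))
  expect_true(all(onset_tau(d, g) >= 2 & onset_tau(d, g) <= 12))
  expect_error(genotype_params("x", tau_min = 5, tau_max = 1), "tau_min")
})

test_that("noiseless trace without drug is constant at v0", {
  cfg <- quiet_cfg(dt = 5, duration_baseline = 2, duration_post = 2, seed = 1)
  tr <- simulate_trace(
    genotype_presets("tgMOR"),
    list(treatment_event(2, "vehicle", 0)), cfg,
    v0 = 0.3
  )
  expect_true(all(tr$speed_mm_s == 0.3))
  expect_equal(nrow(tr), 4 * 60 / 5)
})

test_that("instant full effect steps speed to zero at application", {
  g <- genotype_params("x",
    Emax = 1, EC50 = 20, tau_min = 0, tau_max = 0,
    recovery_tau = Inf
  )
  cfg <- quiet_cfg(dt = 10, duration_baseline = 2, duration_post = 3, seed = 1)
  tr <- simulate_trace(g, list(treatment_event(2, "fentanyl", 1e6)), cfg, v0 = 0.5)
  pre <- tr$time_s < 120
  expect_true(all(tr$speed_mm_s[pre] == 0.5))
  # Hill effect at 1e6 uM is 1 up to ~1e-10; the step is complete to that order
  expect_lt(max(tr$speed_mm_s[!pre]), 1e-8)
})

test_that("mono-exponential onset matches its closed form", {
  # r(t_apply + tau) = 1 - E * (1 - exp(-1))
  g <- genotype_params("x",
    Emax = 0.5, EC50 = 1e-6, hill_h = 1,
    tau_min = 2, tau_max = 2, recovery_tau = Inf
  )
  cfg <- quiet_cfg(dt = 1, duration_baseline = 5, duration_post = 10, seed = 1)
  tr <- simulate_trace(g, list(treatment_event(5, "fentanyl", 1e6)), cfg, v0 = 1)
  at <- tr$speed_mm_s[tr$time_s == (5 + 2) * 60]
  expect_equal(at, 1 - 0.5 * (1 - exp(-1)), tolerance = 1e-9)
  expect_equal(at, 0.6839, tolerance = 1e-4)
})

test_that("naloxone pre-treatment blocks and post-treatment reverses", {
  g <- genotype_params("x",
    Emax = 1, tau_min = 0, tau_max = 0,
    recovery_tau = Inf
  )
  cfg <- quiet_cfg(
    dt = 30, duration_baseline = 5, duration_post = 30, seed = 1,
    naloxone_kb = 2, naloxone_reversal_tau = 3
  )
  # pre-block: effect multiplied by 1 / (1 + 20/2)
  pre <- simulate_trace(g, list(
    treatment_event(0, "naloxone", 20),
    treatment_event(5, "fentanyl", 1e6)
  ), cfg, v0 = 1)
  late <- pre$speed_mm_s[pre$time_s >= 10 * 60]
  expect_equal(unique(late), 1 - 1 / 11, tolerance = 1e-9)
  # post-application reversal: effect decays with tau = 3 min
  post <- simulate_trace(g, list(
    treatment_event(5, "fentanyl", 1e6),
    treatment_event(10, "naloxone", 20)
  ), cfg, v0 = 1)
  at15 <- post$speed_mm_s[post$time_s == 15 * 60]
  expect_equal(at15, 1 - exp(-5 / 3), tolerance = 1e-9)
  expect_equal(post$speed_mm_s[post$time_s == 8 * 60], 0)
})

test_that("contradictory and malformed schedules are rejected", {
  g <- genotype_presets("tgMOR")
  cfg <- quiet_cfg(dt = 30, duration_baseline = 2, duration_post = 5, seed = 1)
  expect_error(
    simulate_trace(g, list(
      treatment_event(2, "fentanyl", 40),
      treatment_event(2, "naloxone", 20)
    ), cfg, v0 = 1),
    "schedule error"
  )
  expect_error(
    simulate_trace(g, list(
      treatment_event(2, "fentanyl", 20),
      treatment_event(3, "fentanyl", 40)
    ), cfg, v0 = 1),
    "schedule error"
  )
  expect_error(
    simulate_trace(g, list(
      treatment_event(3, "fentanyl", 40),
      treatment_event(2, "vehicle", 0)
    ), cfg, v0 = 1),
    "sorted"
  )
  expect_error(treatment_event(-1, "fentanyl", 40), "t_apply")
  expect_error(treatment_event(1, "vehicle", 10), "vehicle")
})

test_that("tracker table has one row per time sample per animal", {
  cfg <- quiet_cfg(
    dt = 60, duration_baseline = 1, duration_post = 1,
    animals_per_well = 4, wells_per_group = 1, n_experiments = 1, seed = 1
  )
  tab <- simulate_experiment(mini_design(cfg), cfg)
  expect_equal(nrow(tab), 4 * 2) # 4 animals x 2 samples
  expect_named(tab, c("time_s", "experiment_id", "well_id", "animal_id", "speed_mm_s"))
})

test_that("identical seed and config give identical tables", {
  cfg <- generator_config(
    dt = 2, duration_baseline = 2, duration_post = 3,
    wells_per_group = 2, n_experiments = 2, seed = 42
  )
  d <- mini_design(cfg)
  t1 <- simulate_experiment(d, cfg)
  t2 <- simulate_experiment(d, cfg)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_tracker_table(t1, f1)
  write_tracker_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- generator_config(
    dt = 2, duration_baseline = 2, duration_post = 3,
    wells_per_group = 2, n_experiments = 2, seed = 43
  )
  expect_false(identical(simulate_experiment(d, cfg2), t1))
})

test_that("simulate_experiment does not disturb the caller's RNG stream", {
  cfg <- generator_config(
    dt = 10, duration_baseline = 1, duration_post = 1,
    wells_per_group = 1, n_experiments = 1, seed = 5
  )
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_experiment(mini_design(cfg), cfg))
  expect_identical(.Random.seed, before)
})

test_that("full dropout leaves every well short of one animal", {
  cfg <- generator_config(
    dt = 10, duration_baseline = 1, duration_post = 1,
    wells_per_group = 3, n_experiments = 2, seed = 8, dropout_rate = 1
  )
  tab <- simulate_experiment(mini_design(cfg), cfg)
  counts <- tab |>
    dplyr::distinct(experiment_id, well_id, animal_id) |>
    dplyr::count(experiment_id, well_id)
  expect_true(all(counts$n == cfg$animals_per_well - 1L))
})

test_that("vehicle traces preserve the null: post/pre speed ratio near 1", {
  cfg_base <- quiet_cfg(
    dt = 2, duration_baseline = 5, duration_post = 5,
    animals_per_well = 2, wells_per_group = 1, n_experiments = 1
  )
  cfg_base$noise <- list(enabled = TRUE, cv = 0.15, phi_1s = 0.5)
  d <- mini_design(cfg_base, compound = "vehicle", dose = 0)
  ratios <- vapply(1:120, function(s) {
    cfg <- cfg_base
    cfg$seed <- s
    tab <- simulate_experiment(d, cfg)
    pre <- mean(tab$speed_mm_s[tab$time_s < 300])
    post <- mean(tab$speed_mm_s[tab$time_s >= 300])
    post / pre
  }, numeric(1))
  ci <- mean(ratios) + c(-1, 1) * 1.96 * stats::sd(ratios) / sqrt(length(ratios))
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("genotype presets reproduce the qualitative response ordering", {
  cfg <- quiet_cfg(
    dt = 5, duration_baseline = 10, duration_post = 35,
    wells_per_group = 1, n_experiments = 1, seed = 1
  )
  run_one <- function(genotype) {
    d <- mini_design(cfg, genotype = genotype)
    analyze_table(simulate_experiment(d, cfg), well_metadata(d))
  }
  m <- lapply(
    c("tgMOR", "goa-1", "egl-10", "eat-16"),
    run_one
  )
  names(m) <- c("tgMOR", "goa-1", "egl-10", "eat-16")
  expect_equal(m[["goa-1"]]$magnitude_pct, 0, tolerance = 1e-9)
  expect_gt(m[["egl-10"]]$magnitude_pct, m[["tgMOR"]]$magnitude_pct)
  expect_lt(m[["eat-16"]]$t_max_effect_min, m[["tgMOR"]]$t_max_effect_min)
})
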