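#' Generator configuration for synthetic tracker tables
#'
#' Holds the acquisition and noise settings used by [simulate_trace()] and
#' [simulate_experiment()]. Defaults mirror the assay design the package
#' quantifies: a 10-min pre-treatment baseline followed by continued
#' recording, 4 animals per liquid-filled well, 5 wells per genotype and
#' treatment per experiment, and 3 independent experiments.
#'
#' @param dt Sampling interval (s).
#' @param duration_baseline Pre-treatment recording (min).
#' @param duration_post Post-treatment recording (min).
#' @param animals_per_well Animals per well.
#' @param wells_per_group Wells per genotype x treatment per experiment.
#' @param n_experiments Independent experiments (separate plates/days).
#' @param seed Integer seed; identical config + seed gives identical tables.
#' @param noise List with elements `enabled` (logical), `cv` (stationary
#'   coefficient of variation of the multiplicative noise) and `phi_1s`
#'   (lag-1 autocorrelation at 1-s sampling; rescaled as `phi_1s^dt`).
#' @param dropout_rate Probability that a well loses one animal entirely
#'   (simulated tracking failure), for QC testing.
#' @param naloxone_kb Antagonist block constant (uM): a pre-applied naloxone
#'   dose d multiplies the agonist effect by `1 / (1 + d / naloxone_kb)`.
#' @param naloxone_reversal_tau Time constant (min) of effect reversal when
#'   naloxone is applied after the agonist.
#'
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 1, noise = list(enabled = FALSE))
#' @export
generator_config <- function(dt = 1,
                             duration_baseline = 10,
                             duration_post = 45,
                             animals_per_well = 4,
                             wells_per_group = 5,
                             n_experiments = 3,
                             seed = 1L,
                             noise = list(),
                             dropout_rate = 0,
                             naloxone_kb = 2,
                             naloxone_reversal_tau = 3) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  counts <- c(animals_per_well, wells_per_group, n_experiments)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (duration_baseline < 0 || duration_post <= 0) {
    stop("recording durations must be positive", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("`dropout_rate` must lie in [0, 1]", call. = FALSE)
  }
  noise_defaults <- list(enabled = TRUE, cv = 0.15, phi_1s = 0.5)
  unknown <- setdiff(names(noise), names(noise_defaults))
  if (length(unknown)) {
    stop("unknown noise settings: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  noise <- utils::modifyList(noise_defaults, noise)
  if (noise$cv < 0 || noise$phi_1s < 0 || noise$phi_1s >= 1) {
    stop("noise `cv` must be >= 0 and `phi_1s` in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      dt = dt,
      duration_baseline = duration_baseline,
      duration_post = duration_post,
      animals_per_well = as.integer(animals_per_well),
      wells_per_group = as.integer(wells_per_group),
      n_experiments = as.integer(n_experiments),
      seed = as.integer(seed),
      noise = noise,
      dropout_rate = dropout_rate,
      naloxone_kb = naloxone_kb,
      naloxone_reversal_tau = naloxone_reversal_tau
    ),
    class = "generator_config"
  )
}

#' Treatment event
#'
#' One liquid addition to a well: the agonist (fentanyl), the antagonist
#' (naloxone), or vehicle. Times are minutes from recording start; doses are
#' final in-well concentrations.
#'
#' @param t_apply Application time (min, >= 0).
#' @param compound One of `"fentanyl"`, `"naloxone"`, `"vehicle"`.
#' @param dose Dose (uM, >= 0); vehicle must have dose 0.
#' @return An object of class `treatment_event`.
#' @examples
#' treatment_event(10, "fentanyl", 40)
#' @export
treatment_event <- function(t_apply, compound, dose = 0) {
  compound <- match.arg(compound, c("fentanyl", "naloxone", "vehicle"))
  if (t_apply < 0) stop("`t_apply` must be >= 0", call. = FALSE)
  if (dose < 0) stop("`dose` must be >= 0", call. = FALSE)
  if (compound == "vehicle" && dose != 0) {
    stop("vehicle events must have dose 0", call. = FALSE)
  }
  structure(
    list(t_apply = t_apply, compound = compound, dose = dose),
    class = "treatment_event"
  )
}

#' Plate design
#'
#' A plate design maps wells to genotypes and treatment schedules across
#' independent experiments. `plate_design()` validates a prepared well table;
#' [build_plate_design()] constructs the standard factorial layout.
#'
#' @param wells A data frame with columns `experiment_id`, `well_id`,
#'   `genotype`, `treatment` (group label), `dose` (uM), and a list column
#'   `schedule` of lists of [treatment_event()]s.
#' @return An object of class `plate_design` (a tibble).
#' @export
plate_design <- function(wells) {
  required <- c("experiment_id", "well_id", "genotype", "treatment", "dose", "schedule")
  missing <- setdiff(required, names(wells))
  if (length(missing)) {
    stop("design is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(wells) == 0L) stop("design has no wells", call. = FALSE)
  dup <- duplicated(wells[c("experiment_id", "well_id")])
  if (any(dup)) {
    stop("well ids must be unique within an experiment: ",
      paste(unique(wells$well_id[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  ok <- vapply(
    wells$schedule,
    function(s) all(vapply(s, inherits, logical(1), "treatment_event")),
    logical(1)
  )
  if (!all(ok)) stop("`schedule` entries must be lists of treatment_event", call. = FALSE)
  structure(tibble::as_tibble(wells), class = c("plate_design", class(tibble::tibble())))
}

#' Build a factorial plate design
#'
#' Expands one row per genotype x treatment group into
#' `cfg$wells_per_group` wells in each of `cfg$n_experiments` experiments,
#' with the treatment applied at the end of the baseline recording.
#'
#' @param groups Data frame with columns `genotype` (preset name or label),
#'   `compound` and `dose`; an optional `treatment` column overrides the
#'   auto-generated group label (`"vehicle"` or `"<compound>_<dose>"`).
#' @param cfg A [generator_config()].
#' @param t_apply Treatment application time (min); defaults to the end of
#'   the baseline window.
#' @return A [plate_design()].
#' @examples
#' cfg <- generator_config(seed = 1)
#' groups <- data.frame(
#'   genotype = c("tgMOR", "tgMOR"),
#'   compound = c("vehicle", "fentanyl"),
#'   dose = c(0, 40)
#' )
#' design <- build_plate_design(groups, cfg)
#' @export
build_plate_design <- function(groups, cfg, t_apply = cfg$duration_baseline) {
  stopifnot(is.data.frame(groups), all(c("genotype", "compound", "dose") %in% names(groups)))
  if (!"treatment" %in% names(groups)) {
    groups$treatment <- ifelse(
      groups$compound == "vehicle", "vehicle",
      paste0(groups$compound, "_", groups$dose)
    )
  }
  rows <- list()
  for (e in seq_len(cfg$n_experiments)) {
    counter <- 0L
    for (i in seq_len(nrow(groups))) {
      for (w in seq_len(cfg$wells_per_group)) {
        counter <- counter + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          experiment_id = sprintf("E%02d", e),
          well_id = sprintf("W%02d", counter),
          genotype = groups$genotype[i],
          treatment = groups$treatment[i],
          dose = groups$dose[i],
          schedule = list(list(
            treatment_event(t_apply, groups$compound[i], groups$dose[i])
          ))
        )
      }
    }
  }
  plate_design(dplyr::bind_rows(rows))
}

#' Well metadata of a plate design
#'
#' @param design A [plate_design()].
#' @return Tibble with one row per well: `experiment_id`, `well_id`,
#'   `genotype`, `treatment`, `dose`.
#' @export
well_metadata <- function(design) {
  tibble::as_tibble(design[c("experiment_id", "well_id", "genotype", "treatment", "dose")])
}

#' Hill/Emax dose-effect
#'
#' Fractional reduction in swimming speed at dose `d`:
#' `E(d) = Emax * d^h / (d^h + EC50^h)`. Monotone non-decreasing in dose,
#' 0 at dose 0, and approaches `Emax` at saturating dose.
#'
#' @param d Dose (uM), non-negative; vectorized.
#' @param g A [genotype_params()].
#' @return Effect fraction in `[0, Emax]`.
#' @examples
#' dose_effect(c(0, 20, 40, 80), genotype_presets("tgMOR"))
#' @export
dose_effect <- function(d, g) {
  stopifnot(inherits(g, "genotype_params"))
  if (any(d < 0)) stop("dose must be non-negative", call. = FALSE)
  dh <- d^g$hill_h
  out <- g$Emax * dh / (dh + g$EC50^g$hill_h)
  out[d == 0] <- 0 # avoids 0/0 when hill_h underflows
  out
}

#' Onset time constant as a function of dose
#'
#' Mono-exponential onset speeds up with dose:
#' `tau(d) = tau_min + (tau_max - tau_min) * EC50_tau / (EC50_tau + d)`.
#' Monotone non-increasing in dose, bounded in `[tau_min, tau_max]`, equal to
#' the midpoint at `d = EC50_tau`.
#'
#' @inheritParams dose_effect
#' @return Onset time constant (min); vectorized over `d`.
#' @export
onset_tau <- function(d, g) {
  stopifnot(inherits(g, "genotype_params"))
  if (any(d < 0)) stop("dose must be non-negative", call. = FALSE)
  g$tau_min + (g$tau_max - g$tau_min) * g$EC50_tau / (g$EC50_tau + d)
}

# Deterministic expected normalized response r(t) in [0, 1] for one schedule.
# Vectorized over time (seconds from recording start).
response_profile <- function(t_s, g, schedule, cfg) {
  if (length(schedule) == 0L) {
    return(rep(1, length(t_s)))
  }
  t_applies <- vapply(schedule, `[[`, numeric(1), "t_apply")
  compounds <- vapply(schedule, `[[`, character(1), "compound")
  if (is.unsorted(t_applies)) stop("schedule must be sorted by t_apply", call. = FALSE)
  active <- compounds != "vehicle"
  if (anyDuplicated(t_applies[active])) {
    stop("schedule error: overlapping events at identical t_apply", call. = FALSE)
  }
  fent <- which(compounds == "fentanyl")
  if (length(fent) > 1L) {
    stop("schedule error: multiple agonist applications are not supported", call. = FALSE)
  }
  if (length(fent) == 0L) {
    return(rep(1, length(t_s)))
  }
  ev <- schedule[[fent]]
  ta_s <- ev$t_apply * 60
  E0 <- dose_effect(ev$dose, g)
  tau_s <- onset_tau(ev$dose, g) * 60
  plateau_s <- g$t_plateau * 60
  recovery_s <- g$recovery_tau * 60

  block <- 1
  reversal <- rep(1, length(t_s))
  for (i in which(compounds == "naloxone")) {
    nal <- schedule[[i]]
    if (nal$t_apply <= ev$t_apply) {
      # competitive pre-block: antagonist on board before the agonist
      block <- block / (1 + nal$dose / cfg$naloxone_kb)
    } else {
      tn_s <- nal$t_apply * 60
      tau_rev_s <- cfg$naloxone_reversal_tau * 60
      post <- t_s >= tn_s
      reversal[post] <- reversal[post] * exp(-(t_s[post] - tn_s) / tau_rev_s)
    }
  }

  dt_post <- pmax(0, t_s - ta_s)
  onset <- if (tau_s <= 0) as.numeric(t_s >= ta_s) else 1 - exp(-dt_post / tau_s)
  onset[t_s < ta_s] <- 0
  recov <- if (is.infinite(recovery_s)) {
    rep(1, length(t_s))
  } else {
    exp(-pmax(0, dt_post - plateau_s) / recovery_s)
  }
  r <- 1 - E0 * block * onset * recov * reversal
  pmax(r, 0)
}

# Stationary multiplicative AR(1) noise with unit mean, drawn from the
# current RNG stream. Returns a vector of length n.
ar1_noise <- function(n, cfg) {
  if (!isTRUE(cfg$noise$enabled) || cfg$noise$cv <= 0) {
    return(rep(1, n))
  }
  sigma2 <- log(1 + cfg$noise$cv^2)
  sigma <- sqrt(sigma2)
  phi <- cfg$noise$phi_1s^cfg$dt
  z <- stats::rnorm(n)
  innov <- sqrt(1 - phi^2) * sigma * z
  innov[1] <- sigma * z[1] # stationary start
  x <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  exp(x - sigma2 / 2)
}

#' Simulate one animal's speed trace
#'
#' Generates a centroid-speed time series for a single animal: a per-animal
#' baseline speed `v0` drawn from a log-normal with mean
#' `baseline_speed_mu` and CV `baseline_speed_cv`, multiplied by the
#' deterministic pharmacodynamic response profile and (optionally)
#' stationary multiplicative AR(1) noise with unit mean. The response to an
#' agonist applied at `t_apply` is
#' `r(t) = 1 - E(d) * (1 - exp(-(t - t_apply)/tau(d))) *`
#' `exp(-max(0, t - t_apply - t_plateau)/recovery_tau)`, with naloxone
#' either pre-blocking the effect (competitive factor) or reversing it
#' exponentially when applied after the agonist. Speeds are clipped at 0.
#'
#' Draws from the current RNG stream; seed for reproducibility (or use
#' [simulate_experiment()], which seeds from its config).
#'
#' @param g A [genotype_params()].
#' @param schedule List of [treatment_event()]s sorted by `t_apply`.
#' @param cfg A [generator_config()].
#' @param v0 Optional fixed baseline speed (mm/s); if `NULL`, drawn.
#' @return Tibble with columns `time_s` and `speed_mm_s`; baseline speed in
#'   attribute `"v0"`.
#' @examples
#' cfg <- generator_config(seed = 1, noise = list(enabled = FALSE))
#' tr <- simulate_trace(
#'   genotype_presets("tgMOR"),
#'   list(treatment_event(10, "fentanyl", 40)), cfg
#' )
#' @export
simulate_trace <- function(g, schedule, cfg, v0 = NULL) {
  stopifnot(inherits(g, "genotype_params"), inherits(cfg, "generator_config"))
  total_s <- (cfg$duration_baseline + cfg$duration_post) * 60
  t_s <- seq(0, total_s - cfg$dt, by = cfg$dt)
  if (is.null(v0)) {
    cv <- g$baseline_speed_cv
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(g$baseline_speed_mu) - sdlog^2 / 2
      v0 <- stats::rlnorm(1, meanlog, sdlog)
    } else {
      v0 <- g$baseline_speed_mu
    }
  }
  r <- response_profile(t_s, g, schedule, cfg)
  eps <- ar1_noise(length(t_s), cfg)
  out <- tibble::tibble(time_s = t_s, speed_mm_s = pmax(v0 * r * eps, 0))
  attr(out, "v0") <- v0
  out
}

#' Simulate a full tracker table for a plate design
#'
#' Runs [simulate_trace()] for every animal of every well in the design and
#' assembles the long-format tracker table (one row per time sample per
#' animal). The generator is seeded from `cfg$seed`, so identical
#' (design, config) input yields an identical table. If
#' `cfg$dropout_rate > 0`, affected wells lose one randomly chosen animal
#' entirely, emulating a tracking failure.
#'
#' @param design A [plate_design()].
#' @param cfg A [generator_config()].
#' @return Tibble with columns `time_s`, `experiment_id`, `well_id`,
#'   `animal_id`, `speed_mm_s`; the design is attached as attribute
#'   `"design"`.
#' @examples
#' cfg <- generator_config(seed = 1, wells_per_group = 2, n_experiments = 1)
#' design <- build_plate_design(
#'   data.frame(genotype = "tgMOR", compound = "fentanyl", dose = 40), cfg
#' )
#' tab <- simulate_experiment(design, cfg)
#' @export
simulate_experiment <- function(design, cfg) {
  stopifnot(inherits(design, "plate_design"), inherits(cfg, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(cfg$seed)

  presets <- genotype_presets()
  total_s <- (cfg$duration_baseline + cfg$duration_post) * 60
  t_s <- seq(0, total_s - cfg$dt, by = cfg$dt)
  n_t <- length(t_s)
  pieces <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    w <- design[i, ]
    g <- if (w$genotype %in% names(presets)) {
      presets[[w$genotype]]
    } else {
      stop("unknown genotype '", w$genotype, "' in design", call. = FALSE)
    }
    # response profile is deterministic: compute once per well
    r <- response_profile(t_s, g, w$schedule[[1]], cfg)
    keep <- seq_len(cfg$animals_per_well)
    if (cfg$dropout_rate > 0 && stats::runif(1) < cfg$dropout_rate) {
      keep <- setdiff(keep, sample.int(cfg$animals_per_well, 1))
    }
    cv <- g$baseline_speed_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(g$baseline_speed_mu) - sdlog^2 / 2
    speeds <- vector("list", cfg$animals_per_well)
    for (a in seq_len(cfg$animals_per_well)) {
      # draws consumed for dropped animals too, so dropout_rate does not
      # shift the RNG stream of the surviving traces
      v0 <- if (cv > 0) stats::rlnorm(1, meanlog, sdlog) else g$baseline_speed_mu
      eps <- ar1_noise(n_t, cfg)
      if (a %in% keep) speeds[[a]] <- pmax(v0 * r * eps, 0)
    }
    kept <- keep[!vapply(speeds[keep], is.null, logical(1))]
    pieces[[i]] <- tibble::tibble(
      time_s = rep(t_s, length(kept)),
      experiment_id = w$experiment_id,
      well_id = w$well_id,
      animal_id = rep(sprintf("A%d", kept), each = n_t),
      speed_mm_s = unlist(speeds[kept], use.names = FALSE)
    )
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "design") <- design
  out
}
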