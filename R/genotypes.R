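#' Genotype pharmacodynamic parameters
#'
#' Bundle the per-genotype parameters that drive the synthetic locomotor
#' generator: baseline swimming speed, body size, and the Hill/Emax
#' dose-effect and onset/recovery kinetics of the opioid response.
#'
#' All kinetic parameters are phenomenological design values for the
#' simulator; they are not measurements. `Emax` is the maximal fractional
#' reduction of swimming speed (1 = complete paralysis), `EC50` the dose of
#' half-maximal effect, `hill_h` the Hill coefficient. Response onset follows
#' a mono-exponential with time constant `tau(d)` interpolated between
#' `tau_max` (low dose) and `tau_min` (high dose) with midpoint `EC50_tau`.
#' After `t_plateau` minutes at full effect the response decays back toward
#' baseline with time constant `recovery_tau` (use `Inf` for no recovery).
#'
#' @param name Genotype label.
#' @param baseline_speed_mu Mean baseline centroid speed (mm/s).
#' @param baseline_speed_cv Coefficient of variation of per-animal baseline
#'   speed (fraction).
#' @param body_length Body length (mm), used by body-size normalization.
#' @param Emax Maximal fractional speed reduction, in `[0, 1]`.
#' @param EC50 Dose of half-maximal effect (uM); must be positive.
#' @param hill_h Hill coefficient (dimensionless, > 0).
#' @param tau_min,tau_max Bounds of the onset time constant (min),
#'   `tau_min <= tau_max`.
#' @param EC50_tau Dose (uM) at which the onset time constant is midway
#'   between `tau_max` and `tau_min`.
#' @param t_plateau Minutes at maximal effect before recovery begins.
#' @param recovery_tau Recovery time constant (min); `Inf` disables recovery.
#' @param hyperactive_flag Logical; marks presets with elevated raw baseline
#'   locomotion (carried as metadata, does not change the model).
#'
#' @return An object of class `genotype_params` (a named list).
#' @examples
#' g <- genotype_params("tgMOR")
#' dose_effect(40, g)
#' @export
genotype_params <- function(name,
                            baseline_speed_mu = 0.25,
                            baseline_speed_cv = 0.20,
                            body_length = 1.0,
                            Emax = 0.9,
                            EC50 = 20,
                            hill_h = 2,
                            tau_min = 2,
                            tau_max = 12,
                            EC50_tau = 40,
                            t_plateau = 15,
                            recovery_tau = 60,
                            hyperactive_flag = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(baseline_speed_mu) || baseline_speed_mu <= 0) {
    stop("`baseline_speed_mu` must be positive", call. = FALSE)
  }
  if (baseline_speed_cv < 0) {
    stop("`baseline_speed_cv` must be non-negative", call. = FALSE)
  }
  if (body_length <= 0) stop("`body_length` must be positive", call. = FALSE)
  if (Emax < 0 || Emax > 1) stop("`Emax` must lie in [0, 1]", call. = FALSE)
  if (EC50 <= 0) stop("`EC50` must be positive", call. = FALSE)
  if (hill_h <= 0) stop("`hill_h` must be positive", call. = FALSE)
  if (tau_min > tau_max) {
    stop("`tau_min` must not exceed `tau_max`", call. = FALSE)
  }
  if (tau_min < 0) stop("onset time constants must be non-negative", call. = FALSE)
  if (EC50_tau <= 0) stop("`EC50_tau` must be positive", call. = FALSE)
  if (t_plateau < 0) stop("`t_plateau` must be non-negative", call. = FALSE)
  if (recovery_tau <= 0) stop("`recovery_tau` must be positive (use Inf for none)",
    call. = FALSE
  )
  structure(
    list(
      name = name,
      baseline_speed_mu = baseline_speed_mu,
      baseline_speed_cv = baseline_speed_cv,
      body_length = body_length,
      Emax = Emax,
      EC50 = EC50,
      hill_h = hill_h,
      tau_min = tau_min,
      tau_max = tau_max,
      EC50_tau = EC50_tau,
      t_plateau = t_plateau,
      recovery_tau = recovery_tau,
      hyperactive_flag = hyperactive_flag
    ),
    class = "genotype_params"
  )
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("<genotype_params> ", x$name, "\n", sep = "")
  cat(sprintf(
    "  baseline %.3g mm/s (CV %.2g), body %.3g mm\n",
    x$baseline_speed_mu, x$baseline_speed_cv, x$body_length
  ))
  cat(sprintf(
    "  Emax %.3g, EC50 %.3g uM, h %.3g; tau [%.3g, %.3g] min (EC50_tau %.3g uM)\n",
    x$Emax, x$EC50, x$hill_h, x$tau_min, x$tau_max, x$EC50_tau
  ))
  cat(sprintf(
    "  plateau %.3g min, recovery tau %.3g min%s\n",
    x$t_plateau, x$recovery_tau,
    if (isTRUE(x$hyperactive_flag)) ", hyperactive baseline" else ""
  ))
  invisible(x)
}

#' Built-in genotype presets
#'
#' Returns the library of genotype presets used throughout the package:
#' the tgMOR control (transgenic C. elegans expressing mammalian mu-opioid
#' receptor pan-neuronally), a non-transgenic wild type, and tgMOR double
#' mutants for the G protein signaling components studied with this assay.
#' Preset phenotypes encode the qualitative response profiles of the
#' corresponding mutants:
#'
#' * `tgMOR` — dose-dependent slowing, sustained through the scoring window.
#' * `wt` — non-transgenic; no opioid response (`Emax = 0`).
#' * `goa-1` — Galpha-o loss of function: response abolished (`Emax = 0`),
#'   hyperactive raw baseline, smaller body.
#' * `egl-10` — RGS6/7 loss: increased response magnitude (higher `Emax`,
#'   lower `EC50`).
#' * `eat-16` — RGS9 loss: faster onset and recovery, reduced magnitude.
#' * `rsbp-1` — R7BP loss: like `eat-16` (the two act as a complex).
#' * `egl-30gf` — Galpha-q gain of function: reduced magnitude, slower onset.
#'
#' All numeric values are simulator design choices, not measurements.
#'
#' @param name Optional preset name; if given, that single preset is
#'   returned, otherwise the full named list.
#' @return A named list of [genotype_params()] objects, or one such object.
#' @examples
#' names(genotype_presets())
#' genotype_presets("egl-10")
#' @export
genotype_presets <- function(name = NULL) {
  presets <- list(
    "tgMOR" = genotype_params("tgMOR"),
    "wt" = genotype_params("wt", Emax = 0),
    "goa-1" = genotype_params("goa-1",
      baseline_speed_mu = 0.35, body_length = 0.8,
      Emax = 0, hyperactive_flag = TRUE
    ),
    "egl-10" = genotype_params("egl-10", Emax = 0.98, EC50 = 10),
    "eat-16" = genotype_params("eat-16",
      baseline_speed_mu = 0.22, body_length = 0.85,
      Emax = 0.75, tau_min = 0.5, tau_max = 4,
      t_plateau = 5, recovery_tau = 15
    ),
    "rsbp-1" = genotype_params("rsbp-1",
      baseline_speed_mu = 0.24, body_length = 0.9,
      Emax = 0.78, tau_min = 0.5, tau_max = 4,
      t_plateau = 5, recovery_tau = 15
    ),
    "egl-30gf" = genotype_params("egl-30gf",
      Emax = 0.55, EC50 = 25, tau_min = 4, tau_max = 16
    )
  )
  if (is.null(name)) {
    return(presets)
  }
  if (!name %in% names(presets)) {
    stop(
      "unknown genotype preset '", name, "'; available: ",
      paste(names(presets), collapse = ", "),
      call. = FALSE
    )
  }
  presets[[name]]
}
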