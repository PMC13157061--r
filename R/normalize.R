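#' Baseline normalization of binned well traces
#'
#' Divides every bin of a well by the mean speed over the pre-treatment
#' baseline window, so baseline bins average to 1 and post-treatment values
#' are fractions of pre-treatment locomotion. The divisor is computed per
#' well by default; `scope = "genotype"` pools all baseline bins of the
#' same genotype within an experiment instead (requires a `genotype`
#' annotation column).
#'
#' Normalization states never chain: the input must be `"raw"`.
#'
#' @param binned Binned well table from [bin_well_means()].
#' @param baseline_window Two numbers (min, relative to treatment): bins
#'   with centers in `[lo, hi)` form the baseline. Must be pre-treatment.
#' @param scope `"well"` (default) or `"genotype"`.
#' @return The binned table with `mean_speed` divided by the baseline mean
#'   and `normalization_state = "baseline"`.
#' @export
baseline_normalize <- function(binned, baseline_window = c(-10, 0),
                               scope = c("well", "genotype")) {
  scope <- match.arg(scope)
  stopifnot(length(baseline_window) == 2, baseline_window[1] < baseline_window[2])
  if (baseline_window[2] > 0) {
    stop("`baseline_window` must be entirely pre-treatment (<= 0)", call. = FALSE)
  }
  if (!all(binned$normalization_state == "raw")) {
    stop("input must be raw; normalizations never chain", call. = FALSE)
  }
  in_base <- binned$bin_center_min >= baseline_window[1] &
    binned$bin_center_min < baseline_window[2]
  if (!any(in_base)) stop("no bins inside the baseline window", call. = FALSE)
  group_cols <- if (scope == "well") {
    c("experiment_id", "well_id")
  } else {
    if (is.null(binned$genotype)) {
      stop("`scope = \"genotype\"` needs a genotype annotation column", call. = FALSE)
    }
    c("experiment_id", "genotype")
  }
  divisors <- binned[in_base, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(.baseline_mean = mean(.data$mean_speed), .groups = "drop")
  out <- dplyr::left_join(binned, divisors, by = group_cols)
  bad <- is.na(out$.baseline_mean) | out$.baseline_mean <= 0
  if (any(bad)) {
    off <- dplyr::distinct(out[bad, ], .data$experiment_id, .data$well_id)
    stop(
      "baseline mean absent or non-positive for well(s): ",
      paste(off$well_id, collapse = ", "),
      call. = FALSE
    )
  }
  out$mean_speed <- out$mean_speed / out$.baseline_mean
  out$.baseline_mean <- NULL
  out$normalization_state <- "baseline"
  out
}

#' Vehicle-control normalization of binned well traces
#'
#' Divides each well's speed in every time bin by the across-well mean
#' speed of the matched vehicle-control wells — same genotype, same
#' experiment, time-matched bin. Vehicle wells themselves are normalized
#' against their group mean, so they average to 1 in every bin.
#'
#' @param binned Binned well table from [bin_well_means()] carrying
#'   `genotype` and `treatment` annotation columns.
#' @param vehicle_label Treatment label identifying vehicle wells.
#' @return The table with `mean_speed` divided bin-matched by the vehicle
#'   mean and `normalization_state = "vehicle"`.
#' @export
vehicle_normalize <- function(binned, vehicle_label = "vehicle") {
  for (col in c("genotype", "treatment")) {
    if (is.null(binned[[col]])) {
      stop("vehicle normalization needs a `", col, "` annotation column", call. = FALSE)
    }
  }
  if (!all(binned$normalization_state == "raw")) {
    stop("input must be raw; normalizations never chain", call. = FALSE)
  }
  veh <- dplyr::filter(binned, .data$treatment == vehicle_label)
  if (nrow(veh) == 0L) stop("no vehicle wells in the table", call. = FALSE)
  veh_means <- veh |>
    dplyr::group_by(.data$experiment_id, .data$genotype, .data$bin_center_min) |>
    dplyr::summarise(.vehicle_mean = mean(.data$mean_speed), .groups = "drop")
  out <- dplyr::left_join(
    binned, veh_means,
    by = c("experiment_id", "genotype", "bin_center_min")
  )
  if (anyNA(out$.vehicle_mean)) {
    off <- out[is.na(out$.vehicle_mean), ]
    stop(
      sprintf(
        "no matched vehicle bin for genotype %s, experiment %s, bin %g min",
        off$genotype[1], off$experiment_id[1], off$bin_center_min[1]
      ),
      call. = FALSE
    )
  }
  zero <- out$.vehicle_mean <= 0
  if (any(zero)) {
    off <- out[zero, ]
    stop(
      sprintf(
        "vehicle mean is zero at bin %g min (genotype %s, experiment %s)",
        off$bin_center_min[1], off$genotype[1], off$experiment_id[1]
      ),
      call. = FALSE
    )
  }
  out$mean_speed <- out$mean_speed / out$.vehicle_mean
  out$.vehicle_mean <- NULL
  out$normalization_state <- "vehicle"
  out
}

#' Body-size normalization of speed traces
#'
#' Rescales centroid speeds from mm/s to body lengths per second, for
#' genotypes whose body size differs from control.
#'
#' @param traces Tracker table (or any table with a `speed_mm_s` column).
#' @param body_length Body length (mm), positive.
#' @return The table with speeds divided by `body_length`; the speed column
#'   is renamed `speed_bl_s` and the unit recorded in attribute `"units"`.
#' @export
body_size_normalize <- function(traces, body_length) {
  if (!is.numeric(body_length) || length(body_length) != 1 || body_length <= 0) {
    stop("`body_length` must be a single positive number", call. = FALSE)
  }
  if (is.null(traces$speed_mm_s)) stop("no `speed_mm_s` column", call. = FALSE)
  out <- traces
  out$speed_bl_s <- out$speed_mm_s / body_length
  out$speed_mm_s <- NULL
  attr(out, "units") <- "body_lengths_per_s"
  out
}
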