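as_bin_series <- function(bin_centers, values) {
  if (is.data.frame(bin_centers)) {
    df <- bin_centers
    stopifnot(all(c("bin_center_min", "mean_speed") %in% names(df)))
    if (anyDuplicated(df[c("bin_center_min")]) &&
      length(unique(df$well_id)) > 1) {
      stop("expected a single well; got several", call. = FALSE)
    }
    bin_centers <- df$bin_center_min
    values <- df$mean_speed
  }
  stopifnot(is.numeric(bin_centers), is.numeric(values),
    length(bin_centers) == length(values))
  ord <- order(bin_centers)
  list(t = bin_centers[ord], v = values[ord])
}

#' Trapezoidal area under a binned speed curve
#'
#' Integrates the piecewise-linear interpolation of the bin means over a
#' time window, with linear interpolation to the window endpoints. Units:
#' (speed) x minutes.
#'
#' @param bin_centers Bin-center times (min relative to treatment), or a
#'   single-well binned table (then `values` is ignored).
#' @param values Mean speeds per bin.
#' @param window Integration window `c(t_lo, t_hi)` in minutes.
#' @return The trapezoidal integral (scalar).
#' @examples
#' auc_trace(c(0.5, 10, 29.5, 30.5), rep(1, 4), c(1, 30)) # 29
#' @export
auc_trace <- function(bin_centers, values = NULL, window = c(1, 30)) {
  s <- as_bin_series(bin_centers, values)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (length(s$t) < 2) stop("need at least 2 bins to integrate", call. = FALSE)
  if (window[1] < min(s$t) || window[2] > max(s$t)) {
    stop(
      sprintf(
        "window [%g, %g] outside trace support [%g, %g]",
        window[1], window[2], min(s$t), max(s$t)
      ),
      call. = FALSE
    )
  }
  inner <- s$t > window[1] & s$t < window[2]
  ends <- stats::approx(s$t, s$v, xout = window, ties = "ordered")$y
  x <- c(window[1], s$t[inner], window[2])
  y <- c(ends[1], s$v[inner], ends[2])
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Response magnitude as percent of maximum possible speed reduction
#'
#' The assay's AUC-based magnitude statistic over the sensitivity window
#' (default 1-30 min post-treatment):
#' `magnitude(%) = 100 * (A_max - AUC) / A_max`, where
#' `A_max = reference_level * (t_hi - t_lo)` is the maximum possible area
#' above the curve — the area of the full-reduction rectangle. A normalized
#' speed of 0 throughout the window (complete paralysis) gives 100%; no
#' deviation from the reference gives 0%. Values are not clamped: speeds
#' above the reference (hyperlocomotion) yield negative magnitudes.
#'
#' @inheritParams auc_trace
#' @param reference_level Pre-treatment reference of the normalized speed
#'   (1 for baseline- or vehicle-normalized data).
#' @return Magnitude in percent (scalar, <= 100).
#' @examples
#' magnitude_percent(c(0.5, 30.5), c(0.5, 0.5)) # 50
#' @export
magnitude_percent <- function(bin_centers, values = NULL, window = c(1, 30),
                              reference_level = 1) {
  a_max <- reference_level * (window[2] - window[1])
  if (a_max <= 0) stop("maximum area above curve must be positive", call. = FALSE)
  auc <- auc_trace(bin_centers, values, window)
  100 * (a_max - auc) / a_max
}

# Centered rolling mean of odd width k; partial windows at the edges.
rolling_mean <- function(v, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1) {
    return(v)
  }
  half <- (k - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Time to maximum effect
#'
#' Minutes from treatment application to the minimum smoothed speed within
#' the search window. The whole series is first smoothed with a centered
#' rolling mean of `smooth_k` bins (partial windows at the edges); the
#' reported time is the bin center of the smoothed minimum, with ties
#' broken toward the earliest time.
#'
#' @inheritParams auc_trace
#' @param search_window Window `c(t_lo, t_hi)` (min) searched for the
#'   minimum; bin centers in `[t_lo, t_hi]` are eligible.
#' @param smooth_k Rolling-mean width in bins (odd).
#' @return Time of maximum effect (min post-application).
#' @export
time_to_max_effect <- function(bin_centers, values = NULL,
                               search_window = c(1, 30), smooth_k = 3) {
  s <- as_bin_series(bin_centers, values)
  sm <- rolling_mean(s$v, smooth_k)
  eligible <- which(s$t >= search_window[1] & s$t <= search_window[2])
  if (length(eligible) == 0L) {
    stop("no bins inside the search window", call. = FALSE)
  }
  s$t[eligible[which.min(sm[eligible])]]
}

#' Normalized speed at the set time point
#'
#' Mean normalized speed of the time bin containing `t_set` (default
#' 10 min post-treatment), the fixed quantitation point used for
#' cross-genotype comparisons.
#'
#' @inheritParams auc_trace
#' @param t_set Set time point (min post-treatment).
#' @param bin_width Bin width in minutes; inferred from the bin-center
#'   spacing when `NULL`.
#' @return Speed of the covering bin (scalar).
#' @export
set_timepoint_speed <- function(bin_centers, values = NULL, t_set = 10,
                                bin_width = NULL) {
  s <- as_bin_series(bin_centers, values)
  if (is.null(bin_width)) {
    if (length(s$t) < 2) stop("cannot infer bin width from one bin", call. = FALSE)
    bin_width <- min(diff(s$t))
  }
  covering <- which(s$t - bin_width / 2 <= t_set & t_set < s$t + bin_width / 2)
  if (length(covering) == 0L) {
    stop("no bin covers the set time point ", t_set, " min", call. = FALSE)
  }
  s$v[covering[1]]
}

# Auxiliary (not an assay-defined statistic): minutes from the time of
# maximum effect until the smoothed speed re-crosses 50% of the reference.
recovery_half_time <- function(bin_centers, values = NULL, search_window = c(1, 30),
                               smooth_k = 3, reference_level = 1) {
  s <- as_bin_series(bin_centers, values)
  sm <- rolling_mean(s$v, smooth_k)
  t_max <- time_to_max_effect(s$t, s$v, search_window, smooth_k)
  after <- which(s$t > t_max)
  crossed <- after[sm[after] >= reference_level / 2]
  if (sm[which(s$t == t_max)[1]] >= reference_level / 2 || length(crossed) == 0L) {
    return(NA_real_)
  }
  s$t[crossed[1]] - t_max
}

#' Per-well response metrics
#'
#' Computes the three response statistics — magnitude (% of maximum
#' possible reduction), time to maximum effect, and set-time-point speed —
#' for every well of a normalized binned table, plus an auxiliary recovery
#' half-time (time from maximum effect until the smoothed speed re-crosses
#' 50% of reference; `NA` when the response never goes that deep or never
#' recovers).
#'
#' @param binned Normalized binned table ([baseline_normalize()] or
#'   [vehicle_normalize()] output).
#' @param window Sensitivity window `c(t_lo, t_hi)` (min) for magnitude.
#' @param t_set Set time point (min).
#' @param smooth_k Rolling-mean width (bins) for time to maximum effect.
#' @return Tibble with one row per well: ids, annotations if present,
#'   `magnitude_pct`, `t_max_effect_min`, `set_point_speed`,
#'   `recovery_half_time_min`, `window_lo`, `window_hi`,
#'   `normalization_state`.
#' @export
response_metrics <- function(binned, window = c(1, 30), t_set = 10, smooth_k = 3) {
  if (any(binned$normalization_state == "raw")) {
    stop("response metrics require baseline- or vehicle-normalized input",
      call. = FALSE
    )
  }
  ann_cols <- intersect(c("genotype", "treatment", "dose"), names(binned))
  binned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("experiment_id", "well_id", ann_cols, "normalization_state")
    ))) |>
    dplyr::summarise(
      magnitude_pct = magnitude_percent(.data$bin_center_min, .data$mean_speed, window),
      t_max_effect_min = time_to_max_effect(
        .data$bin_center_min, .data$mean_speed, window, smooth_k
      ),
      set_point_speed = set_timepoint_speed(.data$bin_center_min, .data$mean_speed, t_set),
      recovery_half_time_min = recovery_half_time(
        .data$bin_center_min, .data$mean_speed, window, smooth_k
      ),
      window_lo = window[1],
      window_hi = window[2],
      .groups = "drop"
    )
}
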