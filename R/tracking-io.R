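tracker_header <- c("time_s", "experiment_id", "well_id", "animal_id", "speed_mm_s")

#' Read a tracker table
#'
#' Reads the long-format tracker-table TSV dialect used throughout the
#' package: UTF-8, tab-separated, header
#' `time_s  experiment_id  well_id  animal_id  speed_mm_s`, one row per
#' time sample per animal. Missing samples are simply absent — there is no
#' NA sentinel. Times must be strictly increasing within each
#' (experiment, well, animal) and speeds non-negative; violations raise a
#' parse error naming the offending data row.
#'
#' @param path Path to a tracker TSV.
#' @return Tibble with the five dialect columns.
#' @seealso [write_tracker_table()]
#' @export
read_tracker_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, tracker_header)) {
    stop(
      "malformed tracker header: expected '",
      paste(tracker_header, collapse = "\\t"), "'",
      call. = FALSE
    )
  }
  tab <- utils::read.delim(
    path,
    colClasses = c("numeric", "character", "character", "character", "numeric"),
    check.names = FALSE, quote = "", comment.char = ""
  )
  tab <- tibble::as_tibble(tab)
  if (nrow(tab) == 0L) {
    return(tab)
  }
  bad_speed <- which(!is.finite(tab$speed_mm_s) | tab$speed_mm_s < 0)
  if (length(bad_speed)) {
    stop("negative or non-finite speed at data row ", bad_speed[1], call. = FALSE)
  }
  key <- paste(tab$experiment_id, tab$well_id, tab$animal_id, sep = "\r")
  same_as_prev <- c(FALSE, key[-1] == key[-nrow(tab)])
  non_mono <- which(same_as_prev & c(TRUE, diff(tab$time_s) <= 0))
  if (length(non_mono)) {
    stop("non-monotone time at data row ", non_mono[1], call. = FALSE)
  }
  tab
}

#' Write a tracker table
#'
#' Writes the tracker-table dialect with canonical number formatting
#' (up to 15 significant digits), so that writing, reading, and writing
#' again reproduces the file byte for byte.
#'
#' @param traces Tracker table (as from [simulate_experiment()] or
#'   [read_tracker_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracker_table <- function(traces, path) {
  missing <- setdiff(tracker_header, names(traces))
  if (length(missing)) {
    stop("tracker table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  lines <- c(
    paste(tracker_header, collapse = "\t"),
    paste(
      sprintf("%.15g", traces$time_s),
      traces$experiment_id,
      traces$well_id,
      traces$animal_id,
      sprintf("%.15g", traces$speed_mm_s),
      sep = "\t"
    )
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Well-level quality control
#'
#' Applies the assay's well-inclusion rule: a well enters analysis only if
#' exactly `expected_n` animals were successfully tracked in it. An animal
#' counts as tracked only if its trace spans at least `coverage_fraction`
#' of the recording span of its experiment. Wells failing the rule are
#' removed in full and listed in the QC report.
#'
#' @param traces Tracker table.
#' @param expected_n Required number of tracked animals per well.
#' @param coverage_fraction Minimum fraction of the recording span an
#'   animal's trace must cover to count as tracked.
#' @return A list with `kept` (the filtered tracker table) and `report`
#'   (tibble of removed wells: `experiment_id`, `well_id`, `n_tracked`,
#'   `reason`).
#' @export
qc_filter_wells <- function(traces, expected_n = 4, coverage_fraction = 0.9) {
  stopifnot(expected_n >= 1, coverage_fraction >= 0, coverage_fraction <= 1)
  empty_report <- tibble::tibble(
    experiment_id = character(), well_id = character(),
    n_tracked = integer(), reason = character()
  )
  if (nrow(traces) == 0L) {
    return(list(kept = traces, report = empty_report))
  }
  span <- traces |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::summarise(span = max(.data$time_s) - min(.data$time_s), .groups = "drop")
  per_animal <- traces |>
    dplyr::group_by(.data$experiment_id, .data$well_id, .data$animal_id) |>
    dplyr::summarise(cover = max(.data$time_s) - min(.data$time_s), .groups = "drop") |>
    dplyr::left_join(span, by = "experiment_id") |>
    dplyr::mutate(tracked = .data$cover >= coverage_fraction * .data$span)
  per_well <- per_animal |>
    dplyr::group_by(.data$experiment_id, .data$well_id) |>
    dplyr::summarise(n_tracked = sum(.data$tracked), .groups = "drop")
  bad <- dplyr::filter(per_well, .data$n_tracked != expected_n)
  report <- if (nrow(bad)) {
    dplyr::mutate(
      bad,
      n_tracked = as.integer(.data$n_tracked),
      reason = sprintf("tracked animals %d != expected %d", .data$n_tracked, expected_n)
    )
  } else {
    empty_report
  }
  bad_key <- paste(bad$experiment_id, bad$well_id, sep = "\r")
  keep <- !paste(traces$experiment_id, traces$well_id, sep = "\r") %in% bad_key
  list(kept = traces[keep, , drop = FALSE], report = report)
}

#' Time-bin well mean speeds
#'
#' Pools every sample of every animal in a well into half-open time bins
#' `[left, right)` of constant width aligned to the treatment application
#' time, and reports the per-bin mean speed. Bin centers are expressed in
#' minutes relative to `t_apply` (negative = baseline). Bins with no
#' samples are simply absent.
#'
#' @param traces Tracker table (typically after [qc_filter_wells()]).
#' @param bin_width Bin width (s).
#' @param t_apply Treatment application time (min from recording start).
#' @param metadata Optional well metadata (from [well_metadata()]) used to
#'   annotate wells with `genotype`, `treatment`, and `dose`.
#' @return Tibble with one row per well x bin: `experiment_id`, `well_id`,
#'   optional annotation columns, `bin_center_min`, `mean_speed`,
#'   `n_samples`, `n_animals`, and `normalization_state = "raw"`.
#' @export
bin_well_means <- function(traces, bin_width = 60, t_apply = 10, metadata = NULL) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (nrow(traces) == 0L) stop("no samples to bin", call. = FALSE)
  t_apply_s <- t_apply * 60
  bin_idx <- floor((traces$time_s - t_apply_s) / bin_width)
  if (any(bin_idx < -99999 | bin_idx > 99999)) {
    stop("time values implausibly far from `t_apply`", call. = FALSE)
  }
  # rowsum on a zero-padded composite key: fast and sorted by (exp, well, bin)
  key <- paste(traces$experiment_id, traces$well_id,
    sprintf("%06d", bin_idx + 100000L),
    sep = "\r"
  )
  sums <- rowsum(cbind(traces$speed_mm_s, 1), key)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  animal_key <- unique(paste(traces$experiment_id, traces$well_id,
    traces$animal_id,
    sep = "\r"
  ))
  animal_well <- sub("\r[^\r]*$", "", animal_key)
  n_animals_tab <- table(animal_well)
  well_key <- paste(parts[, 1], parts[, 2], sep = "\r")
  out <- tibble::tibble(
    experiment_id = parts[, 1],
    well_id = parts[, 2],
    bin_center_min = (as.integer(parts[, 3]) - 100000L + 0.5) * bin_width / 60,
    mean_speed = unname(sums[, 1] / sums[, 2]),
    n_samples = as.integer(unname(sums[, 2])),
    n_animals = as.integer(unname(n_animals_tab[well_key])),
    normalization_state = "raw"
  )
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, metadata, by = c("experiment_id", "well_id")) |>
      dplyr::relocate("genotype", "treatment", "dose", .after = "well_id")
  }
  attr(out, "bin_width_s") <- bin_width
  attr(out, "t_apply_min") <- t_apply
  out
}
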