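write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  lines <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(unname(df), sep = "\t"))
  )
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' a data source (`"simulate"` with a generator config and group table, or
#' a tracker TSV path plus well metadata), QC settings, the normalization
#' mode, metric parameters, and the statistical tests to run.
#'
#' @param input `"simulate"` or a path to a tracker TSV.
#' @param generator A [generator_config()] (when simulating).
#' @param groups Data frame of genotype x compound x dose groups (when
#'   simulating); see [build_plate_design()].
#' @param metadata Well metadata table (when `input` is a file).
#' @param t_apply Treatment application time (min from recording start).
#' @param qc List: `expected_n`, `coverage_fraction`.
#' @param normalization List: `mode` (`"baseline"` or `"vehicle"`),
#'   `scope` (baseline mode), `baseline_window`.
#' @param metrics List: `window` (c(lo, hi) min), `t_set`, `smooth_k`.
#' @param stats List: `tests` (subset of `"one_way_anova"`,
#'   `"two_way_anova"`), `group_col`, `alpha`.
#' @param bin_width Bin width (s).
#' @param output_dir Where [run_pipeline()] writes its artifacts.
#' @param seed Overrides the generator seed when given.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = "simulate",
                            generator = generator_config(),
                            groups = data.frame(
                              genotype = c("tgMOR", "tgMOR"),
                              compound = c("vehicle", "fentanyl"),
                              dose = c(0, 40)
                            ),
                            metadata = NULL,
                            t_apply = generator$duration_baseline,
                            qc = list(),
                            normalization = list(),
                            metrics = list(),
                            stats = list(),
                            bin_width = 60,
                            output_dir = tempfile("wormpharm_run_"),
                            seed = NULL) {
  qc <- utils::modifyList(list(expected_n = 4, coverage_fraction = 0.9), qc)
  normalization <- utils::modifyList(
    list(mode = "baseline", scope = "well", baseline_window = c(-10, 0)),
    normalization
  )
  metrics <- utils::modifyList(
    list(window = c(1, 30), t_set = 10, smooth_k = 3), metrics
  )
  stats <- utils::modifyList(
    list(tests = c("one_way_anova", "two_way_anova"), group_col = "treatment",
      alpha = 0.05),
    stats
  )
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  cfg <- structure(
    list(
      input = input, generator = generator, groups = groups,
      metadata = metadata, t_apply = t_apply, qc = qc,
      normalization = normalization, metrics = metrics, stats = stats,
      bin_width = bin_width, output_dir = output_dir
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!identical(cfg$input, "simulate") && !file.exists(cfg$input)) {
    stop("validation: input must be 'simulate' or an existing tracker TSV",
      call. = FALSE
    )
  }
  if (identical(cfg$input, "simulate")) {
    stopifnot(inherits(cfg$generator, "generator_config"))
    if (is.null(cfg$groups) || nrow(cfg$groups) == 0L) {
      stop("validation: simulation needs a non-empty `groups` table", call. = FALSE)
    }
  } else if (is.null(cfg$metadata)) {
    stop("validation: file input needs well `metadata`", call. = FALSE)
  }
  w <- cfg$metrics$window
  if (length(w) != 2 || w[1] >= w[2]) {
    stop("validation: metrics window must satisfy t_lo < t_hi", call. = FALSE)
  }
  if (identical(cfg$input, "simulate")) {
    post_min <- cfg$generator$duration_baseline + cfg$generator$duration_post -
      cfg$t_apply
    if (w[2] > post_min) {
      stop("validation: metrics window exceeds the post-treatment recording span",
        call. = FALSE
      )
    }
  }
  if (!cfg$normalization$mode %in% c("baseline", "vehicle")) {
    stop("validation: normalization mode must be 'baseline' or 'vehicle'",
      call. = FALSE
    )
  }
  bad_tests <- setdiff(cfg$stats$tests, c("one_way_anova", "two_way_anova"))
  if (length(bad_tests)) {
    stop("validation: unknown tests: ", paste(bad_tests, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a key-value config file whose sections mirror the
#' [pipeline_config()] arguments (`input`, `generator`, `groups`, `qc`,
#' `normalization`, `metrics`, `stats`, `bin_width`, `output_dir`, `seed`).
#'
#' @param path Path to a YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$input)) args$input <- raw$input
  if (!is.null(raw$generator)) {
    args$generator <- do.call(generator_config, raw$generator)
  }
  if (!is.null(raw$groups)) {
    args$groups <- dplyr::bind_rows(lapply(raw$groups, tibble::as_tibble))
  }
  for (key in c("t_apply", "qc", "normalization", "metrics", "stats",
    "bin_width", "output_dir", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(args$metrics$window)) {
    args$metrics$window <- as.numeric(args$metrics$window)
  }
  if (!is.null(args$normalization$baseline_window)) {
    args$normalization$baseline_window <-
      as.numeric(args$normalization$baseline_window)
  }
  do.call(pipeline_config, args)
}

#' Run the full quantification pipeline
#'
#' Orchestrates generate (or ingest) -> QC -> bin -> normalize -> metrics ->
#' stats and writes every artifact to `cfg$output_dir`:
#' `tracker.tsv` (when simulated), `qc_report.tsv`, `binned_normalized.tsv`,
#' `metrics.tsv`, `stats.tsv`, and `manifest.json` (config hash, seed,
#' versions). Identical config and seed give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts: `traces`,
#'   `qc_report`, `binned`, `metrics`, `stats`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (identical(cfg$input, "simulate")) {
    design <- build_plate_design(cfg$groups, cfg$generator, t_apply = cfg$t_apply)
    traces <- simulate_experiment(design, cfg$generator)
    metadata <- well_metadata(design)
    paths$tracker <- file.path(cfg$output_dir, "tracker.tsv")
    write_tracker_table(traces, paths$tracker)
  } else {
    traces <- read_tracker_table(cfg$input)
    metadata <- tibble::as_tibble(cfg$metadata)
  }

  qc <- qc_filter_wells(traces,
    expected_n = cfg$qc$expected_n,
    coverage_fraction = cfg$qc$coverage_fraction
  )
  paths$qc_report <- file.path(cfg$output_dir, "qc_report.tsv")
  write_tsv_plain(qc$report, paths$qc_report)
  if (nrow(qc$kept) == 0L) {
    stop("stage qc: no wells survived quality control", call. = FALSE)
  }

  binned_raw <- bin_well_means(qc$kept,
    bin_width = cfg$bin_width,
    t_apply = cfg$t_apply, metadata = metadata
  )
  binned <- if (cfg$normalization$mode == "baseline") {
    baseline_normalize(binned_raw,
      baseline_window = cfg$normalization$baseline_window,
      scope = cfg$normalization$scope
    )
  } else {
    vehicle_normalize(binned_raw)
  }
  paths$binned <- file.path(cfg$output_dir, "binned_normalized.tsv")
  write_tsv_plain(binned, paths$binned)

  metrics <- response_metrics(binned,
    window = cfg$metrics$window,
    t_set = cfg$metrics$t_set, smooth_k = cfg$metrics$smooth_k
  )
  paths$metrics <- file.path(cfg$output_dir, "metrics.tsv")
  write_tsv_plain(metrics, paths$metrics)

  group_col <- cfg$stats$group_col
  stat_results <- list()
  n_groups <- length(unique(metrics[[group_col]]))
  if ("one_way_anova" %in% cfg$stats$tests && n_groups >= 2) {
    groups <- split(metrics$magnitude_pct, metrics[[group_col]])
    stat_results$one_way_magnitude <- one_way_anova_bonferroni(groups)
  }
  if ("two_way_anova" %in% cfg$stats$tests && n_groups >= 2) {
    stat_results$two_way_timecourse <- two_way_anova_timecourse(
      binned,
      group_col = group_col,
      window = c(cfg$normalization$baseline_window[1], cfg$metrics$window[2])
    )
  }
  paths$stats <- file.path(cfg$output_dir, "stats.tsv")
  write_tsv_plain(stat_result_table(stat_results), paths$stats)

  cfg_json <- jsonlite::toJSON(
    cfg[setdiff(names(cfg), "metadata")],
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "wormpharm",
    version = as.character(utils::packageVersion("wormpharm")),
    r_version = as.character(getRversion()),
    seed = cfg$generator$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    artifacts = lapply(paths, basename)
  )
  unlink(tmp)
  paths$manifest <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    traces = traces, qc_report = qc$report, binned = binned,
    metrics = metrics, stats = stat_results, paths = paths
  ))
}
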