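#' Significance stars
#'
#' Star coding used in the assay's figures: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p Vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}

new_stat_result <- function(test, ...) {
  structure(c(list(test = test), list(...)), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, "\n", sep = "")
  if (!is.null(x$anova_table)) {
    print(as.data.frame(x$anova_table), row.names = FALSE)
  }
  if (!is.null(x$statistic)) {
    lab <- if (x$test == "t_test") "t" else "F"
    cat(sprintf(
      "  %s = %.4g, df = %s, p = %.4g\n",
      lab, x$statistic, paste(x$df, collapse = ", "), x$p_raw
    ))
  }
  if (!is.null(x$comparisons) && nrow(x$comparisons)) {
    cat("  pairwise (", x$correction, "):\n", sep = "")
    print(as.data.frame(x$comparisons), row.names = FALSE)
  }
  invisible(x)
}

#' Student's t test (pooled variance)
#'
#' Two-sided two-sample t-test with pooled variance, the single-comparison
#' test of the assay. Degenerate input (zero pooled variance) yields
#' `t = 0, p = 1` when the means are equal and an infinite statistic with
#' `degenerate = TRUE` otherwise.
#'
#' @param a,b Numeric vectors of well-level metrics, each of length >= 2.
#' @return A `stat_result` with `statistic`, `df`, `p_raw`.
#' @export
students_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (delta == 0) {
      return(new_stat_result("t_test",
        statistic = 0, df = df, p_raw = 1, degenerate = TRUE
      ))
    }
    return(new_stat_result("t_test",
      statistic = sign(delta) * Inf, df = df, p_raw = 0, degenerate = TRUE
    ))
  }
  t_stat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  new_stat_result("t_test",
    statistic = t_stat, df = df,
    p_raw = 2 * stats::pt(-abs(t_stat), df), degenerate = FALSE
  )
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Fixed-effects one-way ANOVA across groups of well-level metrics,
#' followed by all pairwise pooled-variance t comparisons with Bonferroni
#' correction — the multiple-comparison procedure of the assay.
#'
#' @param groups Named list of numeric vectors (one per group, each of
#'   length >= 2), or a data frame with columns `value` and `group`.
#' @return A `stat_result` with the ANOVA `F`, `df`, `p_raw`, and a
#'   `comparisons` tibble (`comparison`, `estimate`, `t`, `p_raw`,
#'   `p_adjusted`, `stars`).
#' @export
one_way_anova_bonferroni <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop(
      "each group needs n >= 2; degenerate: ",
      paste(names(groups)[sizes < 2], collapse = ", "),
      call. = FALSE
    )
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  f_stat <- tab["group", "F value"]
  p_raw <- tab["group", "Pr(>F)"]
  if (is.na(f_stat)) { # all residual variance zero
    f_stat <- 0
    p_raw <- 1
  }
  mse <- tab["Residuals", "Mean Sq"]
  df_res <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    est <- means[pr[1]] - means[pr[2]]
    se <- sqrt(mse * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    t_stat <- if (se == 0) {
      if (est == 0) 0 else sign(est) * Inf
    } else {
      est / se
    }
    p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df_res)
    tibble::tibble(
      comparison = paste(pr[1], "vs", pr[2]),
      estimate = unname(est), t = unname(t_stat), p_raw = p,
      p_adjusted = min(1, m * p)
    )
  }))
  comparisons$stars <- p_stars(comparisons$p_adjusted)
  new_stat_result("one_way_anova",
    statistic = f_stat,
    df = c(tab["group", "Df"], df_res),
    p_raw = p_raw,
    comparisons = comparisons,
    correction = "bonferroni"
  )
}

#' Two-way ANOVA on binned time courses
#'
#' Fixed-effects two-way ANOVA (main effects + interaction) on well-level
#' binned speeds, with group (genotype or treatment) and time bin as
#' categorical factors and wells as the replicate unit, followed by
#' Bonferroni-adjusted pairwise group contrasts averaged over time
#' (via \pkg{emmeans}). This mirrors the time-course comparison of the
#' assay; no repeated-measures covariance structure is modeled.
#'
#' @param binned Binned (optionally normalized) well table with an
#'   annotation column named by `group_col`.
#' @param group_col Column defining the group factor.
#' @param value_col Column holding the response.
#' @param window Optional time window `c(lo, hi)` (min) restricting the
#'   bins entering the model; `NULL` uses all bins.
#' @return A `stat_result` with an `anova_table` (term, df, F, p) and
#'   Bonferroni-adjusted pairwise `comparisons`.
#' @export
two_way_anova_timecourse <- function(binned, group_col = "treatment",
                                     value_col = "mean_speed", window = NULL) {
  if (is.null(binned[[group_col]])) {
    stop("no column `", group_col, "` in the binned table", call. = FALSE)
  }
  if (!is.null(window)) {
    binned <- binned[binned$bin_center_min >= window[1] &
      binned$bin_center_min <= window[2], ]
  }
  df <- data.frame(
    value = binned[[value_col]],
    group = factor(binned[[group_col]]),
    time = factor(binned$bin_center_min)
  )
  if (nlevels(df$group) < 2 || nlevels(df$time) < 2) {
    stop("need at least 2 levels per factor", call. = FALSE)
  }
  cell_counts <- table(df$group, df$time)
  if (any(cell_counts == 0)) {
    empty <- which(cell_counts == 0, arr.ind = TRUE)
    labs <- apply(empty, 1, function(i) {
      paste0(rownames(cell_counts)[i[1]], " @ ", colnames(cell_counts)[i[2]], " min")
    })
    stop("empty design cells: ", paste(labs, collapse = "; "), call. = FALSE)
  }
  fit <- stats::aov(value ~ group * time, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  anova_table <- tibble::tibble(
    term = c(group_col, "time", paste0(group_col, ":time")),
    df = tab[match(c("group", "time", "group:time"), terms), "Df"],
    F = tab[match(c("group", "time", "group:time"), terms), "F value"],
    p_raw = tab[match(c("group", "time", "group:time"), terms), "Pr(>F)"]
  )
  anova_table$F[is.na(anova_table$F)] <- 0
  anova_table$p_raw[is.na(anova_table$p_raw)] <- 1
  # averaging over the time factor is intentional here; silence the
  # interaction advisory emmeans prints for that situation
  emm <- suppressMessages(emmeans::emmeans(fit, "group"))
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni"))
  prs_raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  comparisons <- tibble::tibble(
    comparison = gsub(" - ", " vs ", prs$contrast),
    estimate = prs$estimate,
    t = prs$t.ratio,
    p_raw = prs_raw$p.value,
    p_adjusted = prs$p.value,
    stars = p_stars(prs$p.value)
  )
  new_stat_result("two_way_anova",
    factors = c(group_col, "time"),
    anova_table = anova_table,
    df_residual = tab[match("Residuals", terms), "Df"],
    comparisons = comparisons,
    correction = "bonferroni"
  )
}

#' Flatten stat results to a tidy table
#'
#' @param results A `stat_result` or list of them.
#' @return Tibble with one row per test term and pairwise comparison,
#'   suitable for TSV export.
#' @export
stat_result_table <- function(results) {
  if (inherits(results, "stat_result")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(r) {
    rows <- list()
    if (!is.null(r$anova_table)) {
      rows[[1]] <- tibble::tibble(
        test = r$test, comparison = paste0("effect:", r$anova_table$term),
        statistic = r$anova_table$F, df = r$anova_table$df,
        p_raw = r$anova_table$p_raw, p_adjusted = NA_real_,
        stars = p_stars(r$anova_table$p_raw)
      )
    } else if (!is.null(r$statistic)) {
      rows[[1]] <- tibble::tibble(
        test = r$test, comparison = "a vs b",
        statistic = unname(r$statistic[1]), df = unname(r$df[1]),
        p_raw = r$p_raw, p_adjusted = NA_real_, stars = p_stars(r$p_raw)
      )
    }
    if (!is.null(r$comparisons) && nrow(r$comparisons)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = r$test, comparison = r$comparisons$comparison,
        statistic = r$comparisons$t, df = NA_real_,
        p_raw = r$comparisons$p_raw, p_adjusted = r$comparisons$p_adjusted,
        stars = r$comparisons$stars
      )
    }
    dplyr::bind_rows(rows)
  }))
}
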