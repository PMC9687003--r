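#' Reflect interface angles about 90 degrees
#'
#' Raw interface orientations lie in `[0, 180)` (0 = parallel to AP).
#' Reflection about 90 folds them to `[0, 90]`, so 0 = AP-aligned and 90 =
#' DV-aligned: `theta' = min(theta, 180 - theta)`.
#'
#' @param angles numeric vector of raw angles in degrees, `[0, 180)`.
#' @return reflected angles in `[0, 90]`.
#' @export
reflect_angles <- function(angles) {
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    stop_validation("angles must be finite numbers")
  }
  if (any(angles < 0 | angles >= 180)) {
    stop_validation("raw angles must lie in [0, 180)")
  }
  pmin(angles, 180 - angles)
}

#' Co-alignment proportion of an angle sample
#'
#' The proportion of interfaces whose reflected orientation lies between
#' `threshold` and 90 degrees from the AP axis (closed interval, so the
#' comparison is inclusive at the threshold) - the proxy for boundary
#' straightness in live embryos.
#'
#' @param angles reflected angles in degrees, `[0, 90]`.
#' @param threshold lower bound of the co-aligned band (default 60).
#' @return proportion in `[0, 1]`.
#' @export
coalignment_proportion <- function(angles, threshold = 60) {
  if (length(angles) == 0L) {
    stop_validation("co-alignment proportion is undefined for an empty sample")
  }
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90)) {
    stop_validation("reflected angles must lie in [0, 90]")
  }
  mean(angles >= threshold)
}

#' Per-timepoint co-alignment proportions
#'
#' Bins an interface table to the nearest minute and computes, per condition
#' and timepoint, the proportion of interfaces with reflected angle at or
#' above `threshold`, inside the plotting window.
#'
#' @param interfaces tibble with `class`, `time_min`, `theta_deg` (raw
#'   angles), e.g. from [classify_interfaces()]; `other` interfaces are
#'   dropped.
#' @param threshold co-alignment threshold in degrees.
#' @param window time window `c(min, max)` in minutes.
#' @return tibble (condition, time_min, n_interfaces, proportion).
#' @export
coalignment_timecourse <- function(interfaces, threshold = 60,
                                   window = c(-10, 50)) {
  interfaces |>
    filter(.data$class != "other") |>
    mutate(time_min = round(.data$time_min)) |>
    filter(.data$time_min >= window[1], .data$time_min <= window[2]) |>
    mutate(theta_ref = reflect_angles(.data$theta_deg)) |>
    group_by(condition = .data$class, time_min = .data$time_min) |>
    summarise(n_interfaces = dplyr::n(),
              proportion = coalignment_proportion(.data$theta_ref, threshold),
              .groups = "drop")
}

#' LOESS-smoothed co-alignment time course
#'
#' Fits a locally weighted quadratic regression (tricube weights, the given
#' span) to the per-timepoint proportions of each condition and adds a 95%
#' pointwise confidence band from the fit's standard error (normal
#' approximation), mirroring the standard presentation of these time
#' courses.
#'
#' @param timecourse tibble from [coalignment_timecourse()].
#' @param span LOESS span in `(0, 1]` (default 0.75).
#' @return input tibble with `loess_fit`, `ci_lo`, `ci_hi` columns.
#' @export
timecourse_with_loess <- function(timecourse, span = 0.75) {
  if (!is.numeric(span) || length(span) != 1L || !is.finite(span) ||
      span <= 0 || span > 1) {
    stop_config("`span` must lie in (0, 1]")
  }
  fit_one <- function(d) {
    if (nrow(d) < 3L) {
      stop_validation("need >= 3 timepoints per condition for smoothing")
    }
    fit <- loess(proportion ~ time_min, data = d, span = span, degree = 2,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
    pr <- predict(fit, newdata = d, se = TRUE)
    mutate(d, loess_fit = as.numeric(pr$fit),
           ci_lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
           ci_hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  }
  timecourse |>
    group_by(.data$condition) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    ungroup()
}

#' Two-sample Kolmogorov-Smirnov comparison of angle distributions
#'
#' Compares the cumulative frequency distributions of two reflected-angle
#' samples: D is the supremum distance between the two empirical CDFs, the
#' p-value is the asymptotic two-sided approximation.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return list of class `ps_ks` with `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop_validation("both samples must be non-empty")
  }
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  structure(list(D = unname(res$statistic), p_value = unname(res$p.value),
                 n_a = length(sample_a), n_b = length(sample_b)),
            class = "ps_ks")
}

#' @export
print.ps_ks <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.4g (n = %d vs %d) %s\n",
              x$D, x$p_value, x$n_a, x$n_b, signif_stars(x$p_value)))
  invisible(x)
}

#' Compare PSB and control interface alignment over time
#'
#' The full co-alignment analysis for one tissue's interface table: smoothed
#' proportion curves per condition (PSB, -1, +1) over the plotting window,
#' plus the three pairwise KS comparisons of reflected-angle distributions
#' at the test timepoint (interfaces within `t_test +/- half_width`
#' minutes). Significance annotations follow the usual convention
#' (ns for p > 0.05, * < 0.05, ** < 0.01, *** < 0.001).
#'
#' @param interfaces tibble from [classify_interfaces()].
#' @param t_test test timepoint in minutes (default 30).
#' @param half_width half-width of the test window in minutes.
#' @param threshold co-alignment threshold in degrees.
#' @param window plotting window in minutes.
#' @param span LOESS span.
#' @return list of class `ps_comparison`: `curves` (tidy tibble: condition,
#'   time_min, n_interfaces, proportion, loess_fit, ci_lo, ci_hi) and `ks`
#'   (tibble: condition_a, condition_b, D, p_value, n_a, n_b, significance).
#' @export
compare_conditions <- function(interfaces, t_test = 30, half_width = 1,
                               threshold = 60, window = c(-10, 50),
                               span = 0.75) {
  tc <- coalignment_timecourse(interfaces, threshold = threshold,
                               window = window)
  curves <- timecourse_with_loess(tc, span = span)

  at_test <- interfaces |>
    filter(.data$class != "other",
           abs(.data$time_min - t_test) <= half_width) |>
    mutate(theta_ref = reflect_angles(.data$theta_deg))
  conds <- c("PSB", "minus1", "plus1")
  present <- conds[conds %in% at_test$class]
  if (length(present) < length(conds)) {
    warn(sprintf("conditions missing at t = %g min: %s (partial report)",
                 t_test, paste(setdiff(conds, present), collapse = ", ")))
  }
  pairs <- utils::combn(present, 2, simplify = FALSE)
  ks <- purrr::map_dfr(pairs, function(p) {
    a <- at_test$theta_ref[at_test$class == p[1]]
    b <- at_test$theta_ref[at_test$class == p[2]]
    r <- ks_compare(a, b)
    tibble(condition_a = p[1], condition_b = p[2], D = r$D,
           p_value = r$p_value, n_a = r$n_a, n_b = r$n_b,
           significance = signif_stars(r$p_value))
  })
  structure(list(curves = curves, ks = ks, t_test = t_test),
            class = "ps_comparison")
}

#' @export
print.ps_comparison <- function(x, ...) {
  cat(sprintf("Co-alignment comparison (KS at t = %g min):\n", x$t_test))
  print(as.data.frame(x$ks), row.names = FALSE)
  invisible(x)
}

#' Plot co-alignment curves
#'
#' Publication-style time-course plot: per-timepoint proportions as points,
#' LOESS curve with its 95% ribbon per condition.
#'
#' @param curves tibble from [timecourse_with_loess()] (or the `curves`
#'   element of [compare_conditions()]).
#' @return a ggplot object.
#' @export
plot_coalignment <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_min,
                                       colour = .data$condition,
                                       fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loess_fit), linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$proportion), size = 0.8,
                        alpha = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time relative to extension onset (min)",
                  y = "Proportion of interfaces > 60° from AP",
                  colour = "Interface", fill = "Interface") +
    ggplot2::theme_classic()
}
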