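#' Straightness index of a traced interface
#'
#' The chord-to-arc ratio of an ordered polyline: the Euclidean distance
#' between the extremities of the trace divided by the trace's arc length.
#' S = 1 for a perfectly straight boundary; S < 1 the wigglier the trace.
#' Invariant under rigid motion and reversal of point order.
#'
#' @param trace tibble (or data frame) with ordered point coordinates `x`,
#'   `y` (>= 2 points).
#' @return list of class `ps_straightness`: `S`, `chord`, `arc`.
#' @export
straightness_index <- function(trace) {
  x <- trace$x; y <- trace$y
  if (length(x) < 2L) stop_validation("a trace needs at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("trace coordinates must be finite")
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- sum(seg)
  if (arc <= 0) stop_validation("trace arc length must be > 0")
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord == 0) {
    warn("trace endpoints coincide: straightness index is 0")
  }
  structure(list(S = chord / arc, chord = chord, arc = arc),
            class = "ps_straightness")
}

#' Background level of a line trace
#'
#' Background normalisation for traced-interface intensities: the dimmest
#' `ceiling(fraction * n)` pixels of the trace define the background; their
#' mean is the background level and they are excluded from the signal.
#'
#' @param intensity numeric vector of per-pixel intensities (>= 2 pixels).
#' @param fraction fraction of pixels treated as background, in (0, 1)
#'   (default 0.20).
#' @return list: `background` (mean of the dimmest pixels), `removed`
#'   (their indices), `retained` (signal pixel indices), `degenerate`
#'   (TRUE when signal and background coincide).
#' @export
trace_background <- function(intensity, fraction = 0.20) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    stop_config("`fraction` must lie strictly between 0 and 1")
  }
  n <- length(intensity)
  if (n < 2L) stop_validation("need at least 2 pixels")
  if (any(!is.finite(intensity))) {
    stop_validation("intensities must be finite")
  }
  k <- as.integer(ceiling(fraction * n))
  ord <- order(intensity) # ties broken by position, deterministic
  removed <- sort(ord[seq_len(k)])
  retained <- setdiff(seq_len(n), removed)
  bg <- mean(intensity[removed])
  degenerate <- isTRUE(all.equal(bg, mean(intensity[retained])))
  if (degenerate) {
    warn("background equals retained signal: degenerate trace")
  }
  list(background = bg, removed = removed, retained = retained,
       degenerate = degenerate)
}

#' Log10 Myosin enrichment ratio of a boundary over its control interface
#'
#' Ratio of background-subtracted mean intensities of the PSB trace over the
#' control (+1) trace, on a log10 scale:
#' `R = log10((mean(PSB retained) - PSB background) /
#'            (mean(control retained) - control background))`,
#' each trace contributing its own dimmest-`fraction` background
#' ([trace_background()]). R = 0 means no enrichment.
#'
#' @param psb,control tibbles with an `intensity` column (the two traces).
#' @param fraction background pixel fraction per trace.
#' @return list of class `ps_enrichment`: `R`, `psb_background`,
#'   `control_background`, `n_retained_psb`, `n_retained_control`.
#' @export
enrichment_ratio <- function(psb, control, fraction = 0.20) {
  b1 <- trace_background(psb$intensity, fraction)
  b2 <- trace_background(control$intensity, fraction)
  num <- mean(psb$intensity[b1$retained]) - b1$background
  den <- mean(control$intensity[b2$retained]) - b2$background
  if (!is.finite(num) || !is.finite(den) || num <= 0 || den <= 0) {
    abort(sprintf(
      "undefined enrichment ratio: background-subtracted signal <= 0 (PSB %.3g, control %.3g)",
      num, den), class = "ps_undefined_ratio")
  }
  structure(list(R = log10(num / den),
                 psb_background = b1$background,
                 control_background = b2$background,
                 n_retained_psb = length(b1$retained),
                 n_retained_control = length(b2$retained)),
            class = "ps_enrichment")
}

#' Batch quantification of (PSB, control) trace pairs
#'
#' Applies the fixed-embryo analytics to a set of trace pairs: pairs whose
#' boundary cells are dividing (`division_flag`) are excluded up front; each
#' remaining pair yields the PSB straightness index S and the log10
#' enrichment ratio R. Pairs with an undefined ratio are retained in the
#' table but marked excluded with a reason. Summary statistics are reported
#' in box-plot form (quartiles and whiskers extending to the most extreme
#' values within 1.5x the interquartile range).
#'
#' @param traces long tibble (pair_id, role in `PSB`/`plus1`, point_index,
#'   x, y, intensity, division_flag), e.g. from
#'   [generate_line_trace_set()].
#' @param fraction background pixel fraction.
#' @return list of class `ps_batch`: `results` tibble (pair_id, S, R,
#'   excluded, reason) and `summary` tibble of box-plot statistics for S
#'   and R.
#' @export
batch_quantify <- function(traces, fraction = 0.20) {
  stopifnot(all(c("pair_id", "role", "intensity", "division_flag") %in%
                  names(traces)))
  traces <- arrange(as_tibble(traces), .data$pair_id, .data$role,
                    .data$point_index)
  flagged <- traces |>
    distinct(.data$pair_id, .data$division_flag) |>
    filter(.data$division_flag)
  if (nrow(flagged)) {
    warn(sprintf("excluding %d pair(s) with dividing boundary cells",
                 nrow(flagged)))
  }
  kept <- filter(traces, !.data$division_flag)
  ids <- unique(kept$pair_id)
  if (length(ids) == 0L) {
    warn("all pairs excluded: empty output")
    return(structure(list(
      results = tibble(pair_id = numeric(), S = numeric(), R = numeric(),
                       excluded = logical(), reason = character()),
      summary = tibble()), class = "ps_batch"))
  }
  res <- purrr::map_dfr(ids, function(id) {
    pr <- filter(kept, .data$pair_id == id)
    psb <- filter(pr, .data$role == "PSB")
    ctl <- filter(pr, .data$role != "PSB")
    S <- straightness_index(psb)$S
    R <- tryCatch(enrichment_ratio(psb, ctl, fraction)$R,
                  ps_undefined_ratio = function(e) NA_real_)
    tibble(pair_id = id, S = S, R = R, excluded = is.na(R),
           reason = ifelse(is.na(R), "undefined_ratio", ""))
  })
  if (any(res$excluded)) {
    warn(sprintf("%d pair(s) excluded for undefined enrichment ratios",
                 sum(res$excluded)))
  }
  boxstats <- function(v) {
    v <- v[is.finite(v)]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    tibble(n = length(v), q1 = q[1], median = q[2], q3 = q[3],
           whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
           whisker_hi = max(v[v <= q[3] + 1.5 * iqr]),
           mean = mean(v))
  }
  summary <- bind_rows(
    mutate(boxstats(res$S), statistic = "S", .before = 1),
    mutate(boxstats(res$R[!res$excluded]), statistic = "R", .before = 1)
  )
  structure(list(results = res, summary = summary), class = "ps_batch")
}

#' @export
print.ps_batch <- function(x, ...) {
  cat(sprintf("Fixed-embryo quantification: %d pairs (%d excluded)\n",
              nrow(x$results), sum(x$results$excluded)))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
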