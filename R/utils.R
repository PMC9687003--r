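#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n rename row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif setNames quantile median sd loess predict
NULL

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ps_config_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ps_validation_error")
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config("`%s` must be a single finite number", name)
  }
  if (x < min || x > max) {
    stop_config("`%s` = %g is outside [%g, %g]", name, x, min, max)
  }
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Orientation of a segment relative to the AP axis
#'
#' Angle in degrees in `[0, 180)` between the anteroposterior axis
#' (AP = +x by convention) and the chord `(dx, dy)`. A dorsoventrally
#' oriented (vertical) interface has angle 90.
#'
#' @param dx,dy chord components in image coordinates.
#' @return numeric vector of angles in degrees, `[0, 180)`.
#' @keywords internal
chord_angle_deg <- function(dx, dy) {
  a <- atan2(dy, dx) * 180 / pi
  a <- a %% 180
  a[a == 180] <- 0
  a
}

signif_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
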