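#' Write / read a tracked mesh
#'
#' JSON serialises the full `ps_tissue` (config, frame times, cells with
#' ground truth, vertices, interfaces) at maximum numeric precision, so a
#' write/read round trip reproduces the object. The CSV format is the
#' long-format vertex table only (frame, cell_id, vertex_index, x, y).
#'
#' @param tissue a `ps_tissue`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_mesh <- function(tissue, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tissue$vertices, path)
    return(invisible(path))
  }
  payload <- list(
    config = unclass(tissue$config),
    time = tissue$time,
    cells = tissue$cells,
    vertices = tissue$vertices,
    interfaces = tissue$interfaces
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh
#' @param strict error (rather than warn) on missing components.
#' @export
read_mesh <- function(path, strict = TRUE) {
  if (grepl("\\.csv$", path)) {
    verts <- read_table_checked(path, c("frame", "cell_id", "vertex_index",
                                        "x", "y"))
    return(verts)
  }
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("config", "time", "cells", "vertices", "interfaces")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    msg <- sprintf("mesh file %s lacks component(s): %s", path,
                   paste(missing, collapse = ", "))
    if (strict) stop_validation(msg) else warn(msg)
  }
  cfg <- obj$config
  class(cfg) <- "ps_config"
  out <- list(cells = as_tibble(obj$cells),
              vertices = as_tibble(obj$vertices),
              interfaces = as_tibble(obj$interfaces),
              time = as_tibble(obj$time),
              config = cfg)
  class(out) <- "ps_tissue"
  out
}

read_table_checked <- function(path, required) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop_validation("file %s is missing column(s): %s", path,
                    paste(missing, collapse = ", "))
  }
  tb
}

#' Read / write dot tables and trace tables
#'
#' Plain CSV with a header row; [read_dots()] requires frame, x, y,
#' intensity columns and [read_traces()] the long trace schema.
#'
#' @param dots,traces tibbles to write.
#' @param path file path.
#' @export
write_dots <- function(dots, path) {
  readr::write_csv(dots, path)
  invisible(path)
}

#' @rdname write_dots
#' @export
read_dots <- function(path) {
  read_table_checked(path, c("frame", "x", "y", "intensity"))
}

#' @rdname write_dots
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_dots
#' @export
read_traces <- function(path) {
  read_table_checked(path, c("pair_id", "role", "point_index", "x", "y",
                             "intensity", "division_flag"))
}

#' Pipeline configuration
#'
#' Defaults collect every analysis parameter in one serialisable list:
#' the synthetic-embryo model, dot tracking (`max_displacement`, `max_gap`),
#' dot-to-cell assignment (`capture_radius`), expressing-cell calling
#' (`min_frames`), and the co-alignment analysis with its published defaults
#' (60 degree threshold, -10..50 min window, LOESS span 0.75, KS test at
#' t = 30 min). `overrides` is a nested list merged over the defaults.
#'
#' @param overrides nested list of overrides, e.g.
#'   `list(synthesis = list(beta = 0))`.
#' @param seed master seed; every stage derives its randomness from it.
#' @return nested list of class `ps_pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), seed = 1L) {
  base <- list(
    seed = as.integer(seed),
    stages = c("simulate", "track", "boundaries", "coalign"),
    write_plots = TRUE,
    synthesis = list(),       # passed to synthesis_config()
    tracking = list(max_displacement = 5, max_gap = 1),
    assignment = list(capture_radius = 5),
    expressing = list(min_frames = 5),
    kymograph = list(ap_bins = 40),
    coalign = list(threshold = 60, window = c(-10, 50), span = 0.75,
                   t_test = 30, half_width = 1),
    traces = list(),          # passed to trace_set_config()
    screen = list()           # passed to generate_screen_fixture()
  )
  cfg <- utils::modifyList(base, overrides)
  class(cfg) <- c("ps_pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}
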