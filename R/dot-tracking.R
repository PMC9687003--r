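#' Detect transcription dots in an intensity image
#'
#' Thresholds a 2D intensity field and reduces each connected component of
#' above-threshold pixels to one dot at its intensity-weighted centroid, with
#' intensity equal to the component maximum. The image is a plain numeric
#' matrix in `[y, x]` (row, column) convention, e.g. a maximum-intensity
#' projection; z-handling is the caller's preprocessing.
#'
#' @param image numeric matrix (2D intensity field).
#' @param threshold pixel intensity threshold (> 0); pixels `>= threshold`
#'   are foreground.
#' @param min_area minimum component size in pixels; smaller components are
#'   discarded.
#' @return tibble (x, y, intensity, area), one row per dot.
#' @export
detect_dots <- function(image, threshold, min_area = 1L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_validation("`image` must be a 2D numeric matrix")
  }
  check_number(threshold, "threshold", min = 1e-12)
  check_number(min_area, "min_area", min = 1)
  empty <- tibble(x = numeric(), y = numeric(),
                  intensity = numeric(), area = integer())
  if (length(image) == 0L) return(empty)
  mask <- matrix(as.numeric(image >= threshold), nrow(image), ncol(image))
  if (!any(mask > 0)) return(empty)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0)
  if (length(idx) == 0L) return(empty)
  comp <- as.integer(lab[idx])
  pos <- arrayInd(idx, dim(image))
  wt <- image[idx]
  df <- tibble(comp = comp, y = pos[, 1], x = pos[, 2], w = wt)
  out <- df |>
    group_by(.data$comp) |>
    summarise(
      x = sum(.data$x * .data$w) / sum(.data$w),
      y = sum(.data$y * .data$w) / sum(.data$w),
      intensity = max(.data$w),
      area = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$area >= min_area) |>
    select("x", "y", "intensity", "area")
  out
}

#' Track dots through time by greedy nearest-neighbour linking
#'
#' Frame-to-frame linking, closest pairs first: at each frame, candidate
#' links between open track ends (last seen at most `max_gap + 1` frames
#' earlier) and current dots are sorted by distance and accepted greedily;
#' links longer than `max_displacement` are forbidden. Unlinked dots start
#' new tracks. Dots are sparse and near-stationary relative to cell size, so
#' greedy linking is close to the minimum-total-displacement matching.
#'
#' @param dots tibble with columns `frame`, `x`, `y` (other columns are
#'   carried through).
#' @param max_displacement maximum link length in pixels (> 0).
#' @param max_gap maximum number of missing frames a track may bridge.
#' @return input tibble with a `track_id` column, ordered by track and frame.
#' @export
track_dots <- function(dots, max_displacement, max_gap = 0L) {
  check_number(max_displacement, "max_displacement", min = 1e-12)
  check_number(max_gap, "max_gap", min = 0)
  stopifnot(all(c("frame", "x", "y") %in% names(dots)))
  dots <- arrange(as_tibble(dots), .data$frame)
  n <- nrow(dots)
  track_id <- integer(n)
  if (n == 0L) return(mutate(dots, track_id = integer()))
  next_id <- 0L
  # open track ends: row index of last dot, per track
  open_row <- integer(0)
  frames <- sort(unique(dots$frame))
  for (f in frames) {
    cur <- which(dots$frame == f)
    keep <- dots$frame[open_row] >= f - 1L - max_gap
    open_row <- open_row[keep]
    linked_cur <- rep(FALSE, length(cur))
    used_open <- rep(FALSE, length(open_row))
    if (length(open_row) && length(cur)) {
      d <- outer(dots$x[open_row], dots$x[cur], "-")^2 +
        outer(dots$y[open_row], dots$y[cur], "-")^2
      cand <- which(d <= max_displacement^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_open[i] || linked_cur[j]) next
          used_open[i] <- TRUE
          linked_cur[j] <- TRUE
          track_id[cur[j]] <- track_id[open_row[i]]
          open_row[i] <- cur[j]
        }
      }
    }
    new <- cur[!linked_cur]
    if (length(new)) {
      track_id[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
      open_row <- c(open_row, new)
    }
  }
  dots$track_id <- track_id
  arrange(dots, .data$track_id, .data$frame)
}

# Minimum distance from each point to the polygon outline, <= tol test.
point_on_boundary <- function(bnd, pts, tol) {
  k <- nrow(bnd)
  jn <- c(2:k, 1L)
  on <- rep(FALSE, nrow(pts))
  for (s in seq_len(k)) {
    ax <- bnd[s, 1]; ay <- bnd[s, 2]
    bx <- bnd[jn[s], 1]; by <- bnd[jn[s], 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    tt <- if (L2 > 0) clamp(((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / L2,
                            0, 1) else 0
    d2 <- (pts[, 1] - (ax + tt * vx))^2 + (pts[, 2] - (ay + tt * vy))^2
    on <- on | d2 <= tol^2
  }
  on
}

# Split one frame's vertex table into per-cell polygon matrices plus
# centroids and bounding boxes.
frame_polygons <- function(vertices_frame) {
  sp <- split(vertices_frame[c("x", "y")], vertices_frame$cell_id)
  ids <- as.numeric(names(sp))
  cx <- vapply(sp, function(p) mean(p$x), 0)
  cy <- vapply(sp, function(p) mean(p$y), 0)
  bb <- t(vapply(sp, function(p) c(min(p$x), max(p$x), min(p$y), max(p$y)),
                 numeric(4)))
  list(ids = ids, polys = sp, cx = cx, cy = cy, bb = bb)
}

#' Assign dots to cells by point-in-polygon
#'
#' Each dot is assigned to the cell polygon containing it. Dots on a shared
#' edge (or claimed by more than one polygon numerically), and dots outside
#' every polygon but within `capture_radius` of a cell centroid, go to the
#' cell with the nearest centroid, ties broken by smaller `cell_id`.
#' Remaining dots are unassigned (`NA`).
#'
#' @param dots tibble with columns `x`, `y` (one frame).
#' @param vertices_frame one frame's vertex table (`cell_id`, `vertex_index`,
#'   `x`, `y`), polygons in vertex order.
#' @param capture_radius assignment radius (px) for dots outside the mesh.
#' @return input tibble with a `cell_id` column (`NA` = unassigned).
#' @export
assign_dots_to_cells <- function(dots, vertices_frame, capture_radius = 5) {
  check_number(capture_radius, "capture_radius", min = 0)
  dots <- as_tibble(dots)
  fp <- frame_polygons(vertices_frame)
  n <- nrow(dots)
  cell_id <- rep(NA_real_, n)
  if (n == 0L) return(mutate(dots, cell_id = numeric()))
  pts <- cbind(dots$x, dots$y)
  tol <- 1e-9
  inside <- matrix(FALSE, n, length(fp$ids))
  for (ci in seq_along(fp$ids)) {
    bb <- fp$bb[ci, ]
    near <- which(pts[, 1] >= bb[1] - tol & pts[, 1] <= bb[2] + tol &
                    pts[, 2] >= bb[3] - tol & pts[, 2] <= bb[4] + tol)
    if (!length(near)) next
    bnd <- as.matrix(fp$polys[[ci]])
    hit <- mgcv::in.out(bnd, pts[near, , drop = FALSE])
    # points numerically on the polygon boundary count as hits for every
    # adjoining cell, so shared-edge dots fall through to the centroid rule
    hit <- hit | point_on_boundary(bnd, pts[near, , drop = FALSE], tol)
    inside[near, ci] <- hit
  }
  for (k in seq_len(n)) {
    hits <- which(inside[k, ])
    if (length(hits) == 1L) {
      cell_id[k] <- fp$ids[hits]
    } else {
      # boundary/ambiguous or outside: nearest centroid, within the capture
      # radius if the dot is outside every polygon
      d2 <- (fp$cx - pts[k, 1])^2 + (fp$cy - pts[k, 2])^2
      cand <- if (length(hits) > 1L) hits else which(d2 <= capture_radius^2)
      if (length(cand)) {
        best <- cand[order(d2[cand], fp$ids[cand])][1]
        cell_id[k] <- fp$ids[best]
      }
    }
  }
  mutate(dots, cell_id = cell_id)
}

#' Assign every frame of a dot table to cells
#'
#' Convenience wrapper applying [assign_dots_to_cells()] frame by frame
#' against a tissue mesh.
#'
#' @param dots tibble with `frame`, `x`, `y`.
#' @param tissue a `ps_tissue` (or anything with a `vertices` tibble).
#' @param capture_radius see [assign_dots_to_cells()].
#' @export
assign_dot_movie <- function(dots, tissue, capture_radius = 5) {
  verts <- if (is.list(tissue) && !is.data.frame(tissue)) tissue$vertices else tissue
  out <- lapply(split(dots, dots$frame), function(d) {
    f <- d$frame[1]
    assign_dots_to_cells(d, filter(verts, .data$frame == f), capture_radius)
  })
  arrange(bind_rows(out), .data$frame)
}

#' Identify expressing cells from assigned dot tracks
#'
#' A cell is called *engrailed*-expressing if dots are assigned to it in at
#' least `min_frames` distinct frames within the window.
#'
#' @param assigned tibble with `frame` and `cell_id` columns (e.g. output of
#'   [assign_dot_movie()]); `NA` cell ids are ignored.
#' @param min_frames minimum number of frames with a dot (>= 1).
#' @param window integer vector `c(first, last)` of frames to consider;
#'   `NULL` = all frames present.
#' @return numeric vector of expressing cell ids, sorted.
#' @export
classify_expressing_cells <- function(assigned, min_frames = 5L, window = NULL) {
  check_number(min_frames, "min_frames", min = 1)
  if (!is.null(window)) {
    if (length(window) != 2L || !is.numeric(window) || window[2] < window[1]) {
      stop_config("`window` must be c(first, last) with first <= last")
    }
    assigned <- filter(assigned, .data$frame >= window[1],
                       .data$frame <= window[2])
  }
  if (nrow(assigned) == 0L) return(numeric(0))
  counts <- assigned |>
    filter(!is.na(.data$cell_id)) |>
    distinct(.data$cell_id, .data$frame) |>
    dplyr::count(.data$cell_id)
  sort(counts$cell_id[counts$n >= min_frames])
}

#' Classify stripe parity from dot brightness
#'
#' Even-numbered parasegments carry brighter transcription dots than odd
#' ones. Given AP-ordered stripes with their mean dot intensities, the two
#' interleaved position classes are compared: if their mean intensities
#' differ by at least `ratio_threshold` and brightness alternates strictly
#' along AP, the brighter class is labelled `even` and the dimmer `odd`.
#' With a single intensity class (e.g. after *ftz* knock-down, where the
#' brighter even stripes are lost) parity is `unknown` unless
#' `force_parity` supplies one; inconsistent alternation is also `unknown`.
#'
#' @param stripes tibble with columns `stripe` (AP order) and
#'   `mean_intensity`.
#' @param ratio_threshold minimum bright/dim mean ratio (>= 1).
#' @param force_parity optional `"even"` or `"odd"` applied to all stripes
#'   when no alternation is detectable.
#' @return input tibble with a `parity` column (`even`/`odd`/`unknown`).
#' @export
classify_stripe_parity <- function(stripes, ratio_threshold = 1.5,
                                   force_parity = NULL) {
  stopifnot(all(c("stripe", "mean_intensity") %in% names(stripes)))
  if (nrow(stripes) < 1L) stop_validation("need at least one stripe")
  if (!is.numeric(ratio_threshold) || ratio_threshold < 1) {
    stop_config("`ratio_threshold` must be >= 1")
  }
  stripes <- arrange(as_tibble(stripes), .data$stripe)
  m <- stripes$mean_intensity
  pos_a <- seq(1, nrow(stripes), by = 2)
  pos_b <- seq_len(nrow(stripes))[-pos_a]
  parity <- rep("unknown", nrow(stripes))
  alternating <- FALSE
  if (length(pos_b) > 0) {
    ma <- mean(m[pos_a]); mb <- mean(m[pos_b])
    ratio <- max(ma, mb) / min(ma, mb)
    if (is.finite(ratio) && ratio >= ratio_threshold) {
      bright <- if (ma >= mb) pos_a else pos_b
      dim_ <- setdiff(seq_len(nrow(stripes)), bright)
      # strict alternation: every bright stripe brighter than every dim one
      if (min(m[bright]) > max(m[dim_])) {
        parity[bright] <- "even"
        parity[dim_] <- "odd"
        alternating <- TRUE
      }
    }
  }
  if (!alternating && !is.null(force_parity)) {
    if (!force_parity %in% c("even", "odd")) {
      stop_config("`force_parity` must be \"even\" or \"odd\"")
    }
    parity[] <- force_parity
  }
  mutate(stripes, parity = parity)
}

#' Build a kymograph of dot positions along the AP axis
#'
#' Histograms dot AP (x) positions per frame into `ap_bins` bins, giving the
#' familiar AP-position x time representation in which the alternating
#' bright/dim *engrailed* stripes appear as bands.
#'
#' @param dots tibble with `frame`, `x` and (for intensity mode) `intensity`.
#' @param ap_bins number of AP bins (>= 1).
#' @param mode `"count"` or `"intensity"` (summed intensity per bin).
#' @param x_range AP range covered by the bins; defaults to the data range.
#' @return matrix `ap_bins x n_frames` with attributes `breaks` (bin edges)
#'   and `frames` (frame ids, column order). In count mode column sums equal
#'   per-frame dot counts.
#' @export
build_kymograph <- function(dots, ap_bins, mode = c("count", "intensity"),
                            x_range = NULL) {
  mode <- match.arg(mode)
  check_number(ap_bins, "ap_bins", min = 1)
  ap_bins <- as.integer(ap_bins)
  frames <- sort(unique(dots$frame))
  if (is.null(x_range)) x_range <- range(dots$x)
  breaks <- seq(x_range[1], x_range[2], length.out = ap_bins + 1L)
  km <- matrix(0, nrow = ap_bins, ncol = length(frames),
               dimnames = list(NULL, frames))
  bin <- clamp(findInterval(dots$x, breaks, rightmost.closed = TRUE),
               1L, ap_bins)
  w <- if (mode == "count") rep(1, nrow(dots)) else dots$intensity
  for (k in seq_len(nrow(dots))) {
    j <- match(dots$frame[k], frames)
    km[bin[k], j] <- km[bin[k], j] + w[k]
  }
  attr(km, "breaks") <- breaks
  attr(km, "frames") <- frames
  km
}
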