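#' Extract cell-cell interfaces from one frame of a polygon mesh
#'
#' Shared edges between cell polygons are found by matching polygon edges on
#' their (rounded) vertex coordinates; every maximal chain of edges shared by
#' the same unordered cell pair collapses to a single interface whose
#' endpoints are the two farthest-apart shared vertices (its chord). The
#' interface orientation `theta_deg` is the angle between the AP axis (+x)
#' and that chord, in `[0, 180)`. An interface is classed as an AP interface
#' when the adjoining cells' centroid displacement is predominantly along AP
#' (`|dx| > |dy|`); such interfaces separate AP-neighbour cells and are the
#' ones eligible for PSB / -1 / +1 classification.
#'
#' @param vertices_frame one frame's vertex table (`cell_id`, `vertex_index`,
#'   `x`, `y`), polygon vertices in order.
#' @return tibble (cell_a, cell_b, x1, y1, x2, y2, theta_deg, is_ap) with
#'   `cell_a < cell_b`, one row per unordered cell pair.
#' @export
extract_interfaces <- function(vertices_frame) {
  vf <- as_tibble(vertices_frame)
  stopifnot(all(c("cell_id", "vertex_index", "x", "y") %in% names(vf)))
  vf <- vf[order(vf$cell_id, vf$vertex_index), ]
  empty <- tibble(cell_a = numeric(), cell_b = numeric(),
                  x1 = numeric(), y1 = numeric(), x2 = numeric(),
                  y2 = numeric(), theta_deg = numeric(), is_ap = logical())
  if (nrow(vf) == 0L) return(empty)
  # polygon edges: consecutive vertices within each cell, wrapping around
  nv <- as.vector(table(factor(vf$cell_id, levels = unique(vf$cell_id))))
  ends <- cumsum(nv)
  nxt <- seq_len(nrow(vf)) + 1L
  nxt[ends] <- ends - nv + 1L
  k1 <- paste(signif(vf$x, 9), signif(vf$y, 9))
  k2 <- k1[nxt]
  swap <- k1 > k2
  ekey <- paste(ifelse(swap, k2, k1), ifelse(swap, k1, k2), sep = "|")
  cell <- vf$cell_id
  xa <- vf$x; ya <- vf$y; xb <- vf$x[nxt]; yb <- vf$y[nxt]
  # edges shared by exactly two distinct cells
  o <- order(ekey)
  runs <- rle(ekey[o])
  two <- runs$lengths == 2L
  starts <- cumsum(runs$lengths) - runs$lengths + 1L
  i1 <- o[starts[two]]
  i2 <- o[starts[two] + 1L]
  ok <- cell[i1] != cell[i2]
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0L) return(empty)
  ca <- pmin(cell[i1], cell[i2])
  cb <- pmax(cell[i1], cell[i2])
  out <- tibble(cell_a = ca, cell_b = cb,
                x1 = xa[i1], y1 = ya[i1], x2 = xb[i1], y2 = yb[i1])
  # cell pairs sharing several edges (a multi-vertex interface chain)
  # collapse to their chord: the farthest-apart pair of shared vertices
  pkey <- paste(ca, cb)
  dup <- pkey %in% pkey[duplicated(pkey)]
  if (any(dup)) {
    fix <- lapply(split(which(dup), pkey[dup]), function(rows) {
      px <- c(out$x1[rows], out$x2[rows])
      py <- c(out$y1[rows], out$y2[rows])
      d <- outer(px, px, "-")^2 + outer(py, py, "-")^2
      k <- arrayInd(which.max(d), dim(d))
      tibble(cell_a = out$cell_a[rows[1]], cell_b = out$cell_b[rows[1]],
             x1 = px[k[1]], y1 = py[k[1]], x2 = px[k[2]], y2 = py[k[2]])
    })
    out <- bind_rows(out[!dup, ], bind_rows(fix))
  }
  out$theta_deg <- chord_angle_deg(out$x2 - out$x1, out$y2 - out$y1)
  # AP classification from cell centroids
  cx <- tapply(vf$x, vf$cell_id, mean)
  cy <- tapply(vf$y, vf$cell_id, mean)
  a <- match(as.character(out$cell_a), names(cx))
  b <- match(as.character(out$cell_b), names(cx))
  out$is_ap <- abs(cx[b] - cx[a]) > abs(cy[b] - cy[a])
  out <- arrange(out, .data$cell_a, .data$cell_b)
  out
}

#' Label parasegments in one frame from its expressing-cell stripes
#'
#' Expressing cells are grouped into stripes (connected components of the
#' cell adjacency graph restricted to expressing cells), ordered along AP by
#' mean centroid x. Each stripe's anterior border starts a parasegment: the
#' parasegment comprises the stripe plus every cell posterior to it up to
#' (strictly anterior to) the next stripe's anterior border. Cells anterior
#' to the first stripe or posterior to the last stripe's parasegment are
#' out-of-range (`NA`). The AP rank of a cell is its graph distance from its
#' parasegment's stripe in AP-neighbour steps (stripe members have rank 0).
#'
#' @param cells_frame tibble (cell_id, x, y) of one frame's cell centroids.
#' @param interfaces_frame interface table for the frame, as from
#'   [extract_interfaces()].
#' @param expressing vector of expressing cell ids.
#' @return tibble (cell_id, parasegment, ap_rank, stripe); `parasegment` and
#'   `stripe` are 0-based AP-ordered indices, `NA` when out-of-range.
#' @export
label_parasegments <- function(cells_frame, interfaces_frame, expressing) {
  cells_frame <- as_tibble(cells_frame)
  n <- nrow(cells_frame)
  empty <- tibble(cell_id = cells_frame$cell_id,
                  parasegment = NA_integer_, ap_rank = NA_integer_,
                  stripe = NA_integer_)
  expressing <- intersect(expressing, cells_frame$cell_id)
  if (length(expressing) == 0L) {
    warn("no expressing cells: returning an empty parasegment map")
    return(empty)
  }
  idx <- setNames(seq_len(n), cells_frame$cell_id)
  ea <- idx[as.character(interfaces_frame$cell_a)]
  eb <- idx[as.character(interfaces_frame$cell_b)]
  g_all <- igraph::graph_from_edgelist(cbind(ea, eb), directed = FALSE)
  g_all <- igraph::add_vertices(g_all, max(0L, n - igraph::vcount(g_all)))
  ap <- interfaces_frame$is_ap
  g_ap <- igraph::graph_from_edgelist(cbind(ea[ap], eb[ap]), directed = FALSE)
  g_ap <- igraph::add_vertices(g_ap, max(0L, n - igraph::vcount(g_ap)))

  expr_idx <- idx[as.character(expressing)]
  sub <- igraph::induced_subgraph(g_all, expr_idx)
  comp <- igraph::components(sub)$membership
  # stripes ordered along AP by mean centroid x
  mx <- tapply(cells_frame$x[expr_idx], comp, mean)
  ord <- order(mx)
  stripe_of_comp <- match(seq_along(mx), ord) - 1L # component -> AP index
  stripe <- rep(NA_integer_, n)
  stripe[expr_idx] <- stripe_of_comp[comp]
  n_stripes <- length(ord)

  # AP-step distances from every stripe to every cell
  d_ap <- igraph::distances(g_ap, v = expr_idx)
  dist_stripe <- matrix(Inf, n_stripes, n)
  near_x <- matrix(NA_real_, n_stripes, n) # centroid x of nearest member
  for (s in seq_len(n_stripes) - 1L) {
    rows <- which(stripe[expr_idx] == s)
    ds <- d_ap[rows, , drop = FALSE]
    j <- apply(ds, 2, which.min)
    dist_stripe[s + 1L, ] <- ds[cbind(j, seq_len(n))]
    near_x[s + 1L, ] <- cells_frame$x[expr_idx[rows]][j]
  }

  parasegment <- rep(NA_integer_, n)
  ap_rank <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    if (!is.na(stripe[k])) {
      parasegment[k] <- stripe[k]
      ap_rank[k] <- 0L
      next
    }
    dmin <- min(dist_stripe[, k])
    if (!is.finite(dmin)) next # unreachable via AP edges
    s_near <- which(dist_stripe[, k] == dmin)
    # tie between an anterior and a posterior stripe resolves to the same
    # parasegment; prefer the anterior one for the rank reference
    anterior <- near_x[s_near, k] < cells_frame$x[k]
    s_sel <- if (any(anterior)) max(s_near[anterior]) else min(s_near)
    ps <- (s_sel - 1L) - ifelse(near_x[s_sel, k] < cells_frame$x[k], 0L, 1L)
    if (ps < 0L || ps >= n_stripes - 1L) next # out-of-range
    parasegment[k] <- ps
    ap_rank[k] <- as.integer(dist_stripe[ps + 1L, k])
  }
  tibble(cell_id = cells_frame$cell_id, parasegment = parasegment,
         ap_rank = ap_rank, stripe = stripe)
}

# expressing-status helper: AP edges annotated with expression and
# anterior/posterior direction
ap_edge_table <- function(cells_frame, interfaces_frame, expressing) {
  cents <- select(cells_frame, "cell_id", "x")
  interfaces_frame |>
    filter(.data$is_ap) |>
    left_join(rename(cents, cell_a = "cell_id", ax = "x"), by = "cell_a") |>
    left_join(rename(cents, cell_b = "cell_id", bx = "x"), by = "cell_b") |>
    mutate(
      expr_a = .data$cell_a %in% expressing,
      expr_b = .data$cell_b %in% expressing,
      # anterior cell of the pair = smaller centroid x
      ant = ifelse(.data$ax < .data$bx, .data$cell_a, .data$cell_b),
      post = ifelse(.data$ax < .data$bx, .data$cell_b, .data$cell_a),
      ant_expr = ifelse(.data$ax < .data$bx, .data$expr_a, .data$expr_b),
      post_expr = ifelse(.data$ax < .data$bx, .data$expr_b, .data$expr_a)
    )
}

#' Identify PSB interfaces in one frame
#'
#' A parasegmental-boundary interface is an AP interface separating an
#' expressing cell from a non-expressing neighbour on its anterior side: the
#' anterior border of each *engrailed* stripe.
#'
#' @inheritParams label_parasegments
#' @return subset of `interfaces_frame` with `class = "PSB"`.
#' @export
find_psb_interfaces <- function(cells_frame, interfaces_frame, expressing) {
  et <- ap_edge_table(cells_frame, interfaces_frame, expressing)
  psb <- filter(et, .data$post_expr & !.data$ant_expr)
  mutate(select(psb, dplyr::all_of(names(interfaces_frame))), class = "PSB")
}

#' Identify -1 and +1 control interfaces in one frame
#'
#' The control columns of the co-alignment analysis: `+1` interfaces lie one
#' cell diameter posterior to a PSB (between the cells zero and one AP steps
#' posterior of it), `-1` interfaces one cell diameter anterior (between the
#' cells one and two AP steps anterior of it). Only AP interfaces qualify,
#' and only boundaries that are real PSBs (an anterior non-expressing
#' neighbour exists) contribute; parasegments too narrow to host an offset
#' column yield none, with a warning.
#'
#' @inheritParams label_parasegments
#' @param offset `-1` or `+1`.
#' @return subset of `interfaces_frame` with `class` `"minus1"`/`"plus1"`.
#' @export
find_offset_interfaces <- function(cells_frame, interfaces_frame, expressing,
                                   offset) {
  if (!offset %in% c(-1, 1)) stop_config("`offset` must be -1 or +1")
  et <- ap_edge_table(cells_frame, interfaces_frame, expressing)
  psb <- filter(et, .data$post_expr & !.data$ant_expr)
  if (offset == 1) {
    p0 <- unique(psb$post) # expressing cells abutting a PSB
    sel <- filter(et, .data$ant %in% p0, !.data$post %in% p0)
    missing <- setdiff(p0, sel$ant)
    cls <- "plus1"
  } else {
    a1 <- unique(psb$ant) # one AP step anterior of a PSB
    sel <- filter(et, !.data$ant_expr & !.data$post_expr,
                  .data$post %in% a1)
    missing <- setdiff(a1, sel$post)
    cls <- "minus1"
  }
  if (length(missing) && nrow(psb) > 0L) {
    warn(sprintf(
      "%d boundary cell(s) contribute no %s interface (parasegment too narrow or at the tissue edge)",
      length(missing), cls))
  }
  mutate(select(sel, dplyr::all_of(names(interfaces_frame))), class = cls)
}

#' Classify all interfaces of a tissue through time
#'
#' Runs interface extraction and PSB / -1 / +1 classification on every frame
#' of a tracked mesh, against a fixed set of expressing cells (cell
#' identities are persistent, so a classification made at reference frames
#' propagates to all frames). Interfaces not in the three named columns are
#' classed `other`.
#'
#' @param tissue a `ps_tissue` or any list with `vertices`, `cells` and
#'   `time` tibbles in the same schema.
#' @param expressing vector of expressing cell ids (e.g. from
#'   [classify_expressing_cells()]).
#' @return tibble (frame, time_min, cell_a, cell_b, class, x1, y1, x2, y2,
#'   theta_deg), classes partitioning the edges of each frame.
#' @export
classify_interfaces <- function(tissue, expressing) {
  frames <- tissue$time$frame
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    vf <- filter(tissue$vertices, .data$frame == f)
    cf <- tissue$cells |>
      filter(.data$frame == f) |>
      select("cell_id", "x", "y")
    ifc <- extract_interfaces(vf)
    psb <- find_psb_interfaces(cf, ifc, expressing)
    p1 <- withCallingHandlers(
      find_offset_interfaces(cf, ifc, expressing, 1),
      warning = function(w) invokeRestart("muffleWarning"))
    m1 <- withCallingHandlers(
      find_offset_interfaces(cf, ifc, expressing, -1),
      warning = function(w) invokeRestart("muffleWarning"))
    cls <- bind_rows(psb, p1, m1)
    ifc$class <- "other"
    if (nrow(cls)) {
      key <- paste(ifc$cell_a, ifc$cell_b)
      ifc$class[match(paste(cls$cell_a, cls$cell_b), key)] <- cls$class
    }
    ifc$frame <- f
    ifc$time_min <- tissue$time$time_min[match(f, tissue$time$frame)]
    out[[i]] <- select(ifc, "frame", "time_min", "cell_a", "cell_b",
                       "class", "x1", "y1", "x2", "y2", "theta_deg")
  }
  bind_rows(out)
}

#' Propagate parasegment labels through time
#'
#' Cell identities are persistent, so a cell's parasegment label is constant
#' over its track: labels assigned at one or more reference frames are
#' copied to every frame in which the cell exists. Cells labelled at no
#' reference frame stay unlabelled; cells with conflicting labels across
#' reference frames get the majority label, ties resolved in favour of the
#' earliest reference frame.
#'
#' @param tissue a `ps_tissue` (or list with `cells` tibble).
#' @param reference_maps tibble (ref_frame, cell_id, parasegment), e.g. rows
#'   of [label_parasegments()] output for each reference frame.
#' @return tibble (frame, cell_id, parasegment) covering all frames.
#' @export
propagate_labels <- function(tissue, reference_maps) {
  stopifnot(all(c("ref_frame", "cell_id", "parasegment") %in%
                  names(reference_maps)))
  lab <- reference_maps |>
    filter(!is.na(.data$parasegment)) |>
    group_by(.data$cell_id, .data$parasegment) |>
    summarise(votes = dplyr::n(), first_ref = min(.data$ref_frame),
              .groups = "drop") |>
    group_by(.data$cell_id) |>
    arrange(dplyr::desc(.data$votes), .data$first_ref, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("cell_id", "parasegment")
  tissue$cells |>
    select("frame", "cell_id") |>
    left_join(lab, by = "cell_id")
}
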