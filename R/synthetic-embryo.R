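#' Configuration for the synthetic germband generator
#'
#' Bundles every tunable of the synthetic-embryo model: a stripe-patterned
#' epithelium on a jittered rectangular lattice, nascent-transcription dots in
#' the *engrailed*-positive cells, and the jitter schedule that emulates the
#' progressive disordering of cell-cell interfaces during germband extension.
#'
#' The tissue is a grid of `n_rows` x (`n_parasegments` *
#' `parasegment_width_cells`) quadrilateral cells. Parasegment identity is
#' assigned by anteroposterior (AP) column blocks; the anterior-most
#' `en_stripe_width` column(s) of each parasegment are *engrailed*-positive.
#' Lattice vertices are jittered independently per frame with standard
#' deviation `sigma(t) = sigma0 + sigma1 * max(t, 0)` (pixels; `t` in minutes
#' relative to extension onset). Vertices lying on ground-truth parasegmental
#' boundary (PSB) paths are jittered with `sigma(t) * (1 - beta)` instead, so
#' `beta` (boundary tension, in `[0, 1]`) controls how straight PSBs stay
#' while control interfaces disorder. With `initial_alignment = TRUE`, frames
#' before `t = 0` use `sigma0 * initial_jitter_factor` for non-boundary
#' vertices, emulating the transient alignment of all interfaces caused by
#' mesoderm invagination pulling on the ectoderm at extension onset.
#'
#' Jitter draws are clamped at `+/- jitter_clamp_frac * cell_size_px` so that
#' cell polygons remain simple and interior-disjoint and AP column order is
#' preserved at every noise level.
#'
#' @param n_parasegments number of parasegments along AP.
#' @param parasegment_width_cells cells per parasegment along AP (>= 2).
#' @param n_rows cell rows along the dorsoventral (DV) axis.
#' @param en_stripe_width width (in columns) of the *engrailed* stripe at the
#'   anterior of each parasegment.
#' @param beta boundary tension in `[0, 1]`; 1 = perfectly straight PSBs.
#' @param sigma0 baseline vertex jitter s.d. (px).
#' @param sigma1 jitter growth rate after extension onset (px / min).
#' @param initial_alignment logical; reduce all jitter before `t = 0`.
#' @param initial_jitter_factor multiplier on `sigma0` for non-boundary
#'   vertices when `initial_alignment` is active (before `t = 0`).
#' @param t_min,t_max,dt frame times in minutes relative to extension onset.
#' @param cell_size_px lattice pitch (px).
#' @param jitter_clamp_frac clamp on vertex jitter, as a fraction of
#'   `cell_size_px`; must stay below 0.5 to preserve the lattice topology.
#' @param p_on per-frame probability that an *engrailed*-positive cell shows a
#'   transcription dot.
#' @param dot_base_intensity mean dot intensity (a.u.) in odd parasegments.
#' @param parity_brightness_ratio intensity multiplier for even-numbered
#'   parasegments (>= 1; even stripes are the brighter ones).
#' @param dot_jitter s.d. (px) of dot position about the cell centroid.
#' @param dot_noise_sd additive Gaussian noise s.d. on dot intensity (a.u.).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return a list of class `ps_config`.
#' @export
synthesis_config <- function(n_parasegments = 5L,
                             parasegment_width_cells = 4L,
                             n_rows = 10L,
                             en_stripe_width = 1L,
                             beta = 0.9,
                             sigma0 = 1.0,
                             sigma1 = 0.1,
                             initial_alignment = TRUE,
                             initial_jitter_factor = 0.15,
                             t_min = -10,
                             t_max = 50,
                             dt = 1,
                             cell_size_px = 10,
                             jitter_clamp_frac = 0.45,
                             p_on = 0.8,
                             dot_base_intensity = 100,
                             parity_brightness_ratio = 2,
                             dot_jitter = 1.5,
                             dot_noise_sd = 5,
                             seed = 1L) {
  check_number(n_parasegments, "n_parasegments", min = 1)
  check_number(parasegment_width_cells, "parasegment_width_cells", min = 2)
  check_number(n_rows, "n_rows", min = 1)
  check_number(en_stripe_width, "en_stripe_width", min = 1,
               max = parasegment_width_cells - 1)
  check_number(beta, "beta", min = 0, max = 1)
  check_number(sigma0, "sigma0", min = 0)
  check_number(sigma1, "sigma1", min = 0)
  check_number(initial_jitter_factor, "initial_jitter_factor", min = 0, max = 1)
  check_number(t_min, "t_min")
  check_number(t_max, "t_max")
  if (t_max < t_min) stop_config("`t_max` must be >= `t_min`")
  check_number(dt, "dt", min = 1e-9)
  check_number(cell_size_px, "cell_size_px", min = 1e-9)
  check_number(jitter_clamp_frac, "jitter_clamp_frac", min = 0, max = 0.499)
  check_number(p_on, "p_on", min = 0, max = 1)
  check_number(dot_base_intensity, "dot_base_intensity", min = 0)
  if (!is.numeric(parity_brightness_ratio) ||
      !is.finite(parity_brightness_ratio) || parity_brightness_ratio < 1) {
    stop_config("`parity_brightness_ratio` must be >= 1 (even stripes are the brighter ones)")
  }
  check_number(dot_jitter, "dot_jitter", min = 0)
  check_number(dot_noise_sd, "dot_noise_sd", min = 0)
  check_number(seed, "seed")
  cfg <- list(
    n_parasegments = as.integer(n_parasegments),
    parasegment_width_cells = as.integer(parasegment_width_cells),
    n_rows = as.integer(n_rows),
    en_stripe_width = as.integer(en_stripe_width),
    beta = beta, sigma0 = sigma0, sigma1 = sigma1,
    initial_alignment = isTRUE(initial_alignment),
    initial_jitter_factor = initial_jitter_factor,
    t_min = t_min, t_max = t_max, dt = dt,
    cell_size_px = cell_size_px, jitter_clamp_frac = jitter_clamp_frac,
    p_on = p_on, dot_base_intensity = dot_base_intensity,
    parity_brightness_ratio = parity_brightness_ratio,
    dot_jitter = dot_jitter, dot_noise_sd = dot_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "ps_config"
  cfg
}

#' Generate a synthetic stripe-patterned epithelium
#'
#' Produces a tracked cell mesh with persistent cell identities and full
#' ground truth: per-cell parasegment index, AP rank within the parasegment,
#' parity (even/odd parasegment number), *engrailed*-positivity, and per-frame
#' interface classes (`PSB`, `minus1`, `plus1`, `other`) with endpoint
#' coordinates and orientation angles. Coordinates follow the image
#' convention: x increases anterior to posterior (AP), y is DV, units are
#' pixels. All randomness flows from `config$seed`.
#'
#' @param config a [synthesis_config()].
#' @return an object of class `ps_tissue`: a list with tibbles `cells`
#'   (frame, time_min, cell_id, col, row, x, y, parasegment, ap_rank, parity,
#'   en_positive), `vertices` (frame, cell_id, vertex_index, x, y),
#'   `interfaces` (frame, time_min, cell_a, cell_b, class, x1, y1, x2, y2,
#'   theta_deg) and the `config` used.
#' @export
generate_epithelium <- function(config = synthesis_config()) {
  if (!inherits(config, "ps_config")) {
    stop_config("`config` must be built with `synthesis_config()`")
  }
  w <- config$parasegment_width_cells
  n_cols <- config$n_parasegments * w
  n_rows <- config$n_rows
  h <- config$cell_size_px
  times <- seq(config$t_min, config$t_max, by = config$dt)
  n_frames <- length(times)
  clamp_px <- config$jitter_clamp_frac * h

  # vertex grid, 1-based: (n_rows + 1) x (n_cols + 1)
  base_vx <- outer(rep(1, n_rows + 1L), (0:n_cols) * h)
  base_vy <- outer((0:n_rows) * h, rep(1, n_cols + 1L))
  # vertex columns lying on ground-truth PSB paths (internal boundaries)
  psb_vcols <- w * seq_len(config$n_parasegments - 1L) + 1L

  # static per-cell ground truth
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid <- grid[order(grid$row, grid$col), ]
  cell_id <- (grid$row - 1L) * n_cols + grid$col
  ps <- (grid$col - 1L) %/% w
  ap_rank <- (grid$col - 1L) %% w
  truth <- tibble(
    cell_id = cell_id, col = grid$col, row = grid$row,
    parasegment = ps, ap_rank = ap_rank,
    parity = ifelse(ps %% 2L == 0L, "even", "odd"),
    en_positive = ap_rank < config$en_stripe_width
  )

  # static interface topology (vertical = AP interfaces, horizontal = DV)
  vert <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols - 1L))
  vclass <- rep("other", nrow(vert))
  cmod <- vert$col %% w
  # PSB: anterior border of each stripe (internal boundaries only)
  vclass[cmod == 0L] <- "PSB"
  # +1: one cell diameter posterior of a PSB (excludes the first stripe,
  # whose anterior border is the tissue edge, not a PSB)
  vclass[cmod == 1L & vert$col > w] <- "plus1"
  # -1: one cell diameter anterior of a PSB (the last column boundary has no
  # PSB posterior to it)
  vclass[cmod == (w - 1L) & vert$col < n_cols - 1L] <- "minus1"
  horiz <- expand.grid(row = seq_len(n_rows - 1L), col = seq_len(n_cols))

  ids <- function(row, col) (row - 1L) * n_cols + col

  cells_l <- vector("list", n_frames)
  verts_l <- vector("list", n_frames)
  ifc_l <- vector("list", n_frames)

  withr::with_seed(config$seed, {
    for (f in seq_len(n_frames)) {
      t <- times[f]
      sig <- config$sigma0 + config$sigma1 * max(t, 0)
      fac <- matrix(1, n_rows + 1L, n_cols + 1L)
      if (t < 0 && config$initial_alignment) {
        fac[] <- config$initial_jitter_factor
      }
      fac[, psb_vcols] <- 1 - config$beta
      sd_mat <- sig * fac
      nx <- clamp(matrix(rnorm(length(sd_mat)), nrow(sd_mat)) * sd_mat,
                  -clamp_px, clamp_px)
      ny <- clamp(matrix(rnorm(length(sd_mat)), nrow(sd_mat)) * sd_mat,
                  -clamp_px, clamp_px)
      vx <- base_vx + nx
      vy <- base_vy + ny

      r <- grid$row; c <- grid$col
      # corners in order: (r,c) (r,c+1) (r+1,c+1) (r+1,c) of the vertex grid
      i1 <- cbind(r, c); i2 <- cbind(r, c + 1L)
      i3 <- cbind(r + 1L, c + 1L); i4 <- cbind(r + 1L, c)
      cx <- (vx[i1] + vx[i2] + vx[i3] + vx[i4]) / 4
      cy <- (vy[i1] + vy[i2] + vy[i3] + vy[i4]) / 4

      cells_l[[f]] <- mutate(truth, frame = f, time_min = t, x = cx, y = cy,
                             .before = 1)
      verts_l[[f]] <- tibble(
        frame = f,
        cell_id = rep(cell_id, each = 4L),
        vertex_index = rep(1:4, times = nrow(truth)),
        x = as.vector(rbind(vx[i1], vx[i2], vx[i3], vx[i4])),
        y = as.vector(rbind(vy[i1], vy[i2], vy[i3], vy[i4]))
      )

      vr <- vert$row; vc <- vert$col
      vj <- vc + 1L # shared vertex column of the AP interface
      ifc_v <- tibble(
        frame = f, time_min = t,
        cell_a = ids(vr, vc), cell_b = ids(vr, vc + 1L),
        class = vclass,
        x1 = vx[cbind(vr, vj)], y1 = vy[cbind(vr, vj)],
        x2 = vx[cbind(vr + 1L, vj)], y2 = vy[cbind(vr + 1L, vj)]
      )
      hr <- horiz$row; hc <- horiz$col
      ifc_h <- tibble(
        frame = f, time_min = t,
        cell_a = ids(hr, hc), cell_b = ids(hr + 1L, hc),
        class = "other",
        x1 = vx[cbind(hr + 1L, hc)], y1 = vy[cbind(hr + 1L, hc)],
        x2 = vx[cbind(hr + 1L, hc + 1L)], y2 = vy[cbind(hr + 1L, hc + 1L)]
      )
      ifc_l[[f]] <- bind_rows(ifc_v, ifc_h)
    }
  })

  interfaces <- bind_rows(ifc_l)
  interfaces$theta_deg <- chord_angle_deg(interfaces$x2 - interfaces$x1,
                                          interfaces$y2 - interfaces$y1)
  out <- list(
    cells = bind_rows(cells_l),
    vertices = bind_rows(verts_l),
    interfaces = interfaces,
    time = tibble(frame = seq_len(n_frames), time_min = times),
    config = config
  )
  class(out) <- "ps_tissue"
  out
}

#' @export
print.ps_tissue <- function(x, ...) {
  nf <- nrow(x$time)
  nc <- length(unique(x$cells$cell_id))
  cat(sprintf(
    "<ps_tissue> %d cells x %d frames (t = %g..%g min), %d parasegments\n",
    nc, nf, min(x$time$time_min), max(x$time$time_min),
    x$config$n_parasegments))
  invisible(x)
}

#' Generate a synthetic transcription-dot movie
#'
#' For every *engrailed*-positive cell and frame, emits (with probability
#' `p_on`) one nuclear transcription dot at the cell centroid plus Gaussian
#' positional jitter. Dot intensity is `dot_base_intensity` multiplied by
#' `parity_brightness_ratio` in even-numbered parasegments (the brighter
#' stripes), plus additive Gaussian noise, floored at zero. The ground-truth
#' dot-to-cell mapping is returned in `truth_cell_id`.
#'
#' @param tissue a `ps_tissue` from [generate_epithelium()].
#' @param config a [synthesis_config()]; defaults to the tissue's own.
#' @return tibble (frame, time_min, dot_id, x, y, intensity, truth_cell_id).
#' @export
generate_dot_movie <- function(tissue, config = tissue$config) {
  stopifnot(inherits(tissue, "ps_tissue"))
  if (!inherits(config, "ps_config")) {
    stop_config("`config` must be built with `synthesis_config()`")
  }
  en <- filter(tissue$cells, .data$en_positive)
  withr::with_seed(config$seed + 1L, {
    on <- runif(nrow(en)) < config$p_on
    en <- en[on, ]
    base <- config$dot_base_intensity *
      ifelse(en$parity == "even", config$parity_brightness_ratio, 1)
    dots <- tibble(
      frame = en$frame,
      time_min = en$time_min,
      x = en$x + rnorm(nrow(en), 0, config$dot_jitter),
      y = en$y + rnorm(nrow(en), 0, config$dot_jitter),
      intensity = pmax(0, base + rnorm(nrow(en), 0, config$dot_noise_sd)),
      truth_cell_id = en$cell_id
    )
  })
  dots <- arrange(dots, .data$frame, .data$truth_cell_id)
  mutate(dots, dot_id = row_number(), .after = "time_min")
}

#' Render one movie frame as an intensity image
#'
#' Paints isotropic Gaussian spots (amplitude = dot intensity) onto a
#' `height x width` raster; pixel `[y, x]` convention, 1-based centres.
#'
#' @param dots tibble with columns x, y, intensity (one frame).
#' @param width,height image size in pixels.
#' @param psf_sigma Gaussian spot s.d. (px).
#' @param background constant background level.
#' @return numeric matrix `height x width`.
#' @export
render_dot_frame <- function(dots, width, height, psf_sigma = 1.5,
                             background = 0) {
  img <- matrix(background, nrow = height, ncol = width)
  if (nrow(dots) == 0L) return(img)
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  for (i in seq_len(nrow(dots))) {
    img <- img + dots$intensity[i] *
      exp(-((xs - dots$x[i])^2 + (ys - dots$y[i])^2) / (2 * psf_sigma^2))
  }
  img
}

#' Configuration for synthetic fixed-embryo line-trace sets
#'
#' Each pair emulates the two-pixel-wide lines traced along a PSB and its
#' control +1 interface in fixed, immunostained embryos: a fraction `b` of
#' pixels sits at `background_level`, the rest at `background_level +
#' signal_level` (signal multiplied by the enrichment factor `f` on the PSB
#' trace), plus Gaussian noise, with pixel order randomised. Trace coordinates form a straight polyline,
#' optionally perturbed perpendicular to its axis (sinusoidal, amplitude
#' `wiggle_amp`) so chord/arc straightness can be exercised on the same
#' objects.
#'
#' @param n_pairs number of (PSB, control) trace pairs.
#' @param enrichment_factor true PSB/control signal ratio `f > 0`; `f = 1`
#'   makes the two traces identically distributed.
#' @param background_fraction fraction `b` of pixels at background, `[0, 1)`.
#' @param background_level,signal_level intensity levels (a.u.).
#' @param noise_sd additive Gaussian noise s.d. (a.u.).
#' @param trace_length pixels per trace.
#' @param wiggle_amp perpendicular perturbation amplitude (px).
#' @param p_division probability a pair is flagged as having dividing
#'   boundary cells (and so excluded downstream).
#' @param seed integer seed.
#' @export
trace_set_config <- function(n_pairs = 50L,
                             enrichment_factor = 1.5,
                             background_fraction = 0.2,
                             background_level = 20,
                             signal_level = 100,
                             noise_sd = 5,
                             trace_length = 100L,
                             wiggle_amp = 0,
                             p_division = 0,
                             seed = 1L) {
  check_number(n_pairs, "n_pairs", min = 1)
  if (!is.numeric(enrichment_factor) || !is.finite(enrichment_factor) ||
      enrichment_factor <= 0) {
    stop_config("`enrichment_factor` must be > 0")
  }
  check_number(background_fraction, "background_fraction", min = 0, max = 1 - 1e-9)
  check_number(background_level, "background_level")
  check_number(signal_level, "signal_level")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(trace_length, "trace_length", min = 2)
  if (ceiling(background_fraction * trace_length) < 1) {
    stop_config("`background_fraction * trace_length` must be >= 1 pixel")
  }
  check_number(wiggle_amp, "wiggle_amp", min = 0)
  check_number(p_division, "p_division", min = 0, max = 1)
  check_number(seed, "seed")
  cfg <- list(
    n_pairs = as.integer(n_pairs), enrichment_factor = enrichment_factor,
    background_fraction = background_fraction,
    background_level = background_level, signal_level = signal_level,
    noise_sd = noise_sd, trace_length = as.integer(trace_length),
    wiggle_amp = wiggle_amp, p_division = p_division, seed = as.integer(seed)
  )
  class(cfg) <- "ps_trace_config"
  cfg
}

#' Generate a synthetic set of (PSB, control) line-trace pairs
#'
#' @param config a [trace_set_config()].
#' @return long tibble (pair_id, role in `PSB`/`plus1`, point_index, x, y,
#'   intensity, division_flag). The true background-subtracted signal ratio
#'   is `enrichment_factor` whatever the background level, so the expected
#'   downstream enrichment is `log10(enrichment_factor)`.
#' @export
generate_line_trace_set <- function(config = trace_set_config()) {
  stopifnot(inherits(config, "ps_trace_config"))
  L <- config$trace_length
  n_bg <- as.integer(ceiling(config$background_fraction * L))
  f <- config$enrichment_factor
  out <- vector("list", 2L * config$n_pairs)
  withr::with_seed(config$seed, {
    flags <- runif(config$n_pairs) < config$p_division
    for (i in seq_len(config$n_pairs)) {
      xs <- seq_len(L)
      ys <- if (config$wiggle_amp > 0) {
        config$wiggle_amp * sin(2 * pi * xs / L * runif(1, 1, 3))
      } else rep(0, L)
      for (role in c("PSB", "plus1")) {
        # signal rides on top of the background, so the downstream
        # background-subtracted ratio recovers f whatever the background
        lvl <- config$background_level +
          config$signal_level * if (role == "PSB") f else 1
        inten <- c(rep(config$background_level, n_bg), rep(lvl, L - n_bg))
        inten <- inten[sample.int(L)] + rnorm(L, 0, config$noise_sd)
        out[[2L * (i - 1L) + (role == "plus1") + 1L]] <- tibble(
          pair_id = i, role = role, point_index = xs,
          x = xs, y = ys, intensity = inten, division_flag = flags[i]
        )
      }
    }
  })
  bind_rows(out)
}

#' Generate a randomized fixture for the in silico screen
#'
#' Builds three criterion gene lists (stripe-patterned expression, cell
#' surface protein, pair-rule regulated) over a pool of canonical
#' identifiers, with a planted three-way intersection, free-text aliases
#' injected into the lists, a temporal-expression table, and manual QC flags;
#' the ground-truth intersection and post-QC sets are computed directly from
#' the construction (plain set operations, independent of the screen module).
#'
#' @param n_genes size of the gene pool.
#' @param n_striped,n_surface,n_pairrule criterion set sizes.
#' @param n_intersection planted three-way intersection size.
#' @param n_alias number of list entries replaced by alias symbols.
#' @param p_temporal_fail probability an intersection gene has < 5% of its
#'   0-24 h expression in the 0-6 h window.
#' @param p_not_striped,p_non_surface probabilities of the two manual
#'   exclusion flags on intersection genes.
#' @param seed integer seed.
#' @return list with `striped`, `surface`, `pairrule` (character vectors of
#'   symbols as mined, aliases included), `alias` (tibble symbol,
#'   canonical_id), `temporal` (tibble canonical_id, expr_0_6h, expr_0_24h),
#'   `flags` (tibble canonical_id, not_striped_by_eye, non_surface_role) and
#'   `truth` (list: intersection, post_qc, excluded tibble with rule).
#' @export
generate_screen_fixture <- function(n_genes = 300L,
                                    n_striped = 80L,
                                    n_surface = 120L,
                                    n_pairrule = 100L,
                                    n_intersection = 12L,
                                    n_alias = 20L,
                                    p_temporal_fail = 0.2,
                                    p_not_striped = 0.1,
                                    p_non_surface = 0.1,
                                    seed = 1L) {
  for (nm in c("n_striped", "n_surface", "n_pairrule")) {
    n <- get(nm)
    check_number(n, nm, min = 1, max = n_genes)
    if (n_intersection > n) {
      stop_config("inconsistent overlap spec: n_intersection = %d > %s = %d",
                  n_intersection, nm, n)
    }
  }
  check_number(n_intersection, "n_intersection", min = 0)
  check_number(n_genes, "n_genes", min = 1)

  pool <- sprintf("FBgn%07d", seq_len(n_genes))
  withr::with_seed(seed, {
    inter <- sample(pool, n_intersection)
    rest <- setdiff(pool, inter)
    fill <- function(n_total) {
      extra <- sample(rest, n_total - length(inter))
      c(inter, extra)
    }
    striped <- fill(n_striped)
    surface <- fill(n_surface)
    pairrule <- fill(n_pairrule)
    # genes drawn into all three lists by chance would enlarge the planted
    # intersection; strip them from one list and repair its size
    stray <- setdiff(Reduce(intersect, list(striped, surface, pairrule)), inter)
    if (length(stray)) {
      striped <- setdiff(striped, stray)
      avail <- setdiff(rest, union(striped, union(surface, pairrule)))
      striped <- c(striped, sample(avail, length(stray)))
    }

    # temporal expression: intersection genes fail the 5% early rule with
    # probability p_temporal_fail; everything else passes comfortably
    early_frac <- runif(n_genes, 0.1, 0.6)
    names(early_frac) <- pool
    tfail <- inter[runif(length(inter)) < p_temporal_fail]
    early_frac[tfail] <- runif(length(tfail), 0, 0.049)
    total <- runif(n_genes, 50, 500)
    temporal <- tibble(canonical_id = pool,
                       expr_0_6h = early_frac * total,
                       expr_0_24h = total)

    flags <- tibble(
      canonical_id = inter,
      not_striped_by_eye = runif(length(inter)) < p_not_striped,
      non_surface_role = runif(length(inter)) < p_non_surface
    )

    # alias injection: replace some list entries by free-text symbols
    alias <- tibble(symbol = pool, canonical_id = pool)
    targets <- sample(pool, min(n_alias, n_genes))
    alias_syms <- paste0("sym-", targets)
    alias <- bind_rows(alias, tibble(symbol = alias_syms, canonical_id = targets))
    swap <- function(lst) {
      hit <- lst %in% targets
      lst[hit] <- paste0("sym-", lst[hit])
      sample(lst) # shuffle order as a real export would
    }
    striped <- swap(striped); surface <- swap(surface); pairrule <- swap(pairrule)
  })

  # ground truth by brute-force set operations on the construction
  excl <- tibble(canonical_id = character(), rule = character())
  if (length(inter)) {
    fl <- flags[match(inter, flags$canonical_id), ]
    tm <- temporal[match(inter, temporal$canonical_id), ]
    r1 <- inter[fl$not_striped_by_eye]
    r2 <- inter[tm$expr_0_6h / tm$expr_0_24h < 0.05]
    r3 <- inter[fl$non_surface_role]
    excl <- bind_rows(
      tibble(canonical_id = r1, rule = "not_striped_by_eye"),
      tibble(canonical_id = r2, rule = "low_early_expression"),
      tibble(canonical_id = r3, rule = "non_surface_role")
    )
  }
  truth <- list(
    intersection = sort(inter),
    post_qc = sort(setdiff(inter, excl$canonical_id)),
    excluded = arrange(excl, .data$canonical_id, .data$rule)
  )
  list(striped = striped, surface = surface, pairrule = pairrule,
       alias = alias, temporal = temporal, flags = flags, truth = truth)
}
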