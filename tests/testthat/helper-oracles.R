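# Independent oracles and small fixture builders used across the suite.

# Unit-square row mesh: n_cols cells in one row, cell i spanning x in
# [i-1, i]; cell ids 1..n_cols.
make_row_mesh <- function(n_cols) {
  do.call(rbind, lapply(seq_len(n_cols), function(c) {
    data.frame(frame = 1L, cell_id = c,
               vertex_index = 1:4,
               x = c(c - 1, c, c, c - 1),
               y = c(0, 0, 1, 1))
  }))
}

row_mesh_cells <- function(n_cols) {
  data.frame(cell_id = seq_len(n_cols), x = seq_len(n_cols) - 0.5, y = 0.5)
}

# Brute-force two-sample KS D: evaluate both empirical CDFs at every jump
# point and take the sup distance.
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 0)))
}

# Hand-rolled local quadratic regression with tricube weights: an
# independent check on the smoother used for the time courses.
local_quad_tricube <- function(x, y, x0, span) {
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  vapply(x0, function(z) {
    d <- abs(x - z)
    h <- sort(d)[k]
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    fit <- stats::lm(y ~ x + I(x^2), weights = w, subset = use)
    unname(predict(fit, newdata = data.frame(x = z)))
  }, 0)
}

# Brute-force dimmest-fraction background: sort and average.
brute_background <- function(v, fraction) {
  mean(sort(v)[seq_len(ceiling(fraction * length(v)))])
}

# Brute-force screen: plain set operations on already-canonical tables.
brute_screen <- function(striped, surface, pairrule, alias, temporal, flags,
                         min_fraction = 0.05) {
  std <- function(symbols) {
    m <- alias$canonical_id[match(symbols, alias$symbol)]
    sort(unique(m[!is.na(m)]))
  }
  inter <- intersect(intersect(std(striped), std(surface)), std(pairrule))
  tm <- temporal[match(inter, temporal$canonical_id), ]
  fl <- flags[match(inter, flags$canonical_id), ]
  bad <- (tm$expr_0_24h <= 0) |
    (tm$expr_0_6h / tm$expr_0_24h < min_fraction) |
    (!is.na(fl$not_striped_by_eye) & fl$not_striped_by_eye) |
    (!is.na(fl$non_surface_role) & fl$non_surface_role)
  list(intersection = sort(inter), post_qc = sort(inter[!bad]))
}

# Small default tissue for tests that only need structure, not the full
# movie length.
small_tissue <- function(..., seed = 1) {
  generate_epithelium(synthesis_config(..., seed = seed))
}

expressing_truth <- function(tissue) {
  sort(unique(tissue$cells$cell_id[tissue$cells$en_positive]))
}
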