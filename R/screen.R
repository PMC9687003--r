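#' Standardise gene identifiers
#'
#' Maps free-text gene symbols onto canonical identifiers through an alias
#' table (many symbols may map to one canonical id), de-duplicating the
#' result. Symbols absent from the alias table but matching a known
#' canonical id stand for themselves; anything else is reported as
#' unresolved rather than silently dropped. A symbol mapping to two
#' different canonical ids is an error (the table is ambiguous). With an
#' empty alias table the mapping is the identity.
#'
#' @param symbols character vector of gene symbols as mined.
#' @param alias tibble with columns `symbol`, `canonical_id`.
#' @return list: `ids` (sorted unique canonical ids), `unresolved` (sorted
#'   unique unresolved symbols).
#' @export
standardize_ids <- function(symbols, alias) {
  stopifnot(all(c("symbol", "canonical_id") %in% names(alias)))
  amb <- alias |>
    distinct(.data$symbol, .data$canonical_id) |>
    dplyr::count(.data$symbol) |>
    filter(.data$n > 1L)
  if (nrow(amb)) {
    stop_validation("ambiguous alias table: symbol(s) %s map to multiple canonical ids",
                    paste(amb$symbol, collapse = ", "))
  }
  symbols <- unique(as.character(symbols))
  if (nrow(alias) == 0L) {
    return(list(ids = sort(symbols), unresolved = character(0)))
  }
  mapped <- alias$canonical_id[match(symbols, alias$symbol)]
  canon <- unique(alias$canonical_id)
  self <- is.na(mapped) & symbols %in% canon
  mapped[self] <- symbols[self]
  list(ids = sort(unique(mapped[!is.na(mapped)])),
       unresolved = sort(symbols[is.na(mapped)]))
}

#' Three-way criterion intersection
#'
#' Genes satisfying all three screen criteria: striped expression along AP,
#' cell-surface protein, pair-rule regulated.
#'
#' @param striped,surface,pairrule character vectors of canonical ids.
#' @return sorted character vector (exact three-way intersection).
#' @export
intersect_criteria <- function(striped, surface, pairrule) {
  sort(Reduce(intersect, list(unique(striped), unique(surface),
                              unique(pairrule))))
}

#' Temporal early-expression filter
#'
#' Excludes genes with less than 5% of their total embryonic expression
#' (0-24 h after egg laying) occurring in the 0-6 h window; a gene exactly
#' at the threshold is kept (the cut is strict). Genes with zero total
#' expression are excluded with a distinct reason code.
#'
#' @param temporal tibble (canonical_id, expr_0_6h, expr_0_24h).
#' @param min_fraction exclusion threshold on the early fraction
#'   (default 0.05).
#' @return input tibble with `early_fraction`, `keep` and `reason` columns
#'   (`reason` is `""` for kept genes).
#' @export
temporal_filter <- function(temporal, min_fraction = 0.05) {
  stopifnot(all(c("canonical_id", "expr_0_6h", "expr_0_24h") %in%
                  names(temporal)))
  check_number(min_fraction, "min_fraction", min = 0, max = 1)
  temporal |>
    mutate(
      early_fraction = ifelse(.data$expr_0_24h > 0,
                              .data$expr_0_6h / .data$expr_0_24h, NA_real_),
      keep = !is.na(.data$early_fraction) &
        .data$early_fraction >= min_fraction,
      reason = dplyr::case_when(
        .data$expr_0_24h <= 0 ~ "zero_total_expression",
        .data$early_fraction < min_fraction ~ "low_early_expression",
        TRUE ~ ""
      )
    )
}

#' Apply manual quality-control flags to the intersection
#'
#' The three post-intersection exclusion rules: (1) genes judged not striped
#' by eye in the in situ libraries, (2) genes failing the temporal
#' early-expression filter (applied automatically from the temporal table),
#' (3) genes whose described role is not at the cell surface. Returns the
#' surviving list plus a ledger of which rule(s) fired for every excluded
#' gene.
#'
#' @param intersection character vector of canonical ids.
#' @param flags tibble (canonical_id, not_striped_by_eye, non_surface_role);
#'   genes absent from the table are treated as unflagged.
#' @param temporal tibble (canonical_id, expr_0_6h, expr_0_24h); genes
#'   absent from the table are not excluded on temporal grounds.
#' @param min_fraction see [temporal_filter()].
#' @return list: `post_qc` (sorted surviving ids), `excluded` (tibble
#'   canonical_id, rule).
#' @export
apply_manual_flags <- function(intersection, flags, temporal,
                               min_fraction = 0.05) {
  inter <- sort(unique(intersection))
  ledger <- tibble(canonical_id = character(), rule = character())
  if (length(inter) == 0L) {
    return(list(post_qc = character(0), excluded = ledger))
  }
  fl <- flags[match(inter, flags$canonical_id), ]
  r1 <- inter[!is.na(fl$not_striped_by_eye) & fl$not_striped_by_eye]
  r3 <- inter[!is.na(fl$non_surface_role) & fl$non_surface_role]
  tf <- temporal_filter(filter(temporal, .data$canonical_id %in% inter),
                        min_fraction)
  r2 <- tf$canonical_id[!tf$keep]
  ledger <- bind_rows(
    tibble(canonical_id = r1, rule = "not_striped_by_eye"),
    tibble(canonical_id = r2, rule = "low_early_expression"),
    tibble(canonical_id = r3, rule = "non_surface_role")
  ) |>
    arrange(.data$canonical_id, .data$rule)
  list(post_qc = setdiff(inter, ledger$canonical_id), excluded = ledger)
}

#' Run the full in silico screen
#'
#' Identifier standardisation of the three criterion lists, three-way
#' intersection, then the quality-control funnel (manual stripe assessment,
#' temporal early-expression filter, protein-localisation assessment).
#'
#' @param striped,surface,pairrule character vectors of gene symbols as
#'   mined (aliases allowed).
#' @param alias alias table (symbol, canonical_id).
#' @param temporal temporal expression table (canonical_id, expr_0_6h,
#'   expr_0_24h).
#' @param flags manual flag table (canonical_id, not_striped_by_eye,
#'   non_surface_role).
#' @param min_fraction temporal threshold (default 0.05).
#' @return list of class `ps_screen`: `criteria` (canonical sets),
#'   `unresolved` (per-list unresolved symbols), `intersection`, `post_qc`,
#'   `excluded` ledger and `funnel` (tibble of stage counts).
#' @export
run_screen <- function(striped, surface, pairrule, alias, temporal, flags,
                       min_fraction = 0.05) {
  std <- list(
    striped = standardize_ids(striped, alias),
    surface = standardize_ids(surface, alias),
    pairrule = standardize_ids(pairrule, alias)
  )
  inter <- intersect_criteria(std$striped$ids, std$surface$ids,
                              std$pairrule$ids)
  qc <- apply_manual_flags(inter, flags, temporal, min_fraction)
  unresolved <- purrr::map(std, "unresolved")
  n_unres <- sum(lengths(unresolved))
  if (n_unres > 0) {
    warn(sprintf("%d symbol(s) could not be standardised and are excluded from the intersection",
                 n_unres))
  }
  funnel <- tibble(
    stage = c("striped", "surface", "pairrule", "intersection", "post_qc"),
    n_genes = c(length(std$striped$ids), length(std$surface$ids),
                length(std$pairrule$ids), length(inter), length(qc$post_qc))
  )
  structure(list(
    criteria = purrr::map(std, "ids"),
    unresolved = unresolved,
    intersection = inter,
    post_qc = qc$post_qc,
    excluded = qc$excluded,
    funnel = funnel
  ), class = "ps_screen")
}

#' @export
print.ps_screen <- function(x, ...) {
  cat("In silico screen funnel:\n")
  print(as.data.frame(x$funnel), row.names = FALSE)
  if (sum(lengths(x$unresolved))) {
    cat(sprintf("unresolved symbols: %d\n", sum(lengths(x$unresolved))))
  }
  invisible(x)
}
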