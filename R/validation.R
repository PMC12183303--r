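#' Project disease-gene associations into CUI space
#'
#' Expands each (doid, gene_symbol) association through a DOID-to-UMLS-CUI
#' crosswalk: one output row per mapped CUI, deduplicated. Associations whose
#' DOID has no crosswalk entry are dropped and counted (attribute
#' `n_unmapped_doids`). Comparison across vocabularies happens entirely in
#' CUI space; no back-projection to DOIDs is attempted.
#'
#' @param assocs Tibble with `doid` and `gene_symbol` columns (extra columns
#'   are ignored).
#' @param crosswalk Tibble with `doid` and `cui` columns; duplicate rows are
#'   collapsed.
#' @return Tibble with `cui` and `gene_symbol` (uppercased), deduplicated,
#'   sorted; attribute `n_unmapped_doids` counts DOIDs that had associations
#'   but no mapping.
#' @export
to_cui_associations <- function(assocs, crosswalk) {
  assocs <- assocs |>
    as_tibble() |>
    mutate(gene_symbol = normalize_gene_symbol(.data$gene_symbol)) |>
    distinct(.data$doid, .data$gene_symbol)
  crosswalk <- crosswalk |> as_tibble() |> distinct(.data$doid, .data$cui)
  if (nrow(crosswalk) == 0) {
    warn("empty crosswalk: no associations can be mapped to CUIs")
  }
  unmapped <- assocs |>
    anti_join(crosswalk, by = "doid") |>
    distinct(.data$doid) |>
    nrow()
  out <- assocs |>
    inner_join(crosswalk, by = "doid", relationship = "many-to-many") |>
    distinct(.data$cui, .data$gene_symbol) |>
    arrange(.data$cui, .data$gene_symbol)
  structure(out, n_unmapped_doids = unmapped)
}

#' Agreement between two CUI-keyed association sets
#'
#' Compares two disease-gene association sets in CUI space. The CUIs present
#' in both sets are identified first; both sets are restricted to those
#' shared CUIs before any association is counted, so the comparison is only
#' over diseases both resources know about. The headline percentage is the
#' fraction of the right-hand (reference) set's restricted associations that
#' also appear in the left-hand set. Because the left-hand set is typically
#' far larger, the complementary quantities for the left side are reported
#' too rather than conflated.
#'
#' @param left Tibble with `cui` and `gene_symbol`: the inferred set.
#' @param right Tibble with `cui` and `gene_symbol`: the reference set.
#' @return An object of class `ct_overlap`: a list with counts
#'   `n_cui_left`, `n_cui_right`, `n_cui_shared`, `n_assoc_left`,
#'   `n_assoc_right`, `n_gene_left`, `n_gene_right`, `n_overlap`,
#'   `pct_of_right` (percentage of right-hand restricted associations found
#'   in the left set) and `pct_left_unique` (percentage of left-hand
#'   restricted associations absent from the right set).
#' @examples
#' left <- tibble::tibble(cui = "C0011860",
#'                        gene_symbol = c("CISD2", "MC4R", "PPARG"))
#' right <- tibble::tibble(cui = "C0011860",
#'                         gene_symbol = c("PPARG", "TCF7L2"))
#' overlap_report(left, right)
#' @export
overlap_report <- function(left, right) {
  left <- normalize_cui_set(left)
  right <- normalize_cui_set(right)
  shared <- intersect(unique(left$cui), unique(right$cui))
  l <- filter(left, .data$cui %in% shared)
  r <- filter(right, .data$cui %in% shared)
  n_overlap <- nrow(inner_join(l, r, by = c("cui", "gene_symbol")))
  res <- list(
    n_cui_left = dplyr::n_distinct(left$cui),
    n_cui_right = dplyr::n_distinct(right$cui),
    n_cui_shared = length(shared),
    n_assoc_left = nrow(l),
    n_assoc_right = nrow(r),
    n_gene_left = dplyr::n_distinct(l$gene_symbol),
    n_gene_right = dplyr::n_distinct(r$gene_symbol),
    n_overlap = n_overlap,
    pct_of_right = if (nrow(r) == 0) 0 else 100 * n_overlap / nrow(r),
    pct_left_unique = if (nrow(l) == 0) 0
                      else 100 * (1 - n_overlap / nrow(l))
  )
  structure(res, class = "ct_overlap")
}

normalize_cui_set <- function(x) {
  x |>
    as_tibble() |>
    mutate(gene_symbol = normalize_gene_symbol(.data$gene_symbol)) |>
    filter(!is.na(.data$cui), !is.na(.data$gene_symbol)) |>
    distinct(.data$cui, .data$gene_symbol)
}

#' @export
print.ct_overlap <- function(x, ...) {
  cat("Disease-gene association overlap (CUI-restricted)\n")
  cat(sprintf("  CUIs: %d (left) / %d (right), %d shared\n",
              x$n_cui_left, x$n_cui_right, x$n_cui_shared))
  cat(sprintf("  associations over shared CUIs: %d (left) / %d (right)\n",
              x$n_assoc_left, x$n_assoc_right))
  cat(sprintf("  genes over shared CUIs: %d (left) / %d (right)\n",
              x$n_gene_left, x$n_gene_right))
  cat(sprintf("  overlapping associations: %d (%.2f%% of right; %.2f%% of left unique)\n",
              x$n_overlap, x$pct_of_right, x$pct_left_unique))
  invisible(x)
}

#' Distinct-entity integrity counts
#'
#' Summary of the unique identifiers in an association set and crosswalk:
#' the sanity counts one checks before running an overlap comparison.
#'
#' @param assocs Tibble with `doid` and `gene_symbol` (and optionally
#'   `disease_name`/`condition_name`).
#' @param crosswalk Optional tibble with `doid` and `cui`.
#' @return One-row tibble with `n_doid`, `n_gene`, `n_assoc`,
#'   `n_condition`, and (when a crosswalk is given) `n_cui` and
#'   `n_doid_mapped`.
#' @export
integrity_counts <- function(assocs, crosswalk = NULL) {
  assocs <- as_tibble(assocs)
  name_col <- intersect(c("disease_name", "condition_name"), names(assocs))
  out <- tibble(
    n_doid = n_distinct_na(assocs$doid),
    n_gene = n_distinct_na(normalize_gene_symbol(assocs$gene_symbol)),
    n_assoc = nrow(distinct(assocs, .data$doid, .data$gene_symbol)),
    n_condition = if (length(name_col) > 0) {
      n_distinct_na(assocs[[name_col[1]]])
    } else {
      NA_integer_
    }
  )
  if (!is.null(crosswalk)) {
    cw <- distinct(as_tibble(crosswalk), .data$doid, .data$cui)
    out$n_cui <- n_distinct_na(cw$cui)
    out$n_doid_mapped <- n_distinct_na(
      cw$doid[cw$doid %in% assocs$doid]
    )
  }
  out
}

#' Write an overlap report as JSON
#'
#' @param report `ct_overlap` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  out <- unclass(report)
  out$pct_of_right <- round(out$pct_of_right, 2)
  out$pct_left_unique <- round(out$pct_left_unique, 2)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
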