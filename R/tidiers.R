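#' Tidy an overlap report into a long tibble
#'
#' @param x A `ct_overlap` object from [overlap_report()].
#' @param ... Unused.
#' @return Tibble with `statistic` and `value` columns.
#' @export
tidy.ct_overlap <- function(x, ...) {
  tibble(statistic = names(unclass(x)),
         value = as.numeric(unlist(x, use.names = FALSE)))
}

#' One-row summary of an overlap report
#'
#' @inheritParams tidy.ct_overlap
#' @return One-row tibble with every overlap count and percentage.
#' @export
glance.ct_overlap <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Ranked associations as a plain tibble
#'
#' Drops the list-column of drug names (joining it with semicolons) so the
#' result is a flat, writable tibble.
#'
#' @param x A `ct_associations` tibble from [score_associations()].
#' @param ... Unused.
#' @return A plain tibble, one row per disease-gene pair.
#' @export
tidy.ct_associations <- function(x, ...) {
  out <- as_tibble(x)
  if ("drugs" %in% names(out) && is.list(out$drugs)) {
    out$drugs <- purrr::map_chr(out$drugs,
                                function(d) paste(d, collapse = ";"))
  }
  out
}

#' One-row summary of a ranked association table
#'
#' @inheritParams tidy.ct_associations
#' @return One-row tibble with pair, disease and gene counts and the score
#'   distribution's extremes and median.
#' @export
glance.ct_associations <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_diseases = dplyr::n_distinct(x$doid),
    n_genes = dplyr::n_distinct(x$gene_symbol),
    max_score = max(x$meanRankScore),
    median_score = stats::median(x$meanRankScore),
    min_score = min(x$meanRankScore)
  )
}
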