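#' Descending rank with averaged ties
#'
#' The largest value receives rank 1; tied values receive the arithmetic mean
#' of the rank positions they span, so the rank sum is always N(N+1)/2.
#'
#' @param values Numeric vector without missing values (metrics default to
#'   zero, never `NA`).
#' @return Numeric vector of ranks.
#' @examples
#' rank_descending(c(10, 7, 7, 1)) # 1, 2.5, 2.5, 4
#' @export
rank_descending <- function(values) {
  if (length(values) == 0) abort("rank_descending: empty input")
  if (anyNA(values)) abort("rank_descending: missing values not allowed")
  rank(-values, ties.method = "average")
}

#' Mean rank across metrics
#'
#' @param ranks Numeric vector: one rank per metric for a single pair.
#' @return The arithmetic mean of the ranks.
#' @export
mean_rank <- function(ranks) {
  if (length(ranks) == 0) abort("mean_rank: no ranks supplied")
  mean(ranks)
}

#' Mean-rank score on a 0-100 scale
#'
#' Converts mean ranks over N pairs to scores: the mean ranks are ranked
#' ascending (best pair, i.e. smallest mean rank, gets rank 1, ties
#' averaged), converted to a percentile `rank / N * 100`, and the score is
#' `100 - percentile`. The best pair therefore has the highest score, and
#' scores lie in `[0, 100)`: with a unique best pair the maximum attainable
#' score is `100 * (1 - 1/N)`.
#'
#' @param mean_ranks Numeric vector of mean ranks, one per pair.
#' @return Numeric vector of scores, parallel to `mean_ranks`.
#' @examples
#' mean_rank_score(c(1, 2, 3, 4)) # 75, 50, 25, 0
#' @export
mean_rank_score <- function(mean_ranks) {
  if (length(mean_ranks) == 0) abort("mean_rank_score: empty input")
  if (anyNA(mean_ranks)) abort("mean_rank_score: missing values not allowed")
  n <- length(mean_ranks)
  pct <- rank(mean_ranks, ties.method = "average") / n * 100
  100 - pct
}

ct_metric_names <- c("nDiseases", "nDrug", "nStud", "nPub",
                     "nStudyNewness", "nPublicationWeighted")

#' Rank disease-gene associations by aggregated evidence
#'
#' Ranks every pair on each of the six evidence metrics (descending, ties
#' averaged), averages the six ranks into `meanRank`, and converts mean ranks
#' to a 0-100 `meanRankScore` via [mean_rank_score()]. The highest score
#' marks the most promising association. All six metrics are ranked
#' descending; `rank_direction` lets callers flip individual metrics (e.g.
#' `c(nDiseases = "asc")` to favour disease-specific genes) since ranking
#' gene promiscuity upward is a debatable default.
#'
#' @param pair_metrics Tibble from [compute_pair_metrics()] (or any tibble
#'   with `doid`, `gene_symbol` and the six metric columns).
#' @param per_disease If `TRUE`, ranks are computed within each disease
#'   rather than over the global pair table. Default `FALSE` (global).
#' @param rank_direction Optional named character vector mapping metric names
#'   to `"desc"` (default for all) or `"asc"`.
#' @return A tibble of class `ct_associations`, sorted by descending
#'   `meanRankScore` with ties broken by (doid, gene_symbol): the input
#'   columns plus `rank_<metric>` for each metric, `meanRank`,
#'   `percentileMeanRank` and `meanRankScore`.
#' @export
score_associations <- function(pair_metrics, per_disease = FALSE,
                               rank_direction = NULL) {
  pm <- as_tibble(pair_metrics)
  missing_cols <- setdiff(c("doid", "gene_symbol", ct_metric_names),
                          names(pm))
  if (length(missing_cols) > 0) {
    abort(sprintf("pair_metrics is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(pm) == 0) abort("pair_metrics is empty")
  dir <- setNames(rep("desc", length(ct_metric_names)), ct_metric_names)
  if (!is.null(rank_direction)) {
    bad <- setdiff(names(rank_direction), ct_metric_names)
    if (length(bad) > 0) {
      abort(sprintf("unknown metric(s) in rank_direction: %s",
                    paste(bad, collapse = ", ")))
    }
    dir[names(rank_direction)] <- rank_direction
  }

  score_block <- function(block) {
    for (m in ct_metric_names) {
      v <- block[[m]]
      block[[paste0("rank_", m)]] <-
        if (dir[[m]] == "desc") rank_descending(v)
        else rank(v, ties.method = "average")
    }
    rank_cols <- paste0("rank_", ct_metric_names)
    block$meanRank <- rowMeans(block[rank_cols])
    block$meanRankScore <- mean_rank_score(block$meanRank)
    block$percentileMeanRank <- 100 - block$meanRankScore
    block
  }

  out <- if (per_disease) {
    pm |>
      group_by(.data$doid) |>
      dplyr::group_split() |>
      purrr::map(score_block) |>
      bind_rows()
  } else {
    score_block(pm)
  }

  out <- arrange(out, dplyr::desc(.data$meanRankScore), .data$doid,
                 .data$gene_symbol)
  structure(out, class = c("ct_associations", class(out)),
            per_disease = per_disease)
}

#' Write a ranked association table
#'
#' Serializes a [score_associations()] result as TSV with drug lists joined
#' by semicolons and scores printed with five decimal places.
#'
#' @param associations `ct_associations` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(associations, path) {
  out <- as_tibble(associations)
  if ("drugs" %in% names(out) && is.list(out$drugs)) {
    out$drugs <- purrr::map_chr(out$drugs,
                                function(d) paste(d, collapse = ";"))
  }
  for (col in c("nStudyNewness", "nPublicationWeighted", "meanRank",
                "percentileMeanRank", "meanRankScore")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.5f", out[[col]])
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Scatter export of score versus publication count
#'
#' Produces the minimal table behind the dashboard scatterplot: one point per
#' association with `meanRankScore` (x), `nPub` (y) and the target
#' development level used for colouring.
#'
#' @param associations `ct_associations` tibble.
#' @return Tibble with `doid`, `gene_symbol`, `meanRankScore`, `nPub`, `tdl`.
#' @export
scatter_export <- function(associations) {
  out <- as_tibble(associations)
  out <- ensure_cols(out, "tdl")
  select(out, "doid", "gene_symbol", "meanRankScore", "nPub", "tdl")
}
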