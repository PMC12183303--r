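#' Recency-decay configuration
#'
#' The study-newness score weights each trial by an exponential decay of its
#' age, `w = 2 * exp(-t / h)`, with a piecewise half-life parameter: `h =
#' h_recent` (default 5 years) for studies at most `age_threshold` (default
#' 10) years old, and `h = h_old` (default 10 years) for older studies so
#' that decades-old evidence is not discounted to nothing. Note the piecewise
#' rule is applied literally and is therefore discontinuous at the threshold:
#' a study just past 10 years old receives a larger weight (2e^-1) than one
#' at exactly 10 years (2e^-2). See the package vignette for discussion.
#'
#' @param h_recent Half-life in years for studies at most `age_threshold`
#'   years old. Default 5.
#' @param h_old Half-life in years for older studies. Default 10.
#' @param age_threshold Age in years at which the half-life switches.
#'   Default 10.
#' @param as_of Snapshot date (`Date`, `"YYYY-MM-DD"`, or `"auto"`) forwarded
#'   to [build_evidence()] by pipeline drivers; the scoring functions
#'   themselves consume precomputed ages.
#' @return A list of class `decay_config`.
#' @examples
#' decay_config()
#' decay_weight(c(0, 5, 20), decay_config())
#' @export
decay_config <- function(h_recent = 5, h_old = 10, age_threshold = 10,
                         as_of = "auto") {
  if (h_recent <= 0 || h_old <= 0 || age_threshold <= 0) {
    abort("decay half-lives and age threshold must all be positive")
  }
  structure(
    list(h_recent = h_recent, h_old = h_old,
         age_threshold = age_threshold, as_of = as_of),
    class = "decay_config"
  )
}

#' Reference-type publication weights
#'
#' Publications linked to a trial are weighted by how directly they bear on
#' the association: direct findings (RESULT) get weight 1.0, contextual
#' citations (BACKGROUND) 0.5, and secondary analyses (DERIVED) 0.25.
#'
#' @param result Weight for RESULT-type references. Default 1.0.
#' @param background Weight for BACKGROUND-type references. Default 0.5.
#' @param derived Weight for DERIVED-type references. Default 0.25.
#' @return A list of class `reference_weights`.
#' @export
reference_weights <- function(result = 1.0, background = 0.5,
                              derived = 0.25) {
  w <- c(result = result, background = background, derived = derived)
  if (any(w <= 0) || any(w > 1)) {
    abort("reference weights must lie in (0, 1]")
  }
  if (!(result >= background && background >= derived)) {
    abort("weights must satisfy result >= background >= derived")
  }
  structure(as.list(w), class = "reference_weights")
}

#' Exponential recency decay weight
#'
#' `w(t) = 2 * exp(-t / h)` with `h` chosen by the piecewise rule in
#' [decay_config()]. Weights lie in `(0, 2]`: a brand-new study contributes
#' 2, a 5-year-old study about 0.736.
#'
#' @param t Non-negative study age(s) in years.
#' @param config A [decay_config()].
#' @return Numeric vector of weights, same length as `t`.
#' @export
decay_weight <- function(t, config = decay_config()) {
  if (any(is.na(t))) abort("decay_weight: ages must not be NA")
  if (any(t < 0)) abort("decay_weight: ages must be non-negative")
  h <- ifelse(t <= config$age_threshold, config$h_recent, config$h_old)
  2 * exp(-t / h)
}

#' Recency-weighted study-newness score for one association
#'
#' Sums the decay weights of the unique studies supporting a disease-gene
#' pair. When `nct_id` is supplied, duplicate trial rows (as produced by
#' provenance-complete evidence tables) are collapsed first so replication
#' cannot inflate the score.
#'
#' @param ages Study ages in years. `NA` ages (studies with no usable date)
#'   are dropped with a warning.
#' @param config A [decay_config()].
#' @param nct_id Optional trial identifiers parallel to `ages`, used to
#'   deduplicate.
#' @return A single non-negative number; 0 for an empty set.
#' @export
n_study_newness <- function(ages, config = decay_config(), nct_id = NULL) {
  if (!is.null(nct_id)) {
    keep <- !duplicated(nct_id)
    ages <- ages[keep]
  }
  if (anyNA(ages)) {
    warn(sprintf(
      "%d study(ies) without a usable date excluded from study-newness",
      sum(is.na(ages))
    ))
    ages <- ages[!is.na(ages)]
  }
  if (length(ages) == 0) return(0)
  sum(decay_weight(ages, config))
}

#' Weight of a single study-publication reference
#'
#' Maps a reference type to its weight. Unknown types are treated as DERIVED
#' (the lowest weight) with a warning rather than erroring, since registry
#' reference annotations are noisy; the choice is conservative.
#'
#' @param reference_type Character vector of reference types
#'   (case-insensitive).
#' @param weights A [reference_weights()].
#' @return Numeric vector of weights.
#' @export
reference_weight <- function(reference_type,
                             weights = reference_weights()) {
  type <- toupper(stringr::str_squish(as.character(reference_type)))
  out <- dplyr::case_match(
    type,
    "RESULT" ~ weights$result,
    "BACKGROUND" ~ weights$background,
    "DERIVED" ~ weights$derived,
    .default = NA_real_
  )
  unknown <- is.na(out)
  if (any(unknown)) {
    warn(sprintf(
      "%d unknown reference type(s) treated as DERIVED", sum(unknown)
    ))
    out[unknown] <- weights$derived
  }
  out
}

#' Reference-type-weighted publication score for one association
#'
#' Publications are deduplicated by PMID, keeping the maximum weight across
#' the reference types under which a publication appears, and the
#' per-publication weights are summed. References without a PMID are kept in
#' provenance tables but contribute nothing here.
#'
#' @param pmid Publication identifiers.
#' @param reference_type Reference types parallel to `pmid`.
#' @param weights A [reference_weights()].
#' @return A single non-negative number; 0 for an empty set.
#' @examples
#' n_publication_weighted(c("p1", "p2", "p3"),
#'                        c("RESULT", "BACKGROUND", "DERIVED"))
#' @export
n_publication_weighted <- function(pmid, reference_type,
                                   weights = reference_weights()) {
  keep <- !is.na(pmid)
  pmid <- pmid[keep]
  reference_type <- reference_type[keep]
  if (length(pmid) == 0) return(0)
  w <- reference_weight(reference_type, weights)
  sum(tapply(w, pmid, max))
}

#' Compute the six evidence metrics for every disease-gene pair
#'
#' Aggregates an evidence table into one row per (doid, gene_symbol) pair
#' with the six metrics used for ranking:
#' \describe{
#'   \item{nDiseases}{distinct diseases linked to the gene across the whole
#'     evidence set (constant across a gene's pairs)}
#'   \item{nDrug}{distinct normalized drug names supporting the pair}
#'   \item{nStud}{distinct trials supporting the pair}
#'   \item{nPub}{distinct PMIDs supporting the pair}
#'   \item{nStudyNewness}{recency-weighted sum of per-trial decay weights,
#'     see [n_study_newness()]}
#'   \item{nPublicationWeighted}{reference-type-weighted, PMID-deduplicated
#'     publication score, see [n_publication_weighted()]}
#' }
#' Pairs with no linked publications are still emitted (with zero publication
#' metrics). Studies without a usable date count toward `nStud` but are
#' excluded from `nStudyNewness` with a single summary warning.
#'
#' @param evidence Evidence tibble from [build_evidence()].
#' @param decay A [decay_config()].
#' @param weights A [reference_weights()].
#' @return A tibble of class `ct_pair_metrics`: one row per pair with the six
#'   metrics plus `disease_name`, `uniprot`, `tdl` and a semicolon-friendly
#'   `drugs` list-column of the pair's distinct drug names.
#' @export
compute_pair_metrics <- function(evidence, decay = decay_config(),
                                 weights = reference_weights()) {
  ev <- as_tibble(evidence)
  if (nrow(ev) == 0) {
    abort("evidence table is empty; nothing to score")
  }
  ev <- ensure_cols(ev, c("disease_name", "uniprot", "tdl"))

  n_no_date <- ev |>
    distinct(.data$nct_id, .data$study_age_years) |>
    filter(is.na(.data$study_age_years)) |>
    nrow()
  if (n_no_date > 0) {
    warn(sprintf(
      "%d study(ies) without a usable date excluded from study-newness",
      n_no_date
    ))
  }

  gene_dis <- ev |>
    distinct(.data$gene_symbol, .data$doid) |>
    count(.data$gene_symbol, name = "nDiseases")

  pairs <- ev |>
    group_by(.data$doid, .data$gene_symbol) |>
    summarise(
      disease_name = first(.data$disease_name[!is.na(.data$disease_name)],
                           default = NA_character_),
      uniprot = first(.data$uniprot[!is.na(.data$uniprot)],
                      default = NA_character_),
      tdl = first(.data$tdl[!is.na(.data$tdl)], default = NA_character_),
      nDrug = n_distinct(.data$drug_name),
      nStud = n_distinct(.data$nct_id),
      nPub = n_distinct_na(.data$pmid),
      nStudyNewness = pair_newness(.data$nct_id, .data$study_age_years,
                                   decay),
      nPublicationWeighted = pair_pub_weight(.data$pmid,
                                             .data$reference_type, weights),
      drugs = list(sort(unique(.data$drug_name))),
      .groups = "drop"
    ) |>
    left_join(gene_dis, by = "gene_symbol") |>
    relocate("doid", "disease_name", "gene_symbol", "uniprot", "tdl",
             "nDiseases", "nDrug", "nStud", "nPub", "nStudyNewness",
             "nPublicationWeighted", "drugs") |>
    arrange(.data$doid, .data$gene_symbol)

  structure(pairs, class = c("ct_pair_metrics", class(pairs)))
}

# dedupe by trial, drop undated, sum decay weights (no per-group warning:
# compute_pair_metrics warns once over the whole evidence set)
pair_newness <- function(nct_id, ages, decay) {
  keep <- !duplicated(nct_id)
  ages <- ages[keep]
  ages <- ages[!is.na(ages)]
  if (length(ages) == 0) return(0)
  sum(decay_weight(ages, decay))
}

pair_pub_weight <- function(pmid, reference_type, weights) {
  keep <- !is.na(pmid) & !is.na(reference_type)
  # references with a pmid but unknown/missing type: treat type as DERIVED
  untyped <- !is.na(pmid) & is.na(reference_type)
  df <- unique(data.frame(
    pmid = c(pmid[keep], pmid[untyped]),
    w = c(
      if (any(keep)) reference_weight(reference_type[keep], weights)
      else numeric(),
      rep(weights$derived, sum(untyped))
    )
  ))
  if (nrow(df) == 0) return(0)
  sum(tapply(df$w, df$pmid, max))
}
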