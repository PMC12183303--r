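#' Run the full association pipeline on loaded tables
#'
#' Convenience driver: [build_evidence()], [compute_pair_metrics()] and
#' [score_associations()] in sequence with one set of configuration objects.
#'
#' @inheritParams build_evidence
#' @param decay A [decay_config()]; its `as_of` field supplies the snapshot
#'   date for study ages.
#' @param weights A [reference_weights()].
#' @param per_disease Rank within each disease instead of globally.
#' @return List with `evidence` (`ct_evidence`), `pair_metrics`
#'   (`ct_pair_metrics`) and `associations` (`ct_associations`).
#' @examples
#' tabs <- synth_generate(synth_config(seed = 7, n_studies = 50))
#' res <- run_pipeline(tabs$studies, tabs$references, tabs$drug_targets,
#'                     tabs$diseases)
#' head(res$associations)
#' @export
run_pipeline <- function(studies, references, drug_links, disease_links,
                         decay = decay_config(),
                         weights = reference_weights(),
                         per_disease = FALSE) {
  evidence <- build_evidence(studies, references, drug_links, disease_links,
                             as_of = decay$as_of)
  pair_metrics <- compute_pair_metrics(evidence, decay = decay,
                                       weights = weights)
  associations <- score_associations(pair_metrics,
                                     per_disease = per_disease)
  list(evidence = evidence, pair_metrics = pair_metrics,
       associations = associations)
}
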