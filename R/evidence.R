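#' Build per-association evidence rows from the four input tables
#'
#' Joins studies, drug-target annotations, study-disease annotations and
#' study-publication references into one evidence row per
#' (doid, gene_symbol, nct_id, drug_name) combination, replicated once per
#' linked reference so that provenance is row-complete. Downstream metrics
#' always deduplicate by trial and publication identifier, so the replication
#' cannot inflate counts.
#'
#' Only interventional drug studies contribute by default; observational
#' studies and non-drug interventions are excluded. Annotation rows whose
#' `nct_id` does not appear in the studies table are skipped and tallied in
#' the skip report (attached as the `skip_report` attribute).
#'
#' Each row carries the study age in years at `as_of`, measured from the
#' completion date when present, else the start date, floored at zero.
#' Studies with no usable date get `NA` age: they still count toward study
#' counts but are excluded from the recency-weighted score.
#'
#' @param studies Studies tibble (see [read_ct_table()]).
#' @param references References tibble, or `NULL` if no publication links are
#'   available.
#' @param drug_links Drug-target annotation tibble.
#' @param disease_links Study-disease annotation tibble.
#' @param as_of Snapshot date used to compute study ages: a `Date`, a
#'   `"YYYY-MM-DD"` string, or `"auto"` (the default) to use the most recent
#'   reference date across the loaded studies, which keeps runs reproducible
#'   without a wall-clock dependence.
#' @param interventional_only Keep only `study_type == "INTERVENTIONAL"`
#'   (default `TRUE`).
#' @param drug_only Keep only `intervention_type == "DRUG"` (default `TRUE`).
#' @return A tibble of class `ct_evidence` with columns `doid`,
#'   `disease_name`, `gene_symbol`, `uniprot`, `tdl`, `nct_id`, `drug_name`
#'   (normalized), `pmid`, `reference_type`, `study_age_years`, sorted
#'   deterministically. Attributes: `skip_report` (tibble of skipped
#'   `nct_id`s with row counts and source table), `as_of` (resolved date),
#'   `n_studies_no_date`.
#' @examples
#' studies <- tibble::tibble(
#'   nct_id = "NCT00000001", study_type = "INTERVENTIONAL",
#'   intervention_type = "DRUG",
#'   start_date = as.Date("2019-01-01"),
#'   completion_date = as.Date("2020-01-01")
#' )
#' drugs <- tibble::tibble(
#'   nct_id = "NCT00000001", drug_name = "Metformin", smiles = NA,
#'   inchikey = NA, uniprot = "P00001", gene_symbol = "PRKAB1", tdl = "Tclin"
#' )
#' dis <- tibble::tibble(
#'   nct_id = "NCT00000001", doid = "DOID:9352",
#'   disease_name = "type 2 diabetes"
#' )
#' build_evidence(studies, NULL, drugs, dis, as_of = "2024-09-30")
#' @export
build_evidence <- function(studies, references, drug_links, disease_links,
                           as_of = "auto",
                           interventional_only = TRUE,
                           drug_only = TRUE) {
  studies <- ensure_cols(as_tibble(studies),
                         c("intervention_type"))
  for (col in c("start_date", "completion_date")) {
    if (!col %in% names(studies)) studies[[col]] <- as.Date(NA)
  }
  drug_links <- ensure_cols(as_tibble(drug_links), c("uniprot", "tdl"))
  disease_links <- ensure_cols(as_tibble(disease_links), c("disease_name"))
  if (anyDuplicated(studies$nct_id[!is.na(studies$nct_id)]) > 0) {
    abort("studies table has duplicated nct_id values")
  }

  ref_date <- dplyr::coalesce(studies$completion_date, studies$start_date)
  as_of <- resolve_as_of(as_of, ref_date)

  known <- studies$nct_id
  skip_report <- bind_rows(
    count_skipped(drug_links, known, "drug_targets"),
    count_skipped(disease_links, known, "diseases")
  )

  kept <- studies
  if (interventional_only) {
    kept <- filter(kept, !is.na(.data$study_type),
                   .data$study_type == "INTERVENTIONAL")
  }
  if (drug_only) {
    kept <- filter(kept, !is.na(.data$intervention_type),
                   .data$intervention_type == "DRUG")
  }
  kept$study_age_years <- study_age(kept, as_of = as_of)

  dl <- drug_links |>
    filter(.data$nct_id %in% known) |>
    mutate(
      drug_name = normalize_drug_name(.data$drug_name),
      gene_symbol = normalize_gene_symbol(.data$gene_symbol)
    ) |>
    filter(!is.na(.data$drug_name), !is.na(.data$gene_symbol)) |>
    distinct(.data$nct_id, .data$drug_name, .data$gene_symbol,
             .keep_all = TRUE) |>
    select("nct_id", "drug_name", "gene_symbol", "uniprot", "tdl")

  sl <- disease_links |>
    filter(.data$nct_id %in% known, !is.na(.data$doid)) |>
    distinct(.data$nct_id, .data$doid, .keep_all = TRUE) |>
    select("nct_id", "doid", "disease_name")

  core <- kept |>
    select("nct_id", "study_age_years") |>
    inner_join(dl, by = "nct_id") |>
    inner_join(sl, by = "nct_id", relationship = "many-to-many")

  if (!is.null(references) && nrow(as_tibble(references)) > 0) {
    refs <- as_tibble(references) |>
      filter(.data$nct_id %in% core$nct_id) |>
      distinct(.data$nct_id, .data$pmid, .data$reference_type)
    core <- left_join(core, refs, by = "nct_id",
                      relationship = "many-to-many")
  } else {
    core$pmid <- NA_character_
    core$reference_type <- NA_character_
  }

  out <- core |>
    select("doid", "disease_name", "gene_symbol", "uniprot", "tdl",
           "nct_id", "drug_name", "pmid", "reference_type",
           "study_age_years") |>
    distinct() |>
    arrange(.data$doid, .data$gene_symbol, .data$nct_id, .data$drug_name,
            .data$pmid, .data$reference_type)

  structure(
    out,
    class = c("ct_evidence", class(out)),
    skip_report = skip_report,
    as_of = as_of,
    n_studies_no_date = sum(is.na(ref_date))
  )
}

count_skipped <- function(links, known_ids, source) {
  skipped <- links[!(links$nct_id %in% known_ids), , drop = FALSE]
  if (nrow(skipped) == 0) {
    return(tibble(nct_id = character(), n_rows = integer(),
                  source = character()))
  }
  skipped |>
    count(.data$nct_id, name = "n_rows") |>
    mutate(source = source)
}

resolve_as_of <- function(as_of, reference_dates = NULL) {
  if (inherits(as_of, "Date")) return(as_of)
  if (identical(as_of, "auto")) {
    dates <- reference_dates[!is.na(reference_dates)]
    if (length(dates) == 0) {
      abort("as_of = \"auto\" requires at least one dated study")
    }
    return(max(dates))
  }
  d <- as.Date(as_of, format = "%Y-%m-%d")
  if (is.na(d)) abort(sprintf("cannot parse as_of date: %s", as_of))
  d
}

#' Study age in years at a snapshot date
#'
#' Age is the day count from the study's reference date (completion date when
#' present, else start date) to `as_of`, divided by 365.25, floored at zero.
#' A study with neither date has no usable age and returns `NA`; callers
#' exclude such studies from recency weighting.
#'
#' @param studies Studies tibble with `completion_date` and `start_date`
#'   columns (class `Date`).
#' @param as_of Snapshot `Date` (or `"YYYY-MM-DD"` string).
#' @return Numeric vector of non-negative ages in years, `NA` where no date
#'   is available.
#' @examples
#' s <- tibble::tibble(
#'   nct_id = "NCT00000001",
#'   start_date = as.Date("2010-06-01"),
#'   completion_date = as.Date("2012-06-01")
#' )
#' study_age(s, as_of = "2022-06-01")
#' @export
study_age <- function(studies, as_of) {
  as_of <- resolve_as_of(as_of)
  ref <- dplyr::coalesce(studies$completion_date, studies$start_date)
  age <- as.numeric(as_of - ref) / 365.25
  pmax(age, 0)
}

#' Extract provenance rows for one disease-gene association
#'
#' Filters the evidence table to a single (doid, gene_symbol) pair, returning
#' the supporting trials and publications with their reference types and
#' citations (when a references table is supplied to re-attach citation
#' text). This is the tabular equivalent of a per-association provenance
#' view.
#'
#' @param evidence Evidence tibble from [build_evidence()].
#' @param doid Disease Ontology identifier, e.g. `"DOID:9352"`.
#' @param gene_symbol Gene symbol (matched case-insensitively).
#' @param references Optional references tibble used to attach `citation`.
#' @return Tibble with columns `nct_id`, `reference_type`, `pmid`,
#'   `citation`, `drug_name`, one row per evidence row of the pair.
#' @export
association_provenance <- function(evidence, doid, gene_symbol,
                                   references = NULL) {
  gene_symbol <- normalize_gene_symbol(gene_symbol)
  out <- evidence |>
    as_tibble() |>
    filter(.data$doid == !!doid, .data$gene_symbol == !!gene_symbol) |>
    select("nct_id", "reference_type", "pmid", "drug_name") |>
    distinct()
  if (!is.null(references) && "citation" %in% names(references)) {
    cites <- references |>
      as_tibble() |>
      distinct(.data$nct_id, .data$pmid, .data$citation)
    out <- left_join(out, cites, by = c("nct_id", "pmid"))
  } else {
    out$citation <- NA_character_
  }
  relocate(out, "nct_id", "reference_type", "pmid", "citation", "drug_name")
}
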