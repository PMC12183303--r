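#' Table kinds understood by the readers
#'
#' The pipeline consumes five registry-shaped annotation tables plus an
#' external reference set:
#' \describe{
#'   \item{studies}{one row per trial: `nct_id`, `study_type`
#'     (INTERVENTIONAL/OBSERVATIONAL), `intervention_type`, `start_date`,
#'     `completion_date`}
#'   \item{references}{one row per trial-publication link: `nct_id`, `pmid`,
#'     `reference_type` (RESULT/BACKGROUND/DERIVED), `citation`}
#'   \item{drug_targets}{one row per trial-drug-target annotation: `nct_id`,
#'     `drug_name`, `smiles`, `inchikey`, `uniprot`, `gene_symbol`, `tdl`}
#'   \item{diseases}{one row per trial-disease annotation: `nct_id`, `doid`,
#'     `disease_name`}
#'   \item{crosswalk}{`doid`, `cui` pairs linking Disease Ontology IDs to
#'     UMLS concept identifiers}
#'   \item{external}{an external disease-gene association set keyed by CUI:
#'     `cui`, `condition_name`, `gene_symbol`}
#' }
#' @name table-kinds
#' @keywords internal
NULL

ct_table_columns <- list(
  studies = list(
    columns = c("nct_id", "study_type", "intervention_type", "start_date",
                "completion_date"),
    required = c("nct_id", "study_type")
  ),
  references = list(
    columns = c("nct_id", "pmid", "reference_type", "citation"),
    required = c("nct_id", "reference_type")
  ),
  drug_targets = list(
    columns = c("nct_id", "drug_name", "smiles", "inchikey", "uniprot",
                "gene_symbol", "tdl"),
    required = c("nct_id", "drug_name", "gene_symbol")
  ),
  diseases = list(
    columns = c("nct_id", "doid", "disease_name"),
    required = c("nct_id", "doid")
  ),
  crosswalk = list(columns = c("doid", "cui"),
                   required = c("doid", "cui")),
  external = list(
    columns = c("cui", "condition_name", "gene_symbol"),
    required = c("cui", "gene_symbol")
  )
)

ct_study_types <- c("INTERVENTIONAL", "OBSERVATIONAL")
ct_reference_types <- c("RESULT", "BACKGROUND", "DERIVED")
ct_tdl_levels <- c("Tclin", "Tchem", "Tbio", "Tdark")

#' Read a registry-style evidence table
#'
#' Reads one of the tab-separated (or pipe-delimited, as exported by the
#' aggregate registry database) evidence tables into a typed tibble. Enum
#' columns (`study_type`, `reference_type`) are normalized case-insensitively;
#' malformed dates and unrecognized enum values are set to `NA` with a warning
#' naming the offending rows. A missing required column is a hard error;
#' missing optional columns are added as `NA`.
#'
#' @param path Path to the delimited file. A header row is required.
#' @param table_kind One of `"studies"`, `"references"`, `"drug_targets"`,
#'   `"diseases"`, `"crosswalk"`, `"external"`.
#' @param dialect `"tsv"` (tab-separated, the default) or `"aact_pipe"`
#'   (pipe-delimited registry export).
#' @return A tibble with the columns of the requested kind, one row per input
#'   record. An empty (header-only) file yields an empty tibble with a warning.
#' @seealso [write_ct_table()], [build_evidence()]
#' @export
read_ct_table <- function(path,
                          table_kind = c("studies", "references",
                                         "drug_targets", "diseases",
                                         "crosswalk", "external"),
                          dialect = c("tsv", "aact_pipe")) {
  table_kind <- match.arg(table_kind)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  delim <- if (dialect == "tsv") "\t" else "|"
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"),
    progress = FALSE,
    show_col_types = FALSE
  )
  spec <- ct_table_columns[[table_kind]]
  missing_req <- setdiff(spec$required, names(raw))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "table '%s' is missing required column(s): %s",
      table_kind, paste(missing_req, collapse = ", ")
    ))
  }
  for (col in setdiff(spec$columns, names(raw))) {
    raw[[col]] <- NA_character_
  }
  raw <- raw[, spec$columns]
  if (nrow(raw) == 0) {
    warn(sprintf("table '%s' read from %s is empty", table_kind, path))
  }
  typify_ct_table(raw, table_kind)
}

typify_ct_table <- function(tbl, table_kind) {
  tbl <- as_tibble(tbl)
  switch(table_kind,
    studies = {
      tbl$study_type <- normalize_enum(tbl$study_type, ct_study_types,
                                       "study_type")
      tbl$intervention_type <- toupper(stringr::str_squish(
        as.character(tbl$intervention_type)))
      tbl$start_date <- parse_ct_date(tbl$start_date, "start_date")
      tbl$completion_date <- parse_ct_date(tbl$completion_date,
                                           "completion_date")
      tbl
    },
    references = {
      tbl$reference_type <- normalize_enum(tbl$reference_type,
                                           ct_reference_types,
                                           "reference_type")
      tbl
    },
    drug_targets = {
      tbl$gene_symbol <- normalize_gene_symbol(tbl$gene_symbol)
      bad_tdl <- !is.na(tbl$tdl) & !(tbl$tdl %in% ct_tdl_levels)
      if (any(bad_tdl)) {
        warn(sprintf("%d unrecognized tdl value(s) set to NA", sum(bad_tdl)))
        tbl$tdl[bad_tdl] <- NA_character_
      }
      tbl
    },
    diseases = {
      bad <- !is.na(tbl$doid) & !stringr::str_detect(tbl$doid, "^DOID:\\d+$")
      if (any(bad)) {
        warn(sprintf(
          "%d doid value(s) do not match 'DOID:<int>' (rows: %s)",
          sum(bad), paste(utils::head(which(bad), 10), collapse = ", ")
        ))
      }
      tbl
    },
    crosswalk = tbl,
    external = {
      tbl$gene_symbol <- normalize_gene_symbol(tbl$gene_symbol)
      tbl
    }
  )
}

#' Write a registry-style evidence table
#'
#' Inverse of [read_ct_table()]: writes a tibble in either dialect so that
#' reading it back reproduces the records. Dates are serialized as
#' `YYYY-MM-DD`.
#'
#' @param tbl Tibble to write.
#' @param path Output path.
#' @inheritParams read_ct_table
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(tbl, path, dialect = c("tsv", "aact_pipe")) {
  dialect <- match.arg(dialect)
  out <- tbl
  num <- vapply(out, function(x) is.double(x) && !inherits(x, "Date"),
                logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = 15, trim = TRUE))
  })
  if (dialect == "tsv") {
    readr::write_tsv(out, path, na = "")
  } else {
    readr::write_delim(out, path, delim = "|", na = "")
  }
  invisible(path)
}
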