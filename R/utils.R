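#' Normalize a drug name for distinct counting
#'
#' Registry intervention names are noisy: the same compound appears with
#' different capitalization and stray whitespace. Lowercasing and collapsing
#' runs of whitespace removes the dominant source of spurious distinct drug
#' counts without attempting chemical synonym resolution (which is out of
#' scope here and belongs to structure-based mapping).
#'
#' @param x Character vector of drug names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_drug_name(c("Metformin ", "METFORMIN", "met  formin"))
#' @export
normalize_drug_name <- function(x) {
  x <- stringr::str_squish(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  x
}

#' Normalize a gene symbol
#'
#' Uppercases and trims an HGNC-style symbol. Symbols are passed through
#' otherwise verbatim; no correction of malformed symbols is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of uppercased symbols.
#' @export
normalize_gene_symbol <- function(x) {
  x <- toupper(stringr::str_squish(as.character(x)))
  x[x == ""] <- NA_character_
  x
}

# parse "YYYY-MM-DD" strings; malformed entries -> NA, with row numbers
# reported so the caller can warn once per column
parse_ct_date <- function(x, column = "date") {
  x_chr <- as.character(x)
  x_chr[!is.na(x_chr) & stringr::str_squish(x_chr) == ""] <- NA_character_
  d <- as.Date(x_chr, format = "%Y-%m-%d")
  bad <- which(!is.na(x_chr) & is.na(d))
  if (length(bad) > 0) {
    warn(sprintf(
      "%d malformed %s value(s) set to NA (rows: %s)",
      length(bad), column,
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  d
}

# normalize an enum column case-insensitively against allowed levels;
# unmatched non-missing values become NA with a row-numbered warning
normalize_enum <- function(x, levels, column, warn_unknown = TRUE) {
  up <- toupper(stringr::str_squish(as.character(x)))
  up[up == ""] <- NA_character_
  out <- ifelse(up %in% levels, up, NA_character_)
  bad <- which(!is.na(up) & is.na(out))
  if (warn_unknown && length(bad) > 0) {
    warn(sprintf(
      "%d unrecognized %s value(s) set to NA (rows: %s)",
      length(bad), column,
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  out
}

n_distinct_na <- function(x) dplyr::n_distinct(x[!is.na(x)])

# add missing optional columns as NA character so joins and selects are total
ensure_cols <- function(tbl, cols) {
  for (col in setdiff(cols, names(tbl))) tbl[[col]] <- NA_character_
  tbl
}
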