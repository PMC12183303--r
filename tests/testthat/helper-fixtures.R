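# Small in-code fixtures and independent brute-force oracles.

mini_studies <- function() {
  tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000002", "NCT00000003"),
    study_type = c("INTERVENTIONAL", "INTERVENTIONAL", "OBSERVATIONAL"),
    intervention_type = c("DRUG", "DRUG", "OTHER"),
    start_date = as.Date(c("2018-01-01", "2005-03-15", "2010-06-01")),
    completion_date = as.Date(c("2020-01-01", "2007-03-15", NA))
  )
}

mini_references <- function() {
  tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000001", "NCT00000002"),
    pmid = c("30000001", "30000002", "30000003"),
    reference_type = c("RESULT", "BACKGROUND", "DERIVED"),
    citation = paste("Citation", 1:3)
  )
}

mini_drug_targets <- function() {
  tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000002", "NCT00000002"),
    drug_name = c("Metformin", "metformin", "Aspirin"),
    smiles = NA_character_,
    inchikey = NA_character_,
    uniprot = c("P00001", "P00001", "P00002"),
    gene_symbol = c("PRKAB1", "PRKAB1", "PTGS2"),
    tdl = c("Tclin", "Tclin", "Tchem")
  )
}

mini_diseases <- function() {
  tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000002"),
    doid = c("DOID:9352", "DOID:9352"),
    disease_name = "type 2 diabetes"
  )
}

# random evidence-like tibble for property tests
random_evidence <- function(n_rows, n_pairs = 8, seed = 1) {
  withr::with_seed(seed, {
    pairs <- tibble::tibble(
      doid = sprintf("DOID:%d", 100 + sample.int(4, n_pairs, replace = TRUE)),
      gene_symbol = sprintf("G%02d", seq_len(n_pairs))
    )
    idx <- sample.int(n_pairs, n_rows, replace = TRUE)
    tibble::tibble(
      doid = pairs$doid[idx],
      gene_symbol = pairs$gene_symbol[idx],
      nct_id = sprintf("NCT%08d", sample.int(12, n_rows, replace = TRUE)),
      drug_name = sprintf("drug%d", sample.int(6, n_rows, replace = TRUE)),
      pmid = ifelse(runif(n_rows) < 0.2, NA_character_,
                    sprintf("%d", 40000000 + sample.int(15, n_rows,
                                                        replace = TRUE))),
      reference_type = sample(c("RESULT", "BACKGROUND", "DERIVED"),
                              n_rows, replace = TRUE),
      study_age_years = round(runif(n_rows, 0, 25), 3)
    ) |>
      # one age per trial, as build_evidence guarantees
      dplyr::group_by(nct_id) |>
      dplyr::mutate(study_age_years = study_age_years[1]) |>
      dplyr::ungroup()
  })
}

# --- independent oracles -------------------------------------------------

# descending average-tie rank by enumeration: count strictly greater values,
# then spread tied positions over their mean
oracle_rank_desc <- function(v) {
  vapply(seq_along(v), function(i) {
    greater <- sum(v > v[i])
    ties <- sum(v == v[i])
    greater + (ties + 1) / 2
  }, numeric(1))
}

oracle_rank_asc <- function(v) oracle_rank_desc(-v)

# full scoring oracle: O(N^2 * K) re-ranking from the metric columns
oracle_score <- function(pm) {
  metrics <- c("nDiseases", "nDrug", "nStud", "nPub",
               "nStudyNewness", "nPublicationWeighted")
  ranks <- sapply(metrics, function(m) oracle_rank_desc(pm[[m]]))
  mean_rank <- rowMeans(ranks)
  pct <- oracle_rank_asc(mean_rank) / nrow(pm) * 100
  tibble::tibble(
    doid = pm$doid, gene_symbol = pm$gene_symbol,
    meanRank = mean_rank, meanRankScore = 100 - pct
  )
}

# brute-force per-pair metric recount over plain loops
oracle_pair_metrics <- function(ev, h_recent = 5, h_old = 10,
                                threshold = 10,
                                w = c(RESULT = 1, BACKGROUND = 0.5,
                                      DERIVED = 0.25)) {
  keys <- unique(ev[, c("doid", "gene_symbol")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- ev[ev$doid == keys$doid[i] &
                 ev$gene_symbol == keys$gene_symbol[i], ]
    studies <- unique(rows[, c("nct_id", "study_age_years")])
    ages <- studies$study_age_years[!is.na(studies$study_age_years)]
    newness <- 0
    for (t in ages) {
      h <- if (t <= threshold) h_recent else h_old
      newness <- newness + 2 * exp(-t / h)
    }
    pubs <- unique(rows[!is.na(rows$pmid),
                        c("pmid", "reference_type")])
    pw <- 0
    for (p in unique(pubs$pmid)) {
      types <- pubs$reference_type[pubs$pmid == p]
      weights <- ifelse(is.na(types), w[["DERIVED"]], w[types])
      pw <- pw + max(weights)
    }
    out[[i]] <- tibble::tibble(
      doid = keys$doid[i], gene_symbol = keys$gene_symbol[i],
      nDiseases = length(unique(
        ev$doid[ev$gene_symbol == keys$gene_symbol[i]])),
      nDrug = length(unique(rows$drug_name)),
      nStud = length(unique(rows$nct_id)),
      nPub = length(unique(rows$pmid[!is.na(rows$pmid)])),
      nStudyNewness = newness,
      nPublicationWeighted = pw
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), doid, gene_symbol)
}

# nested-loop evidence join for fixtures: every combination of a kept study,
# its drug links and its disease links, replicated per reference
oracle_evidence_size <- function(studies, references, drug_links,
                                 disease_links) {
  n <- 0
  for (i in seq_len(nrow(studies))) {
    s <- studies[i, ]
    if (is.na(s$study_type) || s$study_type != "INTERVENTIONAL") next
    if (is.na(s$intervention_type) || s$intervention_type != "DRUG") next
    dl <- unique(tibble::tibble(
      drug = ctassoc::normalize_drug_name(
        drug_links$drug_name[drug_links$nct_id == s$nct_id]),
      gene = ctassoc::normalize_gene_symbol(
        drug_links$gene_symbol[drug_links$nct_id == s$nct_id])
    ))
    dis <- unique(disease_links$doid[disease_links$nct_id == s$nct_id])
    refs <- unique(references[references$nct_id == s$nct_id,
                              c("pmid", "reference_type")])
    n_refs <- max(1, nrow(refs))
    n <- n + nrow(dl) * length(dis) * n_refs
  }
  n
}
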