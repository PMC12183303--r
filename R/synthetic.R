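#' Configuration for the synthetic evidence-table generator
#'
#' Describes a registry-shaped corpus: interventional and observational
#' trials with start/completion dates spanning decades, drug-target and
#' study-disease annotations, and publication references of the three types.
#' The defaults define the standard test corpus used throughout the package:
#' 300 studies across 20 diseases, 60 genes and 80 drugs, 10% observational,
#' dates drawn uniformly over 1998-2024 so both half-life branches of the
#' recency decay are exercised, about 1.2 references per study with a
#' 35/45/20 RESULT/BACKGROUND/DERIVED mix.
#'
#' `planted_pairs` plants disease-gene signal: for each (disease index, gene
#' index, strength) row, the generator adds extra interventional drug studies
#' linking that disease to drugs targeting that gene. The number added is
#' `ceiling(strength * expected background studies per pair)`, computed from
#' the configuration, so a strength-10 pair has roughly ten times the
#' evidence of an average background pair.
#'
#' @param seed Integer master seed. Each output table draws from its own
#'   stream derived from this seed, so adding a table never perturbs the
#'   others; a fixed seed yields byte-identical output files.
#' @param n_studies Number of background studies.
#' @param n_genes,n_diseases,n_drugs Universe sizes.
#' @param frac_observational Proportion of background studies that are
#'   observational (filtered out by [build_evidence()]).
#' @param frac_nondrug Proportion of interventional studies with a non-drug
#'   intervention.
#' @param date_range Length-2 integer vector `(min_year, max_year)` for
#'   uniform study start dates.
#' @param refs_per_study Poisson mean of references per study.
#' @param type_mix Named probabilities over RESULT, BACKGROUND, DERIVED;
#'   must sum to 1.
#' @param planted_pairs `NULL`, or a data frame with columns `disease`
#'   (index in `1:n_diseases`), `gene` (index in `1:n_genes`) and `strength`
#'   (multiplier relative to the expected background evidence per pair).
#' @param external_planted_frac Fraction of planted pairs copied into the
#'   external association table (via the crosswalk), for overlap testing.
#' @param n_external_background Random background rows in the external
#'   association table.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_studies = 300,
                         n_genes = 60,
                         n_diseases = 20,
                         n_drugs = 80,
                         frac_observational = 0.10,
                         frac_nondrug = 0.10,
                         date_range = c(1998, 2024),
                         refs_per_study = 1.2,
                         type_mix = c(RESULT = 0.35, BACKGROUND = 0.45,
                                      DERIVED = 0.20),
                         planted_pairs = NULL,
                         external_planted_frac = 1.0,
                         n_external_background = 50) {
  if (abs(sum(type_mix) - 1) > 1e-8 || any(type_mix < 0)) {
    abort("type_mix must be non-negative probabilities summing to 1")
  }
  if (!setequal(names(type_mix), c("RESULT", "BACKGROUND", "DERIVED"))) {
    abort("type_mix must be named RESULT, BACKGROUND, DERIVED")
  }
  if (frac_observational < 0 || frac_observational > 1) {
    abort("frac_observational must be in [0, 1]")
  }
  if (length(date_range) != 2 || date_range[1] > date_range[2]) {
    abort("date_range must be (min_year, max_year)")
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    stopifnot(all(c("disease", "gene", "strength") %in%
                    names(planted_pairs)))
    if (any(planted_pairs$disease < 1 |
              planted_pairs$disease > n_diseases) ||
        any(planted_pairs$gene < 1 | planted_pairs$gene > n_genes)) {
      abort("planted pair indices out of range")
    }
  }
  structure(
    list(seed = as.integer(seed), n_studies = n_studies, n_genes = n_genes,
         n_diseases = n_diseases, n_drugs = n_drugs,
         frac_observational = frac_observational,
         frac_nondrug = frac_nondrug, date_range = date_range,
         refs_per_study = refs_per_study, type_mix = type_mix,
         planted_pairs = planted_pairs,
         external_planted_frac = external_planted_frac,
         n_external_background = n_external_background),
    class = "synth_config"
  )
}

# run expr under a dedicated RNG stream, restoring caller RNG state after
with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed)
  force(expr)
}

#' Generate synthetic registry-shaped evidence tables
#'
#' Produces the full file set the pipeline consumes — studies, references,
#' drug-target annotations, study-disease annotations, a DOID-to-CUI
#' crosswalk and an external disease-gene association table — plus a
#' ground-truth manifest of the planted pairs. Entirely deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return Named list of tibbles: `studies`, `references`, `drug_targets`,
#'   `diseases`, `crosswalk`, `external`, `manifest`. The manifest has one
#'   row per planted pair with its DOID, gene symbol, strength and the
#'   number of extra studies planted.
#' @seealso [synth_write()] to materialize the tables as files.
#' @export
synth_generate <- function(config = synth_config()) {
  stream_seeds <- with_stream(config$seed,
                              sample.int(.Machine$integer.max, 10))

  genes <- tibble(
    gene_idx = seq_len(config$n_genes),
    gene_symbol = sprintf("SYNG%04d", seq_len(config$n_genes)),
    uniprot = sprintf("P9%04d", seq_len(config$n_genes)),
    tdl = with_stream(stream_seeds[1],
      sample(ct_tdl_levels, config$n_genes, replace = TRUE,
             prob = c(0.20, 0.30, 0.35, 0.15)))
  )
  diseases <- tibble(
    disease_idx = seq_len(config$n_diseases),
    doid = sprintf("DOID:%d", 1000 + seq_len(config$n_diseases)),
    disease_name = sprintf("synthetic condition %02d",
                           seq_len(config$n_diseases))
  )
  drugs <- tibble(
    drug_idx = seq_len(config$n_drugs),
    drug_name = sprintf("synthodrug%04d", seq_len(config$n_drugs)),
    smiles = sprintf("C1CC%dCC1", seq_len(config$n_drugs)),
    inchikey = NA_character_,
    gene_idx = with_stream(stream_seeds[2],
      sample.int(config$n_genes, config$n_drugs, replace = TRUE))
  )
  # a planted association of strength s must be ~s-fold stronger than a
  # typical background pair on every evidence dimension; the drug dimension
  # requires the gene to actually have ~s drugs targeting it, so drugs are
  # deterministically reassigned to planted genes as needed
  if (!is.null(config$planted_pairs)) {
    pp <- config$planted_pairs
    need <- tapply(pp$strength, pp$gene, max)
    planted_genes <- as.integer(names(need))
    for (k in seq_along(planted_genes)) {
      g <- planted_genes[k]
      want <- min(ceiling(need[k]), max(1L, config$n_drugs %/% 8L))
      have <- sum(drugs$gene_idx == g)
      if (have < want) {
        pool <- which(!(drugs$gene_idx %in% planted_genes))
        drugs$gene_idx[pool[seq_len(min(want - have, length(pool)))]] <- g
      }
    }
  }

  bg <- with_stream(stream_seeds[3],
                    synth_background_studies(config, drugs, diseases))
  planted <- with_stream(stream_seeds[4],
                         synth_planted_studies(config, drugs, diseases,
                                               n_bg_links = nrow(bg$links)))
  studies <- bind_rows(bg$studies, planted$studies)
  links <- bind_rows(bg$links, planted$links)

  drug_targets <- links |>
    inner_join(drugs, by = "drug_idx") |>
    inner_join(genes, by = "gene_idx") |>
    distinct(.data$nct_id, .data$drug_name, .data$smiles, .data$inchikey,
             .data$uniprot, .data$gene_symbol, .data$tdl)
  disease_tbl <- links |>
    inner_join(diseases, by = "disease_idx") |>
    distinct(.data$nct_id, .data$doid, .data$disease_name)

  references <- with_stream(stream_seeds[5],
                            synth_references(config, studies))

  crosswalk <- with_stream(stream_seeds[6], {
    second <- runif(config$n_diseases) < 0.3
    bind_rows(
      tibble(doid = diseases$doid,
             cui = sprintf("C%07d", 5000000 + diseases$disease_idx)),
      tibble(doid = diseases$doid[second],
             cui = sprintf("C%07d",
                           6000000 + diseases$disease_idx[second]))
    ) |> arrange(.data$doid, .data$cui)
  })

  manifest <- planted$manifest |>
    left_join(select(diseases, "disease_idx", "doid"),
              by = c(disease = "disease_idx")) |>
    left_join(select(genes, "gene_idx", "gene_symbol"),
              by = c(gene = "gene_idx")) |>
    select("doid", "gene_symbol", "strength", "n_extra_studies")

  external <- with_stream(stream_seeds[7],
    synth_external(config, diseases, genes, crosswalk, manifest))

  list(studies = studies, references = references,
       drug_targets = drug_targets, diseases = disease_tbl,
       crosswalk = crosswalk, external = external, manifest = manifest)
}

synth_background_studies <- function(config, drugs, diseases) {
  n <- config$n_studies
  if (n == 0) {
    return(list(studies = empty_studies(), links = empty_links()))
  }
  start <- random_dates(n, config$date_range)
  dur_days <- sample(180:1095, n, replace = TRUE)
  completion <- start + dur_days
  max_date <- as.Date(sprintf("%d-12-31", config$date_range[2]))
  completion <- pmin(completion, max_date)
  # a few studies lack completion or any date, exercising the no-date path
  completion[runif(n) < 0.05] <- as.Date(NA)
  no_date <- runif(n) < 0.02
  start[no_date] <- as.Date(NA)
  completion[no_date] <- as.Date(NA)

  obs <- runif(n) < config$frac_observational
  nondrug <- !obs & (runif(n) < config$frac_nondrug)
  studies <- tibble(
    nct_id = sprintf("NCT%08d", seq_len(n)),
    study_type = ifelse(obs, "OBSERVATIONAL", "INTERVENTIONAL"),
    intervention_type = dplyr::case_when(
      obs ~ "OTHER",
      nondrug ~ "BEHAVIORAL",
      .default = "DRUG"
    ),
    start_date = start,
    completion_date = completion
  )
  n_drug_links <- 1 + (runif(n) < 0.25)
  n_dis_links <- 1 + (runif(n) < 0.25)
  links <- tibble(
    nct_id = rep(studies$nct_id, times = n_drug_links * n_dis_links),
    drug_idx = unlist(lapply(seq_len(n), function(i) {
      rep(sample.int(config$n_drugs, n_drug_links[i]),
          times = n_dis_links[i])
    })),
    disease_idx = unlist(lapply(seq_len(n), function(i) {
      rep(sample.int(config$n_diseases, n_dis_links[i]),
          each = n_drug_links[i])
    }))
  )
  list(studies = studies, links = links)
}

synth_planted_studies <- function(config, drugs, diseases, n_bg_links) {
  pp <- config$planted_pairs
  if (is.null(pp) || nrow(pp) == 0) {
    manifest <- tibble(disease = integer(), gene = integer(),
                       strength = numeric(), n_extra_studies = integer())
    return(list(studies = empty_studies(), links = empty_links(),
                manifest = manifest))
  }
  # the background evidence level per realized pair: effective (filtered)
  # link rows divided by the expected number of occupied pairs, from the
  # standard occupancy approximation
  eff_links <- n_bg_links *
    (1 - config$frac_observational) * (1 - config$frac_nondrug)
  n_cells <- config$n_diseases * config$n_genes
  exp_pairs <- n_cells * (1 - exp(-eff_links / n_cells))
  bg_per_pair <- if (exp_pairs > 0) eff_links / exp_pairs else 1

  studies_list <- list()
  links_list <- list()
  n_extra <- integer(nrow(pp))
  counter <- 0L
  for (k in seq_len(nrow(pp))) {
    gene_drugs <- drugs$drug_idx[drugs$gene_idx == pp$gene[k]]
    n_k <- max(1L, ceiling(pp$strength[k] * bg_per_pair))
    n_extra[k] <- n_k
    ids <- sprintf("NCT9%07d", counter + seq_len(n_k))
    counter <- counter + n_k
    start <- random_dates(n_k, config$date_range)
    studies_list[[k]] <- tibble(
      nct_id = ids,
      study_type = "INTERVENTIONAL",
      intervention_type = "DRUG",
      start_date = start,
      completion_date = pmin(start + sample(180:1095, n_k, replace = TRUE),
                             as.Date(sprintf("%d-12-31",
                                             config$date_range[2])))
    )
    # planted studies behave like background studies: they cycle through
    # the gene's drugs and occasionally mention a second disease
    second <- runif(n_k) < 0.25
    links_list[[k]] <- bind_rows(
      tibble(
        nct_id = ids,
        drug_idx = gene_drugs[((seq_len(n_k) - 1L) %% length(gene_drugs)) + 1L],
        disease_idx = pp$disease[k]
      ),
      tibble(
        nct_id = ids[second],
        drug_idx = gene_drugs[((which(second) - 1L) %% length(gene_drugs)) + 1L],
        disease_idx = sample.int(config$n_diseases, sum(second),
                                 replace = TRUE)
      )
    )
  }
  list(
    studies = bind_rows(studies_list),
    links = bind_rows(links_list),
    manifest = tibble(disease = pp$disease, gene = pp$gene,
                      strength = pp$strength, n_extra_studies = n_extra)
  )
}

synth_references <- function(config, studies) {
  n <- nrow(studies)
  if (n == 0) {
    return(tibble(nct_id = character(), pmid = character(),
                  reference_type = character(), citation = character()))
  }
  n_refs <- rpois(n, config$refs_per_study)
  total <- sum(n_refs)
  if (total == 0) {
    return(tibble(nct_id = character(), pmid = character(),
                  reference_type = character(), citation = character()))
  }
  type <- sample(names(config$type_mix), total, replace = TRUE,
                 prob = config$type_mix)
  pmid <- sprintf("%d", 30000000 + seq_len(total))
  pmid[runif(total) < 0.05] <- NA_character_
  tibble(
    nct_id = rep(studies$nct_id, times = n_refs),
    pmid = pmid,
    reference_type = type,
    citation = ifelse(
      is.na(pmid),
      "Synthetic citation without indexed identifier.",
      sprintf("Synthetic et al. Study report %s. J Synth Data.", pmid)
    )
  )
}

synth_external <- function(config, diseases, genes, crosswalk, manifest) {
  first_cui <- crosswalk |>
    group_by(.data$doid) |>
    summarise(cui = min(.data$cui), .groups = "drop")
  planted <- manifest |>
    inner_join(first_cui, by = "doid") |>
    inner_join(select(diseases, "doid", "disease_name"), by = "doid")
  if (nrow(planted) > 0) {
    keep <- seq_len(floor(config$external_planted_frac * nrow(planted)))
    planted <- planted[keep, , drop = FALSE]
  }
  n_bg <- config$n_external_background
  bg <- tibble(
    doid = diseases$doid[sample.int(config$n_diseases, n_bg,
                                    replace = TRUE)],
    gene_symbol = genes$gene_symbol[sample.int(config$n_genes, n_bg,
                                               replace = TRUE)]
  ) |>
    inner_join(first_cui, by = "doid") |>
    inner_join(select(diseases, "doid", "disease_name"), by = "doid")
  bind_rows(
    select(planted, "cui", condition_name = "disease_name",
           "gene_symbol"),
    select(bg, "cui", condition_name = "disease_name", "gene_symbol")
  ) |>
    distinct() |>
    arrange(.data$cui, .data$gene_symbol)
}

random_dates <- function(n, date_range) {
  lo <- as.Date(sprintf("%d-01-01", date_range[1]))
  hi <- as.Date(sprintf("%d-12-31", date_range[2]))
  lo + floor(runif(n) * (as.numeric(hi - lo) + 1))
}

empty_studies <- function() {
  tibble(nct_id = character(), study_type = character(),
         intervention_type = character(),
         start_date = as.Date(character()),
         completion_date = as.Date(character()))
}

empty_links <- function() {
  tibble(nct_id = character(), drug_idx = integer(),
         disease_idx = integer())
}

#' Write synthetic tables to a directory
#'
#' Materializes a [synth_generate()] result as the exact file layout the
#' pipeline consumes: `studies.tsv`, `study_references.tsv`,
#' `study_drug_targets.tsv`, `study_diseases.tsv`, `doid_cui.tsv`,
#' `external_associations.tsv` and `manifest.tsv`. With a fixed seed the
#' files are byte-identical across runs.
#'
#' @param tables List from [synth_generate()].
#' @param out_dir Output directory (created if needed).
#' @param dialect Output dialect, see [write_ct_table()].
#' @return Named character vector of written paths, invisibly.
#' @export
synth_write <- function(tables, out_dir, dialect = c("tsv", "aact_pipe")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(studies = "studies.tsv",
             references = "study_references.tsv",
             drug_targets = "study_drug_targets.tsv",
             diseases = "study_diseases.tsv",
             crosswalk = "doid_cui.tsv",
             external = "external_associations.tsv",
             manifest = "manifest.tsv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  for (nm in names(files)) {
    write_ct_table(tables[[nm]], paths[[nm]], dialect = dialect)
  }
  invisible(paths)
}
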