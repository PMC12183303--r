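test_that("study age is day count over 365.25, floored at zero", {
  s <- tibble::tibble(
    nct_id = "a",
    start_date = as.Date("2008-01-01"),
    completion_date = as.Date("2012-06-01")
  )
  expect_equal(study_age(s, as_of = "2012-06-01"), 0)
  # 3652 days after completion
  expect_equal(study_age(s, as_of = as.Date("2012-06-01") + 3652),
               3652 / 365.25)
  # future-dated study floors at zero
  expect_equal(study_age(s, as_of = "2010-01-01"), 0)
  # completion wins over start; start is the fallback
  s2 <- s
  s2$completion_date <- as.Date(NA)
  expect_equal(study_age(s2, as_of = "2008-01-11"), 10 / 365.25)
  # no usable date -> NA
  s2$start_date <- as.Date(NA)
  expect_true(is.na(study_age(s2, as_of = "2020-01-01")))
})

test_that("decay weight follows the piecewise exponential exactly", {
  cfg <- decay_config()
  expect_identical(decay_weight(0, cfg), 2)
  expect_equal(decay_weight(5, cfg), 2 * exp(-1))
  expect_equal(decay_weight(20, cfg), 2 * exp(-2))
  # the boundary is literal: t = 10 uses the recent half-life
  expect_equal(decay_weight(10, cfg), 2 * exp(-2))
  expect_equal(decay_weight(10 + 1e-9, cfg), 2 * exp(-(10 + 1e-9) / 10))
  expect_error(decay_weight(-1, cfg), "non-negative")
})

test_that("decay weight is strictly decreasing within each branch and bounded", {
  cfg <- decay_config()
  recent <- seq(0, 10, by = 0.25)
  old <- seq(10.01, 60, by = 0.25)
  expect_true(all(diff(decay_weight(recent, cfg)) < 0))
  expect_true(all(diff(decay_weight(old, cfg)) < 0))
  w <- decay_weight(c(recent, old), cfg)
  expect_true(all(w > 0 & w <= 2))
})

test_that("study newness sums decay weights over unique studies", {
  cfg <- decay_config()
  expect_equal(n_study_newness(numeric(0), cfg), 0)
  expect_equal(n_study_newness(c(0, 5), cfg), 2 + 2 * exp(-1))
  # duplicate trial rows are collapsed before summation
  expect_equal(
    n_study_newness(c(0, 0, 0), cfg, nct_id = c("NCT1", "NCT1", "NCT1")),
    2
  )
  # adding a study never decreases the score
  base <- n_study_newness(c(1, 2), cfg)
  expect_gt(n_study_newness(c(1, 2, 30), cfg), base)
})

test_that("reference weights map types to 1.0 / 0.5 / 0.25", {
  w <- reference_weights()
  expect_identical(reference_weight("RESULT", w), 1.0)
  expect_identical(reference_weight("BACKGROUND", w), 0.5)
  expect_identical(reference_weight("DERIVED", w), 0.25)
  expect_identical(reference_weight("Result", w), 1.0)
  expect_warning(wu <- reference_weight("EDITORIAL", w), "DERIVED")
  expect_identical(wu, 0.25)
  expect_error(reference_weights(result = 0.5, background = 0.9),
               "result >= background")
  expect_error(reference_weights(result = 1.5), "\\(0, 1\\]")
})

test_that("publication weighting dedupes by pmid at the maximum weight", {
  w <- reference_weights()
  expect_equal(
    n_publication_weighted(c("p1", "p2", "p3"),
                           c("RESULT", "BACKGROUND", "DERIVED"), w),
    1.75
  )
  expect_equal(
    n_publication_weighted(c("p1", "p1"), c("RESULT", "BACKGROUND"), w),
    1.0
  )
  expect_equal(n_publication_weighted(character(0), character(0), w), 0)
  # pmid-less references contribute nothing
  expect_equal(
    n_publication_weighted(c(NA, "p1"), c("RESULT", "DERIVED"), w),
    0.25
  )
})

test_that("pair metrics match a hand count on a small fixture", {
  ev <- tibble::tibble(
    doid = "DOID:1",
    gene_symbol = "G1",
    nct_id = c("NCT1", "NCT1", "NCT1", "NCT2"),
    drug_name = c("a", "a", "b", "a"),
    pmid = c("p1", "p2", "p3", "p3"),
    reference_type = c("RESULT", "BACKGROUND", "DERIVED", "RESULT"),
    study_age_years = c(0, 0, 0, 5)
  )
  pm <- compute_pair_metrics(ev)
  expect_equal(nrow(pm), 1)
  expect_equal(pm$nStud, 2L)
  expect_equal(pm$nPub, 3L)
  expect_equal(pm$nDrug, 2L)
  expect_equal(pm$nDiseases, 1L)
  expect_equal(pm$nStudyNewness, 2 + 2 * exp(-1))
  # p3 appears as DERIVED and RESULT: max weight wins
  expect_equal(pm$nPublicationWeighted, 1 + 0.5 + 1)
})

test_that("nDiseases counts a gene's diseases across the whole set", {
  ev <- tibble::tibble(
    doid = c("DOID:1", "DOID:2", "DOID:1"),
    gene_symbol = c("G1", "G1", "G2"),
    nct_id = c("NCT1", "NCT2", "NCT1"),
    drug_name = "a",
    pmid = NA_character_,
    reference_type = NA_character_,
    study_age_years = 1
  )
  pm <- compute_pair_metrics(ev)
  g1 <- pm[pm$gene_symbol == "G1", ]
  expect_equal(g1$nDiseases, c(2L, 2L))
  expect_equal(pm$nDiseases[pm$gene_symbol == "G2"], 1L)
})

test_that("pairs without publications are still emitted with zero scores", {
  ev <- tibble::tibble(
    doid = "DOID:1", gene_symbol = "G1", nct_id = "NCT1",
    drug_name = "a", pmid = NA_character_,
    reference_type = NA_character_, study_age_years = 2
  )
  pm <- compute_pair_metrics(ev)
  expect_equal(pm$nPub, 0L)
  expect_equal(pm$nPublicationWeighted, 0)
  expect_equal(pm$nStud, 1L)
})

test_that("undated studies count for nStud but not newness, with a warning", {
  ev <- tibble::tibble(
    doid = "DOID:1", gene_symbol = "G1",
    nct_id = c("NCT1", "NCT2"), drug_name = "a",
    pmid = NA_character_, reference_type = NA_character_,
    study_age_years = c(0, NA)
  )
  expect_warning(pm <- compute_pair_metrics(ev), "without a usable date")
  expect_equal(pm$nStud, 2L)
  expect_equal(pm$nStudyNewness, 2)
})

test_that("pair metrics equal the brute-force recount on random fixtures", {
  for (seed in c(2, 9, 31)) {
    ev <- random_evidence(n_rows = 120, n_pairs = 10, seed = seed)
    pm <- compute_pair_metrics(ev)
    expect_equal(
      as.data.frame(pm[, c("doid", "gene_symbol", "nDiseases", "nDrug",
                           "nStud", "nPub", "nStudyNewness",
                           "nPublicationWeighted")]),
      as.data.frame(oracle_pair_metrics(ev)),
      tolerance = 1e-12
    )
  }
})

test_that("publication weight is bounded by nPub and tight iff all RESULT", {
  w <- reference_weights()
  for (seed in 1:5) {
    ev <- random_evidence(60, n_pairs = 6, seed = seed)
    pm <- compute_pair_metrics(ev)
    expect_true(all(pm$nPublicationWeighted <= pm$nPub * w$result + 1e-12))
    expect_true(all(pm$nStudyNewness <= 2 * pm$nStud + 1e-12))
  }
  all_result <- tibble::tibble(
    doid = "DOID:1", gene_symbol = "G1", nct_id = "NCT1", drug_name = "a",
    pmid = c("p1", "p2"), reference_type = "RESULT", study_age_years = 0
  )
  pm <- compute_pair_metrics(all_result)
  expect_equal(pm$nPublicationWeighted, pm$nPub * w$result)
})
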