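test_that("descending rank averages ties and sums to N(N+1)/2", {
  expect_equal(rank_descending(c(10, 7, 7, 1)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_descending(5), 1)
  expect_equal(rank_descending(rep(3, 4)), rep(2.5, 4))
  for (seed in 1:5) {
    v <- withr::with_seed(seed, sample(0:5, 20, replace = TRUE))
    r <- rank_descending(v)
    expect_equal(sum(r), 20 * 21 / 2)
    expect_equal(r, oracle_rank_desc(v))
  }
  expect_error(rank_descending(numeric(0)), "empty")
  expect_error(rank_descending(c(1, NA)), "missing")
})

test_that("mean rank is the arithmetic mean of the per-metric ranks", {
  expect_equal(mean_rank(1:6), 3.5)
  expect_equal(mean_rank(rep(1, 6)), 1)
  expect_equal(mean_rank(c(1, 4)), 2.5)
  expect_error(mean_rank(numeric(0)))
})

test_that("mean-rank scores follow the percentile formulas", {
  expect_equal(mean_rank_score(c(1, 2, 3, 4)), c(75, 50, 25, 0))
  expect_equal(mean_rank_score(1), 0)
  # two tied mean ranks among N=2: tied rank 1.5 -> percentile 75
  expect_equal(mean_rank_score(c(2, 2)), c(25, 25))
  # scores live in [0, 100); unique best pair attains 100 * (1 - 1/N)
  for (seed in 1:5) {
    mr <- withr::with_seed(seed, runif(30, 1, 30))
    s <- mean_rank_score(mr)
    expect_true(all(s >= 0 & s < 100))
    expect_equal(max(s), 100 * (1 - 1 / 30))
  }
})

test_that("a pair dominating on all metrics outranks the dominated pair", {
  pm <- tibble::tibble(
    doid = c("DOID:1", "DOID:2"), gene_symbol = c("GA", "GB"),
    nDiseases = c(3, 1), nDrug = c(4, 2), nStud = c(10, 3),
    nPub = c(8, 1), nStudyNewness = c(9.1, 2.2),
    nPublicationWeighted = c(5.5, 0.5)
  )
  sc <- score_associations(pm)
  expect_gt(sc$meanRankScore[sc$gene_symbol == "GA"],
            sc$meanRankScore[sc$gene_symbol == "GB"])
})

test_that("identical metric vectors score identically", {
  pm <- tibble::tibble(
    doid = sprintf("DOID:%d", 1:4), gene_symbol = sprintf("G%d", 1:4),
    nDiseases = 1, nDrug = 2, nStud = 3, nPub = 4,
    nStudyNewness = 1.5, nPublicationWeighted = 2.5
  )
  sc <- score_associations(pm)
  expect_equal(length(unique(sc$meanRankScore)), 1)
})

test_that("scoring equals the brute-force oracle on synthetic fixtures", {
  for (seed in c(4, 21)) {
    tabs <- synth_generate(synth_config(seed = seed, n_studies = 45))
    res <- run_pipeline(tabs$studies, tabs$references, tabs$drug_targets,
                        tabs$diseases)
    got <- dplyr::arrange(tibble::as_tibble(res$associations), doid,
                          gene_symbol)
    want <- dplyr::arrange(oracle_score(res$pair_metrics), doid,
                           gene_symbol)
    expect_equal(got$meanRank, want$meanRank, tolerance = 1e-12)
    expect_equal(got$meanRankScore, want$meanRankScore, tolerance = 1e-12)
    # per-metric ranks agree with enumeration too
    for (m in c("nStud", "nPub", "nStudyNewness")) {
      pm_sorted <- dplyr::arrange(tibble::as_tibble(res$pair_metrics),
                                  doid, gene_symbol)
      expect_equal(got[[paste0("rank_", m)]],
                   oracle_rank_desc(pm_sorted[[m]]))
    }
  }
})

test_that("scored output is invariant to pair row order", {
  tabs <- synth_generate(synth_config(seed = 6, n_studies = 40))
  res <- run_pipeline(tabs$studies, tabs$references, tabs$drug_targets,
                      tabs$diseases)
  pm <- tibble::as_tibble(res$pair_metrics)
  sc1 <- score_associations(pm)
  sc2 <- withr::with_seed(1,
                          score_associations(pm[sample.int(nrow(pm)), ]))
  expect_equal(as.data.frame(sc1), as.data.frame(sc2))
})

test_that("raising one metric never lowers that pair's score", {
  tabs <- synth_generate(synth_config(seed = 8, n_studies = 40))
  res <- run_pipeline(tabs$studies, tabs$references, tabs$drug_targets,
                      tabs$diseases)
  pm <- tibble::as_tibble(res$pair_metrics)
  base <- score_associations(pm)
  for (m in c("nStud", "nPublicationWeighted")) {
    bumped <- pm
    bumped[[m]][1] <- bumped[[m]][1] + 10
    sc <- score_associations(bumped)
    key <- paste(pm$doid[1], pm$gene_symbol[1])
    get_score <- function(x) {
      x$meanRankScore[paste(x$doid, x$gene_symbol) == key]
    }
    expect_gte(get_score(sc), get_score(base))
  }
})

test_that("duplicating a pair's metric vector keeps other pairs ordered", {
  pm <- tibble::tibble(
    doid = sprintf("DOID:%d", 1:5), gene_symbol = sprintf("G%d", 1:5),
    nDiseases = c(1, 2, 3, 4, 5), nDrug = c(5, 4, 3, 2, 1),
    nStud = c(2, 2, 3, 1, 4), nPub = c(0, 1, 2, 3, 4),
    nStudyNewness = c(1, 2, 3, 4, 5),
    nPublicationWeighted = c(0, 0.5, 1, 1.5, 2)
  )
  before <- score_associations(pm)
  dup <- pm[3, ]
  dup$doid <- "DOID:99"
  dup$gene_symbol <- "G99"
  after <- score_associations(dplyr::bind_rows(pm, dup))
  # the duplicated vector's original pair (G3) may move within its own tie
  # group; every pair with a distinct vector must keep its relative order
  others <- setdiff(pm$gene_symbol, "G3")
  order_of <- function(x) x$gene_symbol[x$gene_symbol %in% others]
  expect_equal(order_of(after), order_of(before))
})

test_that("per-disease mode ranks within each disease", {
  pm <- tibble::tibble(
    doid = c("DOID:1", "DOID:1", "DOID:2"),
    gene_symbol = c("G1", "G2", "G3"),
    nDiseases = 1, nDrug = c(2, 1, 1), nStud = c(3, 1, 1),
    nPub = c(2, 0, 0), nStudyNewness = c(3, 1, 1),
    nPublicationWeighted = c(1, 0, 0)
  )
  sc <- score_associations(pm, per_disease = TRUE)
  # a singleton disease always scores 0 (percentile 100 of itself)
  expect_equal(sc$meanRankScore[sc$doid == "DOID:2"], 0)
  d1 <- sc[sc$doid == "DOID:1", ]
  expect_equal(d1$meanRankScore[d1$gene_symbol == "G1"], 50)
})

test_that("asc direction override flips a metric's contribution", {
  pm <- tibble::tibble(
    doid = c("DOID:1", "DOID:2"), gene_symbol = c("G1", "G2"),
    nDiseases = c(5, 1), nDrug = 1, nStud = 1, nPub = 1,
    nStudyNewness = 1, nPublicationWeighted = 1
  )
  default_sc <- score_associations(pm)
  flipped <- score_associations(pm, rank_direction = c(nDiseases = "asc"))
  expect_gt(default_sc$meanRankScore[default_sc$gene_symbol == "G1"],
            default_sc$meanRankScore[default_sc$gene_symbol == "G2"])
  expect_lt(flipped$meanRankScore[flipped$gene_symbol == "G1"],
            flipped$meanRankScore[flipped$gene_symbol == "G2"])
})

test_that("association tables serialize with five-decimal scores", {
  tabs <- synth_generate(synth_config(seed = 5, n_studies = 30))
  res <- run_pipeline(tabs$studies, tabs$references, tabs$drug_targets,
                      tabs$diseases)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_associations(res$associations, path)
  back <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  expect_true(all(grepl("^\\d+\\.\\d{5}$", back$meanRankScore)))
  expect_true(all(c("doid", "gene_symbol", "meanRank", "meanRankScore",
                    "drugs") %in% names(back)))
})
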