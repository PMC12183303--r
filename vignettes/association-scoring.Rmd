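---
title: "Scoring disease-target associations from clinical-trial evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease-target associations from clinical-trial evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctassoc)
library(dplyr)
```

## The inference problem

Trial registries record, for each study, the interventions tested and the
conditions studied. When an intervention is a drug with known protein
targets, every (disease, target) pair co-occurring in a trial is a weak
association hypothesis. Single co-occurrences mean little — drugs are
promiscuous, trials study many conditions — but evidence aggregated over
hundreds of thousands of trials, weighted by recency and by how directly a
publication reports on a trial, separates well-supported associations from
incidental ones. `ctassoc` implements that aggregation and the rank-based
confidence score used to sort the hypotheses, together with an
agreement-based validation against an external curated disease-gene
resource.

The package deliberately consumes *annotation tables*, not free text: the
named-entity recognition that maps intervention names to drug structures
and trial descriptions to disease ontology terms is an upstream concern
(and typically commercial tooling); its outputs are the inputs here.

## Evidence model

`build_evidence()` joins four tables into one row per
(doid, gene_symbol, nct_id, drug_name) combination, replicated per linked
reference. Three filtering rules matter:

- Only `study_type == "INTERVENTIONAL"` with
  `intervention_type == "DRUG"` contributes. Observational studies
  co-mention diseases and drugs without testing the drug against the
  disease, so they are excluded outright.
- Annotation rows pointing at trials absent from the studies table are
  skipped and tallied in a skip report rather than erroring: registry
  exports drift out of sync routinely.
- Drug names are lowercased and whitespace-collapsed before any distinct
  counting. Synonymous naming is the dominant source of inflated drug
  counts; structure-level resolution (SMILES/InChIKey) is out of scope, so
  the normalization is deliberately conservative.

Replicating rows per reference makes the evidence table provenance-complete
— `association_provenance()` is a filter, not a recomputation — and is safe
because every metric deduplicates by trial or publication identifier before
counting.

## The six metrics

For each (disease, gene) pair: `nDiseases` (distinct diseases linked to the
gene anywhere in the evidence set), `nDrug`, `nStud`, `nPub`, and two
weighted scores.

**Study newness.** A trial of age $t$ years contributes
$w(t) = 2\,e^{-t/h}$, summed over the pair's unique trials. The half-life
$h$ is 5 years for trials at most 10 years old and 10 years for older ones,
so recent evidence is sharply favoured while decades-old trials retain a
nonzero floor. Two consequences of implementing this rule literally are
worth knowing:

- The weight is *discontinuous* at $t = 10$: $w(10) = 2e^{-2} \approx
  0.271$ but $w(10.01) \approx 2e^{-1} \approx 0.736$, so a trial just past
  the threshold outweighs one at it. `plot_decay_curve()` makes the jump
  visible. The piecewise rule is kept as specified rather than smoothed
  (e.g. by switching at the weight-equality point) because the scores feed
  a rank aggregation in which such local inversions have negligible effect;
  the anomaly is documented rather than silently redefined.
- Ages need a date. The age is measured to the completion date, falling
  back to the start date; trials with neither still count toward `nStud`
  but are excluded from newness with a warning. The snapshot date defaults
  to `"auto"` — the latest reference date in the loaded studies — so runs
  are reproducible without a wall-clock dependence.

**Weighted publications.** Reference types weight how directly a
publication bears on a trial: RESULT 1.0, BACKGROUND 0.5, DERIVED 0.25
(`reference_weights()`; the defaults are the method's definition, not
tuning knobs). Publications are deduplicated by PMID keeping the maximum
weight across their reference types. References lacking a PMID stay in
provenance but are excluded from `nPub` and the weighted score — they
cannot be deduplicated, and counting them would double-count reprints.
Unknown reference types map to the DERIVED weight with a warning rather
than erroring: registry annotations are noisy and the choice is
conservative.

## Rank aggregation

Each metric is ranked descending over all pairs with ties averaged (so rank
sums are exact and ties introduce no bias), the six ranks are averaged into
`meanRank`, and

$$\mathrm{meanRankScore} = 100 - \frac{\mathrm{rank}(\mathrm{meanRank})}{N}\times 100$$

with the inner rank ascending. Scores live in $[0, 100)$; a unique best
pair attains $100(1 - 1/N)$. Rank aggregation rather than metric
combination keeps the score unitless and robust to the wildly different
scales of the metrics, at the cost of being relative to the scored table:
adding pairs changes every score, which is why the tie-break and sort order
are fixed (descending score, then doid, then gene symbol) and the whole
computation is deterministic.

Two genuinely open choices were resolved as follows:

- **All six metrics rank descending, including `nDiseases`.** Ranking a
  gene's disease count upward rewards promiscuous targets, which cuts
  against specificity; the method is defined that way, so it is the
  default, but `rank_direction = c(nDiseases = "asc")` flips it for users
  who want specificity-favouring ranks.
- **Ranks are global** over the pair table; a per-disease view is a filter
  of the global table. `per_disease = TRUE` computes within-disease ranks
  instead for users comparing candidates inside one indication.

## Validation by set agreement

`to_cui_associations()` projects (doid, gene) associations through a
DOID-to-UMLS-CUI crosswalk (one row per mapped CUI, deduplicated; unmapped
DOIDs counted and dropped) and `overlap_report()` compares two such sets:
both are restricted to their shared CUIs *before* counting, so the
comparison covers only diseases both resources describe, and the headline
percentage is the fraction of the reference set's restricted associations
recovered. Because the trial-derived set is typically much larger than a
curated reference, the report also exposes the complementary quantity — the
percentage of inferred associations absent from the reference — separately,
rather than conflating the two; gene symbols are uppercased on both sides
first, since symbol case is the dominant spurious-mismatch source.
Comparison stays in CUI space: when a CUI maps back to several DOIDs no
back-projection is attempted.

## The synthetic corpus

`synth_generate()` emulates the *shape* of a registry extract: trials with
unique NCT identifiers and dates spanning decades, a configurable
observational fraction, drug-target and study-disease annotations, Poisson
reference counts with a RESULT/BACKGROUND/DERIVED mix, a DOID-CUI crosswalk
and an external association table. Defaults (the package's standard test
corpus, chosen once): 300 studies, 20 diseases, 60 genes, 80 drugs, 10%
observational, 10% non-drug interventional, dates uniform over 1998-2024 —
a span exceeding 10 years so both decay branches are always exercised —
1.2 references per study, type mix 0.35/0.45/0.20. RESULT references are a
minority in real registries; the mix keeps all three types present even in
small corpora. Each table draws from its own RNG stream derived from the
master seed, so adding a table never perturbs the others and fixed seeds
give byte-identical files.

**Planted signal.** A planted pair of strength $s$ receives
$\lceil s \times \bar{b} \rceil$ extra interventional drug studies, where
$\bar{b}$ is the mean background evidence per realized pair from an
occupancy approximation of the configuration. Because the score aggregates
six metrics, "$s$-fold stronger" must hold across evidence dimensions, not
just study count: the planted gene is guaranteed roughly $s$ drugs
(deterministic reassignment), planted studies cycle through them, and they
mention a second disease at the background rate. With these semantics,
strength-5 and strength-10 pairs land in the top score decile essentially
always across seeds (verified over 20 replicates in the test suite).

What the generator does *not* emulate: real text fields, eligibility
criteria, correlated disease-drug structure (indication areas), the
registry's historical growth curve, or realistic gene symbol vocabularies.
Passing tests on this corpus demonstrate correctness of the aggregation
arithmetic and the recovery of planted rank signal — not performance on
real registry data, whose noise sources (NER errors, synonym collisions,
annotation lag) are upstream of this package.

## Numerical and degenerate-input choices

- Ages are day counts divided by 365.25, floored at zero (future-dated
  completions are treated as current).
- An empty evidence table is a hard error in `compute_pair_metrics()`; an
  all-filtered corpus yields an empty evidence table from
  `build_evidence()` without error, so callers can distinguish the cases.
- A single-pair table scores 0 (it is its own 100th percentile); a
  singleton disease in per-disease mode likewise.
- Scores are serialized with five decimal places; internal computation is
  double precision throughout.
- Problem sizes in the test suite (30-400 studies, up to ~330 pairs, 20
  replicate seeds for the recovery property) were chosen to exercise every
  code path — both decay branches, undated trials, PMID-less references,
  multi-drug and multi-disease studies — while keeping the suite fast.

## Known limitations

- Co-occurrence in a trial is not causation; the score ranks hypothesis
  strength, not biological validity.
- `nDiseases` as a descending metric favours promiscuous targets (see
  above); flip it if specificity matters to your question.
- Drug normalization is lexical only; two salts of one compound count as
  two drugs.
- The decay discontinuity at the half-life threshold mildly rewards
  trials just older than 10 years.
- Scores are relative to the scored table and not comparable across
  differently-sized tables.
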