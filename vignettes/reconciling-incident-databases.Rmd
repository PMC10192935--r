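---
title: "Reconciling five mass-shooting incident databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling five mass-shooting incident databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdblink)
```

## The problem

There is no consensus definition of a "mass shooting" in the United States,
and the five most widely used incident databases — the FBI's Supplementary
Homicide Report (SHR) and Active Shooter Report (ASR), Mother Jones (MJ),
Everytown for Gun Safety, and the Gun Violence Archive (GVA) — each apply
their own inclusion criteria. The databases consequently contain different,
partially overlapping incident populations, and any single-database estimate
of the burden of mass gun violence inherits that database's definition.
msdblink reconciles such databases end to end: it harmonizes heterogeneous
per-source exports, resolves records that describe the same real-world
incident (including *imperfect duplicates* that disagree on a field or two),
and quantifies the overlap structure as exclusive set intersections — the
counts an UpSet plot displays — both under each database's own definition
and under a common fatality threshold.

Because the live databases are continuously revised, the package also ships
a synthetic five-source generator with complete ground truth, so that every
stage of the pipeline can be validated against known answers.

## Harmonization

Each source export is described by a *dialect* (`source_dialect()`,
bundled as editable YAML): a column map onto the harmonized schema, a date
format, the state style, and two structural quirks that real exports have:

* **Victim-level rows (SHR).** The SHR is one row per homicide victim.
  `subset_shr()` groups rows into incidents by (agency, incident number,
  date) — the standard SHR convention, configurable — and retains incidents
  with a single offender and four or more firearm fatalities. Which weapon
  codes count as firearms is configuration (`DEFAULT_FIREARM_CODES`);
  incidents with unrecognized weapon codes go to a review list rather than
  being silently kept or dropped. The filter is applied to weapon, shooter
  count and fatality count only; no circumstance-code restriction is
  imposed.
* **Perpetrator-inclusive counts.** Where a source counts the perpetrator
  among the dead (`victim_count_basis = "INCLUDES_PERP"`), one is
  subtracted when the perpetrator is known to have died; when the
  perpetrator's fate is unknown the count is kept and the record flagged
  `low_confidence` rather than guessed at. All thresholds in the package are
  perpetrator-exclusive.

Dates parse *strictly* (a value must reproduce itself when the parsed date
is re-formatted): impossible dates are collected in a per-row error report,
never imputed or silently dropped, so the row accounting
`records + errors = data rows` always holds. States normalize to USPS codes
through a fixed internal table; unmatchable values are kept verbatim. The
study window (2013-01-01 to 2020-12-31, the years for which all five
databases have data) is a closed interval; records with unparseable dates
cannot demonstrate membership and are excluded before linkage.

## Declarative definitions

Each database's inclusion criteria are data, not code: a `definition()`
holds a count basis (fatalities vs. casualties), a minimum count,
shooter-count bounds, a known-shooter requirement, excluded motives and an
optional public-location restriction. The five presets mirror the
databases' stated criteria (see `preset_definition()`); MJ's documented
two-shooter school-shooting exceptions are representable through an
`allow_list`, which is empty by default because the package takes no
position on which incidents deserve exceptions.

Unknown fields follow two deliberate policies, each configurable:
**count rules fail closed** (a record with an unknown fatality count cannot
clear a fatality threshold — the rule id is recorded in `failed_rules`),
while **motive and location exclusions fail open** (an unknown motive is
not treated as excluded). This mirrors how the permissive databases include
incidents regardless of motive while the restrictive ones exclude only
*known* disqualifying motives. For the casualty basis, a record with one
unknown count is eligible when the known part alone reaches the threshold,
since the total can only grow. The ASR's "randomness" criterion is
operationalized purely as its stated motive exclusions (gang, drug,
partner/family violence); prose notions of randomness beyond that list are
not evaluable.

## Linkage

The linkage model is deliberately rule-based and transparent — the setting
it emulates used a basic duplicate script plus manual adjudication, and a
trained probabilistic (Fellegi–Sunter) model is out of scope.

**Blocking.** Candidate pairs must come from different sources, agree on
state when both states are known, and lie within ±1 day (`date_window`,
configurable; one day absorbs media-vs-report dating disagreements).
Within-source duplicates are not candidates; they can still end up in one
cluster transitively and are then flagged.

**Scoring.** Six components in [0, 1]: a date similarity
`max(0, 1 - 0.2·|Δdays|)` (1 only on the same day; 0.8 at one day apart —
a linear decay rather than a same-day indicator, so that a one-day dating
disagreement dents rather than destroys an otherwise perfect pair); an
exact-match state indicator; normalized Levenshtein similarities for city
and shooter name (best cross-pairing for multi-shooter name lists); and
count similarities `max(0, 1 - |Δ|/max(a, b, 1))` for killed and injured.
The total is a weighted mean — defaults date 0.25, state 0.20, city 0.20,
name 0.15, killed 0.10, injured 0.10 — **renormalized over present
components**, so a missing field (SHR has no injury counts; some sources
omit shooter names) is neutral rather than penalizing.

**Classification and review.** `total ≥ 0.90` auto-links; `0.70–0.90`
routes to a review queue (CSV out, resolutions CSV in, with strict
validation); below 0.70 is a non-match. With the default weights an exact
agreement scores 1, a single wholly disagreeing field of weight ≥ 0.10
lands at or below 0.90, and typical perturbed twins (±1 day plus a city
typo ≈ 0.92) still auto-link. Both bounds are closed below. Unresolved
review pairs default conservatively to non-match and are reported.

**Clustering.** Connected components over match edges (transitive closure);
singletons stand alone; every record belongs to exactly one cluster. The
canonical merged record takes per-field *maxima* for casualty counts
(sources differ on counts; the maximum preserves "at least" semantics),
majority values for date/place fields with ties broken by a fixed source
priority (SHR > ASR > Everytown > MJ > GVA, configurable), and the union of
shooter names. Cluster ids are assigned after a deterministic sort (date,
state, city, then member key), so identical inputs give byte-identical
outputs.

## Overlap analytics

`build_membership()` turns cluster memberships into a boolean incidents ×
sources matrix; restricting the source set drops incidents present only in
removed sources, which is how the "excluding GVA" sensitivity analysis
works. `exclusive_intersections()` counts clusters by their *exact*
membership pattern — the UpSet convention, adopted here because it makes
the counts partition the union (they always sum to the number of unique
incidents). `run_pipeline()` hard-wires three analyses as report sections —
all configured sources, sources minus GVA, and the subset of clusters
meeting the common four-fatality threshold — because those are the three
standard views of the discrepancy question; arbitrary subsets are available
through the configuration. The threshold re-analysis at cluster level uses
the canonical (max-merged) killed count, while per-source tables use each
source's own reported counts. Overlap proportions should be quoted as
computed ratios of count over union (e.g. 25 of 3155 unique incidents is
0.79%, not 0.008%).

## The synthetic generator

`generate_universe()` draws a ground-truth incident universe and
`emit_source()` inverts each database's definition: a source lists exactly
the incidents eligible under its preset, thinned by an imperfect detection
probability, with fields then perturbed to create imperfect duplicates.

Defaults, chosen once as a plausible emulation of the real severity and
motive mix and not tuned thereafter: fatalities and injuries are
zero-truncated negative binomial with truncated means 2.0 and 3.0
(dispersion 1.0) — overdispersed, mostly small, occasionally large; the
underlying NB mean is solved numerically so the *configured* mean is the
mean of the truncated distribution, which keeps moment checks well-posed.
Motives are categorical (gang .25, family/IPV .25, drug .10, robbery .05,
terror .02, other .33), two-shooter incidents occur at rate .05, the
perpetrator dies with probability .20, and locations are public .30 /
residence .40 / multiple .05 / other .25 (a chosen plausible mix; nothing
downstream is sensitive to it). Cities are drawn from a bundled list of
~200 real U.S. city/state pairs so that typo similarities behave
realistically. Detection is .95 per eligible incident and each perturbation
(±1-day date shift, one-character city typo, ±1 casualty count, dropped
shooter name) applies independently at rate .05.

Two consequences are intentional. First, eligibility is recorded
*pre-perturbation*, so a listed count can disagree with another source's —
exactly the imperfect-duplicate phenomenon the linkage stage must survive,
and an emitted record can even fall below its own database's threshold as
listed. Second, under these defaults the emitted volumes reproduce the real
ordering (GVA by far the largest, MJ the smallest) because a casualty basis
admits far more incidents than a fatality basis and MJ's exclusions are the
strictest.

What the generator does **not** emulate: victim/offender demographics,
within-incident geography beyond city/state, unsolved incidents (ground
truth always knows its shooters; missing names arise only as emission
noise), reporting lags, and same-source double listings. Passing oracle
tests therefore demonstrates the pipeline's correctness under controlled
heterogeneity, not the field accuracy of any particular real database
snapshot — the real databases are live and revisable, so their published
totals are treated as printed inputs (see `filter_ledger()`) rather than
reproduction targets.

## Numerical and engineering choices

* All randomness is seed-controlled; the pipeline itself is deterministic
  (stable sorts everywhere ties are possible).
* Degenerate inputs are defined: empty files warn and return empty record
  sets; an empty review queue still writes a header; a zero-incident
  universe is valid; a threshold of 0 retains every record with a known
  count.
* Validation sizes: oracle-equivalence runs use a 2000-incident universe
  (~2700 emitted records), robustness runs 10 universes of 1000 incidents,
  and brute-force equivalence instances stay below 500 records so the
  O(n²) oracle remains exact; property suites iterate over 1000+ generated
  cases under fixed seeds.

```{r example}
u <- generate_universe(universe_config(n_incidents = 400, seed = 7))
bundle <- write_source_bundle(u, default_source_models(),
  dir = tempfile("demo"), seed = 7
)
report <- run_pipeline(pipeline_config(bundle$paths))
report
report$overlaps$all
linkage_metrics(report$members, bundle$links)
```

## Limitations

The linkage thresholds are calibrated for the bundled similarity model and
the kinds of noise the generator produces; heavier noise (renamed cities,
multi-day dating errors) would shift pairs from auto-link to the review
queue, which is the designed failure mode — the queue, not silent
misclassification, absorbs ambiguity. The SHR incident-grouping convention
and firearm code set are configurable because agencies' reporting practices
vary. No population-size (capture–recapture) estimation is attempted: the
union of reconciled incidents is a lower bound on the true incident count,
not an estimate of it.
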