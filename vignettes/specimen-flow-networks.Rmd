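---
title: "Specimen flow networks: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specimen flow networks: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specflow)
```

## The analysis in one paragraph

`specflow` treats museum specimen custody as a directed, weighted flow
network. Each cleaned occurrence record contributes its specimen count to the
edge from its collection (origin) country to the country of its holding
institution. Networks are built separately for each family × period slice;
topology metrics describe breadth and structure of international exchange,
the Gini coefficient of per-country holdings describes inequality of curation
responsibility, and regressions on period midpoints describe how both change
through time.

## Record filtering

Five quality rules are applied in a fixed order, each removed row attributed
to the *first* rule it fails, so the audit log is deterministic and sums
exactly: basis of record (only preserved specimens), missing origin country,
unresolvable holding institution, collection year outside the retention
window (1900–2020 by default), missing year, non-"present" occurrence
status, counts below one, and unstandardisable origin country values.
Conventions worth noting:

- A four-digit year in `eventDate` is used only when the `year` column is
  empty; an explicit `year` always wins on conflict.
- Missing or non-numeric `individualCount` means a single specimen; values
  below 1 are removed.
- Missing `occurrenceStatus` is treated as "present" (the common aggregator
  convention); only an explicit non-present value removes a row.
- Country standardisation is exact-match (trimmed, case-insensitive) against
  a name/code table. There is no fuzzy matching: historical entities (USSR,
  Yugoslavia, ...) resolve only through explicit override rows supplied by
  the user, otherwise they are logged as invalid and dropped.
- Captive/wild annotations are deliberately not filtered; they are too
  incomplete and inconsistent across institutions to act on.

## Network conventions

- **Self-loops.** Records collected and held in the same country go to a
  separate domestic ledger. They are excluded from node sets and all
  topology metrics, but included in holdings when measuring inequality. A
  country with only domestic activity is therefore invisible to topology but
  a full participant in the Gini.
- **Edge weights** sum record `count` values, not record rows: a record
  representing four specimens moves four units of flow.
- **Reciprocity** is weight-blind (edge presence only), the igraph default
  definition. It is reported as missing, not zero, on edgeless slices.
- **Density** is defined as 0 for networks with fewer than two nodes.
- **Louvain modularity** runs on the undirected projection with antiparallel
  edge weights summed. Louvain is stochastic; the implementation requires a
  seed and reports the best modularity over a configurable number of
  restarts (default 5), making results reproducible and less sensitive to a
  single unlucky sweep.
- **Thresholding** (sensitivity analysis) removes international edges below
  a minimum weight and recomputes the node set, so countries kept alive only
  by thresholded-away flows drop out. The domestic ledger is not
  thresholded.
- **Top-k edge selection** breaks weight ties by origin then holding code,
  so "top 200 flows" is deterministic.

## Inequality

The Gini coefficient uses the population estimator
`G = Σᵢⱼ |xᵢ − xⱼ| / (2 n² μ)` with no small-sample correction, matching the
default of the standard implementation; a sample-corrected variant
(`× n/(n−1)`) is exposed for sensitivity. By default only *participants* —
countries with nonzero holdings in the slice — enter the computation:
treating every non-participating country as a zero would inflate inequality
with non-participation, which is a different phenomenon. The zero-inclusive
variant (zeros = participating countries with zero holdings, i.e. pure
exporters) is retained as a sensitivity setting.

## Trend statistics

Metrics are regressed on period midpoints (1915, 1945, 1975, 2005) by OLS.
With four points per family these fits have 2 residual degrees of freedom;
every fit carries a `low_n` flag and should be read descriptively. The
quadratic-vs-linear comparison is a nested-model F test on (1, 1) df — with
four points the quadratic leaves a single residual df — and detects U-shaped
inequality trajectories. Early-vs-recent comparisons (first two vs last two
periods, configurable) use Welch's t with Satterthwaite df. The two-way
ANOVA on Gini is the additive fixed-effects decomposition on the complete
3 × 4 design; with one observation per cell the interaction is untestable
and serves as the residual. Trend fits are reported per family *and* pooled
across families, since both framings are informative at n = 4. No
multiple-testing correction is applied across metrics.

Degenerate inputs are handled explicitly: constant responses return slope 0
and R² 0 with a missing p-value; an exactly linear series yields F = 0 and a
"linear" preference rather than a 0/0.

## The synthetic world

The generator's defaults are a stated world mirroring the digitised record
the pipeline is designed for: 178 origin countries, 44 holding countries
(a subset of the origin pool), 312,456 raw rows of which 19% carry an
injected defect (leaving ~253k clean records), family shares 37.3/16.2/46.5%
(Canidae/Felidae/Mustelidae), period weights 0.20/0.26/0.31/0.23 with the
1960–1989 bin heaviest, domestic fraction 0.30, and reciprocity target 0.08.

- **Holdings concentration** is a single interpretable knob: holding-country
  shares are drawn once per table from a symmetric Dirichlet(α). The default
  α = 0.1 was calibrated *a priori* with the Monte-Carlo oracle
  `reference_gini()` to give an expected holdings Gini ≈ 0.86 for 44
  holders, inside the observed 0.85–0.89 range for early periods. No
  empirical degree or weight distribution was available to fit, so the
  Dirichlet is a stand-in, not a fitted model.
- **Defects are mutually exclusive per row** (at most one defect each), so
  every downstream filter-log count is exactly predictable from the injected
  counts — this is what makes the filter accounting test exact rather than
  approximate.
- **Reciprocity** is enforced at the level of unordered country pairs among
  clean international rows whose *both* countries are holders (a reverse
  edge needs a holding institution). With probability equal to the target a
  pair becomes mutual (one row re-routed if needed; a pair realised with a
  single row borrows a surplus row from a donor pair); otherwise all its
  rows are forced into one direction. This makes the target-0 and target-1
  endpoints exact by construction, with any unsatisfiable case counted and
  reported. Setting the target to `NA` disables the machinery entirely,
  which is what the parameter-recovery experiments use: re-routing rows
  perturbs the holdings distribution, and the α → Gini mapping should be
  tested with that nuisance switched off.
- **Years** are drawn uniformly within a period chosen by the period
  weights; institutions are drawn uniformly within the record's holding
  country from a registry in which every holding country has at least one
  institution.

### What a green test does and does not establish

The generator emulates marginal structure — concentration, low reciprocity,
domestic retention, temporal spread, contamination — but not several features
of real data: origin countries are uniform rather than biodiversity-weighted,
holding shares are constant through time (no digitisation lag, no
mid-century democratisation built in), and the reciprocity adjustment is
applied to the pooled clean table, so slicing by family × period dilutes
mutual pairs and per-slice reciprocity sits below the target. Passing tests
therefore establish that the *machinery* — filtering, aggregation, metrics,
inequality, trends — is correct and deterministic, not that any particular
real-world trajectory is reproduced. Real-data values (node counts,
specific Gini trajectories, country rankings) require the real download and
are out of scope here.

### Parameter recovery and the reference oracle

`reference_gini()` reports the Monte-Carlo mean of the Gini of
Dirichlet share vectors, its predictive spread `sd` (the standard deviation
of a single draw's Gini) and the standard error `se` of the mean. A measured
table is *one* draw from that distribution, so recovery is judged against
`3 × sd`; judging against `3 × se` would make the band shrink with the
number of oracle replicates, which cannot be right for a single-realisation
comparison. Because the oracle integrates over the full length-44 share
vector — including shares too small to receive any record — the recovery
measurement computes holdings over the whole holder pool with zeros
included; the participants-only convention remains the reporting default
everywhere else.

## Pipeline and determinism

`run_pipeline()` writes eight artefact files (filter log, cleaned records,
edge lists with domestic rows marked by `origin == holding`, metrics, Gini,
rankings, trends, sensitivity) plus a manifest with an MD5 checksum per file
and a hash of the configuration. All randomness flows from one master seed
(Dirichlet draw, sampling, Louvain restarts), so a rerun with the same
configuration is byte-identical — verified in the test suite by comparing
checksums.

## Known limitations

- Occurrence data reflect digitised, shared holdings, not complete
  inventories; the pipeline cannot distinguish loans from permanent
  transfers, nor wild-collected from captive-origin material.
- Country-level aggregation hides within-country structure; institution-level
  analysis is a natural extension the data model already supports (the
  registry keeps institution codes).
- Four periods give weak inferential power per family; the trend machinery
  reports exact statistics but flags them `low_n`.
- The linear mixed-effects comparison of families (with marginal-means
  post-hoc tests) is intentionally not implemented; the fixed-effects
  two-way ANOVA covers the family and period main effects.
- Cartographic rendering is out of scope: the package exports edge lists and
  node statistics ready for mapping, but draws nothing.
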