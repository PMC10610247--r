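---
title: "Methods: disproportionality signal detection and profile clustering for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection and profile clustering for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA's FAERS collect
suspected drug reactions from clinicians, manufacturers and patients. They
have no usage denominator: we observe reports, not patients at risk, so
incidence cannot be estimated. Disproportionality analysis sidesteps this by
asking whether an event (here: drug-induced pruritus, i.e. itching) is
reported *relatively* more often for one drug than for all other drugs. This
package implements that analysis end to end for FAERS-style multi-table
data, plus a synthetic report generator with planted effects so every stage
can be verified against known truth.

## Data model and cleaning chain

FAERS distributes quarterly `"$"`-delimited tables: demographics (DEMO),
drugs (DRUG), reactions (REAC), indications (INDI) and therapy dates (THER),
keyed by a case identifier. The reader (`read_faers_table()`) normalises the
historical layout variants through a fixed alias table and refuses unknown
layouts rather than guessing. Parsing is total: malformed lines and records
(unknown drug role codes, empty case ids or terms, inverted fully-dated
therapy windows) are counted and dropped, never fatal.

The cleaning chain (`build_cohort()`) is:

1. **Deduplication** per table on the columns the analysis needs; among
   versions of one case the highest report version wins, ties broken by the
   last occurrence in file order (later submissions supersede earlier ones).
2. **Merge**: one row per (case, drug, event term) for cases present in
   DEMO. Drugs of every role — suspect, concomitant, interacting — are kept
   as candidate suspects.
3. **Chronological filter**: keep a row only when the event date falls
   within the drug's therapy window.
4. **Indication-overlap exclusion**: whole cases that list a pruritus term
   as an *indication* are removed — when the underlying disease itself is
   itching, a pruritus "reaction" is likely the inadequately treated disease,
   not a drug effect.
5. **Pruritus labelling** against the packaged 37-term preferred-term list,
   and demographic unit conversion with range checks.

An audit object mirrors this chain with per-stage counts, the pruritus share
of linked reports (rounded to one decimal percent) and the post-exclusion
total, so any divergence between two builds is inspectable stage by stage.

### Partial dates

FAERS dates come as `YYYY`, `YYYYMM` or `YYYYMMDD`. We never impute a
missing month or day: a partial date denotes its full containment interval,
and the chronological filter keeps a row iff the event interval intersects
the therapy interval (missing therapy end = open-ended, ongoing therapy).
Rows with no event date, no therapy start, or no therapy record at all are
excluded — a chronological claim cannot be verified without them. The
alternative convention (imputing day 1) silently shifts events to month
starts and biases the filter toward windows that begin early in the month;
interval semantics make the filter conservative and symmetric instead.

### Analysis units

The disproportionality screen counts one row per (case, drug) pair,
collapsed over events into a single pruritus yes/no flag: one patient-drug
exposure is one opportunity to report itching, and a case reporting both
"Pruritus" and "Eye pruritus" should not count twice. The term-level
profile matrix instead uses one row per (case, drug, event) record, since
there the individual term *is* the analysis object. Both units are exposed
through `make_analysis_set()`. Demographic analysis uses one row per case.

### The term list

The 37 itching-related MedDRA preferred terms (with their reference patient
counts) ship as package data and are matched exactly after case-folding.
The wildcard substring search over "itch"/"pruri…" was the one-off
harvesting step that produced the list from the dictionary; using it as the
per-report matcher would also catch unrelated terms, so membership is exact.
Applying the N ≥ 50 patient threshold to the packaged tally retains 17
terms; N ≥ 1 retains 29. Both thresholds are plain parameters
(`select_pts()`), nothing is hard-coded.

## The statistics

### Reporting odds ratio

For a drug $D$ and event $E$, with $a$ = reports with $D$ and $E$, $b$ =
$D$ without $E$, $c$ = $E$ without $D$, $d$ = neither:

$$\mathrm{ROR} = \frac{a'd'}{b'c'}, \qquad
a' = a + 0.5, \ldots \text{(Haldane–Anscombe semi-correction)}$$

$$95\%\ \mathrm{CI} = \exp\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac{1}{a'}+\tfrac{1}{b'}+\tfrac{1}{c'}+\tfrac{1}{d'}}\right)$$

The 0.5 correction is applied to **all four cells unconditionally** (a
`correct = "zeros"` variant is available): unconditional correction keeps
every lnROR finite and every table on the same scale, which matters when the
cells feed a matrix for multivariate analysis. Significance uses the
two-sided Fisher exact probability (minimum-likelihood convention) on the
*uncorrected* integer cells. Two signal definitions circulate and both are
implemented, neither preferred silently: the three-part rule (ROR ≥ 1,
p < 0.05, ≥ 50 reports; the default) and the lower-CI rule
(lower 95% bound > 1). The ≥ 50-report floor counters the instability of
odds ratios at small counts; drugs below it are still computed, only
flagging is gated.

### Demographic tests

Gender uses Fisher's exact test on the 2×2 gender × pruritus table; age and
weight use the two-sided Wilcoxon rank-sum test with mid-rank ties and a
continuity-corrected normal approximation (exact enumeration for small
untied samples — the `stats::wilcox.test()` switching rule). Ages convert
to years (month/12, week/52.18, day/365.25, hour/8766, decade × 10), weights
to kg (lbs × 0.453592); values outside [0, 130] years or (0, 600] kg become
missing rather than dropping the row. Unknown gender is excluded from the
stratified analyses but kept in the overall continuous analyses, so the
overall n exceeds male + female.

### Profile matrix, PCA, Ward clustering

Drugs passing a report-count threshold (configurable; the conventional
large-database choice is the top 200 drugs with more than 10,000 reports)
are profiled over the selected pruritus terms: each cell is the corrected
lnROR of that drug against all others for that term against all other
events. PCA runs on the **covariance** matrix (column-mean centering, no
scaling): the columns are already on a common log-odds scale, and
correlation-PCA would artificially inflate rare terms' noise. Contributions
are eigenvalues over total variance. Sign convention: each loading vector's
largest-magnitude element is made positive, making output reproducible
across linear-algebra backends.

Clustering is agglomerative Ward on Euclidean distance over the drug scores
restricted to the first three components (a configurable count) — the
dimensionality reduction denoises the profile before clustering — cut into
k clusters (default 6; k is a parameter, and the synthetic recovery studies
use the planted k). Merge heights are on the $\sqrt{2\,\Delta\mathrm{ESS}}$
scale and are non-decreasing. Per-cluster signatures report the mean score
and its sign per component, supporting the "positively/negatively
correlated with PC k" characterisation of a cluster.

## The synthetic generator

`synth_generate()` emulates the features of spontaneous-report data the
pipeline must survive: multi-table case structure, duplicate report
versions (some with perturbed weight, to exercise keep-latest logic),
partial and missing dates, therapy windows that deliberately miss the event
for a configured fraction of exposures, gender/age/weight strata differing
by pruritus status, indication-overlap cases, and planted drug-event odds
multipliers. Each case draws drugs independently by marginal probability;
each term's odds are its baseline odds times the product of multipliers of
the case's drugs. All randomness flows from one seed; identical
(config, seed) gives byte-identical tables.

Effects combine multiplicatively on the odds scale because that model has a
closed-form oracle: `expected_ror()` enumerates all $2^D$ drug subsets and
returns the asymptotic ROR, including two conditioning effects a naive
calculation misses — a case enters the analysis set only if it reports at
least one event, and cases co-exposed to the target drug contaminate the
comparator arm. Default demographics follow the large-scale profile for
itching (pruritic cases ≈ 50.3 y / 88.3 kg, others ≈ 53.2 y / 83.4 kg, 55%
female), the default baseline makes about 1% of linked reports pruritic,
and the default indication-overlap rate (0.2%) matches the share such
exclusions take in a large cleaned database.

What the generator does **not** emulate: reporting-dynamics biases (Weber,
notoriety, masking effects), country and reporter mix, drug-name spelling
noise, or real co-prescription correlation structure (drug draws are
independent). Passing recovery tests therefore show that the estimators and
the cleaning chain are correct under the stated generative model — not that
FAERS-derived rankings are unbiased, which no desk-scale test could show.

## Study conditions for the simulation checks

Chosen once, on design grounds, and stated here as the package's own
conditions:

* **Null calibration**: generator defaults (10 drugs, realistic noise
  rates), all multipliers 1, n = 5,000 cases, 200 seeds. The fraction of
  drugs with Fisher p < 0.05 stays below 7% — Fisher is conservative on
  discrete tables, so the nominal 5% is an upper envelope in practice.
* **Effect recovery**: 5 drugs at 0.5% exposure, pruritus baseline 10%,
  one planted multiplier of 4, n = 50,000, 200 seeds. Exposure is kept at
  0.5% so comparator-arm contamination by co-medicated cases keeps the
  model-implied ROR (by `expected_ror()`) within about 1.5% of the planted
  4; the 10% baseline keeps the exposed-event cell near 75 so the Wald
  interval behaves. The 95% CI covers the planted value in ≥ 90% of seeds
  and the mean lnROR bias stays under 0.05.
* **Archetype recovery**: 12 drugs at 8% exposure in three groups of four,
  each group multiplying a disjoint triple of pruritus terms by 6,
  n = 50,000. PCA + Ward at k = 3 recovers the groups (Rand index ≥ 0.9).
* Noise processes are switched off in the recovery configurations; they do
  not bias the estimators and are exercised by their own tests.

The test suite runs the full 200-seed conditions; `scripts/acceptance.R`
reruns scaled-down replicates (60 seeds) plus the end-to-end pipeline and
writes every quantity it computes to JSON.

## Numerical choices and degenerate inputs

* Fisher p-values use the minimum-likelihood two-sided convention with the
  standard $1 + 10^{-7}$ relative tolerance; the suite verifies equality
  with exhaustive hypergeometric enumeration on all tables with total ≤ 24.
* Ward linkage ties are broken by smallest index (the `hclust` convention);
  the suite verifies equality with a naive $O(n^3)$ re-implementation on
  12-point inputs.
* PCA on a zero-variance matrix, selections leaving fewer than two drugs or
  terms, k exceeding the number of drugs, empty test groups and empty
  contingency margins all fail loudly with named errors; the pipeline
  reports the failing stage and leaves a `STALE` marker.
* Degenerate generator configs (empty catalogs, probabilities outside
  [0, 1], non-positive multipliers) are rejected at construction.

## Limitations

The package analyses reporting disproportionality, not incidence; RORs are
relative reporting signals and inherit every reporting bias of the source
database. No multivariable confounding adjustment is attempted (the
bivariate demographic tests are descriptive), therapeutic-class rollups are
accepted only as a user-supplied join table, and drug names are normalised
only by whitespace/case — no ingredient dictionary is applied.
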