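---
title: "Methods: disproportionality screening and time-to-onset analysis for pediatric cataract reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and time-to-onset analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(faerssignal)
```

## The problem and the data model

Spontaneous-report surveillance asks whether a drug–event pair is reported
*disproportionately* often relative to everything else in the database. No
denominators (prescription counts, person-time) exist, so all inference is
internal to the reporting stream. This package implements that workflow for
pediatric cataract: the event set is six MedDRA Preferred Terms (Atopic
cataract 10069649, Cataract 10007739, Cataract cortical 10007748, Cataract
nuclear 10007759, Toxic cataract 10044135, Lenticular opacities 10024214),
with the single PT 10007739 as a narrow sensitivity definition. Because the
narrow set is a subset of the broad one, the sensitivity analysis is a pure
restriction — a property the test suite checks on generated data.

Input is the public FAERS quarterly dialect: `"$"`-delimited ASCII tables
(DEMO, DRUG, REAC, THER, OUTC, INDI, RPSR) linked by `PRIMARYID`. The
dialect has no quoting, so a literal `"$"` in a value is unrepresentable;
the writer refuses it rather than inventing an escape. Headers changed case
over the years and are normalized to lower case; unknown extra columns are
carried along untouched. One deliberate departure from raw FAERS: the REAC
`pt` column here holds MedDRA PT *codes*, not term names. The case
definition is code-level, and shipping a name-to-code dictionary would
require the licensed MedDRA distribution; users with a license can plug
their own mapping upstream.

## Cleaning rules

**Deduplication.** FAERS case versions share a `CASEID`. Among them the
report with the latest `FDA_DT` survives; on ties, the largest `PRIMARYID`.
`fda_dt` and `primaryid` are compared numerically (with a lexicographic
fallback for non-numeric identifiers), `caseid` as a string. Records with no
`caseid` are dropped and counted rather than silently kept. The operation is
idempotent and order-insensitive.

**Age.** Ages arrive as (value, unit) with units YR, MON, WK, DY, DEC;
conversion divides by 12, 52, 365 or multiplies by 10. Anything else — HR,
unknown codes, negative values — is missing, never guessed. The pediatric
filter keeps 0 < age < 18 with *strict* bounds on both ends: an age recorded
as exactly 0 or 18.0 years is excluded, following the literal inclusion
wording this analysis standardizes on.

**Primary suspect.** Only the drug the reporter judged responsible (role
code PS) defines exposure; when a report carries several PS rows the lowest
numeric `DRUG_SEQ` wins, and non-numeric sequence values sort last rather
than erroring. Reports with no PS row stay in the background with no
exposure assignment.

**Onset times.** `EVENT_DT − START_DT` in days, requiring two complete,
valid 8-digit calendar dates and a difference of at least one day. Each
excluded report is categorized exactly once: `missing` (a date absent),
`incomplete` (present but partial or not a valid calendar date — partial
dates are never imputed), `inconsistent` (event on or before start), or
`implausible` (beyond 6,574 days = 18 years, a bound chosen to be inert for
pediatric subjects; configurable). Malformed 8-digit strings such as
`20200230` are classed `incomplete`, grouping all unusable-but-present
dates together.

## The four algorithms and the consensus rule

Every screened drug gets a 2×2 table against the deduplicated pediatric
background (`a, b, c, d`; `N = a+b+c+d`). The background includes reports
without a mappable PS drug; a configuration switch is not needed because
such reports simply contribute to `c` and `d`.

* **ROR** `= ad/bc`, Wald CI on the log scale with multiplier 1.96; flag
  when `a ≥ 3` and the lower bound exceeds 1.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with variance `1/a − 1/(a+b) + 1/c −
  1/(c+d)`, plus the Yates-corrected χ²
  `N(|ad−bc|−N/2)²/((a+b)(c+d)(a+c)(b+d))`, clamped to zero when the
  correction overshoots; flag when `a ≥ 3` and χ² > 4 (strict).
* **BCPNN** information component `IC = log₂ aN/((a+b)(a+c))` with
  Dirichlet-style shrinkage: priors α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1 and the
  per-table normalizer γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)). At
  a = b = c = d = 1 the expectation collapses to exactly 0, a hand-checkable
  identity in the tests. The default flag is `E(IC) > 0`; because published
  screens differ on whether the criterion is the expectation or its lower
  bound, `IC − 2√V(IC)` (an IC025-style bound) is always reported and a
  strict mode flags on it instead.
* **EBGM** here is the relative reporting score `aN/((a+c)(a+b))` with
  `EBGM05 = exp(ln EBGM − 1.95·√(1/a+1/b+1/c+1/d))` — the 1.95 multiplier
  is the convention of the criteria set implemented, kept as is. This is
  *not* the full gamma-Poisson mixture shrinkage estimator sometimes called
  EBGM: small-count scores here are unshrunk, which users comparing against
  MGPS output should keep in mind. Flag: `a > 0` and EBGM05 > 2.

**Zero cells** leave a statistic undefined — no Haldane-style 0.5
correction is applied anywhere, because none is part of the criteria being
implemented; inventing one would change flag behavior at exactly the rare
counts where screening decisions are most fragile. Undefined counts as
not-flagged. The **consensus flag** is the conjunction of all four: highly
specific, deliberately insensitive. Output rows are sorted by descending
ROR with deterministic tie-breaks (larger `a`, then name).

## Time-to-onset model

Included onsets are binned left-open/right-closed over (0,30], (30,60],
(60,90], (90,180], (180,360], >360 days — day 30 falls in the first bin;
the edges are configurable and the convention is fixed so percentages are
reproducible. A two-parameter Weibull is fitted by maximum likelihood via
the accelerated-failure-time parameterization (`survival::survreg`); 95%
intervals come from the observed information on log(shape) and log(scale),
back-transformed so bounds stay positive. There is no censoring model:
FAERS only contains observed events, so the group comparison
(glucocorticoid vs other, from the class column of the drug map) uses
product-limit curves that are empirical distribution complements, tested
with the standard log-rank statistic. Fits are refused below 10
observations or on degenerate (all-equal) data rather than returning
meaningless intervals.

## The synthetic world and what it does (not) show

The generator emits a FAERS-like quarter plus a per-caseid ground-truth
table, and all of its randomness derives from one seed (byte-identical
reruns). Its defaults are fixed once to emulate the study conditions of a
20-year pediatric screen:

* background cataract reporting probability **0.001** per report (the
  real-data case rate is ~0.1%);
* **36%** of caseids carry one superseded version, so removed duplicates are
  ~26.5% of raw rows, matching the observed duplicate burden; 30% of
  duplicates share the kept version's `FDA_DT` so both tie rules are
  exercised;
* pediatric fraction **0.85** with 5% missing ages and units drawn as
  YR/MON/WK/DY/DEC at 55/20/5/15/5%;
* date pathologies **70% missing / 10% incomplete / 1% inconsistent**,
  matching the observed ~72%/9% exclusion pattern of onset data;
* onset times **Weibull(shape 0.72, scale 650 days)**: the shape is the
  published early-failure value and the scale is derived from the published
  52% late-onset fraction, `650 = 360/(ln(1/0.52))^(1/0.72)`, since no
  scale is printed anywhere;
* planted signals act **only through the primary-suspect drug**, with the
  exposed case probability equal to `rate_ratio × p_case` — so for rare
  events the pipeline's ROR should recover the planted rate ratio, which is
  exactly what the recovery tests measure.

Ground truth stores the age the pipeline *will* compute (from the emitted
strings), so truth-vs-pipeline comparisons are exact, not approximate. The
`expected_contingency()` oracle recounts the latent records after ideal
preprocessing; the acceptance suite requires bit-exact agreement with the
real pipeline at 50,000 reports.

What the generator does **not** emulate: real co-prescription structure
(drugs are sampled independently), indication-driven channeling and
confounding by indication, reporting-volume trends over quarters, schema
drift across 20 years of extracts, and the full messiness of verbatim drug
strings (variants are drawn from the packaged map). Passing tests therefore
demonstrate the pipeline's correctness and calibration under independence
and known truth — not that real-data signals are causal, which
disproportionality can never show.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to keep Monte-Carlo
tolerances honest: 50,000-report worlds for oracle equivalence and planted
ρ = 10 recovery over 20 seeds (mean log-ROR within 15% of log ρ); 1,000
null drug–event pairs for the consensus false-positive rate (< 1%); 5,000
Weibull draws for point recovery of shape 0.72 within (0.69, 0.75) and 100
replicates for ≥ 90% CI coverage; 10,000 random tables for 1e-10 agreement
of the Yates χ² with an independently coded reference. The acceptance
script's main world uses 200,000 reports so that several planted signals
express counts above the `a ≥ 3` threshold, mirroring how a rare event
needs a large background.

Other fixed choices: clean generated onsets are capped at the 6,574-day
plausibility bound (affecting ~0.5% of draws at the default scale) so that
"clean" never collides with "implausible"; drug-name normalization
uppercases, collapses punctuation to spaces but preserves `/` as the
combination separator, and is idempotent; combination products are entities
distinct from their components, and designated salt/ester forms (e.g.
prednisolone acetate) remain distinct from the base ingredient via explicit
map rows, because local-ocular and systemic forms of the same steroid carry
very different signal strengths.

## Known limitations

The EBGM column is unshrunk (see above). The BCPNN variance expression is
the standard first-order approximation; at tiny `N` its intervals are
approximate. The Weibull CIs are normal-theory on the log scale, not
profile likelihood. Drug-name harmonization is only as good as the packaged
TSV — unmapped verbatims become their own normalized entities and are
flagged, which fragments counts for drugs missing from the map exactly as
manual harmonization would have before curation. And all results inherit
the fundamental limits of spontaneous reports: no denominators, reporting
bias, and detection lag for an insidious, slowly progressing event in
children who cannot articulate visual symptoms.
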