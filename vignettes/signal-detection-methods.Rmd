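---
title: "Disproportionality signal detection on spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous reporting systems such as FAERS collect voluntarily submitted
case reports of suspected adverse drug reactions. They have no exposure
denominator: we observe how often a drug-event pair is *reported*, never how
often the drug was *taken*. Disproportionality analysis sidesteps the
missing denominator by asking whether a pair is reported more often than
expected given the rest of the database, via a 2x2 table of unique case
reports:

|                | target event | other events |
|----------------|--------------|--------------|
| target drug    | a            | b            |
| other drugs    | c            | d            |

with `N = a + b + c + d`. A flagged pair is a hypothesis for clinical
review, not evidence of causation: reporting is subject to stimulated
reporting, confounding by indication, and channeling, none of which the 2x2
table can see.

## The four statistics

`faersignal` computes the four estimators conventional in pharmacovigilance,
each with a 95% interval and a positivity criterion:

* **ROR** `= ad/bc`, interval
  `exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`;
  positive when the lower bound exceeds 1 and `a ≥ 3`.
* **PRR** `= a(c+d) / c(a+b)` with the 1-df Pearson chi-square
  `N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d))` (no continuity correction);
  positive when `PRR ≥ 2`, `χ² ≥ 4` and `a ≥ 3`.
* **IC** `= log2(aN / ((a+b)(a+c)))`, the information component of the
  BCPNN family — a log2 observed-to-expected reporting ratio; interval
  `E(IC) ± 2·sqrt(V(IC))`; positive when the lower bound (IC025) exceeds 0.
* **EBGM** `= aN / ((a+b)(a+c))`, here the *unshrunk*
  relative-reporting-ratio form, with interval
  `exp(ln EBGM ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`; positive when the
  lower bound (EBGM05) exceeds 2.

Two structural facts follow directly from these definitions and are enforced
as tested invariants: `IC = log2(EBGM)` identically, and for any table with
all cells positive and `ad > bc`, `ROR ≥ PRR ≥ EBGM`.

### Design choices in the statistics

* **V(IC).** The `E(IC) ± 2·sqrt(V(IC))` interval needs a variance, and
  several incompatible conventions circulate. The default here is the
  delta-method dispersion shared by the other intervals, rescaled to log2
  units: `V(IC) = (1/ln 2)²·(1/a + 1/b + 1/c + 1/d)`. The choice is behind a
  strategy argument (`vic_method`) so a fully Bayesian BCPNN posterior
  variance can be added without touching callers. Published IC025 columns
  computed under other conventions will differ; the IC *point* does not.
* **PRR interval.** The standard log-scale delta-method term
  `sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))`.
* **The `a ≥ 3` rule.** The case-count condition in the ROR/PRR criteria is
  read as the cell `a` — the number of target-drug, target-event cases —
  which is the conventional reading in disproportionality practice.
* **Zero cells.** Default behavior is an explicitly flagged undefined result
  that always classifies negative; the Haldane–Anscombe `+0.5` correction is
  available (`haldane = TRUE`) but off by default, because silently finite
  estimates from empty cells invite over-reading.
* **No multiplicity adjustment** across events is applied, matching standard
  signal-detection practice for these four criteria; users scanning
  thousands of PTs should treat the flags as a screening ranking.
* **Rounding.** Report writers round to 2 decimals; all internal computation
  and all returned tibbles are full precision.

### What this EBGM is and is not

The multi-item gamma-Poisson shrinker (MGPS) defines EBGM through an
empirical-Bayes two-component gamma mixture; its hallmark is shrinkage of
small-count cells toward 1. The formula implemented here, `aN/((a+b)(a+c))`,
is the raw observed-to-expected ratio (the MGPS numerator before shrinkage),
so small-count pairs are *not* shrunk and EBGM05 for them is wider, not
pulled in. This is deliberate: the formula is implemented exactly as used in
the analyses this package reproduces.

## Ingest and cleaning

The `$`-delimited quarterly ASCII distribution is the supported dialect
(delimiter configurable); DEMO, DRUG, REAC and OUTC are each mandatory per
quarter, malformed rows and unparseable dates are counted in per-stage logs
rather than silently dropped.

* **Deduplication.** FAERS resubmits updated versions of a case. One record
  per `caseid` is kept: latest receipt date, ties broken by the larger
  version id, then by the later file position — deterministic, idempotent,
  and applied across the whole ingested span rather than per quarter,
  because resubmissions routinely cross quarter boundaries.
* **Drug normalization.** A synonym dictionary (uppercase-trimmed,
  whitespace-collapsed, punctuation-stripped matching) maps verbatims to
  ingredient concepts; absent verbatims map to an explicit `UNMAPPED`
  sentinel. This is a deliberately small stand-in for RxNorm-scale
  normalization — the interface, not the vocabulary, is the point.
* **Reaction terms.** REAC verbatims resolve against a PT/SOC hierarchy
  fixture shaped like MedDRA's two analytically used levels (a licensed
  MedDRA distribution cannot be shipped). Unknown terms are an error by
  default, because silently losing reactions corrupts `b` and `d`; an
  `UNKNOWN` bucket is available by configuration.
* **Ages** normalize to years (MON/12, WK/52.18, DY/365.25, HR/8766;
  missing unit means years). Age bands are closed on both printed endpoints
  with fractional ages floored, so "20–39" is `20 ≤ floor(age) ≤ 39`.
* **Counting unit.** All tables count unique cases: a case with a PT listed
  twice, or two PTs in the same SOC, contributes once per cell. The default
  exposure definition is the primary-suspect role only (`role_filter =
  "PS"`), configurable to any role set. Because published corpus sizes mix
  counting units, `corpus_counts()` exposes case-level and pair-level counts
  side by side rather than privileging one.

## The synthetic corpus

Real FAERS quarters are a multi-gigabyte download; the package instead ships
a generator emitting the same quarterly layout with known ground truth, so
the full pipeline — parsing, joining, deduplication, normalization,
aggregation, statistics — runs end to end in tests and examples.

Each case draws demographics (with configurable missingness), one or more
drug mentions with role codes, one or more PT reactions, serious-outcome
codes, and optionally a second, later-dated, otherwise value-identical
version (exercising exactly the dedup key and nothing else). Default
marginals are set to values typical of a drug-centred FAERS extract:
predominantly female reporting (about 65% of known-gender cases), over half
of ages missing, a US-dominated country mix, and hospitalization as the most
common serious outcome at about 12% — the shape of real
characteristics tables, not a fit to any particular corpus.

**Implantation semantics.** An implanted pair `(drug, PT, ρ)` multiplies the
PT's baseline probability by ρ among cases exposed to the drug, capped at 1,
leaving all other PTs untouched, so the true reporting-rate ratio equals ρ
exactly whenever uncapped. Cases whose sampled reaction set comes out empty
receive a dedicated filler PT ("Drug ineffective", mirroring the most
reported term in real spontaneous data) rather than a resampled catalog
term; conditioning on "at least one reaction" by resampling would bias
realized reporting ratios away from ρ, while a non-implantable filler keeps
them exact. The generator uses a single seeded stream and restores the
caller's RNG state; fixed config implies byte-identical files.

**What the generator does not emulate:** drug co-prescription correlation,
temporal reporting trends, country-specific reporting cultures, duplicate
records that differ in content, and stimulated-reporting bursts. Passing
tests therefore demonstrate correctness of the pipeline's mechanics and
estimator calibration under independence — not robustness to the
confounding structure of real pharmacovigilance data.

## Test problem sizes and calibration checks

The suite runs three statistical experiments, with sizes chosen to give the
binomial arithmetic room to discriminate:

* **Pipeline closure** at n = 1,000 cases with 10–12% duplicates: assembly
  must reproduce the generator's distinct-case count, per-case reaction
  sets, and role codes exactly.
* **Null calibration** at n = 2,000 and n = 20,000 with no implanted pair:
  the fraction of `a ≥ 3` pairs flagged PRR-positive must be small and not
  grow with corpus size (at PRR's truth of 1, the `PRR ≥ 2` condition gets
  strictly harder as counts grow).
* **Parameter recovery** at n = 50,000, 100 replicates per ρ ∈ {2, 5, 10}:
  the EBGM interval must cover ρ in at least 90% of replicates. The
  experiment uses a 0.5%-exposure target drug and a 2%-baseline event. That
  choice is a power calculation, made before running the suite: with common
  exposure the observed-to-expected ratio's finite-database attenuation
  (`ρ/(1 + P(drug)(ρ − 1))`) shifts the interval off ρ by more than its
  width, and nominal coverage is unattainable for any estimator of this
  form; at 0.5% exposure the attenuation for ρ = 10 is about 4% against an
  interval half-width of about 37%, so the 90% criterion tests estimator
  correctness rather than the attenuation artifact.

## Known limitations

* The hierarchy and dictionary fixtures are toys; real analyses must supply
  MedDRA and RxNorm-derived tables in the same two-CSV shapes.
* No stratified (age/sex/period) tables, no shrinkage EBGM, no
  cross-database validation — out of scope by design.
* The FAERS XML dialect is not parsed.
* `reconstruct_table()` assumes its published inputs were internally
  consistent and printed with `ROR > PRR > 1`; heavily rounded rows
  reconstruct cells only to within rounding error.
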