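---
title: "Methods: vitamer-level food composition and dietary intake estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vitamer-level food composition and dietary intake estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitDintake)
```

## The problem

Dietary vitamin D activity comes from four vitamers: vitamin D3 (vitD3),
vitamin D2, and their 25-hydroxylated metabolites 25(OH)D3 and 25(OH)D2.
Food composition databanks have historically carried only vitD3 and vitD2,
yet 25(OH)D3 contributes a substantial fraction of the activity in several
animal foods (most of it in veal, around a quarter of children's total
dietary intake). This package provides the computational machinery for
working at the vitamer level:

1. a **composition layer** — left-censored measurements, composite-food
   derivation, censoring-aware summaries;
2. an **intake engine** — recipe decomposition with market-share weights,
   per-person 7-day diary intake, scenario substitution, age-group
   summaries;
3. a **statistics layer** — one- and two-factor ANOVA (including
   reconstruction from published group summaries), Tukey HSD, regression;
4. a **synthetic diary generator** with closed-form expected intake, so the
   engine can be validated without access to survey microdata.

## Censoring model

Analytical methods for vitamin D vitamers have limits of quantification
(LOQ) between 0.003 and 0.1 µg/100 g depending on matrix and detector. A
measurement below the LOQ is stored as a censored `vitamer_quantity`
(written `"<0.01"` in files) and enters every downstream computation at
**50% of the LOQ** — a single substitution rule used everywhere (summaries,
mixtures, aggregations, intake) so that results remain auditable. Group
summaries are refused (returned as undefined) when **more than 25%** of the
inputs are censored: with that much censoring a substituted mean mostly
reflects the LOQ, not the food. The boundary is inclusive: exactly 25%
censored is still summarised.

## Composite foods

All composite-food rules are linear operations on censor-substituted
contents, per 100 g edible portion:

- **Mixtures** (`mixture_profile`): content of the composite is the
  mass-fraction-weighted sum of component contents; fractions must sum
  to 1 within 1e-9 (inputs are text files with at most ~6 printed
  decimals, so anything beyond that tolerance is a data error, not
  rounding). Fat combines the same way, but only when every component
  carries a fat percentage — fat is never imputed from vitamer values.
  Example: 10%-fat minced pork as 92% lean meat + 8% subcutaneous fat.
- **Part aggregation** (`aggregate_parts`): identical to a mixture with
  fractions proportional to part masses; inedible parts (bone) are
  excluded simply by omission, e.g. a chicken thigh with skin from 133 g
  thigh meat + 21 g skin.
- **Yolk correction** (`yolk_to_whole_egg`): egg vitamers are analysed in
  yolk and scaled by the yolk's mass share (0.33) of the whole egg;
  censored slots stay censored with the LOQ scaled by the same factor,
  since scaling a bound gives a bound.
- **Fat-based prediction** (`fat_predict`): in milk, yoghurt, cream and
  spreadable butter, vitD3 and 25(OH)D3 scale with fat content through the
  origin; the packaged dairy model carries slopes 0.0031 and 0.0012
  µg/100 g per % fat. The slopes are data, not constants: they were fitted
  on the underlying composite samples, and refitting on the rounded
  published means gives different values (0.0025/0.0009), so the package
  ships them rather than re-deriving them. Users can fit their own with
  `linregress(..., zero_intercept = TRUE)`.

Internal computation is always full precision. For display and comparison
with published tables the package rounds **half away from zero**
(`round_half_up`) at the table's printed precision (2 decimals for
µg/100 g; 3 where tables print 3). Two published thigh-with-skin vitD3
cells (0.18 Danish, 1.00 French) cannot be recovered from the rounded
part means (which give 0.19 and 1.05) — they were evidently computed from
unrounded means — so the package documents them as non-reproducible and
its checks target only the arithmetically consistent cells.

## Vitamin D activity and shares

Total activity is `vitD3 + f × 25(OH)D3` with conversion factor `f = 1` by
default (the equipotency assumption supported by current reviews). The D2
vitamers are usually below 0.05 µg/100 g and are excluded unless
`include_d2 = TRUE`. Bioassay work suggests `f` between 1.4 and 1.7, and
some databanks have used 5; `activity_config(factor_f = ...)` explores
these. Vitamer **shares** are always computed on unconverted micrograms —
`100 × ohd3 / (vitd3 + ohd3)` — so they do not depend on `f`.

## Intake engine

Consumption is a tibble of events: person, age (4–75 years), day (1–7),
meal slot (breakfast/lunch/dinner/snack), food or recipe reference, grams.
Recipes form an acyclic graph of variants (market-share weights) over
components (mass proportions); `flatten_recipe` resolves a reference to
effective ingredient fractions as the path-sum of weight × proportion
products. Cycles are a hard error naming the loop — a truncated cycle
would silently lose mass.

Per-person daily intake of each vitamer is the 7-day total divided by
**exactly 7**, not by days with events: the survey design fixes the
recording window, and an empty day is genuine zero consumption.
Age groups are children = [4, 17] and adults = [18, 75], both inclusive;
ages outside the range are rejected at load rather than silently binned.

Population summaries report mean ± SD per age group. The headline
25(OH)D3 share is **pooled** (ratio of group mean intakes — the share of
the group's total consumption, matching how population-level percentage
splits are usually reported); the mean of per-person shares is reported
alongside, since the two differ under between-person heterogeneity.

Scenarios are override tables mapping food ids to replacement profiles
(`apply_scenario` is non-mutating and marks overridden records with
provenance `scenario_override`). `compare_scenarios` runs identical
diaries against each table, which isolates the composition effect.

## Statistics layer

The published composition tables report group means, SDs and sample
sizes. Those are sufficient statistics for the one-way fixed-effects
ANOVA, so `anova_from_summaries` reconstructs the F test directly:
SSB = Σ nᵢ(x̄ᵢ − x̄)², SSW = Σ (nᵢ−1)sᵢ². On summaries computed from raw
groups this is exact (tested to 1e-9 against the raw-data route); on
*rounded published* summaries the recovered p-value is approximate —
checks against published p-values use ±0.02 absolute. All variances are
sample (n−1), matching published SDs. Degenerate inputs (all groups
identical with zero spread) return F = 0, p = 1 by convention.

The two-factor ANOVA is **additive** (no interaction): the analyses it
reproduces report per-factor conclusions only, and with one observation
per chicken per cut an interaction would consume the error degrees of
freedom. It uses sequential (Type-I) sums of squares via least-squares
projections, and Tukey–Kramer HSD pairwise comparisons on the
studentized range distribution with the additive model's residual mean
square. P-values come from the exact F, t and studentized-range
distributions, not permutation, matching the original spreadsheet-era
practice.

## Synthetic diary generator

The generator emulates the *structure* of a 7-day precoded meal-slotted
dietary survey, not its empirical frequencies:

- ages: a two-point child/adult mixture, default 25% children (roughly
  the child share of a general population), integer-uniform within
  4–17 / 18–75;
- consumption: each of the 7 × 4 person-day-slots includes each candidate
  food independently with a per-food probability;
- amounts: lognormal, default `meanlog = log(50)`, `sdlog = 0.6` (median
  portion 50 g, right-skewed, strictly positive).

Each person has a private RNG stream seeded by a fixed integer mix of the
base seed and the person index, so growing the population leaves existing
persons untouched. Expected daily intake has the closed form
`Σ_foods 4 × p × exp(meanlog + sdlog²/2) × content/100`, with recipe
references flattened exactly as the intake engine flattens them; the
empirical population mean is validated against this within 3 standard
errors at n = 1000. The measurement-sample generator draws truncated-at-zero
normals (default CV 10%, the analytical methods' precision) and censors
draws below the LOQ.

What passing these checks shows: the bookkeeping from composition tables
through recipes to population summaries is correct and unbiased. What it
does **not** show: anything about real consumption patterns — the
generator has no day-of-week effects, no food-pairing structure, no
person-level preference heterogeneity, and the packaged ingredient table
is a representative stand-in (the real survey used up to 436 ingredients,
137 contributing vitamin D, from non-public records). Published population
intake estimates therefore cannot be reproduced from this package alone;
the scenario engine is instead validated by identity and scaling laws
(an empty override changes nothing; doubling all contents doubles intakes
and leaves shares fixed).

## Problem sizes and numerical choices

The validation suite uses a 1000-person synthetic population (the
standard-error bound is tight enough there to detect percent-level bias),
random recipe graphs to depth 4 and fan-out 4, and the packaged
composition tables; everything runs in seconds. Tolerances: 1e-9 for
fraction sums and oracle equivalences (text-file inputs), 1e-12 for pure
linear-algebra identities, ±0.02 for p-values recovered from rounded
summaries. Ties in nothing: all operations are deterministic, and file
round-trips preserve censoring state byte-for-byte.

## Known limitations

- No cooking losses or retention factors; contents are raw edible-portion
  values.
- No survey weighting, usual-intake deconvolution or under-reporting
  adjustment.
- Seasonality is represented only as distinct records (e.g. summer vs
  early-spring pork), not modelled.
- The scenario-2/3 override fixtures are illustrative examples; real
  scenario analyses should supply override files built from the relevant
  feeding-trial literature.
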