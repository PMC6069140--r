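---
title: "Deriving water screening values for pharmaceuticals: the method behind pharmwsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving water screening values for pharmaceuticals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmwsv)
```

## The problem

Hundreds of active pharmaceutical ingredients (APIs) are detected in
ambient and source waters, yet very few have health-based guidance
values that say what concentration in drinking water is of negligible
concern. Full toxicological reviews are slow and most of the underlying
study data are proprietary. The rapid-assessment framework implemented
here trades depth for coverage: it derives a *screening* reference dose
(sRfD) and a *water screening value* (WSV) for an API from structured
evidence that can be curated off an FDA-approved drug label in hours,
not months. The resulting values are deliberately conservative — they
are for prioritisation and for giving context to monitoring detections,
not for regulatory limits.

## The model

The derivation is a chain of four steps, each of which this package
exposes as a function.

**1. Point of departure: the lowest therapeutic dose.** The lowest
labelled dose that produces a clinically effective outcome (LTD) is
taken as the point of departure and treated as analogous to a LOAEL —
for the general population, any therapeutic effect is an unwanted
effect, and labels rarely report what happens below the therapeutic
range. Doses are normalised to a full 24-hour amount (a 10 mg tablet
four times daily is 40 mg/day) and divided by a mean body weight:

$$\mathrm{LTD\ (mg/kg\text{-}d)} = \frac{\text{dose (mg/day)}}{BW(\text{age})\ \text{(kg)}}$$

The body-weight table has twelve one-year brackets from 6–7 to 17–18
years plus 80 kg for adults; when a label names an age range, every
covered bracket is evaluated and the minimum quotient wins (usually the
heaviest bracket). Doses already labelled in mg/kg-day pass through
untouched. Special-population schedules (renal or hepatic impairment,
titrated dosing) are never used. `compute_ltd()` implements this;
`body_weight_table()` ships the weights.

**2. Six uncertainty/adjustment factors.** A decision tree assigns six
factors, each 1, 3 or 10, from the curated evidence
(`assign_all_factors()`):

| factor | meaning | values |
|---|---|---|
| `AF_C` | threshold-carcinogenicity adjustment | 1 or 10 |
| `AF_E` | endocrine-activity adjustment | 1, 3 or 10 |
| `UF_Human` | intraspecies variability | always 10 |
| `UF_L_N` | LOAEL-to-NOAEL extrapolation | 3 (default) or 10 |
| `UF_DB` | database deficiencies | 1, 3 or 10 |
| `UF_S_C` | duration of use | 1, 3 or 10 |

The LOAEL factor is never 1 because the LTD is an effect level by
construction. It rises to 10 on any of six label signals: pregnancy
category D or X; category C with the LTD near the reproductive-study
dose; a life-threatening indication; missing or divergent paediatric
testing; serious effects at the LTD; or a relevant boxed warning. When
several fire, all are logged but the factor is applied once.

The two novel adjustment factors are mutually exclusive in the product:
when the cancer factor exceeds 1 it is applied and the endocrine factor
is noted but not multiplied in (`resolve_cancer_endocrine()`). This
avoids stacking two factors that often reflect the same biology.
Genotoxic/non-threshold carcinogens are out of scope entirely — they
need a slope factor, not factor division — and are rejected at the
eligibility screen together with non-oral, OTC-only, supplement,
illicit, discontinued and veterinary-only products
(`screen_eligibility()`). A curator override exists for discontinued
products whose data gaps can be filled from supplementary sources,
because the original assessment itself retained five such compounds.

**3. Half-log combination.** Factors combine on a half-log lattice: 1
contributes exponent 0, 3 contributes 0.5 (treating 3 as
$10^{0.5}$), 10 contributes 1. An integral exponent sum displays as
$10^e$; a half ends in a leading 3, so $3\times3=10$ and
$3\times10=30$. `combine_factors()` stores the exponent, not the
product, so repeated combination accrues no floating drift, and the
display rule (`3`, never `3.16`) matches risk-assessment convention.
The attainable total runs from 30 (intraspecies 10 × default LOAEL 3)
to 100,000; the engine permits the maximum but warns, since
non-overlapping decision criteria make it implausible.

**4. sRfD and WSV.**

$$\mathrm{sRfD} = \frac{\mathrm{LTD}}{(\mathrm{AF_C}\ \text{or}\ \mathrm{AF_E})\times \mathrm{UF_{Human}}\times \mathrm{UF_{L\text{-}N}}\times \mathrm{UF_{DB}}\times \mathrm{UF_{S\text{-}C}}}$$

$$\mathrm{WSV\ (\mu g/L)} = \frac{\mathrm{sRfD}\times \mathrm{RSC}\times 1000\ (\mu g/mg)}{0.289\ \mathrm{(L/kg\text{-}d)}}$$

0.289 L/kg-d is the 95th-percentile water intake of a bottle-fed infant
aged 1–3 months — the most highly exposed life stage per unit body
weight. The relative source contribution (RSC) is 0.8 by default (a
non-patient's exposure is assumed to come mostly through water) and 0.2
for APIs with widespread paediatric over-the-counter use
(`select_rsc()`), where unintended additional intake is a real concern.

## Numerical conventions

The published value table dictates two conventions that the package
treats as part of the method:

* **Significant figures, half away from zero, in decimal.** sRfDs are
  reported to 2 significant figures and WSVs to 1. Ties round away
  from zero, and rounding is decimal-intent: `round_sig()` works on an
  integer mantissa with a one-part-in-10⁹ guard against binary
  representation error, so 0.0125 at 2 figures is 0.013 (base R's
  `signif()`, which rounds half to even in binary, would give 0.012).
* **Two-stage rounding.** The WSV is computed *from the rounded sRfD*,
  not from the raw quotient. The order is observable: an LTD of 12.5
  over a total of 1000 gives sRfD 0.013 and hence WSV 40; the raw
  quotient 0.0125 would give 34.6 → 30. The packaged amoxicillin row
  prints 40, certifying the two-stage order. LTDs themselves are
  reported to 3 significant figures, and the rounded LTD feeds the sRfD
  division — the convention that reproduces the packaged table.

Both conventions, together with the constants, live in `wsv_config()`
and can be overridden explicitly for sensitivity analysis (for example
a 0.070 L/kg-d subchronic intake); any override is echoed into the
provenance header of result files.

Other numerical choices: age ranges are closed-open one-year brackets,
so a range of 12–18 years covers the six brackets 12–13 through 17–18
and an open-ended adult range covers the single 80 kg bracket; ties
between candidate LTDs keep the first schedule in label order; a total
factor supplied as a bare number is checked against the half-log
lattice and rejected otherwise; eligibility reports the *first*
matching exclusion criterion in the fixed screening order (the source
method does not state a precedence, so the table order is this
package's convention) while logging all matches.

## The packaged published data and validation

The package ships the published 119-compound value table
(`published_wsv_table()`), the five-compound comparison against
in-depth health-based guidance (`published_hbg_table()`), the
body-weight table, and a frozen discrepancy list
(`known_discrepancies()`). Validation is strictly one-directional:
`validate_published()` recomputes the sRfD from each row's LTD and
total factor, and the WSV from the *printed* sRfD and RSC, then
compares. The packaged numbers are never altered. Under the
conventions above, 117 of 119 rows reproduce exactly; the two that do
not (doxepin's sRfD, printed 0.00032 where 0.94/3000 rounds to
0.00031, and norfloxacin's WSV, printed 10 where the printed sRfD
yields 9) are recorded in the frozen list with their recomputed
values. Three comparison-table entries (both acetaminophen dose bases,
17a-ethinylestradiol, venlafaxine) do not reproduce from their printed
inputs under the equations; they ship flagged `inconsistent_as_printed`
rather than silently repaired. The published prose also states a WSV
range extending to 400 µg/L while the table's maximum is 300;
`aggregate_stats()` reports what the table contains.

## The synthetic-profile generator

`generate_synthetic_profiles()` draws schema-valid evidence profiles
uniformly over the closed vocabularies, with 1–3 dose schedules per
profile, label-realistic dose ranges (0.5–500 mg per administration,
0.01–30 mg/kg-day for per-kg labels), mostly adult dosing, and
cross-field invariants respected. It emulates the *structure* of
curated label evidence — every enumeration value occurs, eligible and
excluded profiles both arise, and the whole factor lattice is
exercised. It does not emulate the *joint distribution* of real labels:
real evidence fields are correlated (short-term-use antibiotics cluster
with missing chronic studies; endocrine-active compounds cluster with
pregnancy warnings), and real dose magnitudes span a wider, skewed
range. Property tests over generated profiles therefore demonstrate
rule-engine correctness — totals on the half-log lattice within
[30, 100,000], factor monotonicity under evidence strengthening,
cancer/endocrine exclusivity, serialization round-trips — but say
nothing about the field-level accuracy of any real curation, which is
established instead by reproducing the packaged published table.

Test and validation problem sizes: the exhaustive factor-combination
check covers all 3⁶ = 729 value combinations against a brute-force
product oracle; invariant sweeps use 10,000 generated profiles; the
published-table validation covers all 119 rows.

## Known limitations

* The framework applies only to orally administered, non-genotoxic
  prescription APIs; everything else is screened out, and no
  route-to-route extrapolation is attempted.
* Evidence profiles are curated inputs. The package validates them
  structurally (closed vocabularies, cross-field invariants, a JSON
  schema ships in `inst/extdata/`) but cannot detect a wrong curation
  judgement, and it does not parse label text.
* The RSC decision is the binary the method actually used (0.8, or 0.2
  for paediatric-OTC compounds), not a full exposure decision tree.
* Class-level read-across (statins, sulfonamides, tetracyclines in the
  original assessment) is expressed through the evidence fields a
  curator fills in; the package does not infer drug classes.
* Screening values contextualise human ingestion only; they are not
  protective of ecological receptors, and a detection above a WSV is a
  prioritisation signal, not a risk determination.

## A worked derivation

```{r}
profile <- evidence_profile(
  "Sulfamethoxazole", casrn = "723-46-6",
  regimens = list(dose_regimen(4.57, units = "mg_per_kg_day",
                               age_min_years = 0)),
  endocrine = endocrine_evidence("intended_therapeutic_effect"),
  pregnancy_category = "D",
  database_completeness = "missing_key_study",
  duration_profile = "short_term_use")

derive_screening_values(profile)
```

The factor trace shows the endocrine adjustment of 10 (a known drug
class effect on the thyroid), the LOAEL factor at 10 (pregnancy
category D), the database factor at 3 (missing multigenerational
study), the duration factor at 10 (an antibiotic intended for
short-term use), and the constant intraspecies 10 — a total of 30,000
on the half-log lattice, an sRfD of 0.00015 mg/kg-d, and a WSV of
0.4 µg/L, matching the published comparison row.
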