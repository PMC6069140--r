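# pharmwsv

Rapid derivation of drinking-water screening values for active
pharmaceutical ingredients (APIs).

Hundreds of APIs are detected in source and finished drinking water,
but almost none have health-based guidance values. `pharmwsv`
implements a rapid risk-assessment framework that derives a screening
reference dose (sRfD) and a water screening value (WSV) for an API
from structured evidence curated off its FDA-approved drug label. The
audience is risk assessors and environmental-health scientists who
need defensibly conservative numbers for prioritising monitoring
detections, not definitive risk estimates.

## The method in brief

The lowest therapeutic dose (LTD, mg/kg-day) — the smallest labelled
dose with a clinically effective outcome, normalised to a full 24-hour
amount and divided by an age-appropriate mean body weight — serves as
the point of departure and is treated as a LOAEL. A decision tree then
assigns six uncertainty/adjustment factors, each 1, 3 or 10:

```
sRfD (mg/kg-d) = LTD / [(AF_C or AF_E) × UF_Human × UF_L-N × UF_DB × UF_S-C]
WSV  (µg/L)    = sRfD × RSC × 1000 (µg/mg) / 0.289 (L/kg-d)
```

`AF_C` (threshold carcinogenicity) and `AF_E` (endocrine activity) are
mutually exclusive in the product; `UF_Human` (intraspecies
variability) is always 10; `UF_L-N` (LOAEL-to-NOAEL) is 3 by default
and 10 on specific label signals; `UF_DB` and `UF_S-C` cover database
gaps and duration of use. Factors combine with half-log arithmetic
(3 counts as 10^0.5, so 3 × 3 = 10 and 3 × 10 = 30), giving totals
from 30 to 100,000. The relative source contribution (RSC) is 0.8, or
0.2 for APIs with widespread paediatric over-the-counter use, and
0.289 L/kg-d is the 95th-percentile intake of a bottle-fed infant.
sRfDs are reported to 2 significant figures, WSVs to 1, rounding half
away from zero in decimal, with the WSV computed from the already
rounded sRfD.

The package ships the published 119-API screening value table and
recomputes it as a standing cross-check (117/119 rows reproduce
exactly; the two exceptions are frozen in a known-discrepancy file),
plus a five-API comparison against guidance values from full in-depth
reviews.

## Worked example

Sulfamethoxazole: an antibiotic (short-term use, 10), with thyroid
effects as a known class effect (endocrine adjustment 10), pregnancy
category D (LOAEL factor 10), and no multigenerational reproductive
study on the label (database factor 3).

```r
library(pharmwsv)

profile <- evidence_profile(
  "Sulfamethoxazole", casrn = "723-46-6",
  regimens = list(dose_regimen(4.57, units = "mg_per_kg_day",
                               age_min_years = 0)),
  endocrine = endocrine_evidence("intended_therapeutic_effect"),
  pregnancy_category = "D",
  database_completeness = "missing_key_study",
  duration_profile = "short_term_use")

derive_screening_values(profile)
#> <screening_result> Sulfamethoxazole
#>   LTD 4.57 mg/kg-day | total UF/AF 30,000 | sRfD 0.00015 mg/kg-day
#>   RSC 0.8 | WSV 0.4 ug/L
```

The total of 30,000 is the half-log product 10 × 10 × 10 × 3 × 10
(exponent 4.5 → 3 × 10^4). Dividing the LTD of 4.57 mg/kg-day by it
gives an sRfD of 0.00015 mg/kg-d; scaling by the 0.8 RSC and infant
intake gives a WSV of 0.4 µg/L — a detection of sulfamethoxazole below
0.4 µg/L is unlikely to pose a health concern through water ingestion.
Every rule firing is retained in `$trace`:

```r
cat(derive_screening_values(profile)$trace, sep = "\n")
#> LTD=4.57 mg/kg-day (regimen 1)
#> AF_C=1(noted):AF_C.none_reported
#> AF_E=10:AF_E.intended_therapeutic_effect
#> UF_Human=10:UF_Human.default
#> UF_L_N=10:UF_L_N.pregnancy_D_or_X
#> UF_DB=3:UF_DB.missing_key_study
#> UF_S_C=10:UF_S_C.short_term_use
#> total_UF_AF=30000
#> sRfD=0.00015 mg/kg-day
#> RSC=0.8
#> WSV=0.4 ug/L
```

The packaged published table and its validation:

```r
validate_published()
#> <validation_report> 117/119 records reproduce
#>   discrepancies:
#>    - Doxepin: sRfD 0.00032 vs 0.00031, WSV 0.9 vs 0.9
#>    - Norfloxacin: sRfD 0.0033 vs 0.0033, WSV 10 vs 9
```

Monitoring detections screen against the table with
`contextualize_detections()`; a command-line surface
(`exec/pharmwsv`, subcommands `derive`, `validate`, `context`,
`stats`, `fixtures`) wraps the same functions for shell use, e.g.:

```sh
Rscript exec/pharmwsv stats
#> records:      119
#> LTD range:    0.0013 - 25 mg/kg-d
#> sRfD range:   1.6e-07 - 0.11 mg/kg-d
#> WSV range:    0.0004 - 300 ug/L
#> total UF/AF:  100 - 30,000
```

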