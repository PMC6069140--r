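# Fixture builders used across the suite.  All fixtures are built in
# code; per-kg regimens use age_min 0 because per-kg labels need no
# body-weight bracket.

per_kg_regimen <- function(ltd) {
  dose_regimen(ltd, units = "mg_per_kg_day", age_min_years = 0)
}

# A profile with no elevating evidence: every factor at its floor
# (AF_C 1, AF_E 1, UF_Human 10, UF_L-N 3, UF_DB 1, UF_S-C 1, total 30).
minimal_profile <- function(ltd = 1) {
  evidence_profile("minimal-fixture", regimens = list(per_kg_regimen(ltd)))
}

# Inputs of the published sulfamethoxazole comparison row: LTD 4.57,
# AF_E 10, UF_Human 10, UF_L-N 10, UF_DB 3, UF_S-C 10, RSC 0.8.
sulfamethoxazole_profile <- function() {
  evidence_profile(
    "Sulfamethoxazole", casrn = "723-46-6",
    regimens = list(per_kg_regimen(4.57)),
    endocrine = endocrine_evidence("intended_therapeutic_effect"),
    pregnancy_category = "D",
    database_completeness = "missing_key_study",
    duration_profile = "short_term_use")
}

# Inputs of the published carbamazepine comparison row: LTD 1, AF_C 10,
# UF_Human 10, UF_L-N 10, UF_S-C 3, RSC 0.8.
carbamazepine_profile <- function() {
  evidence_profile(
    "Carbamazepine", casrn = "298-46-4",
    regimens = list(per_kg_regimen(1)),
    carcinogenicity = cancer_evidence("threshold_hed_near_or_below_mrhd"),
    pregnancy_category = "D",
    duration_profile = "chronic_tested_new_to_market")
}

# Ibuprofen-like profile: OTC paediatric formulations select RSC 0.2.
otc_pediatric_profile <- function(ltd = 20) {
  evidence_profile(
    "ibuprofen-like", regimens = list(per_kg_regimen(ltd)),
    pregnancy_category = "D",
    database_completeness = "missing_key_study",
    duration_profile = "short_term_use",
    otc_pediatric_use = TRUE)
}

# Evidence-strength ladders used by the monotonicity properties: within
# each field, later entries never yield a smaller factor.
strength_ladders <- list(
  cancer = c("none_reported", "threshold_hed_near_or_below_mrhd"),
  endocrine = c("none", "animal_positive_human_negative",
                "intended_therapeutic_effect"),
  database = c("complete", "missing_key_study", "no_or_minimal_animal_data"),
  duration = c("chronic_fully_tested_no_concern",
               "chronic_tested_new_to_market", "short_term_use"),
  pregnancy = c("A", "D")
)
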