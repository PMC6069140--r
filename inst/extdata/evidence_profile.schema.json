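{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Evidence profile",
  "description": "Curated, label-derived facts about one active pharmaceutical ingredient, as consumed by the screening-value derivation. The closed enumerations mirror wsv_vocabulary in the pharmwsv package; the package constructors are the authoritative validator.",
  "type": "object",
  "required": ["api_name"],
  "properties": {
    "api_name": {"type": "string", "minLength": 1},
    "casrn": {"type": ["string", "null"]},
    "route": {"enum": ["oral", "non_oral"]},
    "regimens": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["amount_mg"],
        "properties": {
          "amount_mg": {"type": "number", "exclusiveMinimum": 0},
          "administrations_per_day": {"type": "integer", "minimum": 1},
          "age_min_years": {"type": "number", "minimum": 0},
          "age_max_years": {"type": ["number", "string"]},
          "units": {"enum": ["mg_per_day_total", "mg_per_administration",
                             "mg_per_kg_day"]},
          "special_population_only": {"type": "boolean"}
        }
      }
    },
    "product_status": {"enum": ["prescription", "otc_only",
      "nutritional_supplement", "illicit", "discontinued_or_unapproved",
      "veterinary_only"]},
    "cancer_finding": {"enum": ["none_reported",
      "threshold_hed_near_or_below_mrhd", "threshold_hed_far_above_mrhd",
      "tumor_type_not_human_relevant", "site_of_administration_only",
      "non_threshold_or_genotoxic"]},
    "cancer_hed_mg_per_kg_day": {"type": ["number", "null"],
                                 "exclusiveMinimum": 0},
    "cancer_mrhd_mg_per_kg_day": {"type": ["number", "null"],
                                  "exclusiveMinimum": 0},
    "endocrine_finding": {"enum": ["none", "animal_positive_human_negative",
      "small_insignificant_hormone_changes",
      "frequent_postmarket_only_animal_negative",
      "infrequent_human_no_animal_support", "intended_therapeutic_effect",
      "warnings_or_pharmacodynamics_section",
      "adverse_reaction_causing_discontinuation",
      "hormonal_lab_monitoring_required", "frequent_with_animal_support",
      "aggravation_only", "rare_effect_only", "masks_endocrine_disease"]},
    "pregnancy_category": {"enum": ["A", "B", "C", "D", "X", "none_stated"]},
    "category_c_ltd_near_reprotox_dose": {"type": "boolean"},
    "black_box_warning_relevant": {"type": "boolean"},
    "life_threatening_indication": {"type": "boolean"},
    "not_tested_in_children_or_different_pediatric_profile":
      {"type": "boolean"},
    "serious_effects_at_ltd": {"type": "boolean"},
    "database_completeness": {"enum": ["complete", "missing_key_study",
                                       "no_or_minimal_animal_data"]},
    "duration_profile": {"enum": ["chronic_fully_tested_no_concern",
      "chronic_untested_long_human_history",
      "chronic_tested_duration_related_risk", "chronic_tested_new_to_market",
      "short_term_use", "subchronic_limited_chronic_testing",
      "chronic_limited_testing_severity_increases"]},
    "otc_pediatric_use": {"type": "boolean"},
    "discontinued_override": {"type": "boolean"},
    "label_source": {"type": ["string", "null"]}
  }
}
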