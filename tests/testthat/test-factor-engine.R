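test_that("cancer adjustment factor follows the HED/MRHD comparison", {
  expect_equal(assign_cancer_af(
    cancer_evidence("threshold_hed_near_or_below_mrhd"))$value, 10)
  for (finding in c("none_reported", "threshold_hed_far_above_mrhd",
                    "tumor_type_not_human_relevant",
                    "site_of_administration_only"))
    expect_equal(assign_cancer_af(cancer_evidence(finding))$value, 1)
  expect_error(assign_cancer_af(
    cancer_evidence("non_threshold_or_genotoxic")), "ineligible")
})

test_that("endocrine adjustment factor maps each finding to its tier", {
  tier10 <- c("intended_therapeutic_effect",
              "warnings_or_pharmacodynamics_section",
              "adverse_reaction_causing_discontinuation",
              "hormonal_lab_monitoring_required",
              "frequent_with_animal_support")
  tier3 <- c("animal_positive_human_negative",
             "small_insignificant_hormone_changes",
             "frequent_postmarket_only_animal_negative",
             "infrequent_human_no_animal_support")
  tier1 <- c("none", "aggravation_only", "rare_effect_only",
             "masks_endocrine_disease")
  for (f in tier10)
    expect_equal(assign_endocrine_af(endocrine_evidence(f))$value, 10)
  for (f in tier3)
    expect_equal(assign_endocrine_af(endocrine_evidence(f))$value, 3)
  for (f in tier1)
    expect_equal(assign_endocrine_af(endocrine_evidence(f))$value, 1)
  expect_setequal(c(tier10, tier3, tier1),
                  wsv_vocabulary$endocrine_finding)
})

test_that("the LOAEL-NOAEL factor defaults to 3 and rises to 10 on any criterion", {
  expect_equal(assign_loael_noael_uf(minimal_profile())$value, 3)
  triggers <- list(
    list(pregnancy_category = "D"),
    list(pregnancy_category = "X"),
    list(pregnancy_category = "C", category_c_ltd_near_reprotox_dose = TRUE),
    list(life_threatening_indication = TRUE),
    list(not_tested_in_children_or_different_pediatric_profile = TRUE),
    list(serious_effects_at_ltd = TRUE),
    list(black_box_warning_relevant = TRUE))
  for (tr in triggers) {
    p <- do.call(evidence_profile, c(list(api_name = "x"), tr))
    a <- assign_loael_noael_uf(p)
    expect_equal(a$value, 10)
    expect_gte(length(a$rationale_codes), 1)
  }
  # several firing criteria: factor applied once, every criterion logged
  p <- evidence_profile("x", pregnancy_category = "X",
                        black_box_warning_relevant = TRUE,
                        serious_effects_at_ltd = TRUE)
  a <- assign_loael_noael_uf(p)
  expect_equal(a$value, 10)
  expect_length(a$rationale_codes, 3)
})

test_that("database and duration factors follow their vocabularies", {
  expect_equal(assign_database_uf(minimal_profile())$value, 1)
  expect_equal(assign_database_uf(evidence_profile("x",
    database_completeness = "missing_key_study"))$value, 3)
  expect_equal(assign_database_uf(evidence_profile("x",
    database_completeness = "no_or_minimal_animal_data"))$value, 10)
  expect_equal(assign_duration_uf(minimal_profile())$value, 1)
  for (d in c("chronic_untested_long_human_history",
              "chronic_tested_duration_related_risk",
              "chronic_tested_new_to_market"))
    expect_equal(assign_duration_uf(evidence_profile("x",
      duration_profile = d))$value, 3)
  for (d in c("short_term_use", "subchronic_limited_chronic_testing",
              "chronic_limited_testing_severity_increases"))
    expect_equal(assign_duration_uf(evidence_profile("x",
      duration_profile = d))$value, 10)
})

test_that("cancer and endocrine factors are mutually exclusive in the product", {
  afc10 <- assign_cancer_af(cancer_evidence("threshold_hed_near_or_below_mrhd"))
  afe10 <- assign_endocrine_af(endocrine_evidence("intended_therapeutic_effect"))
  afc1 <- assign_cancer_af(cancer_evidence())
  afe3 <- assign_endocrine_af(endocrine_evidence("animal_positive_human_negative"))
  afe1 <- assign_endocrine_af(endocrine_evidence())

  both <- resolve_cancer_endocrine(afc10, afe10)
  expect_equal(both$applied_value, 10)
  expect_true(both$afc$applied)
  expect_false(both$afe$applied)    # noted, not applied

  endo <- resolve_cancer_endocrine(afc1, afe3)
  expect_equal(endo$applied_value, 3)
  expect_true(endo$afe$applied)

  neither <- resolve_cancer_endocrine(afc1, afe1)
  expect_equal(neither$applied_value, 1)
})

test_that("half-log combination matches its stated examples", {
  expect_equal(combine_factors(c(3, 10))$display_value, 30)
  expect_equal(combine_factors(c(3, 3))$display_value, 10)
  expect_equal(combine_factors(c(10, 10, 10, 3, 10))$display_value, 30000)
  expect_equal(combine_factors(c(1, 1, 1))$display_value, 1)
  expect_error(combine_factors(c(3, 5)), "1, 3, or 10")
})

test_that("exponent-sum combination agrees with a brute-force product on all 3^6 combinations", {
  # oracle: multiply with 3 read as 10^0.5 and snap to the display rule
  oracle <- function(values) {
    log_total <- sum(log10(ifelse(values == 3, 10^0.5, values)))
    e <- round(2 * log_total) / 2
    if (e %% 1 == 0) 10^e else 3 * 10^floor(e)
  }
  grid <- expand.grid(rep(list(c(1, 3, 10)), 6))
  for (i in seq_len(nrow(grid))) {
    values <- as.numeric(grid[i, ])
    tf <- combine_factors(values)
    expect_identical(tf$display_value, oracle(values))
    expect_true((2 * tf$half_log_exponent) %% 1 == 0)
  }
})

test_that("full assignment reproduces the boundary and comparison totals", {
  fs_min <- assign_all_factors(minimal_profile())
  expect_equal(fs_min$total_uf$display_value, 30)
  expect_equal(fs_min$UF_Human$value, 10)
  expect_equal(fs_min$UF_L_N$value, 3)

  fs_sulfa <- assign_all_factors(sulfamethoxazole_profile())
  expect_equal(fs_sulfa$total_uf$display_value, 30000)
  expect_equal(unname(applied_factor_values(fs_sulfa)),
               c(10, 10, 10, 3, 10))

  # all-maximal profile with endocrine 10 reaches 100,000, with a warning
  maximal <- evidence_profile("maximal",
    regimens = list(per_kg_regimen(1)),
    endocrine = endocrine_evidence("intended_therapeutic_effect"),
    pregnancy_category = "X",
    database_completeness = "no_or_minimal_animal_data",
    duration_profile = "short_term_use")
  expect_warning(fs_max <- assign_all_factors(maximal), "100,000")
  expect_equal(fs_max$total_uf$display_value, 1e5)

  expect_error(assign_all_factors(evidence_profile("x",
    product_status = "otc_only")), "excluded")
})

test_that("total factors stay on the half-log lattice within [30, 100000] for generated profiles", {
  profiles <- generate_synthetic_profiles(42, 400)
  eligible <- Filter(function(p) screen_eligibility(p)$eligible, profiles)
  expect_gt(length(eligible), 10)
  lattice <- sort(c(10^(0:5), 3 * 10^(0:4)))
  for (p in eligible) {
    fs <- suppressWarnings(assign_all_factors(p))
    total <- fs$total_uf$display_value
    expect_gte(total, 30)
    expect_lte(total, 1e5)
    expect_true(total %in% lattice)
    # never both novel factors in the product
    expect_false(fs$AF_C$applied && fs$AF_C$value > 1 &&
                   fs$AF_E$applied && fs$AF_E$value > 1)
    # oracle: total equals the half-log product using max(AF_C, AF_E)
    vals <- c(max(fs$AF_C$value, fs$AF_E$value), fs$UF_Human$value,
              fs$UF_L_N$value, fs$UF_DB$value, fs$UF_S_C$value)
    expect_equal(total, combine_factors(vals)$display_value)
  }
})

test_that("strengthening any single evidence field never lowers a factor or the total", {
  base_fields <- list(
    carcinogenicity = function(p, v) {
      p$carcinogenicity <- cancer_evidence(v); p
    },
    endocrine = function(p, v) { p$endocrine <- endocrine_evidence(v); p },
    database = function(p, v) { p$database_completeness <- v; p },
    duration = function(p, v) { p$duration_profile <- v; p },
    pregnancy = function(p, v) { p$pregnancy_category <- v; p })
  ladders <- list(carcinogenicity = strength_ladders$cancer,
                  endocrine = strength_ladders$endocrine,
                  database = strength_ladders$database,
                  duration = strength_ladders$duration,
                  pregnancy = strength_ladders$pregnancy)
  starts <- Filter(function(p) screen_eligibility(p)$eligible,
                   generate_synthetic_profiles(7, 120))
  for (p in starts[seq_len(min(30, length(starts)))]) {
    for (field in names(ladders)) {
      prev_total <- NULL
      for (v in ladders[[field]]) {
        q <- base_fields[[field]](p, v)
        fs <- suppressWarnings(assign_all_factors(q))
        total <- fs$total_uf$display_value
        if (!is.null(prev_total)) expect_gte(total, prev_total)
        prev_total <- total
      }
    }
    # boolean escalations
    for (flag in c("black_box_warning_relevant",
                   "life_threatening_indication",
                   "serious_effects_at_ltd")) {
      q <- p; q[[flag]] <- TRUE
      expect_gte(suppressWarnings(assign_all_factors(q))$total_uf$display_value,
                 suppressWarnings(assign_all_factors(p))$total_uf$display_value)
    }
  }
})
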