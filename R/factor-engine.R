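# Uncertainty/adjustment factor decision tree --------------------------------
#
# Six factors, each 1, 3, or 10.  The intraspecies factor is always 10;
# the LOAEL-to-NOAEL factor is at least 3 because the lowest therapeutic
# dose is treated as a LOAEL, never a NOAEL.  The cancer and endocrine
# adjustment factors are mutually exclusive in the final product: when
# both fire, the cancer factor is applied and the endocrine factor is
# noted but not multiplied in.  Totals follow half-log arithmetic: a 3
# counts as 10^0.5, so 3 x 3 = 10 and 3 x 10 = 30.

FACTOR_IDS <- c("AF_C", "AF_E", "UF_Human", "UF_L_N", "UF_DB", "UF_S_C")

new_factor_assignment <- function(factor_id, value, rationale_codes,
                                  applied = TRUE) {
  stopifnot(factor_id %in% FACTOR_IDS, value %in% c(1, 3, 10))
  if (value > 1 && length(rationale_codes) == 0L)
    stop("a factor above 1 needs at least one rationale code", call. = FALSE)
  structure(list(factor_id = factor_id, value = value,
                 rationale_codes = as.character(rationale_codes),
                 applied = applied),
            class = "factor_assignment")
}

#' @export
print.factor_assignment <- function(x, ...) {
  cat(sprintf("<factor> %s = %g%s  [%s]\n", x$factor_id, x$value,
              if (x$applied) "" else " (noted, not applied)",
              paste(x$rationale_codes, collapse = ", ")))
  invisible(x)
}

#' Cancer adjustment factor
#'
#' Threshold carcinogens receive a 10-fold adjustment when the human
#' equivalent dose (HED) associated with tumours is near or below the
#' maximum recommended human dose or the lowest therapeutic dose.  No
#' adjustment is applied when the tumour HED lies far above the human
#' dose, when the tumour type is not human-relevant (rodent thyroid and
#' liver tumours), or when carcinogenicity appears only at the site of a
#' non-oral administration.  Non-threshold/genotoxic carcinogens never
#' reach this operation — they are excluded at screening because an
#' uncertainty-factor division cannot stand in for a cancer slope
#' factor.
#'
#' @param ev a [cancer_evidence()] object.
#' @return A `factor_assignment` with id `AF_C` and value 1 or 10.
#' @export
assign_cancer_af <- function(ev) {
  if (!inherits(ev, "cancer_evidence"))
    stop("`ev` must be a cancer_evidence object", call. = FALSE)
  if (ev$finding == "non_threshold_or_genotoxic")
    stop("non-threshold/genotoxic carcinogens are ineligible for the ",
         "rapid method", call. = FALSE)
  if (ev$finding == "threshold_hed_near_or_below_mrhd")
    new_factor_assignment("AF_C", 10, "AF_C.hed_near_or_below_mrhd")
  else
    new_factor_assignment("AF_C", 1, paste0("AF_C.", ev$finding))
}

AFE_VALUE_10 <- c("intended_therapeutic_effect",
                  "warnings_or_pharmacodynamics_section",
                  "adverse_reaction_causing_discontinuation",
                  "hormonal_lab_monitoring_required",
                  "frequent_with_animal_support")
AFE_VALUE_3 <- c("animal_positive_human_negative",
                 "small_insignificant_hormone_changes",
                 "frequent_postmarket_only_animal_negative",
                 "infrequent_human_no_animal_support")

#' Endocrine activity adjustment factor
#'
#' A 10-fold adjustment applies when endocrine activity is the intended
#' therapeutic effect, is flagged in the warnings/precautions or
#' pharmacodynamics label sections, led to treatment discontinuation,
#' requires hormonal lab monitoring, or is frequent with supporting
#' animal data.  A 3-fold adjustment applies to weaker signals:
#' animal-only findings with negative human testing, clinically
#' insignificant hormone changes, frequent post-market reports without
#' animal support, or infrequent human reports without animal data.  No
#' adjustment applies when effects merely aggravate pre-existing
#' endocrine disease, are rare, or mask endocrine disease by controlling
#' symptoms.
#'
#' @param ev an [endocrine_evidence()] object.
#' @return A `factor_assignment` with id `AF_E` and value 1, 3, or 10.
#' @export
assign_endocrine_af <- function(ev) {
  if (!inherits(ev, "endocrine_evidence"))
    stop("`ev` must be an endocrine_evidence object", call. = FALSE)
  value <- if (ev$finding %in% AFE_VALUE_10) 10
           else if (ev$finding %in% AFE_VALUE_3) 3
           else 1
  new_factor_assignment("AF_E", value, paste0("AF_E.", ev$finding))
}

#' LOAEL-to-NOAEL (dosing) uncertainty factor
#'
#' The lowest therapeutic dose is by construction an effect level, so a
#' 3-fold factor applies as the default.  It rises to 10 when the label
#' signals effects of concern at or around that dose: pregnancy category
#' D or X; pregnancy category C with the therapeutic dose near the
#' reproductive-study dose; a life-threatening indication; absent or
#' divergent paediatric testing with adult-only dosing; serious adverse
#' effects at the lowest therapeutic dose; or a relevant boxed warning.
#' Multiple firing criteria are all recorded but the factor is applied
#' once.
#'
#' @param profile an [evidence_profile()].
#' @return A `factor_assignment` with id `UF_L_N` and value 3 or 10.
#' @export
assign_loael_noael_uf <- function(profile) {
  codes <- character(0)
  if (profile$pregnancy_category %in% c("D", "X"))
    codes <- c(codes, "UF_L_N.pregnancy_D_or_X")
  if (profile$pregnancy_category == "C" &&
      profile$category_c_ltd_near_reprotox_dose)
    codes <- c(codes, "UF_L_N.category_C_ltd_near_reprotox_dose")
  if (profile$life_threatening_indication)
    codes <- c(codes, "UF_L_N.life_threatening_indication")
  if (profile$not_tested_in_children_or_different_pediatric_profile)
    codes <- c(codes, "UF_L_N.pediatric_profile")
  if (profile$serious_effects_at_ltd)
    codes <- c(codes, "UF_L_N.serious_effects_at_ltd")
  if (profile$black_box_warning_relevant)
    codes <- c(codes, "UF_L_N.blackbox")
  if (length(codes)) new_factor_assignment("UF_L_N", 10, codes)
  else new_factor_assignment("UF_L_N", 3, "UF_L_N.default_loael")
}

#' Database uncertainty factor
#'
#' 3-fold when an otherwise well-tested compound is missing a key study
#' (most commonly the multigenerational reproductive/developmental
#' study); 10-fold when the label and supporting sources describe no or
#' minimal animal testing; 1 when the database is complete.
#'
#' @param profile an [evidence_profile()].
#' @return A `factor_assignment` with id `UF_DB`.
#' @export
assign_database_uf <- function(profile) {
  switch(profile$database_completeness,
    complete = new_factor_assignment("UF_DB", 1, "UF_DB.complete"),
    missing_key_study =
      new_factor_assignment("UF_DB", 3, "UF_DB.missing_key_study"),
    no_or_minimal_animal_data =
      new_factor_assignment("UF_DB", 10, "UF_DB.no_or_minimal_animal_data"))
}

DURATION_VALUE_3 <- c("chronic_untested_long_human_history",
                      "chronic_tested_duration_related_risk",
                      "chronic_tested_new_to_market")
DURATION_VALUE_10 <- c("short_term_use",
                       "subchronic_limited_chronic_testing",
                       "chronic_limited_testing_severity_increases")

#' Duration-of-use uncertainty factor
#'
#' 10-fold for compounds intended for short-term use (days to weeks),
#' for subchronic use with limited or no chronic testing, or for chronic
#' use with limited testing and evidence of increasing severity over
#' time.  3-fold for chronic-use compounds with a long human-use history
#' but little chronic animal testing, with duration-related risk
#' signals, or that are new to market.  1 for fully tested chronic-use
#' compounds without duration concern.
#'
#' @param profile an [evidence_profile()].
#' @return A `factor_assignment` with id `UF_S_C`.
#' @export
assign_duration_uf <- function(profile) {
  d <- profile$duration_profile
  value <- if (d %in% DURATION_VALUE_10) 10
           else if (d %in% DURATION_VALUE_3) 3
           else 1
  new_factor_assignment("UF_S_C", value, paste0("UF_S_C.", d))
}

#' Resolve the mutually exclusive cancer/endocrine adjustment factors
#'
#' At most one of the two novel adjustment factors is multiplied into
#' the total.  When the cancer factor exceeds 1 it is the one applied;
#' the endocrine factor is then still noted in the trace but marked not
#' applied.  Otherwise the endocrine factor is applied as assigned.
#'
#' @param afc,afe `factor_assignment` objects for `AF_C` and `AF_E`.
#' @return A list with `applied_value`, and the two (possibly updated)
#'   assignments `afc` and `afe`.
#' @export
resolve_cancer_endocrine <- function(afc, afe) {
  stopifnot(inherits(afc, "factor_assignment"), afc$factor_id == "AF_C",
            inherits(afe, "factor_assignment"), afe$factor_id == "AF_E")
  if (afc$value > 1) {
    if (afe$value > 1) afe$applied <- FALSE
    list(applied_value = afc$value, afc = afc, afe = afe)
  } else {
    afc$applied <- FALSE
    list(applied_value = afe$value, afc = afc, afe = afe)
  }
}

#' Combine individual factors with half-log arithmetic
#'
#' Each factor contributes an exponent of base 10: a value of 1
#' contributes 0, a value of 3 contributes 0.5 (a half-log), and a value
#' of 10 contributes 1.  The combined total is displayed as `10^e` when
#' the exponent sum `e` is integral and as `3 x 10^floor(e)` when it
#' ends in a half: two 3s combine to 10, and a 3 with a 10 combines to
#' 30.  The exponent is the stored representation, so repeated
#' combination accumulates no floating-point drift.
#'
#' @param values numeric vector of applied factor values, each 1, 3, or
#'   10.
#' @return An object of class `total_factor` with elements
#'   `half_log_exponent` and `display_value`.
#' @export
combine_factors <- function(values) {
  if (!length(values) || !all(values %in% c(1, 3, 10)))
    stop("factor values must each be 1, 3, or 10", call. = FALSE)
  exponent <- sum(vapply(values, function(v)
    if (v == 1) 0 else if (v == 3) 0.5 else 1, numeric(1)))
  new_total_factor(exponent)
}

new_total_factor <- function(exponent) {
  stopifnot(exponent >= 0, (2 * exponent) %% 1 == 0)
  display <- if (exponent %% 1 == 0) 10^exponent else 3 * 10^floor(exponent)
  structure(list(half_log_exponent = exponent, display_value = display),
            class = "total_factor")
}

#' @export
print.total_factor <- function(x, ...) {
  cat(sprintf("<total_factor> %s (10^%.1f)\n",
              format(x$display_value, big.mark = ",", scientific = FALSE),
              x$half_log_exponent))
  invisible(x)
}

#' Assign all six uncertainty/adjustment factors for a profile
#'
#' Runs the full decision tree: the cancer and endocrine adjustment
#' factors from their evidence objects, the constant 10-fold
#' intraspecies factor, and the LOAEL-to-NOAEL, database, and duration
#' factors from the profile flags.  Cancer/endocrine exclusivity is
#' resolved, the applied factors are combined with half-log arithmetic,
#' and the complete rationale trace is retained.  The attainable total
#' ranges from 30 (intraspecies 10 with the default LOAEL factor 3) to
#' 100,000; totals at the very top of the range are possible in
#' principle but flagged with a warning because non-overlapping decision
#' criteria make them unlikely.
#'
#' @param profile an eligible [evidence_profile()].
#' @return An object of class `factor_set`: the six `factor_assignment`s
#'   plus `total_uf`, a [combine_factors()] result.
#' @export
assign_all_factors <- function(profile) {
  decision <- screen_eligibility(profile)
  if (!decision$eligible)
    stop(sprintf("profile is excluded (%s); no factors can be assigned",
                 decision$reason), call. = FALSE)
  afc <- assign_cancer_af(profile$carcinogenicity)
  afe <- assign_endocrine_af(profile$endocrine)
  resolved <- resolve_cancer_endocrine(afc, afe)
  uf_human <- new_factor_assignment("UF_Human", 10, "UF_Human.default")
  uf_ln <- assign_loael_noael_uf(profile)
  uf_db <- assign_database_uf(profile)
  uf_sc <- assign_duration_uf(profile)
  applied <- c(resolved$applied_value, uf_human$value, uf_ln$value,
               uf_db$value, uf_sc$value)
  total <- combine_factors(applied)
  if (total$display_value >= 1e5)
    warning("total UF/AF of 100,000 reached; non-overlapping decision ",
            "criteria make this combination implausible -- review the profile",
            call. = FALSE)
  structure(list(AF_C = resolved$afc, AF_E = resolved$afe,
                 UF_Human = uf_human, UF_L_N = uf_ln, UF_DB = uf_db,
                 UF_S_C = uf_sc, total_uf = total),
            class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  for (id in FACTOR_IDS) print(x[[id]])
  print(x$total_uf)
  invisible(x)
}

#' Applied factor values of a factor set
#'
#' @param fs a `factor_set`.
#' @return Named numeric vector of the five values multiplied into the
#'   total (the resolved cancer-or-endocrine factor plus the four
#'   uncertainty factors).
#' @export
applied_factor_values <- function(fs) {
  stopifnot(inherits(fs, "factor_set"))
  ce <- if (fs$AF_C$applied) fs$AF_C else fs$AF_E
  c(AF_C_or_AF_E = ce$value, UF_Human = fs$UF_Human$value,
    UF_L_N = fs$UF_L_N$value, UF_DB = fs$UF_DB$value,
    UF_S_C = fs$UF_S_C$value)
}
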