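# Evidence vocabulary -------------------------------------------------------
#
# The framework consumes curated, label-derived facts.  Every qualitative
# fact is a member of a closed enumeration so that rule firing is exactly
# reproducible; free text is restricted to identifiers and provenance.

#' Closed vocabularies used by evidence profiles
#'
#' Named list of the enumeration levels accepted in an
#' [evidence_profile()].  Each element is a character vector naming the
#' allowed values of one categorical field.
#'
#' @format A named list of character vectors:
#' \describe{
#'   \item{route}{administration route; only oral products are assessable}
#'   \item{product_status}{regulatory/market status of the product}
#'   \item{cancer_finding}{summary of label carcinogenicity evidence,
#'     phrased relative to the human equivalent dose (HED) and maximum
#'     recommended human dose (MRHD)}
#'   \item{endocrine_finding}{the single strongest endocrine-activity
#'     observation applicable to the compound}
#'   \item{pregnancy_category}{pre-2015 FDA letter category}
#'   \item{database_completeness}{extent of toxicity testing on the label}
#'   \item{duration_profile}{intended duration of use crossed with the
#'     extent of duration-relevant testing}
#'   \item{regimen_units}{units a labelled dose schedule is expressed in}
#' }
#' @export
wsv_vocabulary <- list(
  route = c("oral", "non_oral"),
  product_status = c("prescription", "otc_only", "nutritional_supplement",
                     "illicit", "discontinued_or_unapproved",
                     "veterinary_only"),
  cancer_finding = c("none_reported",
                     "threshold_hed_near_or_below_mrhd",
                     "threshold_hed_far_above_mrhd",
                     "tumor_type_not_human_relevant",
                     "site_of_administration_only",
                     "non_threshold_or_genotoxic"),
  endocrine_finding = c("none",
                        "animal_positive_human_negative",
                        "small_insignificant_hormone_changes",
                        "frequent_postmarket_only_animal_negative",
                        "infrequent_human_no_animal_support",
                        "intended_therapeutic_effect",
                        "warnings_or_pharmacodynamics_section",
                        "adverse_reaction_causing_discontinuation",
                        "hormonal_lab_monitoring_required",
                        "frequent_with_animal_support",
                        "aggravation_only",
                        "rare_effect_only",
                        "masks_endocrine_disease"),
  pregnancy_category = c("A", "B", "C", "D", "X", "none_stated"),
  database_completeness = c("complete", "missing_key_study",
                            "no_or_minimal_animal_data"),
  duration_profile = c("chronic_fully_tested_no_concern",
                       "chronic_untested_long_human_history",
                       "chronic_tested_duration_related_risk",
                       "chronic_tested_new_to_market",
                       "short_term_use",
                       "subchronic_limited_chronic_testing",
                       "chronic_limited_testing_severity_increases"),
  regimen_units = c("mg_per_day_total", "mg_per_administration",
                    "mg_per_kg_day")
)

#' The seven exclusion reasons, in screening order
#'
#' Reason codes returned by [screen_eligibility()], in the order in which
#' the criteria are checked.  The first matching criterion names the
#' decision; all matching criteria are logged.
#'
#' @export
wsv_exclusion_reasons <- c("non_oral", "nutritional_supplement", "otc_only",
                           "illicit", "discontinued_or_unapproved",
                           "veterinary_only", "non_threshold_carcinogen")

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_enum <- function(value, field, levels) {
  if (!(is.character(value) && length(value) == 1L && !is.na(value)))
    stop_field(field, "must be a single character value")
  if (!value %in% levels)
    stop_field(field, sprintf("'%s' is not one of {%s}", value,
                              paste(levels, collapse = ", ")))
  value
}

check_flag <- function(value, field) {
  if (!(is.logical(value) && length(value) == 1L && !is.na(value)))
    stop_field(field, "must be TRUE or FALSE")
  value
}

check_scalar_number <- function(value, field, positive = TRUE,
                                allow_null = FALSE) {
  if (is.null(value)) {
    if (allow_null) return(NULL)
    stop_field(field, "must be supplied")
  }
  if (!(is.numeric(value) && length(value) == 1L && is.finite(value)))
    stop_field(field, "must be a single finite number")
  if (positive && value <= 0)
    stop_field(field, "must be strictly positive")
  if (!positive && value < 0)
    stop_field(field, "must be nonnegative")
  as.numeric(value)
}

#' Carcinogenicity evidence for one compound
#'
#' Summarises what the label's carcinogenicity section supports.  Findings
#' are stated relative to the human equivalent dose (HED) at which tumours
#' occurred and the maximum recommended human dose (MRHD).  A
#' `non_threshold_or_genotoxic` finding makes the whole profile ineligible
#' for the rapid method (linear carcinogens need a slope factor, not an
#' uncertainty-factor division).
#'
#' @param finding one of `wsv_vocabulary$cancer_finding`.
#' @param hed_mg_per_kg_day,mrhd_mg_per_kg_day optional positive doses
#'   (mg/kg-day) recording the comparison behind the finding.
#' @return An object of class `cancer_evidence`.
#' @export
cancer_evidence <- function(finding = "none_reported",
                            hed_mg_per_kg_day = NULL,
                            mrhd_mg_per_kg_day = NULL) {
  finding <- check_enum(finding, "carcinogenicity$finding",
                        wsv_vocabulary$cancer_finding)
  hed <- check_scalar_number(hed_mg_per_kg_day,
                             "carcinogenicity$hed_mg_per_kg_day",
                             allow_null = TRUE)
  mrhd <- check_scalar_number(mrhd_mg_per_kg_day,
                              "carcinogenicity$mrhd_mg_per_kg_day",
                              allow_null = TRUE)
  structure(list(finding = finding, hed_mg_per_kg_day = hed,
                 mrhd_mg_per_kg_day = mrhd),
            class = "cancer_evidence")
}

#' Endocrine-activity evidence for one compound
#'
#' One finding per compound: the strongest applicable observation, chosen
#' by the curator.  The vocabulary distinguishes observations that warrant
#' a 10-fold adjustment (intended hormonal effect, warnings/
#' pharmacodynamics statements, treatment-limiting reactions, required
#' hormonal lab monitoring, frequent effects with animal support) from
#' those warranting 3-fold (animal-only or infrequent/unsupported human
#' signals) and those warranting none (aggravation of pre-existing
#' disease, rare effects, masking of endocrine disease).
#'
#' @param finding one of `wsv_vocabulary$endocrine_finding`.
#' @return An object of class `endocrine_evidence`.
#' @export
endocrine_evidence <- function(finding = "none") {
  finding <- check_enum(finding, "endocrine$finding",
                        wsv_vocabulary$endocrine_finding)
  structure(list(finding = finding), class = "endocrine_evidence")
}

#' A labelled dose schedule
#'
#' One dosing instruction from a drug label: an amount, a frequency, the
#' age range it applies to, and the units the label uses.  Schedules for
#' special populations (renal or hepatic impairment, titrated dosing) are
#' retained for the record but never used to set the lowest therapeutic
#' dose.
#'
#' @param amount_mg positive dose.  Interpreted per administration, per
#'   day, or per kg-day according to `units`.
#' @param administrations_per_day positive integer; ignored for
#'   `mg_per_day_total` and `mg_per_kg_day` units.
#' @param age_min_years,age_max_years the age range the schedule covers,
#'   as a half-open interval `[age_min, age_max)`.  Use `Inf` for an
#'   open-ended adult range.
#' @param units one of `wsv_vocabulary$regimen_units`.
#' @param special_population_only `TRUE` for renal/hepatic/titrated dosing
#'   that does not apply to the general population.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(amount_mg, administrations_per_day = 1L,
                         age_min_years = 18, age_max_years = Inf,
                         units = "mg_per_day_total",
                         special_population_only = FALSE) {
  amount_mg <- check_scalar_number(amount_mg, "regimen$amount_mg")
  if (!(is.numeric(administrations_per_day) &&
        length(administrations_per_day) == 1L &&
        is.finite(administrations_per_day) &&
        administrations_per_day >= 1 &&
        administrations_per_day == as.integer(administrations_per_day)))
    stop_field("regimen$administrations_per_day",
               "must be a positive whole number")
  if (!(is.numeric(age_min_years) && length(age_min_years) == 1L &&
        age_min_years >= 0))
    stop_field("regimen$age_min_years", "must be nonnegative")
  if (!(is.numeric(age_max_years) && length(age_max_years) == 1L &&
        age_max_years > age_min_years))
    stop_field("regimen$age_max_years", "must exceed age_min_years")
  units <- check_enum(units, "regimen$units", wsv_vocabulary$regimen_units)
  special_population_only <- check_flag(special_population_only,
                                        "regimen$special_population_only")
  structure(list(amount_mg = amount_mg,
                 administrations_per_day = as.integer(administrations_per_day),
                 age_min_years = as.numeric(age_min_years),
                 age_max_years = as.numeric(age_max_years),
                 units = units,
                 special_population_only = special_population_only),
            class = "dose_regimen")
}

#' A curated evidence profile for one active pharmaceutical ingredient
#'
#' Collects everything the screening framework needs about one compound:
#' identity, route and market status, the labelled dose schedules, and
#' the categorical findings that drive the uncertainty/adjustment-factor
#' decision tree.  Construction validates every field against the closed
#' vocabularies in [wsv_vocabulary] and enforces cross-field invariants
#' (the reproductive-toxicity proximity flag is only meaningful for
#' pregnancy category C).
#'
#' @param api_name compound name (required, non-empty).
#' @param casrn CAS registry number, or `NA` when not assigned.
#' @param route `"oral"` or `"non_oral"`.
#' @param regimens list of [dose_regimen()] objects.  May be empty only
#'   for profiles that will be excluded at screening.
#' @param product_status one of `wsv_vocabulary$product_status`.
#' @param carcinogenicity a [cancer_evidence()] object.
#' @param endocrine an [endocrine_evidence()] object.
#' @param pregnancy_category pre-2015 FDA letter category or
#'   `"none_stated"`.
#' @param category_c_ltd_near_reprotox_dose `TRUE` when the compound is
#'   category C and its lowest therapeutic dose approximates the dose
#'   used in the label's reproductive/developmental studies.
#' @param black_box_warning_relevant `TRUE` when a boxed warning concerns
#'   serious effects not tied to the treated condition.
#' @param life_threatening_indication `TRUE` when the compound treats
#'   life-threatening conditions.
#' @param not_tested_in_children_or_different_pediatric_profile `TRUE`
#'   when paediatric testing is absent or showed a different safety
#'   profile with adult-only dosing.
#' @param serious_effects_at_ltd `TRUE` when serious adverse effects are
#'   linked to the lowest therapeutic dose itself.
#' @param database_completeness extent of toxicity testing on the label.
#' @param duration_profile intended duration of use crossed with the
#'   extent of duration-relevant testing.
#' @param otc_pediatric_use `TRUE` for compounds with numerous
#'   over-the-counter paediatric formulations; selects the 0.2 relative
#'   source contribution.
#' @param discontinued_override `TRUE` lets a curator assess a
#'   discontinued or unapproved product anyway (used for compounds whose
#'   labels are outdated but for which supplementary sources fill the
#'   gaps).
#' @param label_source free-text provenance (label date, packager).
#' @return An object of class `evidence_profile`.
#' @seealso [screen_eligibility()], [derive_screening_values()]
#' @export
evidence_profile <- function(api_name,
                             casrn = NA_character_,
                             route = "oral",
                             regimens = list(),
                             product_status = "prescription",
                             carcinogenicity = cancer_evidence(),
                             endocrine = endocrine_evidence(),
                             pregnancy_category = "none_stated",
                             category_c_ltd_near_reprotox_dose = FALSE,
                             black_box_warning_relevant = FALSE,
                             life_threatening_indication = FALSE,
                             not_tested_in_children_or_different_pediatric_profile = FALSE,
                             serious_effects_at_ltd = FALSE,
                             database_completeness = "complete",
                             duration_profile = "chronic_fully_tested_no_concern",
                             otc_pediatric_use = FALSE,
                             discontinued_override = FALSE,
                             label_source = NA_character_) {
  if (!(is.character(api_name) && length(api_name) == 1L &&
        !is.na(api_name) && nzchar(api_name)))
    stop_field("api_name", "must be a non-empty character scalar")
  if (!(length(casrn) == 1L && (is.na(casrn) || is.character(casrn))))
    stop_field("casrn", "must be a character scalar or NA")
  route <- check_enum(route, "route", wsv_vocabulary$route)
  if (!is.list(regimens) ||
      !all(vapply(regimens, inherits, logical(1), "dose_regimen")))
    stop_field("regimens", "must be a list of dose_regimen objects")
  product_status <- check_enum(product_status, "product_status",
                               wsv_vocabulary$product_status)
  if (!inherits(carcinogenicity, "cancer_evidence"))
    stop_field("carcinogenicity", "must be a cancer_evidence object")
  if (!inherits(endocrine, "endocrine_evidence"))
    stop_field("endocrine", "must be an endocrine_evidence object")
  pregnancy_category <- check_enum(pregnancy_category, "pregnancy_category",
                                   wsv_vocabulary$pregnancy_category)
  category_c_ltd_near_reprotox_dose <-
    check_flag(category_c_ltd_near_reprotox_dose,
               "category_c_ltd_near_reprotox_dose")
  if (category_c_ltd_near_reprotox_dose && pregnancy_category != "C")
    stop_field("category_c_ltd_near_reprotox_dose",
               "may be TRUE only when pregnancy_category is 'C'")
  database_completeness <- check_enum(database_completeness,
                                      "database_completeness",
                                      wsv_vocabulary$database_completeness)
  duration_profile <- check_enum(duration_profile, "duration_profile",
                                 wsv_vocabulary$duration_profile)
  structure(list(
    api_name = api_name,
    casrn = as.character(casrn),
    route = route,
    regimens = regimens,
    product_status = product_status,
    carcinogenicity = carcinogenicity,
    endocrine = endocrine,
    pregnancy_category = pregnancy_category,
    category_c_ltd_near_reprotox_dose = category_c_ltd_near_reprotox_dose,
    black_box_warning_relevant =
      check_flag(black_box_warning_relevant, "black_box_warning_relevant"),
    life_threatening_indication =
      check_flag(life_threatening_indication, "life_threatening_indication"),
    not_tested_in_children_or_different_pediatric_profile =
      check_flag(not_tested_in_children_or_different_pediatric_profile,
                 "not_tested_in_children_or_different_pediatric_profile"),
    serious_effects_at_ltd =
      check_flag(serious_effects_at_ltd, "serious_effects_at_ltd"),
    database_completeness = database_completeness,
    duration_profile = duration_profile,
    otc_pediatric_use = check_flag(otc_pediatric_use, "otc_pediatric_use"),
    discontinued_override =
      check_flag(discontinued_override, "discontinued_override"),
    label_source = as.character(label_source)
  ), class = "evidence_profile")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat(sprintf("<evidence_profile> %s (CASRN %s)\n", x$api_name,
              ifelse(is.na(x$casrn), "-", x$casrn)))
  cat(sprintf("  route: %s | status: %s | regimens: %d\n",
              x$route, x$product_status, length(x$regimens)))
  cat(sprintf("  cancer: %s | endocrine: %s | pregnancy: %s\n",
              x$carcinogenicity$finding, x$endocrine$finding,
              x$pregnancy_category))
  cat(sprintf("  database: %s | duration: %s\n",
              x$database_completeness, x$duration_profile))
  invisible(x)
}

# Eligibility screen ---------------------------------------------------------

#' Screen an evidence profile against the exclusion criteria
#'
#' Applies the seven exclusion criteria in a fixed order: non-oral route,
#' nutritional supplement, over-the-counter only, illicit substance,
#' discontinued or unapproved product, veterinary-only registration, and
#' genotoxic/non-threshold carcinogenicity.  The decision carries the
#' first matching criterion as its reason; all matching criteria are
#' reported alongside.  A discontinued product with
#' `discontinued_override = TRUE` is not excluded on that ground — the
#' original assessment itself retained five discontinued compounds whose
#' data gaps could be filled from supplementary sources.
#'
#' @param profile an [evidence_profile()].
#' @return A list of class `eligibility_decision` with elements
#'   `eligible` (logical), `reason` (first matching exclusion code or
#'   `NA`), and `all_reasons` (every matching code, possibly empty).
#' @export
screen_eligibility <- function(profile) {
  if (!inherits(profile, "evidence_profile"))
    stop("`profile` must be an evidence_profile", call. = FALSE)
  hits <- character(0)
  if (profile$route == "non_oral")
    hits <- c(hits, "non_oral")
  if (profile$product_status == "nutritional_supplement")
    hits <- c(hits, "nutritional_supplement")
  if (profile$product_status == "otc_only")
    hits <- c(hits, "otc_only")
  if (profile$product_status == "illicit")
    hits <- c(hits, "illicit")
  if (profile$product_status == "discontinued_or_unapproved" &&
      !profile$discontinued_override)
    hits <- c(hits, "discontinued_or_unapproved")
  if (profile$product_status == "veterinary_only")
    hits <- c(hits, "veterinary_only")
  if (profile$carcinogenicity$finding == "non_threshold_or_genotoxic")
    hits <- c(hits, "non_threshold_carcinogen")
  structure(list(eligible = length(hits) == 0L,
                 reason = if (length(hits)) hits[[1L]] else NA_character_,
                 all_reasons = hits),
            class = "eligibility_decision")
}

#' @export
print.eligibility_decision <- function(x, ...) {
  if (x$eligible) cat("<eligibility> eligible\n")
  else cat(sprintf("<eligibility> excluded: %s%s\n", x$reason,
                   if (length(x$all_reasons) > 1L)
                     sprintf(" (also: %s)",
                             paste(x$all_reasons[-1L], collapse = ", "))
                   else ""))
  invisible(x)
}

# Synthetic profiles ---------------------------------------------------------

#' Generate synthetic evidence profiles for property testing
#'
#' Draws schema-valid profiles uniformly over the closed vocabularies.
#' Cross-field invariants are respected (the category-C proximity flag is
#' only ever set for category C profiles; every profile carries at least
#' one general-population regimen).  The generator is deterministic for a
#' given seed and leaves the caller's random-number state untouched.
#'
#' @param seed integer seed.
#' @param n number of profiles (`n >= 0`).
#' @return A list of `n` [evidence_profile()] objects.
#' @export
generate_synthetic_profiles <- function(seed, n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 0)
  n <- as.integer(n)
  out <- vector("list", n)
  if (n == 0L) return(out)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  pick <- function(levels) levels[sample.int(length(levels), 1L)]
  for (i in seq_len(n)) {
    preg <- pick(wsv_vocabulary$pregnancy_category)
    n_reg <- sample.int(3L, 1L)
    regimens <- lapply(seq_len(n_reg), function(j) {
      units <- pick(wsv_vocabulary$regimen_units)
      if (units == "mg_per_kg_day") {
        dose_regimen(amount_mg = signif(stats::runif(1, 0.01, 30), 3),
                     age_min_years = 0, age_max_years = Inf, units = units)
      } else {
        ages <- sort(sample(6:18, 2L))
        adult <- stats::runif(1) < 0.7
        dose_regimen(
          amount_mg = signif(stats::runif(1, 0.5, 500), 3),
          administrations_per_day = sample.int(4L, 1L),
          age_min_years = if (adult) 18 else ages[[1L]],
          age_max_years = if (adult) Inf else ages[[2L]],
          units = units)
      }
    })
    out[[i]] <- evidence_profile(
      api_name = sprintf("synthetic-%04d", i),
      casrn = sprintf("%d-%02d-%d", 1000L + i, i %% 100L, i %% 10L),
      route = pick(wsv_vocabulary$route),
      regimens = regimens,
      product_status = pick(wsv_vocabulary$product_status),
      carcinogenicity = cancer_evidence(pick(wsv_vocabulary$cancer_finding)),
      endocrine = endocrine_evidence(pick(wsv_vocabulary$endocrine_finding)),
      pregnancy_category = preg,
      category_c_ltd_near_reprotox_dose =
        preg == "C" && stats::runif(1) < 0.5,
      black_box_warning_relevant = stats::runif(1) < 0.5,
      life_threatening_indication = stats::runif(1) < 0.5,
      not_tested_in_children_or_different_pediatric_profile =
        stats::runif(1) < 0.5,
      serious_effects_at_ltd = stats::runif(1) < 0.5,
      database_completeness = pick(wsv_vocabulary$database_completeness),
      duration_profile = pick(wsv_vocabulary$duration_profile),
      otc_pediatric_use = stats::runif(1) < 0.1,
      discontinued_override = stats::runif(1) < 0.1,
      label_source = "synthetic fixture"
    )
  }
  out
}
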