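# Lowest therapeutic dose ---------------------------------------------------
#
# The point of departure is the lowest labelled dose that produces a
# clinically effective outcome, expressed per kg body weight.  Doses are
# normalised to mg/day first (the full 24-h amount, not the per-tablet
# amount), then divided by the mean body weight of every one-year age
# bracket the schedule covers; the minimum quotient wins.

#' Mean body weights by age bracket
#'
#' Returns the body-weight reference table used to convert mg/day doses
#' to mg/kg-day: twelve one-year brackets from 6-7 through 17-18 years
#' plus a single adult (>= 18) value of 80 kg.  The table derives from
#' the EPA Exposure Factors Handbook mean weights; the 80 kg adult value
#' reflects the current US adult average and, being higher than the
#' historical 70 kg convention, yields lower (more conservative) doses.
#' Doses for children under 6 are labelled per-kg and never need the
#' table.
#'
#' @return A data frame with columns `age_min` (bracket start, years),
#'   `age_max` (bracket end, `Inf` for adults) and `weight_kg`.
#' @export
body_weight_table <- function() {
  path <- system.file("extdata", "table2_bodyweights.csv",
                      package = "pharmwsv", mustWork = TRUE)
  bw <- utils::read.csv(path, stringsAsFactors = FALSE)
  bw$age_max[is.na(bw$age_max)] <- Inf
  stopifnot(nrow(bw) == 13L, all(bw$weight_kg > 0))
  bw
}

#' Total daily dose of a labelled schedule
#'
#' Normalises a schedule to mg/day.  Amounts stated per administration
#' are multiplied by the administrations per day so that the full 24-hour
#' amount is used (a 10 mg tablet taken 4 times a day is a 40 mg/day
#' dose).  Amounts already stated per day pass through.  Schedules
#' stated in mg/kg-day have no meaningful mg/day form and are rejected;
#' [compute_ltd()] takes them straight through without body-weight
#' division.
#'
#' @param regimen a [dose_regimen()].
#' @return Dose in mg/day.
#' @export
daily_dose <- function(regimen) {
  if (!inherits(regimen, "dose_regimen"))
    stop("`regimen` must be a dose_regimen", call. = FALSE)
  switch(regimen$units,
    mg_per_day_total = regimen$amount_mg,
    mg_per_administration = regimen$amount_mg * regimen$administrations_per_day,
    mg_per_kg_day = stop(
      "regimen is already in mg/kg-day; it bypasses the body-weight division",
      call. = FALSE))
}

#' Mean body weight for an age bracket
#'
#' @param age_years the bracket's starting age in whole years (6 through
#'   17), or any age of 18 or more for the adult value.
#' @return Weight in kg from the reference table.
#' @export
lookup_body_weight <- function(age_years) {
  stopifnot(is.numeric(age_years), length(age_years) == 1L,
            is.finite(age_years) || age_years >= 18)
  if (age_years < 6)
    stop("doses for ages under 6 are labelled in mg/kg-day; ",
         "use the per-kg pass-through rather than a body-weight lookup",
         call. = FALSE)
  bw <- body_weight_table()
  row <- bw[bw$age_min <= age_years & age_years < bw$age_max, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  row$weight_kg
}

# One-year brackets [a, a+1) whose intersection with the half-open
# regimen range [age_min, age_max) is non-empty; adults are one bracket.
covered_brackets <- function(age_min, age_max) {
  bw <- body_weight_table()
  keep <- bw$age_min < age_max & age_min < bw$age_max
  bw[keep, , drop = FALSE]
}

#' Lowest therapeutic dose across a set of labelled schedules
#'
#' For every general-population schedule, computes candidate doses in
#' mg/kg-day: schedules already labelled in mg/kg-day pass through
#' unchanged, while mg/day schedules are divided by the mean body weight
#' of each one-year age bracket their age range covers (the bracket with
#' the highest mean weight usually yields the lowest dose).  Quotients
#' are rounded to 3 significant figures; the overall minimum across
#' schedules and brackets is the LTD.  Special-population schedules
#' (renal/hepatic impairment, titrated dosing) are excluded from
#' consideration.
#'
#' @param regimens a list of [dose_regimen()] objects (or a single one).
#' @return A list of class `ltd_result`: `ltd_mg_kg_day`, plus a trace
#'   with the selected regimen index, the selected bracket, and every
#'   candidate evaluated.  Ties keep the first candidate in label order.
#' @export
compute_ltd <- function(regimens) {
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  if (!is.list(regimens) ||
      !all(vapply(regimens, inherits, logical(1), "dose_regimen")))
    stop("`regimens` must be a list of dose_regimen objects", call. = FALSE)
  general <- Filter(function(r) !r$special_population_only, regimens)
  if (length(general) == 0L)
    stop("no general-population dose: every regimen is special-population only",
         call. = FALSE)

  candidates <- data.frame(regimen = integer(0), age_min = numeric(0),
                           weight_kg = numeric(0), ltd = numeric(0))
  idx_general <- which(!vapply(regimens, `[[`, logical(1),
                               "special_population_only"))
  for (i in idx_general) {
    r <- regimens[[i]]
    if (r$units == "mg_per_kg_day") {
      candidates <- rbind(candidates, data.frame(
        regimen = i, age_min = NA_real_, weight_kg = NA_real_,
        ltd = r$amount_mg))
      next
    }
    if (r$age_min_years < 6)
      stop("regimens for ages under 6 must be labelled in mg/kg-day",
           call. = FALSE)
    dd <- daily_dose(r)
    brackets <- covered_brackets(r$age_min_years, r$age_max_years)
    if (nrow(brackets) == 0L)
      stop("regimen age range covers no body-weight bracket", call. = FALSE)
    candidates <- rbind(candidates, data.frame(
      regimen = i, age_min = brackets$age_min,
      weight_kg = brackets$weight_kg,
      ltd = round_sig(dd / brackets$weight_kg, 3L)))
  }
  best <- which.min(candidates$ltd)  # first minimum wins on ties
  structure(list(ltd_mg_kg_day = candidates$ltd[[best]],
                 selected_regimen = candidates$regimen[[best]],
                 selected_age_min = candidates$age_min[[best]],
                 selected_weight_kg = candidates$weight_kg[[best]],
                 candidates = candidates),
            class = "ltd_result")
}

#' @export
print.ltd_result <- function(x, ...) {
  cat(sprintf("<ltd_result> %g mg/kg-day (regimen %d%s)\n",
              x$ltd_mg_kg_day, x$selected_regimen,
              if (is.na(x$selected_age_min)) ", per-kg label"
              else sprintf(", bracket %g, %g kg", x$selected_age_min,
                           x$selected_weight_kg)))
  invisible(x)
}
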