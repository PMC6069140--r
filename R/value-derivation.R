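# sRfD and WSV derivation ----------------------------------------------------
#
# sRfD = LTD / total UF-AF, reported to 2 significant figures.
# WSV  = sRfD x RSC x 1000 (ug/mg) / 0.289 (L/kg-d), reported to 1
# significant figure and computed FROM the already-rounded sRfD
# (two-stage rounding).  0.289 L/kg-d is the 95th-percentile intake of a
# bottle-fed infant aged 1-3 months.  The RSC (relative source
# contribution) is 0.8 except for compounds with widespread paediatric
# over-the-counter use, which receive 0.2.

#' Screening-derivation configuration
#'
#' Collects the numeric conventions of the derivation so they can be
#' varied explicitly for sensitivity analysis.  The defaults reproduce
#' the published method exactly; any override is echoed into the
#' provenance block of serialized results.
#'
#' @param intake_L_kg_d drinking-water intake rate (default 0.289, the
#'   95th-percentile intake of a bottle-fed 1-3-month-old).
#' @param conversion_ug_mg unit conversion (default 1000 ug/mg).
#' @param rsc_default relative source contribution for
#'   prescription-dominated compounds (default 0.8).
#' @param rsc_otc relative source contribution for compounds with
#'   widespread paediatric over-the-counter use (default 0.2).
#' @param srfd_sig significant figures for the screening reference dose
#'   (default 2).
#' @param wsv_sig significant figures for the water screening value
#'   (default 1).
#' @return A list of class `wsv_config`.
#' @export
wsv_config <- function(intake_L_kg_d = 0.289, conversion_ug_mg = 1000,
                       rsc_default = 0.8, rsc_otc = 0.2,
                       srfd_sig = 2L, wsv_sig = 1L) {
  stopifnot(intake_L_kg_d > 0, conversion_ug_mg > 0,
            rsc_default > 0, rsc_default <= 1,
            rsc_otc > 0, rsc_otc <= 1,
            srfd_sig >= 1, wsv_sig >= 1)
  structure(list(intake_L_kg_d = intake_L_kg_d,
                 conversion_ug_mg = conversion_ug_mg,
                 rsc_default = rsc_default, rsc_otc = rsc_otc,
                 srfd_sig = as.integer(srfd_sig),
                 wsv_sig = as.integer(wsv_sig),
                 rounding = "half-away-from-zero"),
            class = "wsv_config")
}

#' Round to significant figures, half away from zero
#'
#' Decimal-intent rounding used throughout the derivation: the mantissa
#' is scaled to `n` digits, half-way cases round away from zero, and a
#' one-part-in-10^9 guard absorbs the binary representation error of
#' decimal inputs (so 0.0125 at 2 figures is 0.013, not the
#' round-half-even 0.012 that `signif()` would give).
#'
#' @param x positive number(s).
#' @param n number of significant figures (`n >= 1`).
#' @return `x` rounded to `n` significant figures.
#' @export
round_sig <- function(x, n) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0),
            length(n) == 1L, n >= 1, n %% 1 == 0)
  e <- floor(log10(x))
  mantissa <- x / 10^e                       # in [1, 10) up to fp error
  m <- mantissa * 10^(n - 1)
  rm <- floor(m + 0.5 + 1e-9)                # half away from zero
  carry <- rm >= 10^n                        # 9.96 at 2 sf -> 10
  rm[carry] <- rm[carry] / 10
  e[carry] <- e[carry] + 1
  k <- e - n + 1
  # divide for negative powers so the result is the correctly rounded
  # double of the decimal value (13/1000 gives the same double as 0.013)
  ifelse(k < 0, rm / 10^(-k), rm * 10^k)
}

#' Screening reference dose from LTD and total factor
#'
#' Divides the lowest therapeutic dose by the combined
#' uncertainty/adjustment factor and rounds to the configured number of
#' significant figures (2 by default).
#'
#' @param ltd_mg_kg_day positive dose (mg/kg-day).
#' @param total a [combine_factors()] result, or a bare total such as
#'   `100` or `30000` (which must lie on the half-log lattice).
#' @param config a [wsv_config()].
#' @return sRfD in mg/kg-day, rounded.
#' @export
compute_srfd <- function(ltd_mg_kg_day, total, config = wsv_config()) {
  stopifnot(is.numeric(ltd_mg_kg_day), length(ltd_mg_kg_day) == 1L,
            ltd_mg_kg_day > 0)
  total_value <- as_total_display(total)
  round_sig(ltd_mg_kg_day / total_value, config$srfd_sig)
}

as_total_display <- function(total) {
  if (inherits(total, "total_factor")) return(total$display_value)
  stopifnot(is.numeric(total), length(total) == 1L, total > 0)
  e <- log10(total)
  on_lattice <- abs(e - round(e)) < 1e-9 ||
    abs(log10(total / 3) - round(log10(total / 3))) < 1e-9
  if (!on_lattice)
    stop(sprintf("total UF/AF %g is not on the half-log lattice", total),
         call. = FALSE)
  total
}

#' Relative source contribution for a profile
#'
#' 0.2 for compounds with numerous over-the-counter paediatric
#' formulations (unintended-overdose concern leaves less of the dose
#' budget to drinking water); 0.8 for everything else, on the assumption
#' that individuals not taking the medication receive most of their
#' exposure through water.
#'
#' @param profile an [evidence_profile()].
#' @param config a [wsv_config()].
#' @return 0.8 or 0.2 (or their configured overrides).
#' @export
select_rsc <- function(profile, config = wsv_config()) {
  if (!inherits(profile, "evidence_profile"))
    stop("`profile` must be an evidence_profile", call. = FALSE)
  if (profile$otc_pediatric_use) config$rsc_otc else config$rsc_default
}

#' Water screening value from a rounded sRfD
#'
#' `WSV = sRfD x RSC x 1000 / 0.289`, rounded to 1 significant figure.
#' The input is the already-rounded sRfD: the published values follow
#' this two-stage convention, and it is observable — an LTD of 12.5 over
#' a total factor of 1000 gives 40 ug/L through the rounded sRfD of
#' 0.013 but would give 30 ug/L from the unrounded quotient 0.0125.
#'
#' @param srfd_mg_kg_day positive, already rounded to the sRfD
#'   convention.
#' @param rsc relative source contribution (0.8 or 0.2 under the
#'   defaults).
#' @param config a [wsv_config()].
#' @return WSV in ug/L, rounded.
#' @export
compute_wsv <- function(srfd_mg_kg_day, rsc, config = wsv_config()) {
  stopifnot(is.numeric(srfd_mg_kg_day), length(srfd_mg_kg_day) == 1L,
            srfd_mg_kg_day > 0, is.numeric(rsc), length(rsc) == 1L,
            rsc > 0, rsc <= 1)
  raw <- srfd_mg_kg_day * rsc * config$conversion_ug_mg / config$intake_L_kg_d
  round_sig(raw, config$wsv_sig)
}

#' Derive screening values end to end for one profile
#'
#' Composes the whole pipeline: eligibility screen, lowest therapeutic
#' dose, the six-factor decision tree with half-log combination, the
#' screening reference dose, the relative source contribution, and the
#' water screening value.  Every rule firing is retained in the result's
#' trace.
#'
#' @param profile an eligible [evidence_profile()] with at least one
#'   general-population regimen.
#' @param config a [wsv_config()].
#' @return An object of class `screening_result` with elements
#'   `api_name`, `casrn`, `ltd_mg_kg_day`, `factors` (a `factor_set`),
#'   `total_uf`, `srfd_mg_kg_day`, `rsc`, `wsv_ug_L`, `config`, and
#'   `trace` (ordered rationale codes).
#' @export
derive_screening_values <- function(profile, config = wsv_config()) {
  decision <- screen_eligibility(profile)
  if (!decision$eligible)
    stop(sprintf("profile '%s' is excluded (%s)", profile$api_name,
                 decision$reason), call. = FALSE)
  ltd <- compute_ltd(profile$regimens)
  factors <- assign_all_factors(profile)
  srfd <- compute_srfd(ltd$ltd_mg_kg_day, factors$total_uf, config)
  rsc <- select_rsc(profile, config)
  wsv <- compute_wsv(srfd, rsc, config)
  trace <- unlist(lapply(FACTOR_IDS, function(id) {
    a <- factors[[id]]
    sprintf("%s=%g%s:%s", a$factor_id, a$value,
            if (a$applied) "" else "(noted)", a$rationale_codes)
  }), use.names = FALSE)
  trace <- c(sprintf("LTD=%g mg/kg-day (regimen %d)", ltd$ltd_mg_kg_day,
                     ltd$selected_regimen),
             trace,
             sprintf("total_UF_AF=%g", factors$total_uf$display_value),
             sprintf("sRfD=%g mg/kg-day", srfd),
             sprintf("RSC=%g%s", rsc,
                     if (profile$otc_pediatric_use) " (OTC pediatric use)"
                     else ""),
             sprintf("WSV=%g ug/L", wsv))
  structure(list(api_name = profile$api_name, casrn = profile$casrn,
                 ltd_mg_kg_day = ltd$ltd_mg_kg_day, ltd_detail = ltd,
                 factors = factors,
                 total_uf = factors$total_uf$display_value,
                 srfd_mg_kg_day = srfd, rsc = rsc, wsv_ug_L = wsv,
                 config = config, trace = trace),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %s\n", x$api_name))
  cat(sprintf("  LTD %g mg/kg-day | total UF/AF %s | sRfD %g mg/kg-day\n",
              x$ltd_mg_kg_day,
              format(x$total_uf, big.mark = ",", scientific = FALSE),
              x$srfd_mg_kg_day))
  cat(sprintf("  RSC %g | WSV %g ug/L\n", x$rsc, x$wsv_ug_L))
  invisible(x)
}

#' Tabulate screening results
#'
#' @param x a `screening_result` or list of them.
#' @param ... unused.
#' @return A data frame with one row per result (columns `api_name`,
#'   `casrn`, `ltd_mg_kg_d`, `total_uf`, `srfd_mg_kg_d`, `rsc`,
#'   `wsv_ug_L`).
#' @export
as.data.frame.screening_result <- function(x, ...) {
  data.frame(api_name = x$api_name, casrn = x$casrn,
             ltd_mg_kg_d = x$ltd_mg_kg_day, total_uf = x$total_uf,
             srfd_mg_kg_d = x$srfd_mg_kg_day, rsc = x$rsc,
             wsv_ug_L = x$wsv_ug_L, stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.screening_result
#' @export
screening_results_table <- function(x) {
  if (inherits(x, "screening_result")) x <- list(x)
  do.call(rbind, lapply(x, as.data.frame))
}
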