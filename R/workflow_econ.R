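# Workflow economics: audit summaries, Welch-Satterthwaite intervals, the
# reporting-session duplication model, and the savings/cost table for
# reflex testing and ROC operating points.
#
# Durations are carried internally in minutes; printed figures are rounded
# half-up to integers at the very end.

#' Summary of one audited group
#'
#' @param n Group size.
#' @param mean Group mean (in `unit`).
#' @param sd Standard deviation (optional if only a CI is known).
#' @param ci95 Optional 95% CI `c(lo, hi)` as printed in the audit.
#' @param unit Unit tag ("hours" or "minutes").
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd = NULL, ci95 = NULL, unit = "minutes") {
  if (!is_count(n, min = 1)) abort("n must be a positive count", "ihctriage_validation_error")
  if (!is.null(sd)) {
    if (sd < 0) abort("sd must be >= 0", "ihctriage_validation_error")
    if (n < 2) abort("n must be >= 2 when sd is used", "ihctriage_validation_error")
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd, ci95 = ci95, unit = unit),
            class = "group_summary")
}

#' Audited turnaround and reporting time summaries
#'
#' The retrospective audit figures the economics defaults are built on:
#' mean turnaround of 7 days 10 h (178 h) for IHC-requested cases
#' (n = 380) versus 4 days 5 h (101 h) without IHC (n = 576), and mean
#' hands-on reporting time of 33.4 min with IHC (n = 133) versus 17.9 min
#' without (n = 128). CIs are the printed ones (no raw data are
#' distributable).
#'
#' @return List with `turnaround` and `reporting`, each a list of two
#'   [group_summary()] objects (`ihc`, `no_ihc`).
#' @export
audit_summaries <- function() {
  list(
    turnaround = list(
      ihc = group_summary(380, 178, ci95 = c(170, 184), unit = "hours"),
      no_ihc = group_summary(576, 101, ci95 = c(96, 105), unit = "hours")
    ),
    reporting = list(
      ihc = group_summary(133, 33.4, ci95 = c(30.7, 36.2), unit = "minutes"),
      no_ihc = group_summary(128, 17.9, ci95 = c(16.7, 19.0), unit = "minutes")
    )
  )
}

#' Welch two-sample interval from group summaries
#'
#' Mean difference `mean1 - mean2` with a t interval on
#' `sqrt(sd1^2/n1 + sd2^2/n2)` and effective degrees of freedom by the
#' Welch-Satterthwaite approximation. For equal variances and equal n the
#' df collapse to `n1 + n2 - 2` exactly.
#'
#' @param g1,g2 [group_summary()] objects with `sd` present and equal units.
#' @param level Confidence level (default 0.95).
#' @return List with `diff`, `lower`, `upper`, `df`, `level`, `unit`.
#' @export
welch_interval <- function(g1, g2, level = 0.95) {
  if (is.null(g1$sd) || is.null(g2$sd)) {
    abort("both groups need an sd; supply the printed CI via audit_differences() instead",
          "ihctriage_input_error")
  }
  if (g1$unit != g2$unit) abort("unit mismatch between groups", "ihctriage_input_error")
  v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
  se2 <- v1 + v2
  df <- se2^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  diff <- g1$mean - g2$mean
  tq <- stats::qt(1 - (1 - level) / 2, df)
  list(diff = diff, lower = diff - tq * sqrt(se2), upper = diff + tq * sqrt(se2),
       df = df, level = level, unit = g1$unit)
}

#' Differences between audited groups
#'
#' Turnaround difference in hours and reporting difference in minutes from
#' the group means, passing through the printed CIs (which come from the
#' audit itself, not from a recomputation).
#'
#' @param turnaround List of two `group_summary` (ihc, no_ihc) in hours.
#' @param reporting List of two `group_summary` (ihc, no_ihc) in minutes.
#' @return List with `turnaround_diff_hours`, `reporting_diff_minutes`, and
#'   the pass-through CIs.
#' @export
audit_differences <- function(turnaround = audit_summaries()$turnaround,
                              reporting = audit_summaries()$reporting) {
  if (turnaround$ihc$unit != turnaround$no_ihc$unit ||
      reporting$ihc$unit != reporting$no_ihc$unit) {
    abort("unit mismatch within a comparison", "ihctriage_input_error")
  }
  list(
    turnaround_diff_hours = turnaround$ihc$mean - turnaround$no_ihc$mean,
    reporting_diff_minutes = reporting$ihc$mean - reporting$no_ihc$mean,
    turnaround_ci = list(ihc = turnaround$ihc$ci95, no_ihc = turnaround$no_ihc$ci95),
    reporting_ci = list(ihc = reporting$ihc$ci95, no_ihc = reporting$no_ihc$ci95)
  )
}

#' Reporting-session duplication model
#'
#' Components of pathologist time duplicated when an IHC case is reviewed
#' over two sessions instead of one: re-reviewing the H&E, the extra
#' decision step, and raising the IHC request. Reviewing the IHC itself is
#' not duplicated work and is excluded from the saving.
#'
#' @param reread_he_min Minutes re-reviewing the H&E in session 2.
#' @param review_ihc_min Minutes reviewing the IHC (not a duplication).
#' @param extra_decision_min Minutes for the additional decision step.
#' @param request_task_min Minutes spent raising the IHC request.
#' @return Object of class `session_model`.
#' @export
session_model <- function(reread_he_min = 7.5, review_ihc_min = 7.5,
                          extra_decision_min = 1.5, request_task_min = 1.0) {
  vals <- c(reread_he_min, review_ihc_min, extra_decision_min, request_task_min)
  if (any(vals < 0)) abort("session components must be non-negative", "ihctriage_validation_error")
  structure(list(reread_he_min = reread_he_min, review_ihc_min = review_ihc_min,
                 extra_decision_min = extra_decision_min,
                 request_task_min = request_task_min),
            class = "session_model")
}

#' Minutes saved per case by avoiding session duplication
#'
#' Sum of the duplicated components: H&E re-review + extra decision +
#' request task. With the default components this is 10 minutes; the
#' 11-minute per-case figure used in the economics table is a separate,
#' deliberately conservative input parameter (see the methods vignette).
#'
#' @param model A [session_model()].
#' @return Minutes saved per case.
#' @export
session_duplication <- function(model = session_model()) {
  model$reread_he_min + model$extra_decision_min + model$request_task_min
}

#' Economics parameters
#'
#' @param n_cases Audited IHC-requested cases the table is scaled to.
#' @param per_case_turnaround_saving_h Hours of turnaround saved per
#'   detected case (default 74 = 3 days 2 h, the conservative audit bound).
#' @param per_case_reporting_saving_min Minutes of reporting time saved per
#'   detected case.
#' @param ihc_unit_cost Cost of one unnecessary IHC order (GBP).
#' @return Object of class `econ_params`.
#' @export
econ_params <- function(n_cases = 380L, per_case_turnaround_saving_h = 74,
                        per_case_reporting_saving_min = 11, ihc_unit_cost = 11) {
  vals <- c(n_cases, per_case_turnaround_saving_h,
            per_case_reporting_saving_min, ihc_unit_cost)
  if (any(vals < 0)) abort("economics parameters must be non-negative", "ihctriage_validation_error")
  structure(list(n_cases = as.integer(n_cases),
                 per_case_turnaround_saving_h = per_case_turnaround_saving_h,
                 per_case_reporting_saving_min = per_case_reporting_saving_min,
                 ihc_unit_cost = ihc_unit_cost),
            class = "econ_params")
}

#' Operating assumptions for the economics table
#'
#' Each assumption is a detection fraction d (share of IHC-needing cases
#' the tool flags in advance) and a false-positive fraction f (share of
#' slides over-ordered). Reflex testing orders IHC on everything: d = 1,
#' f = 1. The default set is reflex testing plus the three ROC operating
#' points at specificities 0.6 / 0.75 / 0.9, whose detection and
#' false-positive fractions are scenario inputs taken from the audit.
#'
#' @param label Row label.
#' @param detection_fraction d in `[0, 1]`.
#' @param false_positive_fraction f in `[0, 1]`.
#' @return A one-row data frame (`operating_assumption`).
#' @export
operating_assumption <- function(label, detection_fraction, false_positive_fraction) {
  if (detection_fraction < 0 || detection_fraction > 1 ||
      false_positive_fraction < 0 || false_positive_fraction > 1) {
    abort("fractions must lie in [0, 1]", "ihctriage_validation_error")
  }
  data.frame(label = label, detection_fraction = detection_fraction,
             false_positive_fraction = false_positive_fraction,
             stringsAsFactors = FALSE)
}

#' @rdname operating_assumption
#' @export
default_operating_assumptions <- function() {
  rbind(
    operating_assumption("reflex_testing", 1.0, 1.0),
    operating_assumption("point_1_spec_0.60", 0.60, 0.15),
    operating_assumption("point_2_spec_0.75", 0.75, 0.33),
    operating_assumption("point_3_spec_0.90", 0.90, 0.48)
  )
}

#' Savings and cost table for a set of operating assumptions
#'
#' Per row: turnaround savings in days
#' `round(d * n_cases * saving_h / 24)`, reporting savings in hours
#' `round(d * n_cases * saving_min / 60)`, and the extra cost of
#' unnecessary IHC `round(f * n_cases * unit_cost)`; rounding is half-up to
#' integers, applied only at the end. Pure arithmetic in the inputs.
#'
#' @param params An [econ_params()].
#' @param assumptions Data frame of operating assumptions.
#' @return Data frame with rounded columns `turnaround_savings_days`,
#'   `reporting_savings_hours`, `extra_cost_currency` and their `_exact`
#'   unrounded counterparts.
#' @export
econ_table <- function(params = econ_params(),
                       assumptions = default_operating_assumptions()) {
  d <- assumptions$detection_fraction
  f <- assumptions$false_positive_fraction
  if (any(d < 0 | d > 1 | f < 0 | f > 1)) {
    abort("fractions must lie in [0, 1]", "ihctriage_validation_error")
  }
  turn_exact <- d * params$n_cases * params$per_case_turnaround_saving_h / 24
  rep_exact <- d * params$n_cases * params$per_case_reporting_saving_min / 60
  cost_exact <- f * params$n_cases * params$ihc_unit_cost
  data.frame(
    label = assumptions$label,
    detection_fraction = d,
    false_positive_fraction = f,
    turnaround_savings_days = round_half_up(turn_exact),
    reporting_savings_hours = round_half_up(rep_exact),
    extra_cost_currency = round_half_up(cost_exact),
    turnaround_savings_days_exact = turn_exact,
    reporting_savings_hours_exact = rep_exact,
    extra_cost_currency_exact = cost_exact,
    stringsAsFactors = FALSE
  )
}

#' Reporting-time saving scaled to many biopsy sets
#'
#' `n_sets * d * per_case_min / 60` hours: the pathologist time saved
#' across `n_sets` sets of prostate biopsies needing IHC when a fraction
#' `d` of them is detected in advance.
#'
#' @param n_sets Number of biopsy sets.
#' @param detection_fraction Detected fraction d.
#' @param per_case_min Minutes saved per detected set.
#' @return Hours saved.
#' @examples
#' scaled_reporting_saving(1000, 0.9, 11)  # 165 h
#' @export
scaled_reporting_saving <- function(n_sets, detection_fraction, per_case_min = 11) {
  if (any(c(n_sets, detection_fraction, per_case_min) < 0)) {
    abort("inputs must be non-negative", "ihctriage_validation_error")
  }
  n_sets * detection_fraction * per_case_min / 60
}
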