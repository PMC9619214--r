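#' Drug component of a regimen
#'
#' @param drug Drug name; must have a unit price (per mg) in the locale.
#' @param dose Dose amount per administration, in the unit of
#'   `dose_rule`.
#' @param dose_rule How the dose resolves to milligrams: `"per_mg"`
#'   (flat mg), `"per_m2"` (mg per m2 of body surface area) or
#'   `"per_kg"` (mg per kg of body weight).
#' @param schedule `"per_day"` (one administration per day of the
#'   cycle) or `"per_cycle"` (one administration per cycle).
#' @param max_cycles Number of cycles the component is given
#'   (`Inf` = until progression); e.g. 4 for a four-cycle platinum.
#' @param iv Intravenous administration?  IV components attract the
#'   locale's infusion cost per administration.
#' @return A `drug_component` list.
#' @export
drug_component <- function(drug, dose,
                           dose_rule = c("per_mg", "per_m2", "per_kg"),
                           schedule = c("per_day", "per_cycle"),
                           max_cycles = Inf, iv = FALSE) {
  dose_rule <- match.arg(dose_rule)
  schedule <- match.arg(schedule)
  if (dose <= 0) stop("drug_component: dose must be > 0", call. = FALSE)
  if (max_cycles < 1) stop("drug_component: max_cycles must be >= 1", call. = FALSE)
  structure(list(drug = drug, dose = dose, dose_rule = dose_rule,
                 schedule = schedule, max_cycles = max_cycles,
                 iv = isTRUE(iv)),
            class = "drug_component")
}

#' Treatment regimen
#'
#' @param name Regimen label.
#' @param components List of [drug_component()]s.
#' @return A `regimen` object.
#' @export
regimen <- function(name, components) {
  stopifnot(all(vapply(components, inherits, logical(1), "drug_component")))
  structure(list(name = name, components = components), class = "regimen")
}

#' Locale-specific economic inputs
#'
#' Unit prices and non-drug costs for one payer perspective, plus the
#' anthropometrics that resolve per-m2 / per-kg dosing.
#'
#' @param prices Named list/vector of drug unit prices in $ per mg.
#' @param bsa Body surface area in m2 (e.g. 1.79 US, 1.72 China).
#' @param weight Body weight in kg (e.g. 70 US, 65 China).
#' @param costs Named list with elements `egfr_testing` (one-off at
#'   entry), `followup_per_cycle`, `bsc_per_cycle`, `end_of_life`
#'   (one-off at death), `radiotherapy`, `infusion_per_admin`.
#' @param discount_rate_annual Annual discount rate.
#' @param wtp Willingness-to-pay threshold(s), $ per QALY.
#' @return A `locale_economics` object.
#' @export
locale_economics <- function(prices, bsa, weight, costs,
                             discount_rate_annual, wtp) {
  prices <- as.list(prices)
  costs <- as.list(costs)
  need <- c("egfr_testing", "followup_per_cycle", "bsc_per_cycle",
            "end_of_life", "radiotherapy", "infusion_per_admin")
  missing <- setdiff(need, names(costs))
  if (length(missing) > 0) {
    stop(sprintf("locale_economics: missing cost entries: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(unlist(costs) < 0) || any(unlist(prices) < 0)) {
    stop("locale_economics: costs and prices must be >= 0", call. = FALSE)
  }
  if (bsa <= 0 || weight <= 0) {
    stop("locale_economics: bsa and weight must be > 0", call. = FALSE)
  }
  structure(list(prices = prices, bsa = bsa, weight = weight,
                 costs = costs,
                 discount_rate_annual = discount_rate_annual, wtp = wtp),
            class = "locale_economics")
}

#' Drug-acquisition cost of one model cycle
#'
#' Sums, over the regimen components active at `cycle_index` (0-based;
#' a component with `max_cycles = m` contributes for cycles
#' `0 .. m-1`):
#' `resolved dose (mg) x unit price ($/mg) x administrations per
#' cycle`, plus the locale infusion cost per administration for IV
#' components.  Daily components administer once per day of the cycle.
#'
#' @param reg A [regimen()].
#' @param cycle_index 0-based cycle number.
#' @param locale A [locale_economics()].
#' @param settings A [model_settings()] (supplies days per cycle).
#' @return Cost in $ for that cycle.
#' @export
regimen_cycle_cost <- function(reg, cycle_index, locale, settings) {
  stopifnot(inherits(reg, "regimen"), inherits(locale, "locale_economics"))
  if (any(cycle_index < 0)) {
    stop("regimen_cycle_cost: cycle_index must be >= 0", call. = FALSE)
  }
  days <- settings$cycle_length_days
  vapply(cycle_index, function(k) {
    total <- 0
    for (comp in reg$components) {
      if (k >= comp$max_cycles) next
      price <- locale$prices[[comp$drug]]
      if (is.null(price)) {
        stop(sprintf("regimen_cycle_cost: no unit price configured for drug '%s'",
                     comp$drug), call. = FALSE)
      }
      mg <- comp$dose * switch(comp$dose_rule,
                               per_mg = 1, per_m2 = locale$bsa,
                               per_kg = locale$weight)
      admins <- if (comp$schedule == "per_day") days else 1
      total <- total + mg * price * admins +
        (if (comp$iv) locale$costs$infusion_per_admin * admins else 0)
    }
    total
  }, numeric(1))
}

#' Filter a trial adverse-event table for model inclusion
#'
#' Keeps grade >= 3 adverse events whose incidence differs between the
#' arms by strictly more than `threshold` (default 5 percentage
#' points), the usual inclusion rule for trial-based models.
#'
#' @param ae_table Data frame with columns `name`, `inc_a`, `inc_b`
#'   (per-arm incidences in `[0, 1]`), `cost` (one-off management
#'   cost), `disutility`, `duration_years`.
#' @param threshold Absolute incidence-difference cutoff (strict
#'   inequality).
#' @return The filtered data frame (possibly 0 rows).
#' @export
filter_adverse_events <- function(ae_table, threshold = 0.05) {
  ae_table <- validate_ae_table(ae_table)
  ae_table[abs(ae_table$inc_a - ae_table$inc_b) > threshold, , drop = FALSE]
}

validate_ae_table <- function(ae_table) {
  need <- c("name", "inc_a", "inc_b", "cost", "disutility", "duration_years")
  if (!is.data.frame(ae_table)) {
    stop("ae_table must be a data frame", call. = FALSE)
  }
  if (nrow(ae_table) == 0L) {
    for (col in need) if (!col %in% names(ae_table)) ae_table[[col]] <- numeric(0)
    return(ae_table)
  }
  missing <- setdiff(need, names(ae_table))
  if (length(missing) > 0) {
    stop(sprintf("ae_table: missing columns %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(ae_table$inc_a < 0 | ae_table$inc_a > 1 |
          ae_table$inc_b < 0 | ae_table$inc_b > 1)) {
    stop("ae_table: incidences must be in [0, 1]", call. = FALSE)
  }
  if (any(ae_table$duration_years < 0)) {
    stop("ae_table: durations must be >= 0", call. = FALSE)
  }
  ae_table
}

#' Expected adverse-event burden for one arm
#'
#' Expected one-off management cost and QALY decrement of the included
#' adverse events, both applied at model entry:
#' cost `= sum(incidence x cost)`, decrement
#' `= sum(incidence x disutility x duration)`.
#'
#' @param included Adverse-event table (after
#'   [filter_adverse_events()]).
#' @param arm `"a"` or `"b"`: which incidence column applies.
#' @return List with `one_off_cost` and `qaly_decrement`.
#' @export
ae_burden <- function(included, arm = c("a", "b")) {
  arm <- match.arg(arm)
  included <- validate_ae_table(included)
  inc <- included[[paste0("inc_", arm)]]
  list(one_off_cost = sum(inc * included$cost),
       qaly_decrement = sum(inc * included$disutility *
                              included$duration_years))
}

#' Strategy (arm) specification
#'
#' Everything needed to evaluate one treatment strategy: survival
#' curves, regimen, utilities, adverse-event burden, post-progression
#' policy and the locale economics.
#'
#' @param name Arm label.
#' @param pfs,os Survival curves (`dist_spec`, `hr_spec` or
#'   `survival_fit`).
#' @param reg The arm's [regimen()].
#' @param utilities List with `pfs` and `pd` state utilities.
#' @param locale A [locale_economics()].
#' @param discontinuation Fraction of patients who stop the assigned
#'   drug for toxicity while progression-free (drug cost removed for
#'   that fraction from cycle 2 onward).
#' @param subsequent_fraction Fraction of progressed patients receiving
#'   active subsequent therapy (the remainder receive best supportive
#'   care only).
#' @param subsequent_cost_per_cycle Per-cycle cost of subsequent
#'   therapy for those who receive it.
#' @param ae_table Adverse-event table (see
#'   [filter_adverse_events()]); filtered on construction.
#' @param ae_arm Which incidence column (`"a"`/`"b"`) is this arm.
#' @param ae_threshold Inclusion cutoff passed to
#'   [filter_adverse_events()].
#' @return An `arm_spec` object.
#' @export
arm_spec <- function(name, pfs, os, reg, utilities, locale,
                     discontinuation = 0,
                     subsequent_fraction = 0,
                     subsequent_cost_per_cycle = 0,
                     ae_table = NULL, ae_arm = "a",
                     ae_threshold = 0.05) {
  stopifnot(inherits(reg, "regimen"), inherits(locale, "locale_economics"))
  if (discontinuation < 0 || discontinuation > 1 ||
      subsequent_fraction < 0 || subsequent_fraction > 1) {
    stop("arm_spec: fractions must be in [0, 1]", call. = FALSE)
  }
  if (is.null(ae_table)) {
    ae_table <- data.frame(name = character(0), inc_a = numeric(0),
                           inc_b = numeric(0), cost = numeric(0),
                           disutility = numeric(0),
                           duration_years = numeric(0))
  }
  structure(list(
    name = name, pfs = as_curve(pfs), os = as_curve(os), regimen = reg,
    utilities = utilities, locale = locale,
    discontinuation = discontinuation,
    subsequent_fraction = subsequent_fraction,
    subsequent_cost_per_cycle = subsequent_cost_per_cycle,
    ae_included = filter_adverse_events(ae_table, ae_threshold),
    ae_arm = ae_arm
  ), class = "arm_spec")
}

#' Per-cycle value streams for an arm
#'
#' Assembles the cost and utility streams the engine accrues:
#'
#' * progression-free state: drug acquisition (scaled by
#'   `1 - discontinuation` from the second cycle onward) + follow-up
#'   (infusion costs are folded into the regimen cost);
#' * progressed state: `fraction x subsequent therapy +
#'   (1 - fraction) x best supportive care` per cycle;
#' * one-offs: EGFR mutation testing and expected adverse-event
#'   management cost at entry, end-of-life cost at death;
#' * utilities: state utilities, with the expected adverse-event QALY
#'   decrement applied once at entry.
#'
#' @param arm An [arm_spec()].
#' @param settings A [model_settings()].
#' @param n_cycles Number of model cycles the streams must cover.
#' @return List with `cost` (list for [accrue()]), `utilities`, and
#'   `ae_decrement`.
#' @export
build_value_streams <- function(arm, settings, n_cycles) {
  stopifnot(inherits(arm, "arm_spec"))
  locale <- arm$locale
  k <- seq_len(n_cycles) - 1L
  drug <- regimen_cycle_cost(arm$regimen, k, locale, settings)
  keep <- ifelse(k == 0, 1, 1 - arm$discontinuation)
  pfs_cost <- drug * keep + locale$costs$followup_per_cycle
  pd_cost <- arm$subsequent_fraction * arm$subsequent_cost_per_cycle +
    (1 - arm$subsequent_fraction) * locale$costs$bsc_per_cycle
  ae <- ae_burden(arm$ae_included, arm$ae_arm)
  list(
    cost = list(
      pfs = pfs_cost,
      pd = rep(pd_cost, n_cycles),
      entry_one_off = locale$costs$egfr_testing + ae$one_off_cost,
      death_one_off = locale$costs$end_of_life
    ),
    utilities = arm$utilities,
    ae_decrement = ae$qaly_decrement
  )
}

#' Evaluate one strategy: discounted cost, life-years and QALYs
#'
#' Builds the cohort trace from the arm's curves and accrues the value
#' streams of [build_value_streams()].
#'
#' @param arm An [arm_spec()].
#' @param settings A [model_settings()]; its discount rate defaults to
#'   the arm locale's rate if `NULL`.
#' @return List of class `arm_result`: `name`, `cost`, `ly`, `qaly`,
#'   `trace`.
#' @export
evaluate_arm <- function(arm, settings = NULL) {
  stopifnot(inherits(arm, "arm_spec"))
  if (is.null(settings)) {
    settings <- model_settings(
      discount_rate_annual = arm$locale$discount_rate_annual)
  }
  trace <- build_trace(arm$pfs, arm$os, settings)
  n_cycles <- nrow(trace) - 1L
  streams <- build_value_streams(arm, settings, n_cycles)
  cost <- accrue(trace, streams$cost, settings)
  ly <- life_years(trace, settings)
  qy <- qalys(trace, streams$utilities, streams$ae_decrement, settings)
  structure(list(name = arm$name, cost = cost, ly = ly, qaly = qy,
                 trace = trace),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost $%.0f, %.3f LY, %.3f QALY\n",
              x$name, x$cost, x$ly, x$qaly))
  invisible(x)
}
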