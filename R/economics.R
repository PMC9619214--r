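#' Incremental cost-effectiveness analysis of two strategies
#'
#' Computes incremental cost, effectiveness, ICERs and the dominance
#' classification of strategy `a` versus comparator `b`.
#'
#' The ICER is reported as the plain ratio `dC/dE` in every quadrant
#' (so a more expensive, less effective strategy prints a negative
#' ICER, and a cheaper, less effective one a positive south-west ICER
#' that must be compared against the willingness-to-pay threshold with
#' the decision rule reversed); the `dominance` flag carries the
#' interpretation: `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and less effective), `"tradeoff"`
#' otherwise, `"equal_effect"` when `dE = 0` (ICER undefined, NMB
#' still valid).
#'
#' @param a,b Arm results: lists with `cost`, `qaly`, `ly` and
#'   optionally `name` ([evaluate_arm()] output, or plain lists of
#'   published totals).
#' @return An object of class `ce_result` with per-arm totals and
#'   `delta_cost`, `delta_qaly`, `delta_ly`, `icer_qaly`, `icer_ly`,
#'   `dominance`.
#' @examples
#' a <- list(name = "new", cost = 224575, qaly = 1.75, ly = 2.31)
#' b <- list(name = "std", cost = 156987, qaly = 1.32, ly = 1.81)
#' incremental_analysis(a, b)
#' @export
incremental_analysis <- function(a, b) {
  for (x in list(a, b)) {
    if (!all(c("cost", "qaly", "ly") %in% names(x))) {
      stop("incremental_analysis: arms need cost, qaly and ly elements",
           call. = FALSE)
    }
  }
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  dl <- a$ly - b$ly
  icer_q <- if (dq != 0) dc / dq else NA_real_
  icer_l <- if (dl != 0) dc / dl else NA_real_
  dominance <-
    if (dq == 0) "equal_effect"
    else if (dc <= 0 && dq > 0) "dominant"
    else if (dc >= 0 && dq < 0) "dominated"
    else "tradeoff"
  structure(list(
    arm_a = list(name = a$name %||% "a", cost = a$cost, qaly = a$qaly,
                 ly = a$ly),
    arm_b = list(name = b$name %||% "b", cost = b$cost, qaly = b$qaly,
                 ly = b$ly),
    delta_cost = dc, delta_qaly = dq, delta_ly = dl,
    icer_qaly = icer_q, icer_ly = icer_l,
    dominance = dominance
  ), class = "ce_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s\n", x$arm_a$name, x$arm_b$name))
  cat(sprintf("  %-22s cost $%11.0f  %6.3f QALY  %6.3f LY\n",
              x$arm_a$name, x$arm_a$cost, x$arm_a$qaly, x$arm_a$ly))
  cat(sprintf("  %-22s cost $%11.0f  %6.3f QALY  %6.3f LY\n",
              x$arm_b$name, x$arm_b$cost, x$arm_b$qaly, x$arm_b$ly))
  cat(sprintf("  dC = $%.0f, dQALY = %.3f, ICER = %s $/QALY  [%s]\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer_qaly)) "undefined"
              else sprintf("%.0f", x$icer_qaly),
              x$dominance))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp x QALY - cost`.  Between two strategies, the one with
#' the higher NMB is preferred; when `dQALY > 0` this agrees with the
#' rule "adopt if ICER < WTP".
#'
#' @param cost Discounted cost ($).
#' @param qaly Discounted QALYs.
#' @param wtp Willingness-to-pay threshold ($/QALY), `>= 0`.
#' @return NMB in $.  Vectorized over all arguments.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) {
    stop("net_monetary_benefit: wtp must be >= 0", call. = FALSE)
  }
  wtp * qaly - cost
}

#' Incremental net monetary benefit of a comparison
#'
#' `wtp x dQALY - dCost`; positive means the intervention is
#' preferred at that threshold.
#'
#' @param ce A `ce_result` (or list with `delta_cost`, `delta_qaly`).
#' @param wtp Threshold(s), $/QALY.
#' @return Incremental NMB, vectorized over `wtp`.
#' @export
incremental_nmb <- function(ce, wtp) {
  wtp * ce$delta_qaly - ce$delta_cost
}

#' Drug-price threshold search
#'
#' Finds the unit price at which the intervention's incremental net
#' monetary benefit is zero at a given willingness-to-pay threshold —
#' the price below which the intervention becomes cost-effective.
#' Because the total accrued drug cost is linear in the unit price, the
#' incremental NMB is monotone in price and bisection converges to the
#' requested tolerance.
#'
#' @param model A function `price -> ce_result` (or any list with
#'   `delta_cost` and `delta_qaly`) that re-evaluates the full model at
#'   that unit price.
#' @param wtp Willingness-to-pay threshold ($/QALY).
#' @param bracket Length-2 price bracket; the incremental NMB must
#'   change sign across it.
#' @param tol Price tolerance in $/mg (default 1e-5, so the residual
#'   incremental NMB at the returned price is far below $1 for
#'   realistic accrued quantities).
#' @return List with `price`, the `ce_result` re-evaluated at it, and
#'   its residual `inmb`.
#' @export
price_threshold_search <- function(model, wtp, bracket, tol = 1e-5) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  f <- function(p) incremental_nmb(model(p), wtp)
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) {
    stop(sprintf("price_threshold_search: no sign change in bracket [%g, %g]: inmb(%g) = %.2f, inmb(%g) = %.2f",
                 lo, hi, lo, f_lo, hi, f_hi), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (f_mid == 0) { lo <- mid; hi <- mid; break }
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid }
    else hi <- mid
  }
  price <- (lo + hi) / 2
  ce <- model(price)
  list(price = price, ce = ce, inmb = incremental_nmb(ce, wtp))
}

#' Subgroup specification
#'
#' A subgroup is defined, relative to the full trial population, only
#' by its treatment-effect hazard ratios: all other model inputs are
#' inherited from the base case.
#'
#' @param name Subgroup label.
#' @param hr_pfs,hr_os Hazard ratios (intervention vs comparator) for
#'   progression-free and overall survival, `> 0`.
#' @param hr_pfs_ci,hr_os_ci Optional length-2 95% confidence
#'   intervals.
#' @return A `subgroup_spec` object.
#' @export
subgroup_spec <- function(name, hr_pfs, hr_os,
                          hr_pfs_ci = NULL, hr_os_ci = NULL) {
  if (is.null(hr_pfs) || is.null(hr_os) ||
      is.na(hr_pfs) || is.na(hr_os) || hr_pfs <= 0 || hr_os <= 0) {
    stop("subgroup_spec: hr_pfs and hr_os must be > 0", call. = FALSE)
  }
  structure(list(name = name, hr_pfs = hr_pfs, hr_os = hr_os,
                 hr_pfs_ci = hr_pfs_ci, hr_os_ci = hr_os_ci),
            class = "subgroup_spec")
}

#' Run a subgroup analysis
#'
#' The subgroup's intervention-arm survival curves are derived from the
#' *comparator's* fitted curves by hazard-ratio adjustment
#' ([hr_adjust()]) with the subgroup's `hr_pfs` and `hr_os`; the
#' comparator arm and every other input are inherited unchanged from
#' the base case.
#'
#' @param intervention,comparator Base-case [arm_spec()]s.
#' @param subgroup A [subgroup_spec()].
#' @param settings A [model_settings()] (defaults from the locale as in
#'   [evaluate_arm()]).
#' @param hr_mode Hazard-ratio adjustment mode, see
#'   [hr_adjusted_survival()].
#' @return A `ce_result` for the subgroup.
#' @export
run_subgroup <- function(intervention, comparator, subgroup,
                         settings = NULL,
                         hr_mode = c("proportional_hazards",
                                     "rate_multiply")) {
  stopifnot(inherits(subgroup, "subgroup_spec"))
  hr_mode <- match.arg(hr_mode)
  sg_arm <- intervention
  sg_arm$name <- paste0(intervention$name, " (", subgroup$name, ")")
  sg_arm$pfs <- hr_adjust(comparator$pfs, subgroup$hr_pfs, hr_mode)
  sg_arm$os <- hr_adjust(comparator$os, subgroup$hr_os, hr_mode)
  incremental_analysis(evaluate_arm(sg_arm, settings),
                       evaluate_arm(comparator, settings))
}

#' Willingness-to-pay scenario analysis
#'
#' For a deterministic `ce_result`: the preferred strategy at each
#' threshold by net monetary benefit.  For a PSA sample
#' ([run_psa()]): the acceptance probability at each threshold
#' (delegates to [ceac()]).
#'
#' @param x A `ce_result` or `psa_sample`.
#' @param wtp_list Non-empty vector of thresholds ($/QALY).
#' @return Data frame with one row per threshold: `wtp`, and either
#'   `inmb` + `preferred`, or `prob_cost_effective`.
#' @export
run_scenario <- function(x, wtp_list) {
  if (length(wtp_list) == 0L) {
    stop("run_scenario: empty WTP list", call. = FALSE)
  }
  if (inherits(x, "psa_sample")) {
    return(ceac(x, wtp_list))
  }
  stopifnot(inherits(x, "ce_result"))
  inmb <- incremental_nmb(x, wtp_list)
  data.frame(
    wtp = wtp_list,
    inmb = inmb,
    preferred = ifelse(inmb > 0, x$arm_a$name,
                       ifelse(inmb < 0, x$arm_b$name, "indifferent"))
  )
}

#' Write base-case results as CSV
#'
#' One row per strategy with discounted cost, QALYs, LYs and (on the
#' intervention row) the ICERs, mirroring the usual base-case results
#' table of a cost-effectiveness paper.
#'
#' @param ce A `ce_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_result <- function(ce, path) {
  stopifnot(inherits(ce, "ce_result"))
  df <- data.frame(
    strategy = c(ce$arm_a$name, ce$arm_b$name),
    cost = c(ce$arm_a$cost, ce$arm_b$cost),
    qaly = c(ce$arm_a$qaly, ce$arm_b$qaly),
    ly = c(ce$arm_a$ly, ce$arm_b$ly),
    icer_per_qaly = c(ce$icer_qaly, NA_real_),
    icer_per_ly = c(ce$icer_ly, NA_real_),
    dominance = c(ce$dominance, NA_character_)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write subgroup results as CSV
#'
#' @param results Named list of `ce_result`s (one per subgroup).
#' @param specs Matching list of [subgroup_spec()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subgroup_results <- function(results, specs, path) {
  rows <- lapply(seq_along(results), function(i) {
    ce <- results[[i]]; sg <- specs[[i]]
    data.frame(subgroup = sg$name, hr_pfs = sg$hr_pfs, hr_os = sg$hr_os,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer_per_qaly = ce$icer_qaly, dominance = ce$dominance)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
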