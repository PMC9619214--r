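#' Sensitivity-analysis parameter definition
#'
#' One uncertain model input: its base value, deterministic range and
#' the probabilistic distribution implied by its role, following the
#' usual conventions of health-economic models: costs are gamma,
#' probabilities and utilities are beta, hazard ratios / body surface
#' area / body weight are normal (truncated positive at draw time).
#'
#' When no interval is supplied the range defaults to +/-25% of the
#' base value; when no standard error is supplied it is derived from
#' the range read as a 95% interval, `se = (high - low)/(2 x 1.96)`
#' (divisor configurable via `z`).
#'
#' @param name Parameter name (also the override key for the model
#'   closure).
#' @param base Base-case value.
#' @param role One of `"cost"`, `"probability"`, `"utility"`, `"hr"`,
#'   `"bsa"`, `"weight"`.
#' @param low,high Deterministic bounds (default `0.75 x base`,
#'   `1.25 x base`).
#' @param se Standard error for the PSA distribution (default from the
#'   bounds).
#' @param path Character vector addressing the parameter inside a run
#'   configuration (used by [make_model()]); defaults to `name`.
#' @param z Quantile divisor used when deriving `se` from the bounds.
#' @return A `param_def` object.
#' @export
param_def <- function(name, base,
                      role = c("cost", "probability", "utility", "hr",
                               "bsa", "weight"),
                      low = NULL, high = NULL, se = NULL,
                      path = NULL, z = 1.96) {
  role <- match.arg(role)
  if (is.null(low)) low <- 0.75 * base
  if (is.null(high)) high <- 1.25 * base
  if (role %in% c("probability", "utility")) {
    low <- max(low, 0); high <- min(high, 1)
  }
  if (!(low <= base && base <= high)) {
    stop(sprintf("param_def '%s': need low <= base <= high", name),
         call. = FALSE)
  }
  if (is.null(se)) se <- (high - low) / (2 * z)
  if (se < 0) stop(sprintf("param_def '%s': se must be >= 0", name),
                   call. = FALSE)
  structure(list(name = name, base = base, role = role,
                 low = low, high = high, se = se,
                 path = path %||% name),
            class = "param_def")
}

#' Moment matching for sensitivity-analysis distributions
#'
#' Converts a (mean, se) pair into the distribution parameters implied
#' by the parameter's role:
#'
#' * cost -> gamma: `shape = mean^2/se^2`, `scale = se^2/mean`;
#' * probability / utility -> beta:
#'   `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#'   `nu = mean(1 - mean)/se^2 - 1` (requires `se^2 < mean(1 - mean)`);
#' * hr / bsa / weight -> normal: `(mean, se)`.
#'
#' The returned distribution reproduces the requested mean and se
#' exactly.
#'
#' @param role Parameter role, see [param_def()].
#' @param mean,se Target mean and standard error (`se > 0`; for beta,
#'   `mean` in `(0, 1)`).
#' @return List with `dist` (`"gamma"`, `"beta"` or `"normal"`) and
#'   the named parameters.
#' @export
moment_match <- function(role, mean, se) {
  role <- match.arg(role, c("cost", "probability", "utility", "hr",
                            "bsa", "weight"))
  if (se <= 0) stop("moment_match: se must be > 0", call. = FALSE)
  if (role == "cost") {
    if (mean <= 0) stop("moment_match: gamma requires mean > 0", call. = FALSE)
    list(dist = "gamma", shape = mean^2 / se^2, scale = se^2 / mean)
  } else if (role %in% c("probability", "utility")) {
    if (mean <= 0 || mean >= 1) {
      stop("moment_match: beta requires mean in (0, 1)", call. = FALSE)
    }
    if (se^2 >= mean * (1 - mean)) {
      stop(sprintf("moment_match: beta infeasible, se^2 = %.4g >= mean(1-mean) = %.4g",
                   se^2, mean * (1 - mean)), call. = FALSE)
    }
    nu <- mean * (1 - mean) / se^2 - 1
    list(dist = "beta", alpha = mean * nu, beta = (1 - mean) * nu)
  } else {
    list(dist = "normal", mean = mean, sd = se)
  }
}

# n draws for one parameter; degenerate se gives the base value exactly;
# normal draws truncated > 0 by redraw (hr/bsa/weight cannot be negative)
draw_param <- function(def, n) {
  if (def$se == 0) return(rep(def$base, n))
  mm <- moment_match(def$role, def$base, def$se)
  x <- switch(mm$dist,
    gamma  = stats::rgamma(n, shape = mm$shape, scale = mm$scale),
    beta   = stats::rbeta(n, mm$alpha, mm$beta),
    normal = stats::rnorm(n, mm$mean, mm$sd)
  )
  if (mm$dist == "normal") {
    bad <- which(x <= 0)
    guard <- 0L
    while (length(bad) > 0 && guard < 1000L) {
      x[bad] <- stats::rnorm(length(bad), mm$mean, mm$sd)
      bad <- which(x <= 0)
      guard <- guard + 1L
    }
    if (length(bad) > 0) x[bad] <- def$base
  }
  x
}

#' One-way (deterministic) sensitivity analysis
#'
#' Re-evaluates the model with each parameter set to its low and high
#' bound, all others at base, and reports the ICER at both bounds and
#' the span `|ICER_high - ICER_low|`, sorted descending by span — the
#' tornado-diagram table.  If the incremental effect changes sign (or
#' hits zero) across a parameter's bounds, the ICER is undefined at
#' that bound and the span is computed on incremental net monetary
#' benefit instead (flagged in the `metric` column).
#'
#' @param model Function `overrides -> ce_result`, where `overrides` is
#'   a named list of parameter values (see [make_model()]).
#' @param defs List of [param_def()]s.
#' @param wtp Threshold used for the NMB fallback.
#' @return Data frame of class `owsa_table`: `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `span`, `metric`; attribute
#'   `base_icer`.
#' @export
owsa <- function(model, defs, wtp) {
  stopifnot(length(defs) > 0)
  base <- model(list())
  rows <- lapply(defs, function(def) {
    ce_lo <- model(stats::setNames(list(def$low), def$name))
    ce_hi <- model(stats::setNames(list(def$high), def$name))
    icers <- c(ce_lo$icer_qaly, ce_hi$icer_qaly)
    de <- c(ce_lo$delta_qaly, ce_hi$delta_qaly)
    if (any(is.na(icers)) || any(de == 0) ||
        sign(de[1]) != sign(de[2]) || sign(de[1]) != sign(base$delta_qaly)) {
      span <- abs(incremental_nmb(ce_hi, wtp) - incremental_nmb(ce_lo, wtp))
      metric <- "nmb"
    } else {
      span <- abs(icers[2] - icers[1])
      metric <- "icer"
    }
    data.frame(parameter = def$name, low = def$low, high = def$high,
               icer_low = icers[1], icer_high = icers[2],
               span = span, metric = metric)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, class = c("owsa_table", "data.frame"),
            base_icer = base$icer_qaly, base_ce = base)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: every parameter is
#' drawn independently from its role-implied distribution
#' ([moment_match()]) in each iteration, the model is re-evaluated, and
#' per-draw costs, QALYs and increments are recorded.  Reproducible for
#' a given seed.
#'
#' @param model Function `overrides -> ce_result` (see [make_model()]).
#' @param defs List of [param_def()]s.
#' @param iterations Number of Monte Carlo draws (default 10000).
#' @param seed Integer RNG seed.
#' @return An object of class `psa_sample`: data frame with one row per
#'   draw — the parameter values, `cost_a`, `qaly_a`, `cost_b`,
#'   `qaly_b`, `delta_cost`, `delta_qaly` — plus attributes `defs` and
#'   `seed`.
#' @export
run_psa <- function(model, defs, iterations = 10000, seed = 1L) {
  stopifnot(length(defs) > 0, iterations >= 1)
  # validate all distributions before any draw
  for (def in defs) {
    if (def$se > 0) moment_match(def$role, def$base, def$se)
  }
  set.seed(seed)
  draws <- vapply(defs, draw_param, numeric(iterations), n = iterations)
  if (iterations == 1L) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- vapply(defs, `[[`, character(1), "name")
  res <- matrix(NA_real_, nrow = iterations, ncol = 6,
                dimnames = list(NULL, c("cost_a", "qaly_a", "cost_b",
                                        "qaly_b", "delta_cost",
                                        "delta_qaly")))
  for (i in seq_len(iterations)) {
    ce <- model(as.list(draws[i, ]))
    res[i, ] <- c(ce$arm_a$cost, ce$arm_a$qaly, ce$arm_b$cost,
                  ce$arm_b$qaly, ce$delta_cost, ce$delta_qaly)
  }
  out <- cbind(as.data.frame(draws), as.data.frame(res))
  structure(out, class = c("psa_sample", "data.frame"),
            defs = defs, seed = seed)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the fraction of PSA draws in
#' which the intervention has positive incremental net monetary
#' benefit.
#'
#' @param sample A [run_psa()] result (or any data frame with
#'   `delta_cost` and `delta_qaly` columns).
#' @param wtp_grid Non-empty vector of thresholds ($/QALY).
#' @return Data frame with `wtp` and `prob_cost_effective` in `[0, 1]`.
#' @export
ceac <- function(sample, wtp_grid) {
  if (length(wtp_grid) == 0L) stop("ceac: empty WTP grid", call. = FALSE)
  if (nrow(sample) == 0L) stop("ceac: empty sample", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * sample$delta_qaly - sample$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Write PSA scatter / CEAC to CSV
#'
#' @param sample A `psa_sample`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_scatter <- function(sample, path) {
  utils::write.csv(
    data.frame(delta_qaly = sample$delta_qaly,
               delta_cost = sample$delta_cost),
    path, row.names = FALSE)
  invisible(path)
}

#' @param curve A [ceac()] result.
#' @rdname write_psa_scatter
#' @export
write_ceac <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
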