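#' Parametric survival distribution specification
#'
#' Constructs the distribution object used throughout the package to
#' represent one fitted (or assumed) survival endpoint of one treatment
#' arm.  Four families are supported, in the parameterizations below
#' (time is in months everywhere at the interface):
#'
#' * `exponential`: rate \eqn{\lambda > 0}, \eqn{S(t) = e^{-\lambda t}}
#' * `weibull`: scale \eqn{\lambda > 0} and shape \eqn{\gamma > 0},
#'   \eqn{S(t) = e^{-\lambda t^{\gamma}}}.  Note this is the
#'   "health-economics" parameterization, not the one used by
#'   [stats::dweibull()]; the conversion is
#'   \eqn{\lambda = b^{-\gamma}} where `b` is R's `scale`.
#' * `loglogistic`: scale \eqn{\alpha > 0} and shape \eqn{\beta > 0},
#'   \eqn{S(t) = 1 / (1 + (t/\alpha)^{\beta})}; \eqn{\alpha} is the
#'   median survival time.
#' * `lognormal`: location \eqn{\mu} (any real) and spread
#'   \eqn{\sigma > 0} of log-time, as in [stats::plnorm()].
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`.
#' @param params Numeric vector of parameters in the order documented
#'   above.  Names are optional and ignored; length must match the
#'   family (1 for exponential, 2 otherwise).
#' @return An object of class `dist_spec`.
#' @examples
#' sp <- dist_spec("weibull", c(scale = 0.1, shape = 1.5))
#' survival_at(sp, c(0, 4, 12))
#' median_survival(sp)
#' @export
dist_spec <- function(family, params) {
  family <- match.arg(family, dist_families())
  params <- as.numeric(params)
  k <- if (family == "exponential") 1L else 2L
  if (length(params) != k) {
    stop(sprintf("family '%s' takes %d parameter(s), got %d",
                 family, k, length(params)), call. = FALSE)
  }
  names(params) <- switch(family,
    exponential = "rate",
    weibull     = c("scale", "shape"),
    loglogistic = c("scale", "shape"),
    lognormal   = c("meanlog", "sdlog")
  )
  positive <- if (family == "lognormal") 2L else seq_len(k)
  if (any(!is.finite(params)) || any(params[positive] <= 0)) {
    stop(sprintf("invalid parameters for family '%s': all constrained parameters must be finite and > 0",
                 family), call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "dist_spec")
}

#' Supported distribution families, in canonical order
#'
#' The fixed order is also the tie-break order used by
#' [select_distribution()].
#' @return Character vector of family names.
#' @export
dist_families <- function() {
  c("exponential", "weibull", "loglogistic", "lognormal")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s)  [time in %s]\n", x$family,
              paste(sprintf("%s=%.6g", names(x$params), x$params),
                    collapse = ", "),
              x$time_unit))
  invisible(x)
}

#' Survival function
#'
#' Evaluates \eqn{S(t)}, the probability of being event-free at time
#' `t`, for a parametric specification or a hazard-ratio-adjusted
#' curve ([hr_adjust()]).
#'
#' @param spec A `dist_spec` or `hr_spec` object.
#' @param t Time(s) in months, all `>= 0`.  Vectorized.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1` for every
#'   family and `S` is non-increasing in `t`.
#' @export
survival_at <- function(spec, t) {
  UseMethod("survival_at")
}

#' @export
survival_at.dist_spec <- function(spec, t) {
  if (any(t < 0)) stop("survival_at: t must be >= 0", call. = FALSE)
  p <- spec$params
  switch(spec$family,
    exponential = exp(-p[[1]] * t),
    weibull     = exp(-p[[1]] * t ^ p[[2]]),
    loglogistic = 1 / (1 + (t / p[[1]]) ^ p[[2]]),
    lognormal   = stats::plnorm(t, meanlog = p[[1]], sdlog = p[[2]],
                                lower.tail = FALSE)
  )
}

#' Log-density of the event-time distribution
#'
#' Used by the likelihood in [fit_mle()].  Vectorized over `t`; `t`
#' must be positive (event times).
#' @inheritParams survival_at
#' @return `log f(t)`.
#' @keywords internal
log_density <- function(spec, t) {
  p <- spec$params
  switch(spec$family,
    exponential = log(p[[1]]) - p[[1]] * t,
    weibull     = log(p[[1]]) + log(p[[2]]) + (p[[2]] - 1) * log(t) -
                  p[[1]] * t ^ p[[2]],
    loglogistic = {
      z <- (t / p[[1]]) ^ p[[2]]
      log(p[[2]]) - log(p[[1]]) + (p[[2]] - 1) * (log(t) - log(p[[1]])) -
        2 * log1p(z)
    },
    lognormal   = stats::dlnorm(t, meanlog = p[[1]], sdlog = p[[2]],
                                log = TRUE)
  )
}

#' Quantile of the survival function
#'
#' Returns the time `t` such that `S(t) = p` (the inverse survival
#' function), in closed form per family.  Used for median survival and
#' for inverse-transform simulation.
#'
#' @inheritParams survival_at
#' @param p Survival probabilities in `(0, 1)`.  Vectorized.
#' @return Times in months.
#' @export
survival_quantile <- function(spec, p) {
  UseMethod("survival_quantile")
}

#' @export
survival_quantile.dist_spec <- function(spec, p) {
  if (any(p <= 0 | p >= 1)) {
    stop("survival_quantile: p must be in (0, 1)", call. = FALSE)
  }
  par <- spec$params
  switch(spec$family,
    exponential = -log(p) / par[[1]],
    weibull     = (-log(p) / par[[1]]) ^ (1 / par[[2]]),
    loglogistic = par[[1]] * ((1 - p) / p) ^ (1 / par[[2]]),
    lognormal   = stats::qlnorm(p, meanlog = par[[1]], sdlog = par[[2]],
                                lower.tail = FALSE)
  )
}

#' @export
survival_quantile.hr_spec <- function(spec, p) {
  if (spec$mode != "proportional_hazards") {
    stop("survival_quantile is only defined for proportional_hazards adjustment",
         call. = FALSE)
  }
  survival_quantile(spec$base, p ^ (1 / spec$hr))
}

#' Median survival time
#'
#' The time at which `S(t) = 0.5`, in closed form: `log(2)/rate`
#' (exponential), `(log(2)/scale)^(1/shape)` (Weibull), `scale`
#' (log-logistic), `exp(meanlog)` (log-normal).
#'
#' @inheritParams survival_at
#' @return Median time in months.
#' @export
median_survival <- function(spec) {
  survival_quantile(spec, 0.5)
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of leaving the state during the cycle `[t, t + u)` given
#' occupancy at `t`: `1 - S(t + u) / S(t)`.  Independent of `t` for the
#' exponential family.
#'
#' @inheritParams survival_at
#' @param t Cycle start time in months (`>= 0`).
#' @param u Cycle length in months (`>= 0`).
#' @return Probability in `[0, 1]`.  If `S(t) = 0` the state mass is
#'   already absorbed; the function warns and returns 1.
#' @export
cycle_transition_prob <- function(spec, t, u) {
  if (any(t < 0) || any(u < 0)) {
    stop("cycle_transition_prob: t and u must be >= 0", call. = FALSE)
  }
  s0 <- survival_at(spec, t)
  s1 <- survival_at(spec, t + u)
  out <- ifelse(s0 == 0, 1, 1 - s1 / s0)
  if (any(s0 == 0)) {
    warning("cycle_transition_prob: S(t) = 0, state mass already absorbed; returning 1")
  }
  pmin(pmax(out, 0), 1)
}

#' Hazard-ratio adjustment of a survival probability
#'
#' Two readings of "applying a hazard ratio to a survival curve":
#'
#' * `proportional_hazards` (default, the standard transform):
#'   \eqn{S^{HR}}, always a valid survival probability.
#' * `rate_multiply`: the literal survival-scale product
#'   \eqn{HR \cdot S}, clamped to `[0, 1]`.  Not a valid survival
#'   transform when `hr * S > 1`; provided for replication of analyses
#'   that multiply published survival rates by a hazard ratio.
#'
#' @param s_ref Reference survival probabilities in `[0, 1]`.
#' @param hr Hazard ratio, `> 0`.
#' @param mode `"proportional_hazards"` or `"rate_multiply"`.
#' @return Adjusted probabilities in `[0, 1]`.
#' @export
hr_adjusted_survival <- function(s_ref, hr,
                                 mode = c("proportional_hazards",
                                          "rate_multiply")) {
  mode <- match.arg(mode)
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("hr_adjusted_survival: hr must be a single finite value > 0",
         call. = FALSE)
  }
  if (any(s_ref < 0 | s_ref > 1)) {
    stop("hr_adjusted_survival: s_ref must be in [0, 1]", call. = FALSE)
  }
  if (mode == "proportional_hazards") s_ref ^ hr
  else pmin(pmax(hr * s_ref, 0), 1)
}

#' Hazard-ratio-adjusted survival curve object
#'
#' Wraps a base curve so the adjusted curve can be used anywhere a
#' `dist_spec` is accepted (trace building, subgroup analysis).
#'
#' @param base A `dist_spec` (or `hr_spec`) for the reference arm.
#' @param hr Hazard ratio of the adjusted arm versus the reference.
#' @param mode See [hr_adjusted_survival()].
#' @return An object of class `hr_spec`.
#' @export
hr_adjust <- function(base, hr,
                      mode = c("proportional_hazards", "rate_multiply")) {
  mode <- match.arg(mode)
  if (!inherits(base, c("dist_spec", "hr_spec"))) {
    stop("hr_adjust: base must be a dist_spec or hr_spec", call. = FALSE)
  }
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("hr_adjust: hr must be a single finite value > 0", call. = FALSE)
  }
  structure(list(base = base, hr = hr, mode = mode), class = "hr_spec")
}

#' @export
survival_at.hr_spec <- function(spec, t) {
  hr_adjusted_survival(survival_at(spec$base, t), spec$hr, spec$mode)
}

#' @export
print.hr_spec <- function(x, ...) {
  cat(sprintf("<hr_spec> hr=%.4g (%s) applied to:\n  ", x$hr, x$mode))
  print(x$base)
  invisible(x)
}
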