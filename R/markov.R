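#' Cohort model settings
#'
#' Cycle length, horizon, discounting and half-cycle correction for the
#' three-state model.  The default cycle is 3 weeks (matching a
#' 21-day oncology administration schedule); times at the interface are
#' in months, discounting converts to years internally
#' (1 month = 1/12 year, 1 cycle = 21/365.25 years).
#'
#' @param cycle_length_days Cycle length in days (default 21).
#' @param horizon_years Maximum model horizon in years (default 20).
#'   The trace is additionally truncated once overall survival falls
#'   below `survival_floor` ("lifetime" horizon).
#' @param discount_rate_annual Annual discount rate applied to both
#'   costs and health outcomes (e.g. 0.03 US, 0.05 China).
#' @param half_cycle_correction Apply the trapezoid half-cycle
#'   correction (state occupancy averaged over adjacent cycle
#'   boundaries)?  Default `TRUE`.
#' @param survival_floor Overall-survival level below which the cohort
#'   is considered extinct (default 0.001).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_days = 21,
                           horizon_years = 20,
                           discount_rate_annual = 0.03,
                           half_cycle_correction = TRUE,
                           survival_floor = 0.001) {
  if (cycle_length_days <= 0) stop("cycle_length_days must be > 0", call. = FALSE)
  if (discount_rate_annual < 0 || discount_rate_annual >= 1) {
    stop("discount_rate_annual must be in [0, 1)", call. = FALSE)
  }
  if (horizon_years <= 0) stop("horizon_years must be > 0", call. = FALSE)
  structure(list(
    cycle_length_days = cycle_length_days,
    cycle_length_months = cycle_length_days * 12 / 365.25,
    cycle_length_years = cycle_length_days / 365.25,
    horizon_years = horizon_years,
    discount_rate_annual = discount_rate_annual,
    half_cycle_correction = isTRUE(half_cycle_correction),
    survival_floor = survival_floor
  ), class = "model_settings")
}

#' Discount factor
#'
#' Continuous-time compound discounting, `(1 + rate)^(-t)`.
#'
#' @param rate_annual Annual discount rate.
#' @param t_years Time in years (`>= 0`), vectorized.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(rate_annual, t_years) {
  if (any(t_years < 0)) stop("discount_factor: t must be >= 0", call. = FALSE)
  (1 + rate_annual) ^ (-t_years)
}

#' Build the partitioned-survival cohort trace
#'
#' State occupancies are read directly off the two survival curves at
#' each cycle boundary `t_k`:
#' progression-free `= S_pfs(t_k)`, dead `= 1 - S_os(t_k)`, and
#' progressed `= max(0, S_os(t_k) - S_pfs(t_k))`.  Where the fitted
#' curves cross (`S_pfs > S_os`) the progressed state is clamped to 0
#' and the progression-free state to `S_os`; the number of clamped
#' cycles is reported as the `clamped` attribute.
#'
#' @param pfs,os Progression-free and overall survival curves: a
#'   `dist_spec`, `hr_spec` or `survival_fit`.
#' @param settings A [model_settings()] object.
#' @param markov_mode Alternative per-cycle transition construction
#'   (occupancies propagated with [cycle_transition_prob()] instead of
#'   read off the curves); agrees with the default for non-crossing
#'   curves and exists for comparison.
#' @return An object of class `cohort_trace`: data frame with columns
#'   `cycle`, `time_months`, `pfs`, `pd`, `dead` (one row per cycle
#'   boundary), with attributes `settings` and `clamped`.
#' @export
build_trace <- function(pfs, os, settings, markov_mode = FALSE) {
  stopifnot(inherits(settings, "model_settings"))
  pfs <- as_curve(pfs); os <- as_curve(os)
  u <- settings$cycle_length_months
  k_max <- floor(settings$horizon_years * 12 / u + 1e-9)
  if (k_max < 1L) {
    stop("build_trace: horizon shorter than one cycle", call. = FALSE)
  }
  t_k <- (0:k_max) * u
  s_os <- survival_at(os, t_k)
  s_pfs <- survival_at(pfs, t_k)

  # lifetime horizon: stop once the cohort is effectively extinct
  extinct <- which(s_os < settings$survival_floor)
  if (length(extinct) > 0 && extinct[1] < length(t_k)) {
    keep <- seq_len(extinct[1])
    t_k <- t_k[keep]; s_os <- s_os[keep]; s_pfs <- s_pfs[keep]
  }

  if (markov_mode) {
    n <- length(t_k)
    pfs_m <- numeric(n); pd_m <- numeric(n); dead_m <- numeric(n)
    pfs_m[1] <- 1
    for (k in seq_len(n - 1)) {
      t0 <- t_k[k]
      p_prog <- cycle_transition_prob(pfs, t0, u)
      p_die <- cycle_transition_prob(os, t0, u)
      pfs_m[k + 1] <- pfs_m[k] * (1 - p_prog)
      dead_m[k + 1] <- dead_m[k] + (pfs_m[k] + pd_m[k]) * p_die
      pd_m[k + 1] <- max(0, 1 - pfs_m[k + 1] - dead_m[k + 1])
    }
    trace <- data.frame(cycle = seq_along(t_k) - 1L, time_months = t_k,
                        pfs = pfs_m, pd = pd_m, dead = dead_m)
    clamped <- 0L
  } else {
    clamped <- sum(s_pfs > s_os + 1e-12)
    pfs_occ <- pmin(s_pfs, s_os)
    pd_occ <- pmax(0, s_os - s_pfs)
    trace <- data.frame(cycle = seq_along(t_k) - 1L, time_months = t_k,
                        pfs = pfs_occ, pd = pd_occ, dead = 1 - s_os)
  }
  structure(trace,
            class = c("cohort_trace", "data.frame"),
            settings = settings, clamped = clamped)
}

# accept dist_spec, hr_spec or survival_fit anywhere a curve is needed
as_curve <- function(x) {
  if (inherits(x, "survival_fit")) return(x$spec)
  if (inherits(x, c("dist_spec", "hr_spec"))) return(x)
  stop("expected a dist_spec, hr_spec or survival_fit", call. = FALSE)
}

#' Accrue discounted, half-cycle-corrected totals over a trace
#'
#' Sums per-cycle values weighted by state occupancy and discounting:
#' \deqn{\sum_k df(t_k + u/2) \left[v^{pfs}_k \bar m^{pfs}_k +
#'       v^{pd}_k \bar m^{pd}_k\right] + \mbox{one-offs}}
#' where \eqn{\bar m_k} is the mean of the occupancies at the two
#' boundaries of cycle `k` (half-cycle correction on) or the occupancy
#' at the cycle start (off), and `df` is evaluated mid-cycle (cycle
#' start when correction is off).  Values are *per cycle in the state*
#' (for time-denominated quantities such as life-years, fold the cycle
#' length into the stream — see [life_years()]).
#'
#' One-off values: `death_one_off` attaches to each cycle's death
#' increment (discounted like the cycle); `entry_one_off` is added
#' undiscounted at model entry.
#'
#' @param trace A [build_trace()] result.
#' @param values List with `pfs` and `pd`: scalars or vectors of
#'   per-cycle values (length = number of cycles), and optional
#'   scalars `death_one_off` and `entry_one_off`.
#' @param settings A [model_settings()]; defaults to the trace's own.
#' @return Discounted total (scalar).
#' @export
accrue <- function(trace, values, settings = attr(trace, "settings")) {
  stopifnot(inherits(trace, "cohort_trace"))
  n_cycles <- nrow(trace) - 1L
  if (n_cycles < 1L) return(0)
  get_stream <- function(v) {
    if (is.null(v)) return(rep(0, n_cycles))
    if (length(v) == 1L) return(rep(v, n_cycles))
    if (length(v) < n_cycles) {
      stop(sprintf("accrue: value stream of length %d shorter than the %d model cycles",
                   length(v), n_cycles), call. = FALSE)
    }
    v[seq_len(n_cycles)]
  }
  v_pfs <- get_stream(values$pfs)
  v_pd <- get_stream(values$pd)
  u_years <- settings$cycle_length_years
  k <- seq_len(n_cycles)
  if (settings$half_cycle_correction) {
    m_pfs <- (trace$pfs[k] + trace$pfs[k + 1]) / 2
    m_pd <- (trace$pd[k] + trace$pd[k + 1]) / 2
    t_disc <- (trace$time_months[k] / 12) + u_years / 2
  } else {
    m_pfs <- trace$pfs[k]
    m_pd <- trace$pd[k]
    t_disc <- trace$time_months[k] / 12
  }
  df <- discount_factor(settings$discount_rate_annual, t_disc)
  total <- sum(df * (v_pfs * m_pfs + v_pd * m_pd))
  death_inc <- trace$dead[k + 1] - trace$dead[k]
  if (!is.null(values$death_one_off) && values$death_one_off != 0) {
    total <- total + values$death_one_off * sum(df * death_inc)
  }
  if (!is.null(values$entry_one_off)) {
    total <- total + values$entry_one_off
  }
  total
}

#' Discounted life-years of a trace
#'
#' [accrue()] with a value of one cycle length (in years) per cycle
#' alive in either state.
#'
#' @inheritParams accrue
#' @return Discounted life-years.
#' @export
life_years <- function(trace, settings = attr(trace, "settings")) {
  u <- settings$cycle_length_years
  accrue(trace, list(pfs = u, pd = u), settings)
}

#' Discounted quality-adjusted life-years of a trace
#'
#' Life-years weighted by state utilities, minus a one-off
#' quality-of-life decrement for adverse events (applied undiscounted
#' at model entry).
#'
#' @inheritParams accrue
#' @param utilities List with `pfs` and `pd` state utilities (scalars
#'   or per-cycle vectors).  Values outside `[0, 1]` trigger a warning
#'   (disutilities can legitimately push an effective utility below a
#'   state utility) but are used as given.
#' @param ae_decrement One-off QALY decrement (expected adverse-event
#'   disutility x duration), default 0.
#' @return Discounted QALYs.
#' @export
qalys <- function(trace, utilities, ae_decrement = 0,
                  settings = attr(trace, "settings")) {
  uv <- c(utilities$pfs, utilities$pd)
  if (any(uv < 0 | uv > 1)) {
    warning("qalys: utility outside [0, 1]")
  }
  u <- settings$cycle_length_years
  accrue(trace,
         list(pfs = u * utilities$pfs, pd = u * utilities$pd,
              entry_one_off = -ae_decrement),
         settings)
}

#' Export a cohort trace as CSV
#'
#' Writes cycle index, cycle start time (months and years), state
#' occupancies and the per-cycle discounted life-year increment.
#'
#' @param trace A [build_trace()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  settings <- attr(trace, "settings")
  df <- as.data.frame(trace)
  df$time_years <- df$time_months / 12
  n <- nrow(df)
  inc <- numeric(n)
  if (n > 1) {
    k <- seq_len(n - 1)
    alive <- ((df$pfs[k] + df$pd[k]) + (df$pfs[k + 1] + df$pd[k + 1])) / 2
    inc[k] <- discount_factor(settings$discount_rate_annual,
                              df$time_years[k] + settings$cycle_length_years / 2) *
      settings$cycle_length_years * alive
  }
  df$discounted_ly_increment <- inc
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
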