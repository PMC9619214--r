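#' Digitized Kaplan-Meier curve
#'
#' Container for a published KM curve read off a figure: the curve
#' coordinates plus the numbers-at-risk table printed under it.
#'
#' @param points Data frame with columns `time` (months) and `surv`
#'   (survival probability), sorted by time, starting at `(0, 1)`.
#' @param risk_table Data frame with columns `time` (months) and
#'   `n_risk` (patients at risk), sorted by time, starting at time 0.
#' @param validate Check invariants (monotonicity, ranges).
#' @return An object of class `digitized_km`.
#' @export
digitized_km <- function(points, risk_table, validate = TRUE) {
  points <- as.data.frame(points)[, c("time", "surv")]
  risk_table <- as.data.frame(risk_table)[, c("time", "n_risk")]
  if (validate) {
    if (nrow(points) < 1L || points$time[1] != 0 || points$surv[1] != 1) {
      stop("digitized_km: points must start at (time = 0, surv = 1)",
           call. = FALSE)
    }
    if (is.unsorted(points$time)) {
      stop("digitized_km: point times must be sorted ascending", call. = FALSE)
    }
    if (any(points$surv < 0 | points$surv > 1)) {
      stop("digitized_km: survival probabilities must be in [0, 1]",
           call. = FALSE)
    }
    if (any(diff(points$surv) > 1e-12)) {
      stop("digitized_km: survival increases between points", call. = FALSE)
    }
    if (nrow(risk_table) < 1L || is.unsorted(risk_table$time)) {
      stop("digitized_km: risk-table times must be sorted ascending",
           call. = FALSE)
    }
    if (any(diff(risk_table$n_risk) > 0)) {
      stop("digitized_km: numbers at risk must be non-increasing",
           call. = FALSE)
    }
    if (any(risk_table$n_risk < 0)) {
      stop("digitized_km: numbers at risk must be >= 0", call. = FALSE)
    }
  }
  structure(list(points = points, risk_table = risk_table),
            class = "digitized_km")
}

#' @export
print.digitized_km <- function(x, ...) {
  cat(sprintf("<digitized_km> %d curve points over [0, %.3g] months, %d risk-table entries (n0 = %d)\n",
              nrow(x$points), max(x$points$time), nrow(x$risk_table),
              x$risk_table$n_risk[1]))
  invisible(x)
}

#' Step-function evaluation of a KM curve
#'
#' Right-continuous step interpolation: the value at `t` is the
#' survival recorded at the last curve point at or before `t`.
#'
#' @param km A `digitized_km` object.
#' @param t Times in months.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$points$time)
  ifelse(idx == 0, 1, km$points$surv[pmax(idx, 1L)])
}

#' Reconstruct interval event/censoring counts from a digitized curve
#'
#' Rebuilds, for each numbers-at-risk interval, how many events and how
#' many censorings must have occurred, in the spirit of the published
#' algorithms for recovering patient-level data from KM figures:
#'
#' * events at each digitized drop are `n_at_risk * (1 - S_i/S_{i-1})`,
#'   with the at-risk count reduced by preceding events within the
#'   interval (within-interval censoring is treated as occurring
#'   uniformly and does not enter the event equation);
#' * the censored count is the residual
#'   `n_start - n_end - events`, so the risk table is conserved
#'   exactly;
#' * fractional events are rounded to integers by largest-remainder
#'   allocation within the interval, preserving the interval total;
#' * after the last risk-table entry, drops are still converted to
#'   events but censoring is assumed administrative, i.e. placed only
#'   at the final follow-up time.
#'
#' @param km A [digitized_km()] object with at least 2 risk-table rows.
#' @return An object of class `interval_counts`: a list with
#'   `intervals` (data frame: `start`, `end`, `n_start`, `d`, `c`,
#'   `tail`), `drops` (per-interval data frames of drop `time` and
#'   integer `events`), `n0` and `final_time`.
#' @export
reconstruct_interval_counts <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  rt <- km$risk_table
  if (nrow(rt) < 2L) {
    stop("reconstruct_interval_counts: need at least 2 risk-table entries",
         call. = FALSE)
  }
  pts <- km$points
  final_time <- max(pts$time, rt$time)
  n0 <- rt$n_risk[1]

  # interval boundaries: risk-table times, plus a tail interval from the
  # last risk entry to the end of follow-up
  starts <- rt$time
  ends <- c(rt$time[-1], final_time)
  n_starts <- rt$n_risk
  n_ends <- c(rt$n_risk[-1], NA_real_)  # tail end count is free
  is_tail <- c(rep(FALSE, nrow(rt) - 1L), TRUE)

  intervals <- list()
  drops <- list()
  for (j in seq_along(starts)) {
    t0 <- starts[j]; t1 <- ends[j]
    # drop points: digitized points in (t0, t1] where survival decreases
    cand <- which(pts$time > t0 & pts$time <= t1)
    s_prev <- km_survival_at(km, t0)
    n_cur <- n_starts[j]
    d_real <- numeric(0); d_times <- numeric(0)
    for (i in cand) {
      s_i <- pts$surv[i]
      if (s_i < s_prev - 1e-12) {
        di <- if (s_prev > 0) n_cur * (1 - s_i / s_prev) else 0
        d_real <- c(d_real, di)
        d_times <- c(d_times, pts$time[i])
        n_cur <- n_cur - di
      }
      s_prev <- s_i
    }
    d_total_real <- sum(d_real)

    if (is_tail[j]) {
      d <- min(round(d_total_real), n_starts[j])
      cens <- 0L  # administrative censoring handled at final time
    } else {
      removed <- n_starts[j] - n_ends[j]
      c_real <- removed - d_total_real
      if (c_real < -1) {
        stop(sprintf("reconstruct_interval_counts: risk table inconsistent with curve in interval [%g, %g]: implied censored count %.2f < 0",
                     t0, t1, c_real), call. = FALSE)
      }
      d <- max(0L, min(round(d_total_real), removed))
      cens <- removed - d
    }
    d_int <- largest_remainder_round(d_real, d)
    intervals[[j]] <- data.frame(start = t0, end = t1,
                                 n_start = n_starts[j], d = d, c = cens,
                                 tail = is_tail[j])
    drops[[j]] <- data.frame(time = d_times, events = d_int)
  }
  intervals <- do.call(rbind, intervals)
  structure(list(intervals = intervals, drops = drops,
                 n0 = n0, final_time = final_time),
            class = "interval_counts")
}

# allocate integer total among fractional shares, largest remainder,
# earlier entries win ties
largest_remainder_round <- function(shares, total) {
  if (length(shares) == 0L) return(integer(0))
  if (total <= 0 || sum(shares) <= 0) return(integer(length(shares)))
  scaled <- shares * total / sum(shares)
  base <- floor(scaled)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(scaled - base, -seq_along(shares), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf("<interval_counts> n0 = %d, %d intervals, %d events, %d censored (+%d administrative at %.3g months)\n",
              x$n0, nrow(x$intervals), sum(x$intervals$d),
              sum(x$intervals$c),
              x$n0 - sum(x$intervals$d) - sum(x$intervals$c),
              x$final_time))
  invisible(x)
}

#' Expand interval counts to pseudo individual patient data
#'
#' Events are placed at the digitized drop times; censored records are
#' spread deterministically at equal spacing over their interval (a
#' count of `c` censorings over `[a, b)` is placed at
#' `a + k (b - a) / (c + 1)`, `k = 1..c`).  Patients still at risk
#' after the last interval are censored administratively at the final
#' follow-up time, so the record count equals the initial number at
#' risk.
#'
#' @param counts An [reconstruct_interval_counts()] result.
#' @return Data frame with columns `time` (months) and `event`
#'   (1 = event, 0 = censored), `nrow == n0`.
#' @export
expand_to_ipd <- function(counts) {
  stopifnot(inherits(counts, "interval_counts"))
  times <- numeric(0); events <- integer(0)
  for (j in seq_len(nrow(counts$intervals))) {
    iv <- counts$intervals[j, ]
    dr <- counts$drops[[j]]
    if (nrow(dr) > 0 && sum(dr$events) > 0) {
      times <- c(times, rep(dr$time, dr$events))
      events <- c(events, rep(1L, sum(dr$events)))
    }
    if (iv$c > 0) {
      ct <- iv$start + seq_len(iv$c) * (iv$end - iv$start) / (iv$c + 1)
      times <- c(times, ct)
      events <- c(events, rep(0L, iv$c))
    }
  }
  n_remaining <- counts$n0 - length(times)
  if (n_remaining < 0) {
    stop("expand_to_ipd: counts exceed initial n at risk", call. = FALSE)
  }
  if (n_remaining > 0) {
    times <- c(times, rep(counts$final_time, n_remaining))
    events <- c(events, rep(0L, n_remaining))
  }
  ord <- order(times, -events)
  data.frame(time = times[ord], event = events[ord])
}

#' Product-limit (Kaplan-Meier) estimator
#'
#' Plain product-limit estimate from individual patient data; used for
#' round-trip validation of the reconstruction and by the synthetic
#' digitizer.  Ties at a time point are handled with the standard
#' convention that events precede censorings.
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @return A [digitized_km()] whose `points` are `(0, 1)` followed by
#'   the distinct event times with their survival estimates, and whose
#'   `risk_table` holds the at-risk counts just before each of those
#'   times.
#' @export
km_from_ipd <- function(ipd) {
  ipd <- validate_ipd_km(ipd)
  n0 <- nrow(ipd)
  ev_times <- sort(unique(ipd$time[ipd$event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(ipd$time >= t), numeric(1))
  d <- vapply(ev_times, function(t) sum(ipd$time == t & ipd$event == 1),
              numeric(1))
  s <- cumprod(1 - d / n_risk)
  digitized_km(
    points = data.frame(time = c(0, ev_times), surv = c(1, s)),
    risk_table = data.frame(time = c(0, ev_times), n_risk = c(n0, n_risk)),
    validate = FALSE
  )
}

validate_ipd_km <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd))) {
    stop("ipd must be a data frame with columns 'time' and 'event'",
         call. = FALSE)
  }
  if (nrow(ipd) == 0L) stop("ipd is empty", call. = FALSE)
  ipd
}

#' Read / write digitized KM curves as CSV
#'
#' The curve and the risk table are stored in two CSV files:
#' `points_path` with columns `time_months`, `survival` and
#' `risk_path` with columns `time_months`, `n_at_risk`.
#'
#' @param km A `digitized_km` object.
#' @param points_path,risk_path CSV file paths.
#' @return `read_digitized_km` returns a `digitized_km`;
#'   `write_digitized_km` returns the paths invisibly.
#' @export
write_digitized_km <- function(km, points_path, risk_path) {
  stopifnot(inherits(km, "digitized_km"))
  utils::write.csv(
    data.frame(time_months = km$points$time, survival = km$points$surv),
    points_path, row.names = FALSE)
  utils::write.csv(
    data.frame(time_months = km$risk_table$time,
               n_at_risk = km$risk_table$n_risk),
    risk_path, row.names = FALSE)
  invisible(c(points_path, risk_path))
}

#' @rdname write_digitized_km
#' @export
read_digitized_km <- function(points_path, risk_path) {
  pts <- utils::read.csv(points_path)
  rt <- utils::read.csv(risk_path)
  need <- function(df, cols, path) {
    if (!all(cols %in% names(df))) {
      stop(sprintf("%s: expected columns %s", path,
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
  }
  need(pts, c("time_months", "survival"), points_path)
  need(rt, c("time_months", "n_at_risk"), risk_path)
  digitized_km(points = data.frame(time = pts$time_months,
                                   surv = pts$survival),
               risk_table = data.frame(time = rt$time_months,
                                       n_risk = rt$n_at_risk))
}
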