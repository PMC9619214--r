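#' Simulate one trial arm endpoint
#'
#' Draws event times from a parametric truth by inverse-transform
#' sampling, applies administrative censoring at a fixed follow-up
#' cutoff plus independent exponential random censoring, and returns
#' patient-level records.
#'
#' @param n Number of patients.
#' @param truth A [dist_spec()] for the true event-time distribution
#'   (months).
#' @param admin_cutoff Administrative censoring time in months
#'   (`Inf` = none).
#' @param censor_rate Rate (per month) of the exponential random
#'   censoring process (0 = none).
#' @param seed Optional integer seed (set for reproducibility).
#' @return Data frame with `time` (months) and `event` (1/0).
#' @export
simulate_arm <- function(n, truth, admin_cutoff = Inf, censor_rate = 0,
                         seed = NULL) {
  stopifnot(inherits(truth, "dist_spec"), n >= 1, admin_cutoff > 0,
            censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  event_time <- survival_quantile(truth, stats::runif(n))
  censor_time <- if (censor_rate > 0) {
    pmin(admin_cutoff, stats::rexp(n, censor_rate))
  } else {
    rep(admin_cutoff, n)
  }
  data.frame(time = pmin(event_time, censor_time),
             event = as.integer(event_time <= censor_time))
}

#' Synthetic digitization of a KM curve
#'
#' Emulates reading a published figure: computes the product-limit
#' estimate of the patient-level data, samples it at a fixed time grid,
#' rounds the survival values to a plot-reading precision, and tabulates
#' the exact numbers at risk at the risk-table grid times.
#'
#' @param ipd Patient-level data (`time`, `event`).
#' @param time_grid Digitization times in months (0 is prepended if
#'   absent).
#' @param risk_grid Numbers-at-risk table times (0 is prepended if
#'   absent).
#' @param round_digits Decimal places survival is rounded to
#'   (default 3, mimicking plot-reading precision); `NULL` disables
#'   rounding.
#' @return A [digitized_km()].
#' @export
digitize <- function(ipd, time_grid, risk_grid, round_digits = 3) {
  km <- km_from_ipd(ipd)
  time_grid <- sort(unique(c(0, time_grid)))
  risk_grid <- sort(unique(c(0, risk_grid)))
  if (max(time_grid) > max(ipd$time) + 1e-9) {
    stop("digitize: time grid extends beyond follow-up", call. = FALSE)
  }
  s <- km_survival_at(km, time_grid)
  if (!is.null(round_digits)) s <- round(s, round_digits)
  n_risk <- vapply(risk_grid, function(t) sum(ipd$time >= t - 1e-12),
                   numeric(1))
  digitized_km(points = data.frame(time = time_grid, surv = s),
               risk_table = data.frame(time = risk_grid, n_risk = n_risk))
}

# ---------------------------------------------------------------------------
# Fixture study: a two-arm EGFR-mutant NSCLC trial shaped like the one the
# package is designed around.  Survival truths are anchored to the published
# medians (PFS 10.1 vs 4.4 months; OS 26.8 vs 22.5 months; CNS PFS 8.5 vs
# 4.2 months); every economic input is a synthetic stand-in.

fixture_truths <- function(population) {
  itt <- list(
    intervention = list(
      pfs = dist_spec("loglogistic", c(10.1, 1.8)),
      os = dist_spec("loglogistic", c(26.8, 2.2))
    ),
    comparator = list(
      pfs = dist_spec("weibull", c(log(2) / 4.4^1.3, 1.3)),
      os = dist_spec("weibull", c(log(2) / 22.5^1.4, 1.4))
    )
  )
  if (population == "ITT") return(itt)
  list(
    intervention = list(
      pfs = dist_spec("loglogistic", c(8.5, 1.8)),
      os = NULL  # derived from comparator OS via the OS hazard ratio
    ),
    comparator = list(
      pfs = dist_spec("weibull", c(log(2) / 4.2^1.3, 1.3)),
      os = itt$comparator$os  # assumed equal to the full-population curve
    )
  )
}

fixture_sim_design <- function(population) {
  list(
    n = if (population == "ITT") c(intervention = 279, comparator = 140)
        else c(intervention = 93, comparator = 51),
    # digitization grid fine enough to capture individual KM steps (as a
    # careful read of a published figure does); risk tables at the calendar
    # times printed under such figures
    pfs = list(cutoff = 27, censor_rate = 0.01,
               time_grid = seq(0.25, 27, by = 0.25),
               risk_grid = seq(0, 27, by = 3)),
    os = list(cutoff = 45, censor_rate = 0.005,
              time_grid = seq(0.5, 45, by = 0.5),
              risk_grid = seq(0, 45, by = 6)),
    # fixed per-endpoint seed offsets; the comparator OS offset is shared
    # between populations so the CNS bundle reuses the identical curve
    seed_offsets = c(int_pfs = if (population == "ITT") 1L else 5L,
                     int_os = 2L,
                     comp_pfs = if (population == "ITT") 3L else 6L,
                     comp_os = 4L)
  )
}

fixture_economics <- function(locale) {
  # synthetic stand-in unit costs and utilities (only the drug prices,
  # anthropometrics, discount rates and WTP thresholds are published values)
  if (locale == "US") {
    list(
      bsa = 1.79, weight = 70,
      prices = list(osimertinib = 6.62, pemetrexed = 0.60,
                    cisplatin = 0.02),
      costs = list(egfr_testing = 300, followup_per_cycle = 350,
                   bsc_per_cycle = 1200, end_of_life = 11000,
                   radiotherapy = 9000, infusion_per_admin = 140),
      discount_rate_annual = 0.03,
      wtp = 150000, wtp_list = c(100000, 150000),
      utilities = list(pfs = 0.81, pd = 0.67),
      # stand-in 95% CIs for the utility estimates (sensitivity ranges)
      utility_ci = list(pfs = c(0.76, 0.86), pd = c(0.61, 0.73)),
      subsequent = c(intervention = 3000, comparator = 5000),
      ae = data.frame(
        name = c("neutropenia", "anaemia", "thrombocytopenia",
                 "diarrhoea", "rash"),
        inc_intervention = c(0.02, 0.01, 0.01, 0.01, 0.01),
        inc_comparator = c(0.11, 0.12, 0.07, 0.01, 0.005),
        cost = c(4000, 2500, 3000, 1500, 800),
        disutility = c(0.20, 0.12, 0.11, 0.10, 0.04),
        duration_years = c(0.08, 0.10, 0.06, 0.03, 0.05)
      )
    )
  } else {
    list(
      bsa = 1.72, weight = 65,
      prices = list(osimertinib = 0.36, pemetrexed = 0.08,
                    cisplatin = 0.004),
      costs = list(egfr_testing = 150, followup_per_cycle = 80,
                   bsc_per_cycle = 300, end_of_life = 1800,
                   radiotherapy = 1500, infusion_per_admin = 25),
      discount_rate_annual = 0.05,
      wtp = 37489, wtp_list = c(19003, 37489, 85176),
      utilities = list(pfs = 0.78, pd = 0.64),
      utility_ci = list(pfs = c(0.73, 0.83), pd = c(0.58, 0.70)),
      subsequent = c(intervention = 350, comparator = 400),
      ae = data.frame(
        name = c("neutropenia", "anaemia", "thrombocytopenia",
                 "diarrhoea", "rash"),
        inc_intervention = c(0.02, 0.01, 0.01, 0.01, 0.01),
        inc_comparator = c(0.11, 0.12, 0.07, 0.01, 0.005),
        cost = c(500, 400, 450, 200, 100),
        disutility = c(0.20, 0.12, 0.11, 0.10, 0.04),
        duration_years = c(0.08, 0.10, 0.06, 0.03, 0.05)
      )
    )
  }
}

#' Generate a complete synthetic study bundle
#'
#' Builds everything one end-to-end analysis needs, without any
#' external data: simulated patient-level data for both arms and
#' endpoints (true medians anchored to the published trial medians),
#' digitized KM curves and risk tables written as CSV, and a full run
#' configuration (regimens with the published doses, the published
#' drug prices, anthropometrics, discount rates and WTP thresholds per
#' locale; all other unit costs, utilities and adverse-event inputs
#' are synthetic stand-ins, flagged as such in the config).
#'
#' In the CNS-metastases population the comparator overall-survival
#' curve is the identical object generated for the full (ITT)
#' population — the published analysis assumes the comparator OS is
#' unchanged in that subgroup — and the intervention OS is declared in
#' the config as a hazard-ratio adjustment (HR 1.19) of the comparator
#' curve rather than a digitized curve of its own.
#'
#' @param locale `"US"` or `"China"`.
#' @param population `"ITT"` or `"CNS"`.
#' @param seed Integer seed; the bundle is bit-identical for a given
#'   `(locale, population, seed)`.
#' @param dir Directory for the CSV/YAML files (created if needed;
#'   default a fresh temporary directory).
#' @return List of class `fixture_study`: `config` (run configuration,
#'   see [load_config()]), `config_path`, `km` (the `digitized_km`
#'   objects), `ipd` (the simulated truth records), `truth` (the true
#'   `dist_spec`s) and `dir`.
#' @export
make_fixture_study <- function(locale = c("US", "China"),
                               population = c("ITT", "CNS"),
                               seed = 1L, dir = NULL) {
  locale <- match.arg(locale)
  population <- match.arg(population)
  if (is.null(dir)) dir <- tempfile("fixture_study_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  truths <- fixture_truths(population)
  design <- fixture_sim_design(population)
  # comparator arm size for the shared (ITT) comparator OS curve
  n_comp_os <- fixture_sim_design("ITT")$n[["comparator"]]
  econ <- fixture_economics(locale)
  off <- design$seed_offsets

  sim_one <- function(truth, endpoint, n, offset) {
    d <- design[[endpoint]]
    ipd <- simulate_arm(n, truth, d$cutoff, d$censor_rate,
                        seed = seed * 1000L + offset)
    fu <- max(ipd$time)  # grids cannot extend beyond observed follow-up
    km <- digitize(ipd, d$time_grid[d$time_grid <= fu],
                   d$risk_grid[d$risk_grid <= fu])
    list(ipd = ipd, km = km)
  }

  sims <- list(
    intervention = list(
      pfs = sim_one(truths$intervention$pfs, "pfs",
                    design$n[["intervention"]], off[["int_pfs"]]),
      os = if (!is.null(truths$intervention$os)) {
        sim_one(truths$intervention$os, "os",
                design$n[["intervention"]], off[["int_os"]])
      }
    ),
    comparator = list(
      pfs = sim_one(truths$comparator$pfs, "pfs",
                    design$n[["comparator"]], off[["comp_pfs"]]),
      os = sim_one(truths$comparator$os, "os", n_comp_os,
                   off[["comp_os"]])
    )
  )

  # write curves and assemble the config's curve declarations
  curve_cfg <- list()
  km_out <- list(intervention = list(), comparator = list())
  ipd_out <- list(intervention = list(), comparator = list())
  for (arm in names(sims)) {
    for (ep in names(sims[[arm]])) {
      s <- sims[[arm]][[ep]]
      if (is.null(s)) next
      stem <- file.path(dir, paste0(tolower(population), "_", arm, "_", ep))
      write_digitized_km(s$km, paste0(stem, "_points.csv"),
                         paste0(stem, "_risk.csv"))
      utils::write.csv(s$ipd, paste0(stem, "_ipd_truth.csv"),
                       row.names = FALSE)
      curve_cfg[[arm]][[ep]] <- list(points_csv = paste0(stem, "_points.csv"),
                                     risk_csv = paste0(stem, "_risk.csv"))
      km_out[[arm]][[ep]] <- s$km
      ipd_out[[arm]][[ep]] <- s$ipd
    }
  }
  if (population == "CNS") {
    curve_cfg$intervention$os <- list(hr_of_comparator_os = 1.19)
  }

  config <- list(
    label = sprintf("synthetic fixture study (%s, %s); all costs, utilities and AE inputs are synthetic stand-ins",
                    locale, population),
    locale = locale,
    population = population,
    settings = list(cycle_length_days = 21, horizon_years = 20,
                    discount_rate_annual = econ$discount_rate_annual,
                    half_cycle_correction = TRUE),
    wtp = econ$wtp,
    wtp_list = econ$wtp_list,
    hr_mode = "proportional_hazards",
    selection_criterion = "aic",
    economics = list(bsa = econ$bsa, weight = econ$weight,
                     prices = econ$prices, costs = econ$costs),
    utilities = econ$utilities,
    arms = list(
      intervention = list(
        name = "osimertinib",
        regimen = list(
          list(drug = "osimertinib", dose = 80, dose_rule = "per_mg",
               schedule = "per_day", max_cycles = "until_progression",
               iv = FALSE)
        ),
        discontinuation = 0.07,
        subsequent_fraction = 0.53,
        subsequent_cost_per_cycle = unname(econ$subsequent["intervention"]),
        curves = curve_cfg$intervention
      ),
      comparator = list(
        name = "platinum-pemetrexed",
        regimen = list(
          list(drug = "cisplatin", dose = 75, dose_rule = "per_m2",
               schedule = "per_cycle", max_cycles = 4, iv = TRUE),
          list(drug = "pemetrexed", dose = 500, dose_rule = "per_m2",
               schedule = "per_cycle", max_cycles = "until_progression",
               iv = TRUE)
        ),
        discontinuation = 0.10,
        subsequent_fraction = 0.81,
        subsequent_cost_per_cycle = unname(econ$subsequent["comparator"]),
        curves = curve_cfg$comparator
      )
    ),
    adverse_events = econ$ae,
    psa = list(iterations = 2000, seed = seed),
    # sensitivity ranges: 95% CIs where the inputs carry them (utilities;
    # the subgroup OS hazard ratio), +/-25% defaults everywhere else
    parameter_ranges = c(
      list(
        utility_pfs = list(low = econ$utility_ci$pfs[1],
                           high = econ$utility_ci$pfs[2]),
        utility_pd = list(low = econ$utility_ci$pd[1],
                          high = econ$utility_ci$pd[2])
      ),
      if (population == "CNS") {
        list(hr_os = list(low = 0.79, high = 1.83))
      }
    ),
    subgroup = if (population == "CNS") {
      list(hr_pfs = 0.32, hr_os = 1.19)
    }
  )
  config <- config[!vapply(config, is.null, logical(1))]

  config_path <- file.path(dir, "config.yaml")
  cfg_yaml <- config
  cfg_yaml$adverse_events <- lapply(seq_len(nrow(econ$ae)), function(i) {
    as.list(econ$ae[i, ])
  })
  yaml::write_yaml(cfg_yaml, config_path)

  structure(list(config = config, config_path = config_path,
                 km = km_out, ipd = ipd_out, truth = truths,
                 locale = locale, population = population,
                 seed = seed, dir = dir),
            class = "fixture_study")
}

#' @export
print.fixture_study <- function(x, ...) {
  cat(sprintf("<fixture_study> %s / %s (seed %d) in %s\n",
              x$locale, x$population, x$seed, x$dir))
  invisible(x)
}
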