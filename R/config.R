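#' Load and validate a run configuration
#'
#' Reads a YAML run configuration describing one two-arm
#' cost-effectiveness comparison: locale economics, model settings,
#' arm regimens and survival-curve sources, adverse events, utilities
#' and PSA settings.  See the configuration written by
#' [make_fixture_study()] for a complete example of the schema.
#'
#' Validation is strict: unknown top-level keys are rejected, and all
#' validation errors are collected and reported together, each naming
#' the offending key.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("load_config: file not found: %s", path), call. = FALSE)
  }
  config <- yaml::read_yaml(path)
  # resolve curve CSV paths relative to the config file
  base_dir <- dirname(normalizePath(path))
  for (arm in names(config$arms)) {
    for (ep in names(config$arms[[arm]]$curves)) {
      cv <- config$arms[[arm]]$curves[[ep]]
      for (key in c("points_csv", "risk_csv")) {
        if (!is.null(cv[[key]]) && !file.exists(cv[[key]])) {
          cand <- file.path(base_dir, cv[[key]])
          if (file.exists(cand)) {
            config$arms[[arm]]$curves[[ep]][[key]] <- cand
          }
        }
      }
    }
  }
  validate_config(config)
}

config_top_keys <- function() {
  c("label", "locale", "population", "settings", "wtp", "wtp_list",
    "hr_mode", "selection_criterion", "economics", "utilities", "arms",
    "adverse_events", "psa", "subgroup", "parameter_ranges")
}

#' Validate a run configuration
#'
#' @param config A configuration list (from [yaml::read_yaml()] or
#'   built in code).
#' @return The normalized configuration (class `run_config`); stops
#'   with a message listing *all* validation errors otherwise.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)

  unknown <- setdiff(names(config), config_top_keys())
  if (length(unknown) > 0) {
    add(sprintf("unknown top-level key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in c("locale", "settings", "wtp", "economics", "utilities", "arms")) {
    if (is.null(config[[key]])) add(sprintf("missing required key: %s", key))
  }

  s <- config$settings
  if (!is.null(s)) {
    if (!is.null(s$discount_rate_annual) &&
        (s$discount_rate_annual < 0 || s$discount_rate_annual >= 1)) {
      add("settings.discount_rate_annual must be in [0, 1)")
    }
    if (!is.null(s$cycle_length_days) && s$cycle_length_days <= 0) {
      add("settings.cycle_length_days must be > 0")
    }
    if (!is.null(s$horizon_years) && s$horizon_years <= 0) {
      add("settings.horizon_years must be > 0")
    }
  }
  if (!is.null(config$wtp) && any(config$wtp < 0)) add("wtp must be >= 0")
  if (!is.null(config$wtp_list) && any(config$wtp_list < 0)) {
    add("wtp_list entries must be >= 0")
  }

  e <- config$economics
  if (!is.null(e)) {
    if (is.null(e$bsa) || e$bsa <= 0) add("economics.bsa must be > 0")
    if (is.null(e$weight) || e$weight <= 0) add("economics.weight must be > 0")
    if (is.null(e$prices) || length(e$prices) == 0) {
      add("economics.prices must be a non-empty named list ($/mg)")
    } else if (any(unlist(e$prices) < 0)) {
      add("economics.prices entries must be >= 0")
    }
    need <- c("egfr_testing", "followup_per_cycle", "bsc_per_cycle",
              "end_of_life", "radiotherapy", "infusion_per_admin")
    missing <- setdiff(need, names(e$costs))
    if (length(missing) > 0) {
      add(sprintf("economics.costs missing: %s", paste(missing, collapse = ", ")))
    } else if (any(unlist(e$costs) < 0)) {
      add("economics.costs entries must be >= 0")
    }
  }

  u <- config$utilities
  if (!is.null(u)) {
    for (st in c("pfs", "pd")) {
      if (is.null(u[[st]]) || u[[st]] < 0 || u[[st]] > 1) {
        add(sprintf("utilities.%s must be in [0, 1]", st))
      }
    }
  }

  if (!is.null(config$arms)) {
    for (arm in c("intervention", "comparator")) {
      a <- config$arms[[arm]]
      if (is.null(a)) { add(sprintf("arms.%s is required", arm)); next }
      if (is.null(a$regimen) || length(a$regimen) == 0) {
        add(sprintf("arms.%s.regimen must be non-empty", arm))
      }
      for (frac in c("discontinuation", "subsequent_fraction")) {
        v <- a[[frac]]
        if (!is.null(v) && (v < 0 || v > 1)) {
          add(sprintf("arms.%s.%s must be in [0, 1]", arm, frac))
        }
      }
      for (ep in c("pfs", "os")) {
        cv <- a$curves[[ep]]
        if (is.null(cv)) {
          add(sprintf("arms.%s.curves.%s is required", arm, ep))
        } else if (is.null(cv$family) && is.null(cv$points_csv) &&
                   is.null(cv$hr_of_comparator_os)) {
          add(sprintf("arms.%s.curves.%s must give either {family, params}, {points_csv, risk_csv} or {hr_of_comparator_os}",
                      arm, ep))
        }
      }
    }
  }

  ae <- config$adverse_events
  if (!is.null(ae)) {
    ae <- normalize_ae(ae)
    ok <- tryCatch({ validate_ae_table(ae); TRUE },
                   error = function(err) { add(paste0("adverse_events: ",
                                                      conditionMessage(err)))
                                           FALSE })
    if (ok) config$adverse_events <- ae
  }

  pr <- config$parameter_ranges
  if (!is.null(pr)) {
    for (nm in names(pr)) {
      r <- pr[[nm]]
      if (is.null(r$low) || is.null(r$high) || r$low > r$high) {
        add(sprintf("parameter_ranges.%s must give low <= high", nm))
      }
    }
  }

  if (!is.null(config$hr_mode) &&
      !config$hr_mode %in% c("proportional_hazards", "rate_multiply")) {
    add("hr_mode must be 'proportional_hazards' or 'rate_multiply'")
  }
  if (!is.null(config$selection_criterion) &&
      !config$selection_criterion %in% c("aic", "bic")) {
    add("selection_criterion must be 'aic' or 'bic'")
  }

  if (length(errors) > 0) {
    stop(sprintf("invalid configuration (%d error%s):\n  - %s",
                 length(errors), if (length(errors) > 1) "s" else "",
                 paste(errors, collapse = "\n  - ")), call. = FALSE)
  }
  class(config) <- c("run_config", "list")
  config
}

# adverse-event config: list-of-lists (YAML) or data frame, with per-arm
# incidence columns named either inc_intervention/inc_comparator or inc_a/inc_b
normalize_ae <- function(ae) {
  if (is.null(ae)) return(NULL)
  if (!is.data.frame(ae)) {
    ae <- do.call(rbind, lapply(ae, function(r) as.data.frame(r)))
  }
  names(ae)[names(ae) == "inc_intervention"] <- "inc_a"
  names(ae)[names(ae) == "inc_comparator"] <- "inc_b"
  ae
}

config_settings <- function(config) {
  s <- config$settings
  model_settings(
    cycle_length_days = s$cycle_length_days %||% 21,
    horizon_years = s$horizon_years %||% 20,
    discount_rate_annual = s$discount_rate_annual %||% 0.03,
    half_cycle_correction = s$half_cycle_correction %||% TRUE
  )
}

config_regimen <- function(arm_cfg) {
  comps <- lapply(arm_cfg$regimen, function(rc) {
    mc <- rc$max_cycles %||% "until_progression"
    if (identical(mc, "until_progression")) mc <- Inf
    drug_component(rc$drug, rc$dose,
                   dose_rule = rc$dose_rule %||% "per_mg",
                   schedule = rc$schedule %||% "per_cycle",
                   max_cycles = mc, iv = isTRUE(rc$iv))
  })
  regimen(arm_cfg$name, comps)
}

resolve_curve <- function(curve_cfg, criterion, hr_mode,
                          comparator_os = NULL) {
  if (!is.null(curve_cfg$family)) {
    return(list(curve = dist_spec(curve_cfg$family,
                                  unlist(curve_cfg$params)),
                fits = NULL))
  }
  if (!is.null(curve_cfg$hr_of_comparator_os)) {
    if (is.null(comparator_os)) {
      stop("hr_of_comparator_os curve requires the comparator OS curve to be resolved first",
           call. = FALSE)
    }
    return(list(curve = hr_adjust(comparator_os,
                                  curve_cfg$hr_of_comparator_os, hr_mode),
                fits = NULL))
  }
  km <- read_digitized_km(curve_cfg$points_csv, curve_cfg$risk_csv)
  ipd <- expand_to_ipd(reconstruct_interval_counts(km))
  fits <- fit_all_families(ipd, criterion)
  list(curve = fits[[1]], fits = fits)
}

#' Resolve a configuration into evaluable model inputs
#'
#' Reconstructs and fits any curves declared as digitized KM CSVs
#' (skipped for pre-fitted parameter declarations), builds the
#' [locale_economics()], [regimen()]s and [arm_spec()]s, and returns
#' them together with the [model_settings()].
#'
#' @param config A validated configuration ([load_config()] /
#'   [validate_config()]).
#' @return List with `settings`, `arms` (intervention/comparator
#'   [arm_spec()]s), `locale` and `fits` (ranked fit lists for curves
#'   that were fitted from KM input, else `NULL`s).
#' @export
config_to_model_inputs <- function(config) {
  settings <- config_settings(config)
  criterion <- config$selection_criterion %||% "aic"
  hr_mode <- config$hr_mode %||% "proportional_hazards"
  locale <- locale_economics(
    prices = config$economics$prices,
    bsa = config$economics$bsa,
    weight = config$economics$weight,
    costs = config$economics$costs,
    discount_rate_annual = config$settings$discount_rate_annual %||% 0.03,
    wtp = config$wtp
  )
  ae <- normalize_ae(config$adverse_events)

  fits <- list()
  # comparator first: the intervention OS may be an HR adjustment of it
  comp_cfg <- config$arms$comparator
  comp_pfs <- resolve_curve(comp_cfg$curves$pfs, criterion, hr_mode)
  comp_os <- resolve_curve(comp_cfg$curves$os, criterion, hr_mode)
  fits$comparator_pfs <- comp_pfs$fits
  fits$comparator_os <- comp_os$fits
  int_cfg <- config$arms$intervention
  int_pfs <- resolve_curve(int_cfg$curves$pfs, criterion, hr_mode)
  int_os <- resolve_curve(int_cfg$curves$os, criterion, hr_mode,
                          comparator_os = as_curve(comp_os$curve))
  fits$intervention_pfs <- int_pfs$fits
  fits$intervention_os <- int_os$fits

  mk_arm <- function(arm_cfg, pfs, os, ae_arm) {
    arm_spec(
      name = arm_cfg$name,
      pfs = pfs, os = os,
      reg = config_regimen(arm_cfg),
      utilities = config$utilities,
      locale = locale,
      discontinuation = arm_cfg$discontinuation %||% 0,
      subsequent_fraction = arm_cfg$subsequent_fraction %||% 0,
      subsequent_cost_per_cycle = arm_cfg$subsequent_cost_per_cycle %||% 0,
      ae_table = ae, ae_arm = ae_arm
    )
  }
  list(
    settings = settings,
    locale = locale,
    arms = list(
      intervention = mk_arm(int_cfg, int_pfs$curve, int_os$curve, "a"),
      comparator = mk_arm(comp_cfg, comp_pfs$curve, comp_os$curve, "b")
    ),
    fits = fits
  )
}

#' Evaluate a configuration to a cost-effectiveness result
#'
#' @param config A validated configuration.
#' @return A `ce_result` (intervention vs comparator).
#' @export
evaluate_config <- function(config) {
  inputs <- config_to_model_inputs(config)
  incremental_analysis(
    evaluate_arm(inputs$arms$intervention, inputs$settings),
    evaluate_arm(inputs$arms$comparator, inputs$settings)
  )
}

#' Build a re-evaluable model closure from a configuration
#'
#' Resolves the configuration's curves once (any KM reconstruction and
#' fitting happens here, not per draw) and returns a function
#' `overrides -> ce_result` suitable for [owsa()], [run_psa()] and
#' [price_threshold_search()].  `overrides` is a named list of
#' parameter values; names are matched against `defs` and applied at
#' each definition's `path` inside the configuration.
#'
#' @param config A validated configuration.
#' @param defs List of [param_def()]s whose names the closure accepts
#'   (default [default_parameter_defs()]).
#' @return Function `(overrides = list()) -> ce_result`, with the
#'   resolved config as attribute `config` and `defs` as attribute
#'   `defs`.
#' @export
make_model <- function(config, defs = default_parameter_defs(config)) {
  resolved <- config
  inputs <- config_to_model_inputs(config)
  # freeze fitted curves back into the config so per-draw evaluation
  # never refits
  for (arm in c("intervention", "comparator")) {
    for (ep in c("pfs", "os")) {
      cv <- resolved$arms[[arm]]$curves[[ep]]
      if (!is.null(cv$points_csv)) {
        spec <- as_curve(inputs$arms[[arm]][[ep]])
        resolved$arms[[arm]]$curves[[ep]] <-
          list(family = spec$family, params = unname(spec$params))
      }
    }
  }
  paths <- stats::setNames(lapply(defs, `[[`, "path"),
                           vapply(defs, `[[`, character(1), "name"))
  model <- function(overrides = list()) {
    cfg <- resolved
    for (nm in names(overrides)) {
      path <- paths[[nm]]
      if (is.null(path)) {
        stop(sprintf("make_model: unknown parameter '%s'", nm), call. = FALSE)
      }
      cfg[[path]] <- overrides[[nm]]
    }
    evaluate_config(cfg)
  }
  attr(model, "config") <- resolved
  attr(model, "defs") <- defs
  model
}

#' Default sensitivity-analysis parameter set for a configuration
#'
#' Builds [param_def()]s for the standard uncertain inputs: drug unit
#' prices and non-drug unit costs (gamma in PSA), subsequent-therapy
#' costs, state utilities (beta), discontinuation and
#' subsequent-therapy fractions (beta), body surface area and weight
#' (normal), and — when the intervention OS is a hazard-ratio
#' adjustment — the OS hazard ratio (normal, truncated positive).
#'
#' Ranges follow the usual convention: a parameter's 95% confidence
#' interval where one is supplied (via the configuration's
#' `parameter_ranges: {name: {low, high}}` block), otherwise +/-25% of
#' the base value.
#'
#' @param config A validated configuration.
#' @return Named list of `param_def`s.
#' @export
default_parameter_defs <- function(config) {
  defs <- list()
  ranges <- config$parameter_ranges
  add <- function(def) defs[[def$name]] <<- def
  mk_def <- function(name, base, role, path) {
    r <- ranges[[name]]
    param_def(name, base, role, low = r$low, high = r$high, se = r$se,
              path = path)
  }
  for (drug in names(config$economics$prices)) {
    add(mk_def(paste0("price_", drug),
                  base = config$economics$prices[[drug]], role = "cost",
                  path = c("economics", "prices", drug)))
  }
  for (cost in c("egfr_testing", "followup_per_cycle", "bsc_per_cycle",
                 "end_of_life")) {
    add(mk_def(paste0("cost_", cost),
                  base = config$economics$costs[[cost]], role = "cost",
                  path = c("economics", "costs", cost)))
  }
  for (arm in c("intervention", "comparator")) {
    a <- config$arms[[arm]]
    add(mk_def(paste0("subsequent_cost_", arm),
                  base = a$subsequent_cost_per_cycle %||% 0, role = "cost",
                  path = c("arms", arm, "subsequent_cost_per_cycle")))
    if (!is.null(a$discontinuation) && a$discontinuation > 0) {
      add(mk_def(paste0("discontinuation_", arm),
                    base = a$discontinuation, role = "probability",
                    path = c("arms", arm, "discontinuation")))
    }
    if (!is.null(a$subsequent_fraction) && a$subsequent_fraction > 0) {
      add(mk_def(paste0("subsequent_fraction_", arm),
                    base = a$subsequent_fraction, role = "probability",
                    path = c("arms", arm, "subsequent_fraction")))
    }
  }
  for (st in c("pfs", "pd")) {
    add(mk_def(paste0("utility_", st), base = config$utilities[[st]],
                  role = "utility", path = c("utilities", st)))
  }
  add(mk_def("bsa", base = config$economics$bsa, role = "bsa",
                path = c("economics", "bsa")))
  add(mk_def("weight", base = config$economics$weight, role = "weight",
                path = c("economics", "weight")))
  hr_cfg <- config$arms$intervention$curves$os$hr_of_comparator_os
  if (!is.null(hr_cfg)) {
    add(mk_def("hr_os", base = hr_cfg, role = "hr",
                  path = c("arms", "intervention", "curves", "os",
                           "hr_of_comparator_os")))
  }
  defs
}

#' Run the full pipeline for one configuration
#'
#' Reconstruct (if digitized curves are given) -> fit -> select ->
#' trace -> accrue -> incremental analysis, optionally writing the
#' result artifacts: a base-case results table, per-arm traces, the
#' fit report and (when `wtp_list` is configured) a WTP scenario
#' table.  Output files are deterministic for a given configuration.
#'
#' @param config A configuration list, or the path to a YAML file
#'   (passed through [load_config()]).
#' @param outdir Optional output directory for CSV artifacts.
#' @return List of class `pipeline_result`: `ce` (the `ce_result`),
#'   `inputs` (resolved model inputs incl. fits), `scenario` (or
#'   `NULL`), `outdir` and `files`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- stage("reconstruct/fit", config_to_model_inputs(config))
  results <- stage("evaluate", list(
    a = evaluate_arm(inputs$arms$intervention, inputs$settings),
    b = evaluate_arm(inputs$arms$comparator, inputs$settings)
  ))
  ce <- stage("incremental", incremental_analysis(results$a, results$b))
  scenario <- if (!is.null(config$wtp_list)) {
    stage("scenario", run_scenario(ce, config$wtp_list))
  }

  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    write_ce_result(ce, p("base_case.csv"))
    write_trace(results$a$trace, p("trace_intervention.csv"))
    write_trace(results$b$trace, p("trace_comparator.csv"))
    files <- c(p("base_case.csv"), p("trace_intervention.csv"),
               p("trace_comparator.csv"))
    selected <- Filter(Negate(is.null), lapply(inputs$fits, function(f) {
      if (is.null(f)) NULL else f[[1]]
    }))
    if (length(selected) > 0) {
      write_fits(selected, p("fits.csv"))
      files <- c(files, p("fits.csv"))
    }
    if (!is.null(scenario)) {
      utils::write.csv(scenario, p("scenario.csv"), row.names = FALSE)
      files <- c(files, p("scenario.csv"))
    }
    log_lines <- c(
      sprintf("psmcea %s / R %s.%s",
              as.character(utils::packageVersion("psmcea")),
              R.version$major, R.version$minor),
      sprintf("locale=%s population=%s", config$locale,
              config$population %||% "NA"),
      sprintf("selection_criterion=%s hr_mode=%s",
              config$selection_criterion %||% "aic",
              config$hr_mode %||% "proportional_hazards"),
      sprintf("psa_seed=%s", config$psa$seed %||% "NA")
    )
    writeLines(log_lines, p("run_log.txt"))
    files <- c(files, p("run_log.txt"))
  }
  structure(list(ce = ce, inputs = inputs, scenario = scenario,
                 outdir = outdir, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$ce)
  invisible(x)
}
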