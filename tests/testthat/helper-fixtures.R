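# shared builders for the test suite; everything is generated in code

# minimal locale with all-zero costs unless overridden
test_locale <- function(prices = list(drugA = 1),
                        costs = list(),
                        bsa = 1.79, weight = 70,
                        discount_rate_annual = 0, wtp = 50000) {
  base <- list(egfr_testing = 0, followup_per_cycle = 0,
               bsc_per_cycle = 0, end_of_life = 0, radiotherapy = 0,
               infusion_per_admin = 0)
  base[names(costs)] <- costs
  locale_economics(prices = prices, bsa = bsa, weight = weight,
                   costs = base,
                   discount_rate_annual = discount_rate_annual, wtp = wtp)
}

test_regimen <- function(drug = "drugA", dose = 1,
                         dose_rule = "per_mg", schedule = "per_cycle",
                         max_cycles = Inf, iv = FALSE, name = "test") {
  regimen(name, list(drug_component(drug, dose, dose_rule, schedule,
                                    max_cycles, iv)))
}

test_arm <- function(name = "arm", pfs, os, locale = test_locale(),
                     reg = test_regimen(), utilities = list(pfs = 1, pd = 1),
                     ...) {
  arm_spec(name, pfs, os, reg, utilities, locale, ...)
}

# simple exponential arms with a known gap
test_exp_arms <- function(rate_pfs_a = 0.10, rate_os_a = 0.04,
                          rate_pfs_b = 0.20, rate_os_b = 0.05,
                          locale = test_locale()) {
  list(
    a = test_arm("a", dist_spec("exponential", rate_pfs_a),
                 dist_spec("exponential", rate_os_a), locale),
    b = test_arm("b", dist_spec("exponential", rate_pfs_b),
                 dist_spec("exponential", rate_os_b), locale)
  )
}

# independent product-limit estimator used as oracle against km_from_ipd
naive_product_limit <- function(ipd, at) {
  ts <- sort(unique(ipd$time[ipd$event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (tt in ts[ts <= t]) {
      n <- sum(ipd$time >= tt)
      d <- sum(ipd$time == tt & ipd$event == 1)
      s <- s * (1 - d / n)
    }
    s
  }, numeric(1))
}
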