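test_that("trace partitions the cohort across the three states", {
  st <- model_settings(discount_rate_annual = 0)
  # identical curves: nobody occupies the progressed state
  sp <- dist_spec("exponential", 0.05)
  tr <- build_trace(sp, sp, st)
  expect_true(all(tr$pd == 0))
  expect_equal(tr$pfs + tr$pd + tr$dead, rep(1, nrow(tr)), tolerance = 1e-9)

  # first-cycle death probability from the OS curve, 3-week cycle
  os <- dist_spec("exponential", 0.03)
  pfs <- dist_spec("exponential", 0.10)
  tr2 <- build_trace(pfs, os, st)
  u <- 21 * 12 / 365.25
  expect_equal(tr2$dead[2], 1 - exp(-0.03 * u), tolerance = 1e-12)
  expect_equal(tr2$time_months[2], u)
  # occupancy invariants
  expect_true(all(diff(tr2$dead) >= 0))
  expect_true(all(diff(tr2$pfs) <= 0))
  expect_true(all(tr2$pd >= 0 & tr2$pd <= 1))
  expect_equal(tr2$pfs + tr2$pd + tr2$dead, rep(1, nrow(tr2)),
               tolerance = 1e-9)

  # crossing curves: progressed state clamped at zero, clamps reported
  crossing <- build_trace(dist_spec("exponential", 0.02),
                          dist_spec("exponential", 0.05), st)
  expect_gt(attr(crossing, "clamped"), 0)
  expect_true(all(crossing$pd == 0))

  expect_error(build_trace(pfs, os, model_settings(horizon_years = 0.01)),
               "shorter than one cycle")
})

test_that("partitioned-survival and per-cycle transition modes agree", {
  st <- model_settings(discount_rate_annual = 0.03)
  pfs <- dist_spec("weibull", c(0.08, 1.3))
  os <- dist_spec("weibull", c(0.02, 1.2))
  tr_ps <- build_trace(pfs, os, st)
  tr_mk <- build_trace(pfs, os, st, markov_mode = TRUE)
  expect_equal(tr_mk$pfs, tr_ps$pfs, tolerance = 1e-9)
  expect_equal(tr_mk$pd, tr_ps$pd, tolerance = 1e-9)
  expect_equal(tr_mk$dead, tr_ps$dead, tolerance = 1e-9)
})

test_that("discount factors follow compound discounting", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(0.05, 2), 1 / 1.1025, tolerance = 1e-12)
  expect_error(discount_factor(0.03, -1), ">= 0")
})

test_that("accrual reproduces closed-form life expectancy and conserves one-offs", {
  # all mass stays progression-free, value 1 per cycle, no discounting
  st <- model_settings(discount_rate_annual = 0, horizon_years = 1)
  never <- dist_spec("exponential", 1e-9)
  tr <- build_trace(never, never, st)
  n_cycles <- nrow(tr) - 1
  expect_equal(accrue(tr, list(pfs = 1)), n_cycles, tolerance = 1e-6)

  # undiscounted life-years under exponential OS = 1/rate (within 1%)
  st2 <- model_settings(discount_rate_annual = 0, horizon_years = 60,
                        survival_floor = 0)
  os <- dist_spec("exponential", 0.5 / 12)  # 0.5 per year in months
  tr2 <- build_trace(os, os, st2)
  expect_equal(life_years(tr2), 2.0, tolerance = 0.01)

  # trapezoid quadrature of the OS curve matches the engine
  auc <- integrate(function(t) survival_at(os, t * 12), 0, 60,
                   rel.tol = 1e-10)$value
  expect_equal(life_years(tr2), auc, tolerance = 0.001)

  # one-off end-of-life value is conserved when everyone dies in horizon
  os3 <- dist_spec("exponential", 0.1)
  st3 <- model_settings(discount_rate_annual = 0, horizon_years = 60,
                        survival_floor = 0)
  tr3 <- build_trace(os3, os3, st3)
  expect_equal(accrue(tr3, list(death_one_off = 1000)),
               1000 * tr3$dead[nrow(tr3)], tolerance = 1e-9)
  expect_gt(tr3$dead[nrow(tr3)], 0.999)

  expect_error(accrue(tr3, list(pfs = rep(1, 5))), "shorter than")
})

test_that("discounted totals decrease in the rate and half-cycle correction is bounded", {
  pfs <- dist_spec("weibull", c(0.08, 1.3))
  os <- dist_spec("weibull", c(0.02, 1.2))
  lys <- vapply(c(0, 0.03, 0.05, 0.10), function(r) {
    life_years(build_trace(pfs, os, model_settings(discount_rate_annual = r)))
  }, numeric(1))
  expect_true(all(diff(lys) < 0))

  # half-cycle correction changes the total by less than one cycle's value
  st_on <- model_settings(discount_rate_annual = 0.03)
  st_off <- model_settings(discount_rate_annual = 0.03,
                           half_cycle_correction = FALSE)
  ly_on <- life_years(build_trace(pfs, os, st_on))
  ly_off <- life_years(build_trace(pfs, os, st_off))
  expect_lt(abs(ly_on - ly_off), st_on$cycle_length_years)
})

test_that("QALYs weight life-years by utilities and warn on odd values", {
  st <- model_settings(discount_rate_annual = 0)
  pfs <- dist_spec("exponential", 0.08)
  os <- dist_spec("exponential", 0.03)
  tr <- build_trace(pfs, os, st)
  # utility 1 everywhere: QALY = LY
  expect_equal(qalys(tr, list(pfs = 1, pd = 1)), life_years(tr),
               tolerance = 1e-12)

  # hand-summable weighted total (brute-force oracle)
  u <- st$cycle_length_years
  k <- seq_len(nrow(tr) - 1)
  m_pfs <- (tr$pfs[k] + tr$pfs[k + 1]) / 2
  m_pd <- (tr$pd[k] + tr$pd[k + 1]) / 2
  by_hand <- sum(0.8 * u * m_pfs + 0.5 * u * m_pd)
  expect_equal(qalys(tr, list(pfs = 0.8, pd = 0.5)), by_hand,
               tolerance = 1e-12)
  expect_lte(qalys(tr, list(pfs = 0.8, pd = 0.5)), life_years(tr))

  # AE decrement comes off the total once
  expect_equal(qalys(tr, list(pfs = 0.8, pd = 0.5), ae_decrement = 0.01),
               by_hand - 0.01, tolerance = 1e-12)

  expect_warning(qalys(tr, list(pfs = 1.2, pd = 0.5)), "utility")
})

test_that("traces export to CSV with discounted increments", {
  st <- model_settings()
  tr <- build_trace(dist_spec("exponential", 0.08),
                    dist_spec("exponential", 0.03), st)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(tr))
  expect_equal(sum(df$discounted_ly_increment), life_years(tr),
               tolerance = 1e-9)
})
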