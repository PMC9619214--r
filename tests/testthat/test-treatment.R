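test_that("regimen cycle costs resolve doses, schedules and cutoffs", {
  st <- model_settings()
  us <- test_locale(prices = list(osimertinib = 6.62, pemetrexed = 0.60,
                                  cisplatin = 0.02),
                    bsa = 1.79, weight = 70)
  # 80 mg daily oral drug over a 21-day cycle at 6.62 $/mg
  oral <- test_regimen("osimertinib", 80, "per_mg", "per_day")
  expect_equal(regimen_cycle_cost(oral, 0, us, st), 80 * 21 * 6.62)

  # per-m2 dosing: 500 mg/m2 at BSA 1.79 -> 895 mg per administration
  pem <- test_regimen("pemetrexed", 500, "per_m2", "per_cycle")
  expect_equal(regimen_cycle_cost(pem, 3, us, st), 895 * 0.60)

  # four-cycle platinum stops contributing from cycle index 4
  cis <- test_regimen("cisplatin", 75, "per_m2", "per_cycle", max_cycles = 4)
  expect_gt(regimen_cycle_cost(cis, 3, us, st), 0)
  expect_equal(regimen_cycle_cost(cis, 5, us, st), 0)

  # per-kg dosing and infusion add-on
  wloc <- test_locale(prices = list(drugB = 2), weight = 70,
                      costs = list(infusion_per_admin = 100))
  perkg <- test_regimen("drugB", 3, "per_kg", "per_cycle", iv = TRUE)
  expect_equal(regimen_cycle_cost(perkg, 0, wloc, st), 3 * 70 * 2 + 100)

  # doubling BSA doubles per-m2 contributions only
  us2 <- test_locale(prices = list(osimertinib = 6.62, pemetrexed = 0.60),
                     bsa = 2 * 1.79)
  expect_equal(regimen_cycle_cost(pem, 0, us2, st),
               2 * regimen_cycle_cost(pem, 0, us, st))
  expect_equal(regimen_cycle_cost(oral, 0, us2, st),
               regimen_cycle_cost(oral, 0, us, st))

  expect_error(regimen_cycle_cost(test_regimen("mystery", 1), 0, us, st),
               "no unit price configured for drug 'mystery'")
  expect_error(regimen_cycle_cost(oral, -1, us, st), ">= 0")
})

test_that("adverse events filter on the incidence-difference rule", {
  ae <- data.frame(
    name = c("overall", "mid", "edge", "tiny"),
    inc_a = c(0.09, 0.10, 0.10, 0.01),
    inc_b = c(0.34, 0.14, 0.151, 0.012),
    cost = 1, disutility = 0.1, duration_years = 0.1
  )
  kept <- filter_adverse_events(ae)
  # 0.25 and 0.051 differences pass; 0.04 and 0.002 do not
  expect_setequal(kept$name, c("overall", "edge"))
  # boundary is strict: exactly 5 points is excluded
  ae5 <- data.frame(name = "five", inc_a = 0.10, inc_b = 0.15, cost = 1,
                    disutility = 0, duration_years = 0)
  expect_equal(nrow(filter_adverse_events(ae5)), 0)
  expect_error(filter_adverse_events(transform(ae, inc_a = inc_a + 1)),
               "\\[0, 1\\]")
})

test_that("adverse-event burden is an expectation and adds across events", {
  empty <- filter_adverse_events(data.frame())
  expect_equal(ae_burden(empty, "a"),
               list(one_off_cost = 0, qaly_decrement = 0))

  one <- data.frame(name = "x", inc_a = 0.2, inc_b = 0, cost = 1000,
                    disutility = 0.1, duration_years = 0.25)
  b <- ae_burden(one, "a")
  expect_equal(b$one_off_cost, 200)
  expect_equal(b$qaly_decrement, 0.005)

  two <- rbind(one, data.frame(name = "y", inc_a = 0.5, inc_b = 0,
                               cost = 100, disutility = 0.2,
                               duration_years = 0.1))
  b2 <- ae_burden(two, "a")
  expect_equal(b2$one_off_cost, 200 + 50)
  expect_equal(b2$qaly_decrement, 0.005 + 0.01)
  # the other arm reads its own incidence column
  expect_equal(ae_burden(two, "b")$one_off_cost, 0)

  expect_error(ae_burden(transform(one, duration_years = -1), "a"),
               "durations")
})

test_that("value streams assemble drug, follow-up, mixture and one-off pieces", {
  st <- model_settings()
  loc <- test_locale(prices = list(drugA = 1),
                     costs = list(followup_per_cycle = 10,
                                  bsc_per_cycle = 20,
                                  egfr_testing = 55, end_of_life = 1000))
  arm <- test_arm("x", dist_spec("exponential", 0.1),
                  dist_spec("exponential", 0.05), locale = loc,
                  reg = test_regimen("drugA", 100, "per_mg", "per_cycle"),
                  discontinuation = 0.07,
                  subsequent_fraction = 0.81,
                  subsequent_cost_per_cycle = 100)
  vs <- build_value_streams(arm, st, 5)
  # cycle 0 at full drug cost, later cycles reduced by discontinuation
  expect_equal(vs$cost$pfs[1], 100 + 10)
  expect_equal(vs$cost$pfs[2], 100 * 0.93 + 10)
  # progressed state: subsequent-therapy / BSC mixture
  expect_equal(vs$cost$pd, rep(0.81 * 100 + 0.19 * 20, 5))
  expect_equal(vs$cost$entry_one_off, 55)
  expect_equal(vs$cost$death_one_off, 1000)

  # all-zero cost configuration yields zero streams, utilities untouched
  arm0 <- test_arm("zero", dist_spec("exponential", 0.1),
                   dist_spec("exponential", 0.05),
                   locale = test_locale(prices = list(drugA = 0)),
                   reg = test_regimen("drugA", 100),
                   utilities = list(pfs = 0.8, pd = 0.5))
  vs0 <- build_value_streams(arm0, st, 5)
  expect_true(all(vs0$cost$pfs == 0) && all(vs0$cost$pd == 0))
  expect_equal(vs0$utilities, list(pfs = 0.8, pd = 0.5))
})

test_that("end-of-life one-off accrues exactly once through an arm evaluation", {
  loc <- test_locale(prices = list(drugA = 0),
                     costs = list(end_of_life = 1000),
                     discount_rate_annual = 0)
  arm <- test_arm("x", dist_spec("exponential", 0.2),
                  dist_spec("exponential", 0.15), locale = loc,
                  reg = test_regimen("drugA", 1))
  st <- model_settings(discount_rate_annual = 0, horizon_years = 60,
                       survival_floor = 0)
  res <- evaluate_arm(arm, st)
  expect_equal(res$cost, 1000 * res$trace$dead[nrow(res$trace)],
               tolerance = 1e-9)
  expect_gt(res$trace$dead[nrow(res$trace)], 0.999)
})

test_that("total accrued drug cost is linear in the unit price", {
  st <- model_settings()
  cost_at <- function(price) {
    loc <- test_locale(prices = list(drugA = price))
    arm <- test_arm("x", dist_spec("exponential", 0.1),
                    dist_spec("exponential", 0.05), locale = loc,
                    reg = test_regimen("drugA", 10, schedule = "per_day"))
    evaluate_arm(arm, st)$cost
  }
  c0 <- cost_at(0); c1 <- cost_at(1); c2 <- cost_at(2); c5 <- cost_at(5)
  expect_equal(c0, 0)
  expect_equal(c2 - c0, 2 * (c1 - c0), tolerance = 1e-9)
  expect_equal(c5 - c0, 5 * (c1 - c0), tolerance = 1e-9)
})
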