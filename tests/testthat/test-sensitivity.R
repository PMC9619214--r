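test_that("moment matching reproduces means and variances exactly", {
  g <- moment_match("cost", 100, 25)
  expect_equal(g, list(dist = "gamma", shape = 16, scale = 6.25))
  expect_equal(g$shape * g$scale, 100)            # mean
  expect_equal(g$shape * g$scale^2, 625)          # variance

  b <- moment_match("utility", 0.8, 0.1)
  expect_equal(b, list(dist = "beta", alpha = 12, beta = 3))
  expect_equal(b$alpha / (b$alpha + b$beta), 0.8)
  expect_equal(b$alpha * b$beta /
                 ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1)), 0.01)

  n <- moment_match("hr", 1, 0.2)
  expect_equal(n, list(dist = "normal", mean = 1, sd = 0.2))

  expect_error(moment_match("utility", 0.5, 0.6), "infeasible")
  expect_error(moment_match("cost", 100, 0), "se must be > 0")

  # sampled moments recover the request (large-sample spot check)
  set.seed(123)
  x <- rgamma(1e6, shape = g$shape, scale = g$scale)
  expect_equal(mean(x), 100, tolerance = 0.005)
  expect_equal(sd(x), 25, tolerance = 0.01)
  y <- rbeta(1e6, b$alpha, b$beta)
  expect_equal(mean(y), 0.8, tolerance = 0.005)
  expect_equal(sd(y), 0.1, tolerance = 0.01)
})

test_that("parameter definitions derive ranges and standard errors", {
  p <- param_def("c1", 100, "cost")
  expect_equal(c(p$low, p$high), c(75, 125))
  expect_equal(p$se, 50 / (2 * 1.96))
  # utility ranges clamp into [0, 1]
  u <- param_def("u1", 0.9, "utility")
  expect_equal(u$high, 1)
  expect_error(param_def("bad", 1, "cost", low = 2, high = 3),
               "low <= base <= high")
})

# a tiny analytic model: cost_a = theta * q + k, everything else constant
toy_model <- function(q = 10, k = 1000, qaly_a = 1.4) {
  function(overrides = list()) {
    theta <- overrides$theta %||% 50
    zeta <- overrides$zeta %||% 1  # deliberately unused by the model
    incremental_analysis(
      list(name = "a", cost = theta * q + k, qaly = qaly_a, ly = 2),
      list(name = "b", cost = 800, qaly = 1.0, ly = 1.6)
    )
  }
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("one-way sensitivity analysis ranks spans and handles zero influence", {
  model <- toy_model()
  defs <- list(param_def("theta", 50, "cost"),
               param_def("zeta", 1, "hr"))
  tab <- owsa(model, defs, wtp = 50000)
  # analytic span: d ICER = (high-low) * q / dE
  expect_equal(tab$span[tab$parameter == "theta"],
               (62.5 - 37.5) * 10 / 0.4, tolerance = 1e-9)
  # the inert parameter has zero span and ranks last
  expect_equal(tab$span[tab$parameter == "zeta"], 0)
  expect_equal(tab$parameter[nrow(tab)], "zeta")
  # base-case ICER attached for the tornado axis
  expect_equal(attr(tab, "base_icer"), model(list())$icer_qaly)

  # all parameters at base reproduce the base-case ICER
  expect_equal(model(list(theta = 50))$icer_qaly, attr(tab, "base_icer"))
})

test_that("owsa falls back to NMB when a bound crosses zero effect", {
  # qaly_a crosses the comparator's 1.0 inside the range
  model <- function(overrides = list()) {
    qa <- overrides$qa %||% 1.05
    incremental_analysis(list(cost = 2000, qaly = qa, ly = 2),
                         list(cost = 800, qaly = 1.0, ly = 1.6))
  }
  defs <- list(param_def("qa", 1.05, "hr", low = 0.9, high = 1.2))
  tab <- owsa(model, defs, wtp = 50000)
  expect_equal(tab$metric[1], "nmb")
  expect_equal(tab$span[1],
               abs((50000 * 0.2 - 1200) - (50000 * -0.1 - 1200)))
})

test_that("PSA is seeded, reproducible and degenerates to the base case", {
  model <- toy_model()
  defs <- list(param_def("theta", 50, "cost"),
               param_def("zeta", 1, "hr"))
  s1 <- run_psa(model, defs, iterations = 100, seed = 42)
  s2 <- run_psa(model, defs, iterations = 100, seed = 42)
  expect_identical(s1, s2)
  s3 <- run_psa(model, defs, iterations = 100, seed = 43)
  expect_false(identical(s1$delta_cost, s3$delta_cost))
  expect_equal(nrow(s1), 100)

  # zero-se parameters: every draw equals the base case
  defs0 <- list(param_def("theta", 50, "cost", se = 0),
                param_def("zeta", 1, "hr", se = 0))
  s0 <- run_psa(model, defs0, iterations = 20, seed = 1)
  base <- model(list())
  expect_true(all(s0$delta_cost == base$delta_cost))
  expect_true(all(s0$qaly_a == base$arm_a$qaly))

  # infeasible distribution fails before any draw
  bad <- list(param_def("u", 0.5, "utility", se = 0.9))
  expect_error(run_psa(toy_model(), bad, iterations = 10, seed = 1),
               "infeasible")

  # normal-role draws are truncated positive
  defs_hr <- list(param_def("zeta", 0.2, "hr", se = 0.5))
  shr <- run_psa(model, defs_hr, iterations = 500, seed = 7)
  expect_true(all(shr$zeta > 0))
})

test_that("PSA mean increments track the deterministic base case", {
  # linear model: E[draws] equals base case; check within 3 MC SEs
  model <- toy_model()
  defs <- list(param_def("theta", 50, "cost"))
  s <- run_psa(model, defs, iterations = 2000, seed = 31)
  base <- model(list())
  mc_se <- sd(s$delta_cost) / sqrt(nrow(s))
  expect_lt(abs(mean(s$delta_cost) - base$delta_cost), 3 * mc_se)
  expect_equal(mean(s$delta_qaly), base$delta_qaly)  # not varied
})

test_that("the acceptability curve equals hand-enumerated fractions", {
  # four hand-written draws
  sample <- structure(
    data.frame(delta_cost = c(1000, -500, 2000, 100),
               delta_qaly = c(0.1, -0.05, 0.02, 0)),
    class = c("psa_sample", "data.frame"))
  # at wtp 50,000: inmb = 4000, -2000, -1000, -100 -> 1/4 positive
  expect_equal(ceac(sample, 50000)$prob_cost_effective, 0.25)
  # at wtp 0: fraction with negative incremental cost
  expect_equal(ceac(sample, 0)$prob_cost_effective, 0.25)
  # enumerate across a grid by brute force
  grid <- c(0, 1e4, 5e4, 1e5, 1e6)
  brute <- vapply(grid, function(w) {
    mean(w * sample$delta_qaly - sample$delta_cost > 0)
  }, numeric(1))
  expect_equal(ceac(sample, grid)$prob_cost_effective, brute)
  expect_error(ceac(sample, numeric(0)), "empty")

  # dominance: all draws cheaper and more effective -> probability 1
  dom <- structure(data.frame(delta_cost = c(-1, -2), delta_qaly = c(1, 2)),
                   class = c("psa_sample", "data.frame"))
  expect_true(all(ceac(dom, grid)$prob_cost_effective == 1))

  # with P(dE > 0) = 1, acceptance tends to 1 as wtp grows
  mixed <- structure(data.frame(delta_cost = rnorm(100, 5000, 1000),
                                delta_qaly = runif(100, 0.05, 0.4)),
                     class = c("psa_sample", "data.frame"))
  expect_equal(ceac(mixed, 1e9)$prob_cost_effective, 1)
})
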