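test_that("exponential MLE equals the events-over-time closed form", {
  # 10 events, total observed time 100 months -> rate 0.1
  ipd <- data.frame(time = rep(10, 10), event = 1)
  fit <- fit_mle(ipd, "exponential")
  expect_equal(unname(fit$spec$params), 0.1, tolerance = 1e-10)

  # with censoring: d / sum(all times)
  set.seed(11)
  ipd <- data.frame(time = rexp(200, 0.2), event = rbinom(200, 1, 0.7))
  fit <- fit_mle(ipd, "exponential")
  expect_equal(unname(fit$spec$params), sum(ipd$event) / sum(ipd$time),
               tolerance = 1e-10)

  # information criteria definitions
  expect_equal(fit$aic, 2 * 1 - 2 * fit$log_likelihood)
  expect_equal(fit$bic, log(200) - 2 * fit$log_likelihood)
})

test_that("fitting requires events and valid records", {
  expect_error(fit_mle(data.frame(time = c(1, 2), event = c(0, 0)),
                       "weibull"), "at least one event")
  expect_error(fit_mle(data.frame(time = numeric(0), event = integer(0)),
                       "exponential"), "empty")
  expect_error(fit_mle(data.frame(time = c(1, -2), event = c(1, 1)),
                       "weibull"), "finite and > 0")
})

test_that("parameters are recovered from simulated data, censored and not", {
  truths <- list(
    exponential = dist_spec("exponential", 0.12),
    weibull     = dist_spec("weibull", c(0.08, 1.4)),
    loglogistic = dist_spec("loglogistic", c(9, 1.8)),
    lognormal   = dist_spec("lognormal", c(2.1, 0.8))
  )
  for (fam in names(truths)) {
    truth <- truths[[fam]]
    ipd <- simulate_arm(1000, truth, seed = 101)
    fit <- fit_mle(ipd, fam)
    expect_lt(max(abs(fit$spec$params - truth$params) /
                    abs(truth$params)), 0.05,
              label = sprintf("uncensored recovery, %s", fam))

    # ~20% random censoring
    cens_rate <- 0.25 * unname(switch(fam,
      exponential = truth$params[[1]],
      1 / mean(ipd$time)))
    ipd_c <- simulate_arm(1000, truth, censor_rate = cens_rate, seed = 202)
    expect_gt(mean(ipd_c$event == 0), 0.10)
    fit_c <- fit_mle(ipd_c, fam)
    expect_lt(max(abs(fit_c$spec$params - truth$params) /
                    abs(truth$params)), 0.10,
              label = sprintf("censored recovery, %s", fam))
  }
})

test_that("fits agree with an independent survival-regression oracle", {
  skip_if_not_installed("flexsurv")
  set.seed(77)
  ipd <- simulate_arm(400, dist_spec("weibull", c(0.06, 1.5)),
                      censor_rate = 0.02, seed = 303)
  fit <- fit_mle(ipd, "weibull")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                              dist = "weibull")
  # flexsurv S(t) = exp(-(t/scale)^shape): rate = scale^(-shape)
  shape_fs <- unname(fs$res["shape", "est"])
  rate_fs <- unname(fs$res["scale", "est"]) ^ (-shape_fs)
  expect_equal(unname(fit$spec$params[["shape"]]), shape_fs, tolerance = 1e-3)
  expect_equal(unname(fit$spec$params[["scale"]]), rate_fs, tolerance = 1e-3)
  expect_equal(fit$log_likelihood, fs$loglik, tolerance = 1e-6)

  fitll <- fit_mle(ipd, "loglogistic")
  fsll <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                                dist = "llogis")
  # flexsurv llogis: S(t) = 1/(1 + (t/scale)^shape) -- same parameterization
  expect_equal(unname(fitll$spec$params[["scale"]]),
               unname(fsll$res["scale", "est"]), tolerance = 1e-3)
  expect_equal(unname(fitll$spec$params[["shape"]]),
               unname(fsll$res["shape", "est"]), tolerance = 1e-3)
  expect_equal(fitll$log_likelihood, fsll$loglik, tolerance = 1e-6)
})

test_that("information-criterion ranking sorts, breaks ties and prefers the truth", {
  mk <- function(fam, params, ll, n) {
    fit <- fit_mle(simulate_arm(50, dist_spec("exponential", 0.2),
                                seed = 1), "exponential")
    fit$spec <- dist_spec(fam, params)
    fit$log_likelihood <- ll
    fit$n_params <- length(fit$spec$params)
    fit$n_obs <- n
    fit$aic <- 2 * fit$n_params - 2 * ll
    fit$bic <- fit$n_params * log(n) - 2 * ll
    fit
  }
  # AICs 100, 95, 102 -> sorted ascending
  fits <- list(mk("exponential", 0.1, -49, 100),    # aic 100
               mk("weibull", c(0.1, 1), -45.5, 100), # aic 95
               mk("lognormal", c(1, 1), -49, 100))   # aic 102
  ranked <- select_distribution(fits, "aic")
  expect_equal(vapply(ranked, `[[`, numeric(1), "aic"), c(95, 100, 102))

  # exact AIC tie: fewer parameters first
  tie <- list(mk("weibull", c(0.1, 1), -48, 100),     # k=2, aic 100
              mk("exponential", 0.1, -49, 100))       # k=1, aic 100
  expect_equal(select_distribution(tie, "aic")[[1]]$spec$family,
               "exponential")
  # tie on criterion and k: fixed family order breaks it
  tie2 <- list(mk("lognormal", c(1, 1), -48, 100),
               mk("weibull", c(0.1, 1), -48, 100))
  expect_equal(select_distribution(tie2, "aic")[[1]]$spec$family, "weibull")

  expect_error(select_distribution(list(), "aic"), "empty")

  # data generated from a weibull prefers weibull over exponential
  ipd <- simulate_arm(500, dist_spec("weibull", c(0.08, 1.6)), seed = 55)
  f_w <- fit_mle(ipd, "weibull"); f_e <- fit_mle(ipd, "exponential")
  expect_lt(f_w$aic, f_e$aic)
  expect_equal(fit_all_families(ipd)[[1]]$spec$family, "weibull")
})

test_that("fits are deterministic and serialize losslessly", {
  ipd <- simulate_arm(300, dist_spec("loglogistic", c(8, 2)), seed = 9)
  f1 <- fit_mle(ipd, "loglogistic")
  f2 <- fit_mle(ipd, "loglogistic")
  expect_identical(f1$spec$params, f2$spec$params)

  path <- tempfile(fileext = ".csv")
  write_fits(list(pfs = f1), path)
  back <- read_fits(path)
  expect_equal(back$pfs$spec$params, f1$spec$params, tolerance = 1e-12)
  expect_equal(back$pfs$aic, f1$aic, tolerance = 1e-9)
})
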