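test_that("exponential fit reproduces the closed-form MLE and likelihood", {
  co <- cohort(time = c(2, 4), event = c(1, 1))
  fit <- fit_parametric(co, "exponential")
  # rate = events / person-time = 2/6; loglik = 2 log(1/3) - (1/3) * 6
  expect_equal(exp(-fit$mu), 1 / 3, tolerance = 1e-6)
  expect_equal(fit$loglik, 2 * log(1 / 3) - 2, tolerance = 1e-8)
  expect_equal(fit$n_free, 1L)
  expect_true(fit$converged)
  # var(mu) = 1 / weighted events
  expect_equal(fit$cov[1, 1], 1 / 2, tolerance = 1e-4)
})

test_that("degenerate cohorts are refused", {
  expect_error(fit_parametric(cohort(c(1, 2), c(0, 0)), "exponential"), "events")
  expect_error(fit_parametric(cohort(c(1, 2, 3), c(1, 0, 0)), "weibull"), "events")
  expect_error(fit_parametric(cohort(c(1, 2, 3), c(1, 1, 0)), "gengamma"), "events")
})

test_that("weights act as frequency multipliers on likelihood and covariance", {
  co <- random_cohort(120, seed = 31)
  co2 <- co
  co2$weight <- co$weight * 2
  f1 <- fit_parametric(co, "weibull")
  f2 <- fit_parametric(co2, "weibull")
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(c(f2$mu, f2$sigma), c(f1$mu, f1$sigma), tolerance = 1e-6)
  expect_equal(f2$cov, f1$cov / 2, tolerance = 1e-4)
})

test_that("numeric delta-method SE matches the analytic exponential formula", {
  co <- cohort(time = c(2, 4), event = c(1, 1))
  fit <- fit_parametric(co, "exponential")
  lam <- exp(-fit$mu)
  cv <- parametric_risk_curve(fit, 2)
  # dF/dlambda = t exp(-lambda t); SE(lambda) = lambda / sqrt(D)
  se_analytic <- 2 * exp(-2 * lam) * lam / sqrt(2)
  expect_equal(cv$se, se_analytic, tolerance = 1e-6)
  expect_equal(cv$se, 0.2420272, tolerance = 1e-5)
  expect_equal(cv$risk, 1 - exp(-2 / 3), tolerance = 1e-6)
})

test_that("fits agree with flexsurv on a simulated cohort", {
  skip_if_not_installed("flexsurv")
  sc <- cohort_scenario(500, "gengamma", c(1.5, 1.1, 0.4), 0.05, 8, seed = 17)
  co <- generate_cohort(sc)
  df <- as.data.frame(co)
  for (fam in c("exponential", "weibull", "gengamma")) {
    mine <- fit_quiet(co, fam)
    dist <- switch(fam, exponential = "exp", weibull = "weibull", gengamma = "gengamma")
    ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = df, dist = dist)
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-6)
  }
  mine <- fit_quiet(co, "gengamma")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = df,
                               dist = "gengamma")
  expect_equal(unname(c(mine$mu, mine$sigma, mine$kappa)),
               unname(ref$res[, "est"]), tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(mine$cov))), unname(ref$res[, "se"]), tolerance = 1e-2)
})

test_that("parameters are recovered within 3 SEs under a Weibull truth", {
  mu <- 1.2; sigma <- 0.7
  horizon <- quantile_gengamma(0.7, mu, sigma, 1)  # ~30% administrative censoring
  co <- generate_cohort(cohort_scenario(2000, "weibull", c(mu, sigma), 0,
                                        horizon, seed = 77))
  fit <- fit_parametric(co, "weibull")
  expect_lt(abs(fit$mu - mu), 3 * sqrt(fit$cov["mu", "mu"]))
  expect_lt(abs(fit$sigma - sigma), 3 * sqrt(fit$cov["sigma", "sigma"]))
})

test_that("parametric risk curves are valid and vanish at t -> 0+", {
  co <- generate_cohort(cohort_scenario(400, "weibull", c(1.2, 0.8), 0.05, 8,
                                        seed = 5))
  fit <- fit_parametric(co, "weibull")
  cv <- parametric_risk_curve(fit, c(1e-8, 0.5, 1, 2, 4, 8))
  expect_lt(cv$risk[1], 1e-6)
  expect_true(all(diff(cv$risk) > 0))
  expect_true(all(cv$se >= 0))
  expect_equal(cv$cl_upper - cv$cl_lower, 2 * qnorm(0.975) * cv$se, tolerance = 1e-12)
  expect_error(parametric_risk_curve(fit, c(0, 1)), "positive")
})

test_that("non-converged fits are refused unless forced", {
  co <- generate_cohort(cohort_scenario(200, "weibull", c(1, 1), 0, 8, seed = 2))
  fit <- fit_parametric(co, "weibull")
  fit$converged <- FALSE
  expect_error(parametric_risk_curve(fit, 2), "force")
  expect_s3_class(parametric_risk_curve(fit, 2, force = TRUE), "risk_curve")
})

test_that("nested families have ordered log-likelihoods", {
  for (seed in c(1, 8, 23)) {
    co <- generate_cohort(cohort_scenario(300, "gengamma", c(1.5, 1.1, -0.4),
                                          0.05, 9, seed = seed))
    ll <- suppressWarnings(nested_loglik_check(co))
    expect_lte(ll[["exponential"]], ll[["weibull"]] + 1e-4)
    expect_lte(ll[["weibull"]], ll[["gengamma"]] + 1e-4)
  }
})

test_that("misspecification margin over the exponential grows with n", {
  # heavy left-skewed gengamma truth: the gengamma fit beats the exponential
  # by a gap growing roughly linearly in n
  gaps <- vapply(c(500, 2000, 8000), function(n) {
    co <- generate_cohort(cohort_scenario(n, "gengamma", c(1, 0.9, -0.8),
                                          0, 50, seed = 13))
    ll <- suppressWarnings(nested_loglik_check(co))
    ll[["gengamma"]] - ll[["exponential"]]
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[1], 0)
})
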