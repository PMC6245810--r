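test_that("ghost weighting is the documented uniform weight increment", {
  co <- random_cohort(40, seed = 1)
  n <- co$n_nominal
  expect_identical(apply_ghost_weights(co, 0)$weight, co$weight)
  expect_equal(apply_ghost_weights(co, n)$weight, rep(2, n))  # sample doubled
  expect_error(apply_ghost_weights(co, -1), "non-negative")
  expect_error(apply_ghost_weights(co, 2.5), "integer")
  nonuni <- random_cohort(10, seed = 2, fractional_weights = TRUE)
  expect_error(apply_ghost_weights(nonuni, 1), "uniform")
})

test_that("ghost weighting never perturbs the risk curve, only its precision", {
  co <- random_cohort(60, seed = 3)
  cv <- nelson_aalen_curve(co)
  cv3 <- nelson_aalen_curve(apply_ghost_weights(co, 3 * co$n_nominal))
  expect_equal(cv3$risk, cv$risk, tolerance = 1e-13)
  expect_equal(cv3$times, cv$times)
  # m = 3N quadruples the effective size: all CL widths exactly halved
  expect_equal(cv3$cl_upper - cv3$cl_lower, (cv$cl_upper - cv$cl_lower) / 2,
               tolerance = 1e-12)
})

test_that("closed-form ghost counts handle boundaries by predicate evaluation", {
  expect_equal(closed_form_ghosts(0.048, 0.042, 1164), 357)
  # exact equality at M = 300 must not stop the strict search
  expect_equal(closed_form_ghosts(0.10, 0.05, 100), 301)
  expect_equal(closed_form_ghosts(0.05, 0.10, 1164), 0)
  expect_equal(closed_form_ghosts(0.048, 0.023, 1164), 3906)
  expect_error(closed_form_ghosts(-1, 0.1, 10), "positive")
  expect_error(closed_form_ghosts(0.1, 0, 10), "positive")
  expect_error(closed_form_ghosts(0.1, 0.05, 2.5), "integer")
})

test_that("stepwise search and closed form agree, including equality boundaries", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(20:2000, 1)
    w0 <- runif(1, 0.01, 0.2)
    tgt <- w0 * runif(1, 0.4, 1.4)
    expect_identical(ghost_search_stepwise(w0, tgt, n),
                     closed_form_ghosts(w0, tgt, n))
  }
  for (m_b in c(0, 1, 7, 300)) {
    w0 <- 0.08
    n <- 250
    tgt <- ghost_scaled_width(w0, m_b, n)  # equality exactly at m_b
    expect_identical(ghost_search_stepwise(w0, tgt, n),
                     closed_form_ghosts(w0, tgt, n))
  }
  expect_error(ghost_search_stepwise(0.1, 1e-9, 100, max_m = 1e4), "ceiling")
})

test_that("find_ghosts returns the minimal strict-undercut count", {
  co <- random_cohort(80, seed = 6)
  cv <- nelson_aalen_curve(co)
  t0 <- cv$times[ceiling(length(cv$times) * 0.6)]
  width0 <- cl_width(cv, t0)

  gr <- find_ghosts(co, target_width = width0 * 0.8, eval_time = t0)
  expect_lt(gr$achieved_width, gr$target_width)               # success is strict
  expect_gte(ghost_scaled_width(gr$width0, gr$m - 1, gr$n_nominal),
             gr$target_width)                                 # minimality
  expect_equal(gr$weight, 1 + gr$m / gr$n_nominal)
  # exactness of scaling: no re-estimation drift
  expect_equal(gr$achieved_width * sqrt(1 + gr$m / gr$n_nominal), gr$width0,
               tolerance = 1e-14)

  # already-efficient target
  expect_equal(find_ghosts(co, width0 * 1.5, t0)$m, 0)
  expect_error(find_ghosts(co, -0.1, t0), "positive")
  expect_error(find_ghosts(co, 0.05, min(cv$times) / 2), "no events")
})

test_that("the literal refit search matches the scaling-law search", {
  co <- random_cohort(30, seed = 9)
  cv <- nelson_aalen_curve(co)
  t0 <- stats::median(cv$times)
  tgt <- cl_width(cv, t0) * 0.9
  fast <- find_ghosts(co, tgt, t0, method = "scaling", trajectory = TRUE)
  slow <- find_ghosts(co, tgt, t0, method = "refit", trajectory = TRUE)
  expect_identical(slow$m, fast$m)
  expect_equal(slow$achieved_width, fast$achieved_width, tolerance = 1e-12)
  expect_equal(slow$trajectory$width, fast$trajectory$width, tolerance = 1e-12)
  expect_equal(nrow(fast$trajectory), fast$m + 1)
  expect_true(all(diff(fast$trajectory$width) < 0))
})

test_that("ghost counts are monotone in target, baseline width, and N", {
  tgts <- seq(0.02, 0.09, by = 0.005)
  ms <- vapply(tgts, function(tg) closed_form_ghosts(0.08, tg, 500), numeric(1))
  expect_true(all(diff(ms) <= 0))  # non-increasing in target width

  w0s <- seq(0.03, 0.12, by = 0.005)
  ms <- vapply(w0s, function(w0) closed_form_ghosts(w0, 0.03, 500), numeric(1))
  expect_true(all(diff(ms) >= 0))  # non-decreasing in baseline width

  ns <- c(100, 500, 1164, 5000)
  ms <- vapply(ns, function(n) closed_form_ghosts(0.08, 0.05, n), numeric(1))
  expect_true(all(diff(ms) >= 0))  # non-decreasing in N at fixed width ratio

  # effective-sample-size reading: (N + M)/N ~ (width0 / target)^2
  m <- closed_form_ghosts(0.08, 0.05, 1164)
  expect_lt(abs((1164 + m) / 1164 - (0.08 / 0.05)^2), (1 + 1) / 1164)
})
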