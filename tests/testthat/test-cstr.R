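test_that("cstr_model obeys its closed-form limits", {
  p <- cstr_params(0.02, 0.3, 0.004)
  expect_equal(cstr_model(0, p), 0.02)
  expect_equal(cstr_model(1e9, p), 0.32, tolerance = 1e-12)
  flat <- cstr_params(0.07, 0.3, 0)
  tt <- c(0, 10, 500, 1e5)
  expect_equal(cstr_model(tt, flat), rep(0.07, 4))
  expect_error(cstr_model(-1, p), "negative time")
  expect_error(cstr_params(0.5, 0.7, 0.01), "m_initial \\+ m_max")
  expect_error(cstr_params(0.1, 0.1, -1), "D")
})

test_that("fit_cstr recovers noiseless parameters on the experimental grid", {
  truth <- cstr_params(0.01, 0.30, 0.005)
  fit <- fit_cstr(paper_times, cstr_model(paper_times, truth))
  expect_equal(fit$params$m_initial, 0.01, tolerance = 1e-6)
  expect_equal(fit$params$m_max, 0.30, tolerance = 1e-6)
  expect_equal(fit$params$D, 0.005, tolerance = 1e-6 * 0.005)
  expect_false(fit$degenerate)
  expect_true(fit$converged)
})

test_that("fit_cstr recovers arbitrary noiseless parameter sets (exactness limit)", {
  set.seed(3)
  for (i in 1:8) {
    m0 <- runif(1, 0, 0.1)
    mm <- runif(1, 0.05, 0.5)
    D <- 10^runif(1, -3.5, -1.5)
    truth <- cstr_params(m0, mm, D)
    fit <- fit_cstr(paper_times, cstr_model(paper_times, truth))
    expect_lt(abs(fit$params$D - D) / D, 1e-5)
    expect_lt(abs(fit$params$m_max - mm), 1e-5)
  }
})

test_that("fit_cstr flags constant data as degenerate with D = 0", {
  fit <- fit_cstr(paper_times, rep(0.02, 7))
  expect_true(fit$degenerate)
  expect_equal(fit$params$D, 0)
  expect_equal(fit$params$m_initial, 0.02)
})

test_that("fit_cstr is invariant to observation order and rejects short series", {
  truth <- cstr_params(0.01, 0.25, 0.008)
  y <- cstr_model(paper_times, truth) + c(0.003, -0.002, 0.001, 0, -0.001,
                                          0.002, -0.003)
  f1 <- fit_cstr(paper_times, y)
  ord <- c(4, 1, 7, 2, 6, 3, 5)
  f2 <- fit_cstr(paper_times[ord], y[ord])
  expect_equal(f1$params$D, f2$params$D, tolerance = 1e-9)
  expect_equal(f1$ssr, f2$ssr, tolerance = 1e-12)
  expect_error(fit_cstr(c(0, 10, 60), c(0, 0.1, 0.2)), "4 distinct")
})

test_that("monte_carlo_fit is deterministic and collapses without noise", {
  truth <- cstr_params(0.01, 0.30, 0.005)
  set.seed(21)
  d <- make_cstr_data(truth, sd = 0.01)
  m1 <- monte_carlo_fit(d$time_s, d$value, n_draws = 50, seed = 7)
  m2 <- monte_carlo_fit(d$time_s, d$value, n_draws = 50, seed = 7)
  expect_identical(m1$D_draws, m2$D_draws)
  # zero bootstrap noise: every draw refits the same data
  m0 <- monte_carlo_fit(d$time_s, d$value, n_draws = 20, seed = 7, sd = 0)
  expect_equal(diff(range(m0$D_draws)), 0, tolerance = 1e-12)
  expect_error(monte_carlo_fit(d$time_s, d$value, n_draws = 0), "n_draws")
})

test_that("monte_carlo_fit recovers the dilution rate and tightens with less noise", {
  truth <- cstr_params(0.01, 0.30, 0.005)
  set.seed(31)
  noisy <- make_cstr_data(truth, sd = 0.01)
  quiet <- make_cstr_data(truth, sd = 0.003)
  mc_noisy <- monte_carlo_fit(noisy$time_s, noisy$value, n_draws = 200,
                              seed = 13)
  mc_quiet <- monte_carlo_fit(quiet$time_s, quiet$value, n_draws = 200,
                              seed = 13)
  expect_lt(abs(mean(mc_noisy$D_draws) - 0.005) / 0.005, 0.20)
  expect_lt(abs(mean(mc_quiet$D_draws) - 0.005) / 0.005, 0.20)
  expect_lt(sd(mc_quiet$D_draws), sd(mc_noisy$D_draws))
})
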