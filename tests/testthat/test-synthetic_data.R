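# Generator: determinism, degenerate variances, lognormal moments, realized
# correlation structure, and the closed-form naive split-half expectation.

test_that("simulation is deterministic under params and differs across seeds", {
  p <- tiny_params(seed = 21)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth$subj_speed, s2$truth$subj_speed)
  s3 <- simulate_dataset(tiny_params(seed = 22))
  expect_false(identical(s1$trials$latency_ms, s3$trials$latency_ms))
})

test_that("degenerate variances collapse latencies as the model implies", {
  p <- tiny_params(sd_subj = 0, sigma = 0, sd_item = 0, seed = 23)
  sim <- simulate_dataset(p)
  correct <- sim$trials[sim$trials$response_class == "correct", ]
  for (s in 1:2) {
    lat <- correct$latency_ms[correct$session == s]
    expect_equal(max(lat) - min(lat), 0, tolerance = 1e-9)
    expect_equal(lat[1], exp(p$mu[s]), tolerance = 1e-9)
  }
})

test_that("mean latency matches the lognormal moment formula over seeds", {
  expected <- exp(6.75 + (0.15^2 + 0.3^2 + 0.1^2) / 2)
  means <- vapply(1:10, function(s) {
    sim <- simulate_dataset(generative_params(seed = 300 + s))
    mean(sim$trials$latency_ms[sim$trials$response_class == "correct"])
  }, numeric(1))
  expect_lt(abs(mean(means) / expected - 1), 0.02)
})

test_that("realized participant effects carry the requested correlations", {
  p <- generative_params(rho_subj = 0.77, rho_speed_acc = c(-0.4, -0.4),
                         seed = 25)
  sim <- simulate_dataset(p)
  b <- sim$truth$subj_speed; a <- sim$truth$subj_acc
  # sampling SD of r at n = 50 is about (1 - rho^2)/7; allow 3 SD
  expect_lt(abs(cor(b[, 1], b[, 2]) - 0.77), 3 * (1 - 0.77^2) / 7)
  expect_lt(abs(cor(b[, 1], a[, 1]) - (-0.4)), 3 * (1 - 0.16) / 7)
  # accuracy is near ceiling under the default 3 log-odds intercept
  acc <- mean(sim$trials$response_class == "correct")
  expect_gt(acc, 0.9)
  expect_lt(acc, 0.99)
})

test_that("an inconsistent correlation specification fails before sampling", {
  expect_error(
    generative_params(rho_subj = 0.95, rho_acc = -0.95, rho_speed_acc = 0.9),
    "positive semi-definite")
  expect_error(generative_params(rho_subj = 1.4), "correlations")
  expect_error(generative_params(sd_subj = -1), "SDs")
})

test_that("expected naive split correlation: limits, attenuation, MC oracle", {
  p <- generative_params(sd_subj = 0.15, sigma = 0.3, rho_subj = 0.8)
  # no trial noise: within-condition halves correlate perfectly,
  # between-condition halves at exactly rho
  p0 <- generative_params(sd_subj = 0.15, sigma = 0, rho_subj = 0.8)
  expect_equal(expected_naive_split_correlation(p0, 75, "within"), 1)
  expect_equal(expected_naive_split_correlation(p0, 75, "between"), 0.8)
  # attenuation is strict with noise, increasing in m, with the right limit
  r75 <- expected_naive_split_correlation(p, 75, "between")
  expect_lt(r75, 0.8)
  ms <- c(2, 5, 20, 75, 300, 5000)
  vals <- vapply(ms, expected_naive_split_correlation, numeric(1),
                 params = p, scheme = "within")
  expect_true(all(diff(vals) > 0))
  expect_equal(vals[length(vals)], 1, tolerance = 1e-3)
  expect_error(expected_naive_split_correlation(p, 1), ">= 2")

  # Monte-Carlo oracle: direct simulation of per-participant half means
  # (no item variance, matching the formula's common-item assumption)
  m <- 75; n_p <- 50
  set.seed(404)
  mc <- replicate(200, {
    b <- rnorm(n_p, 0, 0.15)
    h1 <- b + rnorm(n_p, 0, 0.3 / sqrt(m))
    h2 <- b + rnorm(n_p, 0, 0.3 / sqrt(m))
    cor(h1, h2)
  })
  expect_lt(abs(mean(mc) - expected_naive_split_correlation(p, m, "within")),
            0.02)
})
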