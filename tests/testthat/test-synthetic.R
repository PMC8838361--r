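test_that("degenerate generator settings produce the expected structure", {
  # no randomness in either part: identical amounts, identical probabilities
  spec <- generator_spec(n_persons = 5, beta_prob = c(0.5, 0, 0, 0),
                         beta_amt = c(4, 0, 0, 0), lambda = 1,
                         sigma_u1 = 0, sigma_u2 = 0, sigma_e = 0)
  sim <- generate_recalls(spec, seed = 3)
  amts <- sim$dataset$amount[sim$dataset$amount > 0]
  expect_true(all(abs(amts - amts[1]) < 1e-12))
  expect_equal(bc_inverse(4, 1), amts[1])  # inverse of lambda = 1 transform
  expect_equal(length(unique(sim$truth$T_i)), 1)

  # saturated probability intercept: no zero-intake days
  spec2 <- generator_spec(n_persons = 50, beta_prob = c(50, 0, 0, 0))
  sim2 <- generate_recalls(spec2, seed = 4)
  expect_equal(describe_component(sim2$dataset, "energy")$pct_zero, 0)
})

test_that("generation is bit-reproducible under a fixed seed", {
  spec <- generator_spec(n_persons = 30)
  a <- generate_recalls(spec, seed = 99)
  b <- generate_recalls(spec, seed = 99)
  expect_identical(a$dataset$amount, b$dataset$amount)
  expect_identical(a$truth$T_i, b$truth$T_i)
})

test_that("heavy Box-Cox support truncation is rejected as a spec error", {
  # lambda = 1, eta = 0.5, sigma_e = 2: ~23% of draws below the boundary
  spec <- generator_spec(n_persons = 50, beta_prob = c(50, 0, 0, 0),
                         beta_amt = c(0.5, 0, 0, 0), lambda = 1,
                         sigma_u1 = 0, sigma_u2 = 0.1, sigma_e = 2)
  expect_error(generate_recalls(spec, seed = 5),
               class = "generator_spec_error")
})

test_that("analytic usual intake matches closed forms and brute force", {
  # log scale: E[amount | u2] = exp(x'b + u2 + sigma_e^2/2)
  spec <- generator_spec(n_persons = 1, beta_prob = c(50, 0, 0, 0),
                         beta_amt = c(5, -0.2, -0.03, 0.08), lambda = 0,
                         sigma_u1 = 0, sigma_u2 = 0.3, sigma_e = 0.4)
  u2 <- 0.25
  T_quad <- analytic_usual_intake(spec, 0, u2, "female", 50)
  eta <- function(we) sum(c(5, -0.2, -0.03, 0.08) * c(1, 1, 1, we)) + u2
  T_closed <- exp(0.4^2 / 2) * (5 / 7 * exp(eta(0)) + 2 / 7 * exp(eta(1)))
  expect_lt(abs(T_quad / T_closed - 1), 0.001)

  # no residual noise, identity-like transform: T = p * (eta + 1)
  spec2 <- generator_spec(n_persons = 1, beta_prob = c(0.7, 0, 0, 0),
                          beta_amt = c(4, 0, 0, 0), lambda = 1,
                          sigma_u1 = 0.5, sigma_u2 = 0.2, sigma_e = 0)
  u1 <- 0.4; u2 <- -0.1
  T2 <- analytic_usual_intake(spec2, u1, u2, "male", 40)
  p <- 1 / (1 + exp(-(0.7 + u1)))
  expect_equal(T2, p * (4 + u2 + 1), tolerance = 1e-10)

  # brute force: empirical mean over ~4e4 simulated days approaches T_i
  spec3 <- generator_spec(n_persons = 1500, beta_prob = c(0.8, 0, 0, 0.2),
                          beta_amt = c(4.5, 0, 0, 0.05), sigma_u1 = 0.8,
                          sigma_u2 = 0.3, sigma_e = 0.5, rho = 0.5)
  sim <- generate_recalls(spec3, seed = 21)
  emp <- tapply(sim$dataset$amount, sim$dataset$person_id, mean)
  pooled <- mean(emp) / mean(sim$truth$T_i)
  expect_lt(abs(pooled - 1), 0.01)
})

test_that("per-person empirical means converge to the analytic truth", {
  spec <- generator_spec(n_persons = 100, n_seasons = 4, days_per_season = 25,
                         season_prob = rep(0, 4), season_amt = rep(0, 4))
  sim <- generate_recalls(spec, seed = 31)
  emp <- tapply(sim$dataset$amount, sim$dataset$person_id, mean)
  rel <- abs(as.numeric(emp) / sim$truth$T_i - 1)
  expect_lt(median(rel), 0.05)
  expect_gt(cor(as.numeric(emp), sim$truth$T_i), 0.95)
})

test_that("positive effect correlation induces a significant Spearman correlation", {
  sim <- sim_episodic(n = 750, seed = 17)
  p <- describe_component(sim$dataset, "meats")
  expect_gt(p$spearman_r, 0)
  expect_lt(p$spearman_p, 0.05)
})

test_that("calibration recovers targets from a known spec (round trip)", {
  spec_true <- generator_spec(n_persons = 1200, beta_prob = c(1.2, 0, 0, 0.2),
                              beta_amt = c(4.6, -0.2, 0, 0.05),
                              sigma_u1 = 1, sigma_u2 = 0.45, sigma_e = 0.65,
                              component = "meats", unit = "g")
  targets <- describe_component(generate_recalls(spec_true, seed = 8)$dataset,
                                "meats")
  base <- generator_spec(n_persons = 400, beta_prob = c(0.5, 0, 0, 0.2),
                         beta_amt = c(4, -0.2, 0, 0.05), sigma_u1 = 1,
                         sigma_u2 = 0.3, sigma_e = 0.4,
                         component = "meats", unit = "g")
  cal <- calibrate_generator(list(mean = targets$mean,
                                  cv_percent = targets$cv_percent,
                                  variance_ratio = targets$variance_ratio,
                                  pct_zero = targets$pct_zero), base = base)
  ach <- attr(cal, "achieved")
  expect_lt(abs(ach$mean / targets$mean - 1), 0.02)
  expect_lt(abs(ach$cv - targets$cv_percent), 5)
  expect_lt(abs(ach$vr / targets$variance_ratio - 1), 0.20)
  expect_lt(abs(ach$pct_zero - targets$pct_zero), 3)
})

test_that("contradictory calibration targets fail with a best-found report", {
  base <- generator_spec(n_persons = 300)
  err <- tryCatch(
    calibrate_generator(list(mean = 100, cv_percent = 1, variance_ratio = 10,
                             pct_zero = 0), base = base, max_iter = 6),
    calibration_failure = function(e) e)
  expect_s3_class(err, "calibration_failure")
  expect_s3_class(err$best, "generator_spec")
})

test_that("generated zero-intake share tracks the calibrated target", {
  prof <- reference_profiles()
  bn <- prof[prof$component == "beans", ]
  base <- generator_spec(n_persons = 500, component = "beans", unit = "g",
                         beta_prob = c(1, 0, 0, 0.1),
                         beta_amt = c(3.5, -0.1, 0, 0.05),
                         sigma_u1 = 1, rho = 0.6, sigma_u2 = 0.5, sigma_e = 0.7)
  cal <- calibrate_generator(list(mean = bn$mean, cv_percent = bn$cv_percent,
                                  variance_ratio = bn$variance_ratio,
                                  pct_zero = bn$pct_zero), base = base)
  sim <- generate_recalls(cal, seed = 55)
  p <- describe_component(sim$dataset, "beans")
  expect_lt(abs(p$pct_zero - bn$pct_zero), 3)
})
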