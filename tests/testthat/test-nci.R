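test_that("variant selection follows the zero-share and correlation rules", {
  prof <- function(pct_zero, r = NA, p = NA) {
    structure(list(pct_zero = pct_zero, spearman_r = r, spearman_p = p),
              class = "component_profile")
  }
  # daily energy-like: amount model
  expect_equal(select_variant(prof(0.00)), "amount")
  expect_equal(select_variant(prof(4.99, r = 0.5, p = 0.001)), "amount")
  # episodic with significant prob-amount correlation: correlated
  expect_equal(select_variant(prof(26.57, r = 0.89, p = 0.001)), "correlated")
  # episodic without: uncorrelated
  expect_equal(select_variant(prof(41.82, r = 0.12, p = 0.4)), "uncorrelated")
  expect_equal(select_variant(prof(8.99, r = 0.30, p = 0.06)), "uncorrelated")
})

test_that("amount model recovers generator parameters from a 7-day run", {
  spec <- generator_spec(n_persons = 500, n_seasons = 1, days_per_season = 7,
                         beta_amt = c(7.3, -0.2, -0.05, 0.08),
                         sigma_u2 = 0.3, sigma_e = 0.5, lambda = 0)
  sim <- generate_recalls(spec, seed = 41)
  fit <- nci_fit(sim$dataset, "energy", variant = "amount")
  expect_true(fit$converged)
  expect_lt(abs(fit$lambda - 0), 0.2)
  expect_lt(abs(fit$sigma_u2 / 0.3 - 1), 0.15)
  expect_lt(abs(fit$sigma_e / 0.5 - 1), 0.15)
  # fixed effects on the log scale (lambda ~ 0, median pre-scaling shifts
  # only the intercept): slopes should match the generator
  expect_lt(abs(fit$beta2[["female"]] - (-0.2)), 0.08)
  expect_lt(abs(fit$beta2[["weekend"]] - 0.08), 0.05)
})

test_that("uncorrelated and correlated fits agree when the true correlation is zero", {
  sim <- sim_episodic(n = 200, seed = 19, rho = 0)
  w <- extract_window(sim$dataset, "winter")
  fu <- nci_fit(w, "meats", variant = "uncorrelated")
  fc <- nci_fit(w, "meats", variant = "correlated")
  expect_lt(abs(fc$rho), 0.35)
  # nested models: correlated likelihood can only improve, and by little
  expect_gte(fc$loglik, fu$loglik - 1e-3)
  expect_lt(fc$loglik - fu$loglik, qchisq(0.999, df = 1) / 2)
  expect_lt(abs(fc$sigma_u2 / fu$sigma_u2 - 1), 0.25)
})

test_that("degenerate inputs raise estimation errors", {
  ds <- toy_dataset(list(A = c(100, 120, 130)))
  expect_error(nci_fit(ds, "energy"), class = "estimation_error")
  ds0 <- toy_dataset(list(A = rep(0, 3), B = rep(0, 3)))
  expect_error(nci_fit(ds0, "energy", variant = "amount"),
               class = "estimation_error")
})

test_that("a variance-free fit yields a point-mass distribution", {
  fit <- manual_amount_fit(lambda = 0, beta2 = c(7, 0, 0, 0), sigma_u2 = 0,
                           sigma_e = 0)
  persons <- data.frame(person_id = c("a", "b"), sex = "male", age = 40)
  d <- nci_distribution(fit, persons, n_pseudo = 50, seed = 2)
  expect_equal(unname(d$percentiles[["p1"]]), unname(d$percentiles[["p99"]]))
  expect_equal(d$mean, unname(d$percentiles[["p50"]]))
  expect_equal(d$mean, exp(7))
})

test_that("log-scale distribution mean matches the log-normal closed form", {
  fit <- manual_amount_fit(lambda = 0, beta2 = c(5, -0.2, 0, 0.1),
                           sigma_u2 = 0.3, sigma_e = 0.4, scale = 2)
  persons <- data.frame(person_id = sprintf("p%d", 1:100),
                        sex = rep(c("male", "female"), 50), age = 40)
  d <- nci_distribution(fit, persons, n_pseudo = 200, seed = 7)  # 2e4 draws
  eta <- function(fem, we) sum(c(5, -0.2, 0, 0.1) * c(1, fem, 0, we))
  closed_person <- function(fem) {
    2 * exp(0.3^2 / 2 + 0.4^2 / 2) *
      (5 / 7 * exp(eta(fem, 0)) + 2 / 7 * exp(eta(fem, 1)))
  }
  closed <- mean(c(closed_person(0), closed_person(1)))
  expect_lt(abs(d$mean / closed - 1), 0.005)
})

test_that("individual predictions shrink toward the mean and preserve order", {
  # persons differing only in their observed 3-day level
  levels_ <- seq(800, 2600, length.out = 12)
  amounts <- lapply(levels_, function(l) l * c(0.95, 1, 1.05))
  names(amounts) <- sprintf("p%02d", seq_along(levels_))
  ds <- toy_dataset(amounts, days = 4:6)
  fit <- manual_amount_fit(lambda = 0, beta2 = c(log(1500), 0, 0, 0),
                           sigma_u2 = 0.25, sigma_e = 0.35)
  e <- nci_individual(fit, ds)
  e <- e$estimate[order(e$person_id)]
  expect_true(all(diff(e) > 0))          # monotone in the person mean
  t3 <- three_day_mean(ds, "energy")
  t3 <- t3$estimate[order(t3$person_id)]
  expect_lt(sd(e), sd(t3))               # shrinkage
  # low observations pulled up, high pulled down
  expect_gt(e[1], t3[1])
  expect_lt(e[12], t3[12])
})

test_that("quadrature individual predictions match a brute-force posterior mean", {
  sim <- sim_episodic(n = 120, seed = 23)
  w <- extract_window(sim$dataset, "summer")
  fit <- nci_fit(w, "meats", variant = "correlated")
  est <- nci_individual(fit, w)

  dfw <- as.data.frame(w)
  set.seed(505)
  pids <- sort(unique(dfw$person_id))[1:20]
  n_mc <- 2e5
  z1 <- rnorm(n_mc); z2 <- rnorm(n_mc)
  u1 <- fit$sigma_u1 * z1
  u2 <- fit$sigma_u2 * (fit$rho * z1 + sqrt(1 - fit$rho^2) * z2)
  for (p in pids) {
    d <- dfw[dfw$person_id == p, ]
    X <- cbind(1, d$sex == "female", (d$age - fit$age_center) / fit$age_scale,
               d$is_weekend)
    eta1 <- drop(X %*% fit$beta1)
    eta2 <- drop(X %*% fit$beta2)
    ll <- rep(0, n_mc)
    for (j in seq_len(nrow(d))) {
      lp <- eta1[j] + u1
      ll <- ll + (d$amount[j] > 0) * lp - log1p(exp(lp))
      if (d$amount[j] > 0) {
        yt <- bc_transform(d$amount[j] / fit$scale, fit$lambda)
        ll <- ll + dnorm(yt, eta2[j] + u2, fit$sigma_e, log = TRUE)
      }
    }
    wgt <- exp(ll - max(ll)); wgt <- wgt / sum(wgt)
    Tv <- usualintake:::fit_usual_intake(fit, rep(d$sex[1], n_mc),
                                         rep(d$age[1], n_mc), u1, u2)
    bf <- sum(wgt * Tv)
    qd <- est$estimate[est$person_id == p]
    expect_lt(abs(qd / bf - 1), 0.01)
  }
})

test_that("distribution mean is stable in the number of pseudo-persons", {
  sim <- sim_daily(n = 150, seed = 11)
  w <- extract_window(sim$dataset, "winter")
  fit <- nci_fit(w, "energy")
  persons <- unique(as.data.frame(w)[, c("person_id", "sex", "age")])
  d1 <- nci_distribution(fit, persons, n_pseudo = 100, seed = 5)
  d2 <- nci_distribution(fit, persons, n_pseudo = 400, seed = 6)
  expect_lt(abs(d1$mean / d2$mean - 1), 0.02)
})

test_that("amount fit equals the two-part likelihood with part 1 saturated", {
  # zero-free data: the quadrature two-part likelihood evaluated with a
  # saturated probability part must reproduce the exact Gaussian mixed-model
  # likelihood of the amount fit (dual route: own quadrature vs lme4 ML)
  sim <- sim_daily(n = 80, seed = 29)
  w <- extract_window(sim$dataset, "spring")
  fa <- nci_fit(w, "energy", variant = "amount")
  df <- usualintake:::prep_model_frame(w, "energy")
  yt <- bc_transform(df$amount / fa$scale, fa$lambda)
  nl <- usualintake:::two_part_node_loglik(
    df, yt, beta1 = c(50, 0, 0, 0), beta2 = fa$beta2,
    su1 = 1e-3, su2 = fa$sigma_u2, rho = 0, se = fa$sigma_e, gh_nodes = 9)
  ll_quad <- sum(usualintake:::logsumexp_rows(nl$S, log(nl$w))) +
    usualintake:::bc_log_jacobian(df$amount / fa$scale, fa$lambda)
  expect_lt(abs(ll_quad - fa$loglik), 0.02 * abs(fa$loglik))
})
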