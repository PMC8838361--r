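# One-way unbalanced variance decomposition, method of moments.
mom_variance_components <- function(r, pid_int, n_persons) {
  n_i <- tabulate(pid_int, nbins = n_persons)
  used <- n_i > 0
  means <- rowsum(r, pid_int)[, 1] / pmax(n_i[n_i > 0], 1)
  # rowsum only returns groups present; realign
  full_means <- rep(NA_real_, n_persons)
  full_means[sort(unique(pid_int))] <- rowsum(r, pid_int)[, 1] /
    n_i[sort(unique(pid_int))]
  N <- length(r)
  k <- sum(used)
  ssw <- sum((r - full_means[pid_int])^2)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  grand <- mean(r)
  msb <- sum(n_i[used] * (full_means[used] - grand)^2) / max(k - 1, 1)
  n0 <- (N - sum(n_i[used]^2) / N) / max(k - 1, 1)
  var_between <- max((msb - msw) / max(n0, 1e-12), 0)
  list(sigma_w2 = msw, sigma_b2 = var_between, n_i = n_i,
       person_mean = full_means)
}

#' Fit the MSM-style usual intake model
#'
#' Two-part estimator in the style of the Multiple Source Method.  Part 1
#' fits a mixed-effects logistic regression to the daily consumption
#' indicators and converts it to a per-person consumption probability `p_i`
#' (posterior mean of the inverse-logit at the person's covariates,
#' weekday/weekend weighted 5/7 and 2/7); under the default
#' habitual-consumer assumption every `p_i` is positive, and a component with
#' no zero-intake days is treated as consumed daily (`p_i = 1`).  Part 2
#' transforms the consumption-day amounts to approximate normality with a
#' two-parameter Box-Cox transform chosen by a normality score, regresses the
#' transformed amounts on the covariates by OLS, splits the residual variance
#' into between- and within-person components by method of moments, and
#' shrinks each person's mean residual by the BLUP factor
#' `c_i = sigma_b^2 / (sigma_b^2 + sigma_w^2 / n_i)`.  The person's usual
#' consumption-day amount is the back-transform of (covariate prediction +
#' shrunken residual), bias-corrected by Gauss-Hermite integration over
#' Gaussian noise of variance `sigma_b^2 (1 - c_i) + sigma_w^2` (posterior
#' uncertainty of the person effect plus day-level noise), which reduces to
#' the log-normal closed form at `lambda = 0`.
#'
#' @param window A `recall_dataset`, typically from [extract_window()].
#' @param component Component name.
#' @param habitual Treat all persons as habitual consumers (the only
#'   implemented option; external consumption-probability input is a
#'   non-goal).
#' @param lambda_grid Grid of Box-Cox powers searched.
#' @param offset_frac Offsets searched, as fractions of the median positive
#'   amount.
#' @param gh_nodes Quadrature nodes for posterior probabilities and the
#'   back-transform bias correction.
#' @param shrink `"blup"` for `c_i`, `"sqrt"` for `sqrt(c_i)`.
#' @param min_consumers As in [nci_fit()].
#' @return An `msm_fit` object with a per-person table of probabilities,
#'   shrinkage factors and usual intakes.
#' @export
msm_fit <- function(window, component, habitual = TRUE,
                    lambda_grid = seq(-1, 1, by = 0.1),
                    offset_frac = c(0, 0.01, 0.05, 0.1, 0.25),
                    gh_nodes = 9, shrink = c("blup", "sqrt"),
                    min_consumers = 20) {
  shrink <- match.arg(shrink)
  if (!habitual) {
    stop_ui("only the habitual-consumer default is implemented",
            class = "config_error")
  }
  df <- prep_model_frame(window, component)
  if (all(df$amount == 0)) {
    stop_ui("all amounts are zero; nothing to fit", class = "estimation_error")
  }
  persons <- levels(df$pid)
  n_persons <- length(persons)
  pid_int <- as.integer(df$pid)
  person_female <- tapply(df$female, df$pid, function(v) v[[1]])
  person_age_std <- tapply(df$age_std, df$pid, function(v) v[[1]])
  gh <- gauss_hermite_normal(gh_nodes)

  # ---- part 1: per-person consumption probability ----
  any_zero <- any(df$ind == 0)
  if (!any_zero) {
    saturated <- TRUE
    beta1 <- NULL; su1 <- NA_real_
    p_i <- rep(1, n_persons)
  } else {
    saturated <- FALSE
    if (sum(tapply(df$ind, df$pid, max) > 0) < min_consumers) {
      stop_ui("fewer than %d persons with a positive amount; two-part fit unreliable",
              min_consumers, class = "estimation_error")
    }
    p1 <- suppressWarnings(suppressMessages(
      lme4::glmer(ind ~ female + age_std + weekend + (1 | pid), data = df,
                  family = stats::binomial(), nAGQ = gh_nodes)))
    beta1 <- lme4::fixef(p1)
    vc1 <- as.data.frame(lme4::VarCorr(p1))
    su1 <- sqrt(vc1$vcov[vc1$grp == "pid"])
    # posterior-mean probability: per person integrate over u1 | data
    Xd <- cbind(1, df$female, df$age_std, df$weekend)
    eta1 <- drop(Xd %*% beta1)
    Xw <- cbind(1, person_female, person_age_std, 0)
    Xe <- cbind(1, person_female, person_age_std, 1)
    eta_wd <- drop(Xw %*% beta1)
    eta_we <- drop(Xe %*% beta1)
    S <- matrix(0, n_persons, gh_nodes)
    P <- matrix(0, n_persons, gh_nodes)
    for (m in seq_len(gh_nodes)) {
      u <- su1 * gh$z[m]
      lp <- eta1 + u
      ll <- df$ind * lp - log1p(exp(-abs(lp))) - pmax(lp, 0)
      S[, m] <- rowsum(ll, pid_int)
      P[, m] <- WEEKDAY_WEIGHT * invlogit(eta_wd + u) +
        WEEKEND_WEIGHT * invlogit(eta_we + u)
    }
    lw <- sweep(S, 2, log(gh$w), "+")
    lw <- lw - apply(lw, 1, max)
    W <- exp(lw); W <- W / rowSums(W)
    p_i <- rowSums(W * P)
  }

  # ---- part 2: usual consumption-day amount ----
  pos <- df$ind > 0
  dpos <- df[pos, , drop = FALSE]
  med <- stats::median(dpos$amount)
  offsets <- unique(offset_frac) * med
  best <- list(score = -Inf)
  for (off in offsets) for (l in lambda_grid) {
    sc <- normality_score(bc_transform(dpos$amount, l, off))
    if (sc > best$score) best <- list(score = sc, lambda = l, offset = off)
  }
  if (!is.finite(best$score)) { best$lambda <- 1; best$offset <- 0 }
  lambda <- best$lambda; offset <- best$offset
  yt <- bc_transform(dpos$amount, lambda, offset)
  ols <- stats::lm(yt ~ female + age_std + weekend, data = dpos)
  beta2 <- stats::coef(ols)
  r <- stats::resid(ols)
  vc <- mom_variance_components(r, pid_int[pos], n_persons)
  sigma_w2 <- vc$sigma_w2
  sigma_b2 <- vc$sigma_b2
  n_i <- vc$n_i
  rbar <- ifelse(n_i > 0, vc$person_mean, 0)
  c_i <- ifelse(n_i > 0,
                if (sigma_b2 + sigma_w2 <= 0) 0
                else sigma_b2 / (sigma_b2 + sigma_w2 / pmax(n_i, 1)),
                0)
  if (shrink == "sqrt") c_i <- sqrt(c_i)
  rtilde <- rbar * c_i

  Xw <- cbind(1, person_female, person_age_std, 0)
  Xe <- cbind(1, person_female, person_age_std, 1)
  pred <- WEEKDAY_WEIGHT * drop(Xw %*% beta2) + WEEKEND_WEIGHT * drop(Xe %*% beta2)
  v_i <- sigma_b2 * (1 - c_i) + sigma_w2
  a_i <- numeric(n_persons)
  for (m in seq_len(gh_nodes)) {
    y <- pred + rtilde + sqrt(v_i) * gh$z[m]
    a_i <- a_i + gh$w[m] * bc_inverse(y, lambda, offset) * bc_in_support(y, lambda)
  }
  e_i <- p_i * a_i

  out <- list(component = component, season = attr(df, "season"),
              saturated = saturated, beta1 = beta1, sigma_u1 = su1,
              lambda = lambda, offset = offset, beta2 = beta2,
              sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
              normality_score = best$score,
              shrink = shrink,
              n_zero_amount_persons = sum(n_i == 0),
              persons = data.frame(person_id = persons, n_i = n_i, p_i = p_i,
                                   rbar = rbar, c_i = c_i, a_i = a_i,
                                   e_i = e_i, stringsAsFactors = FALSE),
              age_center = attr(df, "age_center"),
              age_scale = attr(df, "age_scale"))
  class(out) <- "msm_fit"
  out
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("MSM-style fit for '%s'%s\n", x$component,
              if (!is.na(x$season)) paste0(", season ", x$season) else ""))
  cat(sprintf("  transform: lambda %.2f, offset %.3g (normality score %.4f)\n",
              x$lambda, x$offset, x$normality_score))
  cat(sprintf("  sigma_b^2 %.4f, sigma_w^2 %.4f, part 1 %s\n", x$sigma_b2,
              x$sigma_w2, if (x$saturated) "saturated (daily)" else "logistic mixed"))
  invisible(x)
}

#' Individual usual intakes from an MSM-style fit
#'
#' `e_i = p_i * a_i`: per-person consumption probability times usual
#' consumption-day amount.  No further estimation step is needed; the group
#' distribution is taken directly from these values.
#'
#' @param fit An `msm_fit`.
#' @return An `individual_estimates` data frame.
#' @export
msm_individual <- function(fit) {
  individual_estimates(fit$persons$person_id, fit$persons$e_i,
                       method = "MSM", component = fit$component,
                       season = fit$season)
}

#' Group usual intake distribution from individual estimates
#'
#' Mean and 1st-99th percentiles of the individual usual intake estimates,
#' under the package-wide quantile convention.
#'
#' @param est An `individual_estimates` data frame (at least 2 persons).
#' @return A `usual_intake_distribution`.
#' @export
group_distribution <- function(est) {
  if (nrow(est) < 2) {
    stop_ui("need at least 2 persons for a group distribution",
            class = "degenerate_error")
  }
  make_distribution(est$estimate, method = attr(est, "method"),
                    component = attr(est, "component"),
                    season = attr(est, "season"))
}
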