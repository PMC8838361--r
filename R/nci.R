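#' Choose the NCI model variant from a component profile
#'
#' Components consumed on (almost) every recall day - less than 5% zero
#' intake days - use the amount-only model.  Episodic components use the
#' two-part model: correlated random effects when the Spearman correlation
#' between consumption probability and consumption-day amount is significant
#' at `alpha`, uncorrelated otherwise.
#'
#' @param profile A [describe_component()] result for the fitting dataset.
#' @param alpha Significance level of the Spearman test.
#' @return One of `"amount"`, `"correlated"`, `"uncorrelated"`.
#' @export
select_variant <- function(profile, alpha = 0.05) {
  if (profile$pct_zero < 5) return("amount")
  if (is.finite(profile$spearman_p) && profile$spearman_p < alpha) "correlated"
  else "uncorrelated"
}

# Common per-day model frame: consumption indicator, amount, covariates with
# age standardised to the sample.
prep_model_frame <- function(ds, component) {
  x <- ds[ds$component == component, , drop = FALSE]
  if (!nrow(x)) stop_ui("component '%s' not in dataset", component, class = "lookup_error")
  persons <- unique(x$person_id)
  if (length(persons) < 2) {
    stop_ui("variance components are unidentifiable from a single person",
            class = "estimation_error")
  }
  age_tab <- tapply(x$age, x$person_id, function(a) a[[1]])
  age_center <- mean(age_tab)
  age_scale <- stats::sd(age_tab)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1
  df <- data.frame(
    pid = factor(x$person_id),
    ind = as.numeric(x$amount > 0),
    amount = x$amount,
    female = as.numeric(x$sex == "female"),
    age_std = (x$age - age_center) / age_scale,
    weekend = as.numeric(x$is_weekend)
  )
  attr(df, "age_center") <- age_center
  attr(df, "age_scale") <- age_scale
  attr(df, "season") <- if (length(unique(x$season)) == 1) x$season[[1]] else NA_character_
  df
}

# Profile log-likelihood of lambda for a Box-Cox linear mixed model on
# (possibly pre-scaled) amounts: exact Gaussian ML via lme4, plus the
# transform's log-Jacobian.
profile_lambda_lmm <- function(a_scaled, df, lambda_grid, refine = TRUE) {
  fit_at <- function(lambda) {
    df$y <- bc_transform(a_scaled, lambda)
    fm <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ female + age_std + weekend + (1 | pid), data = df,
                 REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    list(fit = fm,
         ll = as.numeric(stats::logLik(fm)) + bc_log_jacobian(a_scaled, lambda))
  }
  lls <- vapply(lambda_grid, function(l) fit_at(l)$ll, numeric(1))
  best <- lambda_grid[which.max(lls)]
  if (refine) {
    step <- if (length(lambda_grid) > 1) diff(lambda_grid)[1] else 0.1
    lo <- best - step; hi <- best + step
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- fit_at(x1)$ll; f2 <- fit_at(x2)$ll
    while (hi - lo > 0.01) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- fit_at(x2)$ll
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- fit_at(x1)$ll
      }
    }
    best <- (lo + hi) / 2
  }
  res <- fit_at(best)
  vc <- as.data.frame(lme4::VarCorr(res$fit))
  list(lambda = best,
       beta = lme4::fixef(res$fit),
       sigma_u = sqrt(vc$vcov[vc$grp == "pid"]),
       sigma_e = stats::sigma(res$fit),
       loglik = res$ll)
}

# Per-person log-likelihood contributions of the two-part model on a grid of
# standardised random-effect node pairs.  Returns a persons x (Q*Q) matrix
# S with S[i, m] = log f(data_i | u1_m, u2_m), plus the node values.
two_part_node_loglik <- function(df, yt, beta1, beta2, su1, su2, rho, se,
                                 gh_nodes = 9) {
  gh <- gauss_hermite_normal(gh_nodes)
  grid <- expand.grid(j = seq_len(gh_nodes), k = seq_len(gh_nodes))
  z1 <- gh$z[grid$j]; z2 <- gh$z[grid$k]
  w <- gh$w[grid$j] * gh$w[grid$k]
  u1 <- su1 * z1
  u2 <- su2 * (rho * z1 + sqrt(max(1 - rho^2, 0)) * z2)

  X <- cbind(1, df$female, df$age_std, df$weekend)
  eta1 <- drop(X %*% beta1)
  eta2 <- drop(X %*% beta2)
  pos <- df$ind > 0
  pid_int <- as.integer(df$pid)
  n_persons <- nlevels(df$pid)

  S <- matrix(0, n_persons, length(w))
  for (m in seq_along(w)) {
    lp <- eta1 + u1[m]
    # stable Bernoulli log-likelihood: y*lp - log(1 + exp(lp))
    ll_day <- df$ind * lp - log1p(exp(-abs(lp))) - pmax(lp, 0)
    if (any(pos)) {
      ll_day[pos] <- ll_day[pos] +
        stats::dnorm(yt[pos], eta2[pos] + u2[m], se, log = TRUE)
    }
    S[, m] <- rowsum(ll_day, pid_int)
  }
  list(S = S, w = w, u1 = u1, u2 = u2)
}

logsumexp_rows <- function(S, logw) {
  M <- apply(S, 1, max)
  M + log(rowSums(exp(sweep(S, 2, logw, "+") - M)))
}

#' Fit the NCI-style usual intake model
#'
#' Fits the selected variant of the two-part nonlinear mixed-effects model to
#' a short recall window.  Amounts are pre-scaled so the positive-amount
#' median is 1, then Box-Cox transformed; the power `lambda` is profiled on a
#' grid and refined by golden-section search on the marginal likelihood
#' (including the transform Jacobian).  The amount part is a linear mixed
#' model on the transformed scale; the probability part a mixed-effects
#' logistic regression; in the correlated variant the two person-level random
#' effects are estimated jointly by maximising the Gauss-Hermite-quadrature
#' marginal likelihood.
#'
#' @param window A `recall_dataset`, typically from [extract_window()].
#' @param component Component name.
#' @param variant `"amount"`, `"uncorrelated"`, `"correlated"`, or `NULL` to
#'   choose by [select_variant()] on the window's profile.
#' @param alpha Significance level used when `variant` is chosen
#'   automatically.
#' @param lambda_grid Grid of Box-Cox powers profiled.
#' @param gh_nodes Quadrature nodes per random-effect dimension.
#' @param min_consumers Minimum persons with at least one positive amount for
#'   the two-part variants.
#' @return An `nci_fit` object: transform, fixed effects, variance
#'   components, correlation, log-likelihood and a convergence flag.
#' @export
nci_fit <- function(window, component, variant = NULL, alpha = 0.05,
                    lambda_grid = seq(-1, 1, by = 0.1), gh_nodes = 9,
                    min_consumers = 20) {
  df <- prep_model_frame(window, component)
  if (is.null(variant)) {
    variant <- select_variant(describe_component(window, component), alpha)
  }
  variant <- match.arg(variant, c("amount", "uncorrelated", "correlated"))
  if (all(df$amount == 0)) {
    stop_ui("all amounts are zero; nothing to fit", class = "estimation_error")
  }
  converged <- TRUE
  notes <- character()

  if (variant == "amount") {
    a <- df$amount
    n_zero <- sum(a == 0)
    if (n_zero > 0) {
      # near-daily component: occasional zeros are floored at half the
      # smallest positive amount so the transform is defined
      a[a == 0] <- min(a[a > 0]) / 2
      notes <- c(notes, sprintf("%d zero amounts floored for transform", n_zero))
    }
    scale <- stats::median(a)
    pf <- profile_lambda_lmm(a / scale, df, lambda_grid)
    out <- list(variant = variant, component = component,
                season = attr(df, "season"),
                lambda = pf$lambda, scale = scale,
                beta1 = NULL, sigma_u1 = NA_real_, rho = NA_real_,
                beta2 = pf$beta, sigma_u2 = pf$sigma_u, sigma_e = pf$sigma_e,
                loglik = pf$loglik, converged = converged, notes = notes,
                age_center = attr(df, "age_center"),
                age_scale = attr(df, "age_scale"),
                n_persons = nlevels(df$pid), gh_nodes = gh_nodes)
    class(out) <- "nci_fit"
    return(out)
  }

  # two-part variants
  consumers <- tapply(df$ind, df$pid, max)
  if (sum(consumers > 0) < min_consumers) {
    stop_ui("only %d persons with a positive amount (< %d); two-part fit unreliable",
            sum(consumers > 0), min_consumers, class = "estimation_error")
  }
  p1 <- suppressWarnings(suppressMessages(
    lme4::glmer(ind ~ female + age_std + weekend + (1 | pid), data = df,
                family = stats::binomial(), nAGQ = gh_nodes)))
  beta1 <- lme4::fixef(p1)
  vc1 <- as.data.frame(lme4::VarCorr(p1))
  su1 <- sqrt(vc1$vcov[vc1$grp == "pid"])
  ll1 <- as.numeric(stats::logLik(p1))

  pos <- df$ind > 0
  dpos <- droplevels(df[pos, , drop = FALSE])
  scale <- stats::median(dpos$amount)
  pf <- profile_lambda_lmm(dpos$amount / scale, dpos, lambda_grid)
  lambda <- pf$lambda
  yt <- rep(NA_real_, nrow(df))
  yt[pos] <- bc_transform(df$amount[pos] / scale, lambda)

  if (variant == "uncorrelated") {
    out <- list(variant = variant, component = component,
                season = attr(df, "season"),
                lambda = lambda, scale = scale,
                beta1 = beta1, sigma_u1 = su1, rho = 0,
                beta2 = pf$beta, sigma_u2 = pf$sigma_u, sigma_e = pf$sigma_e,
                loglik = ll1 + pf$loglik,
                converged = converged, notes = notes,
                age_center = attr(df, "age_center"),
                age_scale = attr(df, "age_scale"),
                n_persons = nlevels(df$pid), gh_nodes = gh_nodes)
    class(out) <- "nci_fit"
    return(out)
  }

  # correlated: joint ML over both parts at the profiled lambda
  jac <- bc_log_jacobian(df$amount[pos] / scale, lambda)
  theta0 <- c(beta1, pf$beta,
              log(max(su1, 1e-3)), log(max(pf$sigma_u, 1e-3)),
              log(max(pf$sigma_e, 1e-3)), 0)
  negll <- function(theta) {
    b1 <- theta[1:4]; b2 <- theta[5:8]
    su1_ <- exp(theta[9]); su2_ <- exp(theta[10]); se_ <- exp(theta[11])
    rho_ <- 0.99 * tanh(theta[12])  # keep the correlation off the boundary
    nl <- two_part_node_loglik(df, yt, b1, b2, su1_, su2_, rho_, se_,
                               gh_nodes = gh_nodes)
    -sum(logsumexp_rows(nl$S, log(nl$w)))
  }
  opt <- stats::nlminb(theta0, negll,
                       control = list(iter.max = 300, eval.max = 1000))
  if (opt$convergence != 0) {
    converged <- FALSE
    notes <- c(notes, paste("joint optimiser:", opt$message))
  }
  th <- opt$par
  out <- list(variant = variant, component = component,
              season = attr(df, "season"),
              lambda = lambda, scale = scale,
              beta1 = stats::setNames(th[1:4], names(beta1)),
              sigma_u1 = exp(th[9]), rho = 0.99 * tanh(th[12]),
              beta2 = stats::setNames(th[5:8], names(pf$beta)),
              sigma_u2 = exp(th[10]), sigma_e = exp(th[11]),
              loglik = -opt$objective + jac,
              converged = converged, notes = notes,
              age_center = attr(df, "age_center"),
              age_scale = attr(df, "age_scale"),
              n_persons = nlevels(df$pid), gh_nodes = gh_nodes)
  class(out) <- "nci_fit"
  out
}

#' @export
print.nci_fit <- function(x, ...) {
  cat(sprintf("NCI-style fit (%s variant) for '%s'%s\n", x$variant, x$component,
              if (!is.na(x$season)) paste0(", season ", x$season) else ""))
  cat(sprintf("  lambda %.2f, sigma_u2 %.3f, sigma_e %.3f", x$lambda,
              x$sigma_u2, x$sigma_e))
  if (!is.null(x$beta1)) cat(sprintf(", sigma_u1 %.3f, rho %.3f", x$sigma_u1, x$rho))
  cat(sprintf("\n  log-likelihood %.2f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

# Usual intake T for vectors of random effects and person covariates:
# weekday/weekend-weighted mean of p(consume) * E[amount | consume], the
# residual integrated by Gauss-Hermite with back-transform support
# truncation (out-of-support nodes contribute amount 0).
fit_usual_intake <- function(fit, sex, age, u1, u2, gh_nodes = NULL) {
  if (is.null(gh_nodes)) gh_nodes <- fit$gh_nodes
  gh <- gauss_hermite_normal(gh_nodes)
  w_day <- c(WEEKDAY_WEIGHT, WEEKEND_WEIGHT)
  out <- numeric(length(u2))
  for (k in 1:2) {
    X <- covariate_matrix(sex, age, rep(k == 2, length(sex)),
                          fit$age_center, fit$age_scale)
    p <- if (is.null(fit$beta1)) 1 else invlogit(drop(X %*% fit$beta1) + u1)
    eta2 <- drop(X %*% fit$beta2) + u2
    y <- outer(eta2, gh$z * fit$sigma_e, "+")
    a <- bc_inverse(y, fit$lambda) * bc_in_support(y, fit$lambda)
    ea <- fit$scale * drop(a %*% gh$w)
    out <- out + w_day[k] * p * ea
  }
  out
}

#' Model-implied usual intake distribution (Monte-Carlo pseudo-persons)
#'
#' Draws `n_pseudo` random-effect pairs per person from the fitted
#' distribution, converts each to a usual intake
#' (probability x expected consumption-day amount, weekday/weekend weighted
#' 5/7 and 2/7), and summarises the pooled draws by their mean and the
#' 1st-99th percentiles.
#'
#' @param fit An `nci_fit`.
#' @param persons Data frame of person covariates (`person_id`, `sex`,
#'   `age`), typically the unique persons of the fitting window.
#' @param n_pseudo Random-effect draws per person.
#' @param seed Integer seed.
#' @return A `usual_intake_distribution`.
#' @export
nci_distribution <- function(fit, persons, n_pseudo = 100, seed = 1) {
  set.seed(seed)
  n <- nrow(persons) * n_pseudo
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  su1 <- if (is.null(fit$beta1)) 0 else fit$sigma_u1
  rho <- if (is.null(fit$beta1)) 0 else fit$rho
  u1 <- su1 * z1
  u2 <- fit$sigma_u2 * (rho * z1 + sqrt(max(1 - rho^2, 0)) * z2)
  sex <- rep(persons$sex, each = n_pseudo)
  age <- rep(persons$age, each = n_pseudo)
  values <- fit_usual_intake(fit, sex, age, u1, u2)
  make_distribution(values, method = "NCI", component = fit$component,
                    season = fit$season, n = n, seed = seed)
}

#' Individual usual intake by conditional expectation (shrinkage)
#'
#' For each person in the window, computes
#' `e_i = E[T(u1, u2) | observed indicators and amounts]`, the posterior mean
#' of the model-implied usual intake given the person's short window of
#' recalls.  The posterior over the random effects is integrated by
#' Gauss-Hermite quadrature (exact conjugate-normal posterior in the
#' amount-only variant).
#'
#' @param fit An `nci_fit`.
#' @param window The `recall_dataset` the fit was computed on (or any window
#'   with the same component).
#' @param gh_nodes Quadrature nodes per dimension for the posterior
#'   integration (more than the fitting default, as this is cheap).
#' @return An `individual_estimates` data frame.
#' @export
nci_individual <- function(fit, window, gh_nodes = 15) {
  df <- prep_model_frame(window, fit$component)
  # covariates are standardised exactly as in the fit
  df$age_std <- (df$age_std * attr(df, "age_scale") + attr(df, "age_center") -
                   fit$age_center) / fit$age_scale
  persons <- levels(df$pid)
  X <- cbind(1, df$female, df$age_std, df$weekend)
  pid_int <- as.integer(df$pid)
  person_sex <- ifelse(tapply(df$female, df$pid, function(v) v[[1]]) > 0,
                       "female", "male")
  person_age <- tapply(df$age_std, df$pid, function(v) v[[1]]) * fit$age_scale +
    fit$age_center

  if (fit$variant == "amount") {
    a <- df$amount
    if (any(a == 0)) a[a == 0] <- min(a[a > 0]) / 2
    yt <- bc_transform(a / fit$scale, fit$lambda)
    resid <- yt - drop(X %*% fit$beta2)
    n_i <- tabulate(pid_int, nbins = length(persons))
    sum_r <- rowsum(resid, pid_int)[, 1]
    prec <- 1 / fit$sigma_u2^2 + n_i / fit$sigma_e^2
    post_mean <- (sum_r / fit$sigma_e^2) / prec
    post_sd <- sqrt(1 / prec)
    gh <- gauss_hermite_normal(gh_nodes)
    e <- numeric(length(persons))
    for (m in seq_len(gh_nodes)) {
      u2 <- post_mean + post_sd * gh$z[m]
      e <- e + gh$w[m] *
        fit_usual_intake(fit, person_sex, person_age, rep(0, length(u2)), u2)
    }
    return(individual_estimates(persons, e, method = "NCI",
                                component = fit$component, season = fit$season))
  }

  pos <- df$ind > 0
  yt <- rep(NA_real_, nrow(df))
  if (any(pos)) yt[pos] <- bc_transform(df$amount[pos] / fit$scale, fit$lambda)
  rho <- if (fit$variant == "uncorrelated") 0 else fit$rho
  nl <- two_part_node_loglik(df, yt, fit$beta1, fit$beta2, fit$sigma_u1,
                             fit$sigma_u2, rho, fit$sigma_e,
                             gh_nodes = gh_nodes)
  # posterior weights per person over the node grid
  lw <- sweep(nl$S, 2, log(nl$w), "+")
  lw <- lw - apply(lw, 1, max)
  W <- exp(lw)
  W <- W / rowSums(W)
  Tmat <- matrix(0, length(persons), length(nl$w))
  for (m in seq_along(nl$w)) {
    Tmat[, m] <- fit_usual_intake(fit, person_sex, person_age,
                                  rep(nl$u1[m], length(persons)),
                                  rep(nl$u2[m], length(persons)))
  }
  e <- rowSums(W * Tmat)
  individual_estimates(persons, e, method = "NCI",
                       component = fit$component, season = fit$season)
}

make_distribution <- function(values, method, component, season, n = length(values),
                              seed = NA_integer_) {
  stopifnot(length(values) >= 1)
  pct <- qtile(values, 1:99 / 100)
  structure(list(method = method, component = component, season = season,
                 mean = mean(values), percentiles = stats::setNames(pct, paste0("p", 1:99)),
                 n = n, seed = seed),
            class = "usual_intake_distribution")
}

#' @export
print.usual_intake_distribution <- function(x, ...) {
  cat(sprintf("Usual intake distribution (%s) for '%s'%s\n", x$method, x$component,
              if (!is.na(x$season)) paste0(", season ", x$season) else ""))
  show <- c(5, 10, 25, 50, 75, 90, 95)
  cat(sprintf("  mean %.2f\n", x$mean))
  print(round(x$percentiles[paste0("p", show)], 2))
  invisible(x)
}
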