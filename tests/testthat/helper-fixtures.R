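# Shared simulated fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Energy-like daily component: log-normal amounts, no zero days, VR ~ 1.4.
sim_daily <- function(n = 150, seed = 11) {
  cached(sprintf("daily_%d_%d", n, seed), {
    generate_recalls(generator_spec(n_persons = n), seed = seed)
  })
}

# Meats-like episodic component: ~27% zero days, positive prob-amount
# correlation.
sim_episodic <- function(n = 250, seed = 13, rho = 0.7) {
  cached(sprintf("episodic_%d_%d_%g", n, seed, rho), {
    spec <- generator_spec(
      n_persons = n, component = "meats", unit = "g",
      beta_prob = c(1.0, 0, 0, 0.2), beta_amt = c(4.7, -0.2, 0, 0.05),
      sigma_u1 = 1.1, rho = rho, sigma_u2 = 0.5, sigma_e = 0.7)
    generate_recalls(spec, seed = seed)
  })
}

# Hand-built tiny recall table: one component, explicit days.
toy_dataset <- function(amounts_by_person, component = "energy",
                        days = seq_along(amounts_by_person[[1]]),
                        sex = NULL, age = 40) {
  persons <- names(amounts_by_person)
  if (is.null(sex)) sex <- stats::setNames(rep("male", length(persons)), persons)
  rows <- do.call(rbind, lapply(persons, function(p) {
    data.frame(person_id = p, day_index = days, sex = sex[[p]], age = age,
               component = component, amount = amounts_by_person[[p]],
               stringsAsFactors = FALSE)
  }))
  recall_dataset(rows)
}

# A minimal hand-made amount-variant fit object for analytic checks.
manual_amount_fit <- function(lambda = 0, beta2 = c(7, 0, 0, 0),
                              sigma_u2 = 0.3, sigma_e = 0.4, scale = 1,
                              component = "energy") {
  structure(list(
    variant = "amount", component = component, season = NA_character_,
    lambda = lambda, scale = scale, beta1 = NULL, sigma_u1 = NA_real_,
    rho = NA_real_, beta2 = beta2, sigma_u2 = sigma_u2, sigma_e = sigma_e,
    loglik = NA_real_, converged = TRUE, notes = character(),
    age_center = 40, age_scale = 10, n_persons = NA_integer_, gh_nodes = 21
  ), class = "nci_fit")
}
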