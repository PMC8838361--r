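#' Construct a recall dataset
#'
#' A recall dataset is a long-format data frame of person-day-component
#' intakes from repeated 24-hour recalls, the universal input of the package.
#' Day indices 1..28 partition into four seasonal blocks of seven consecutive
#' days (Monday to Sunday): days 1-7 winter, 8-14 spring, 15-21 summer,
#' 22-28 autumn.  An absent row means the person was not surveyed on that
#' day; an explicit amount of 0 means surveyed with zero consumption.
#'
#' @param df Data frame with columns `person_id`, `day_index`, `season`,
#'   `day_of_week`, `is_weekend`, `sex`, `age`, `component`, `amount`.
#'   `season`, `day_of_week` and `is_weekend` may be omitted and are then
#'   derived from `day_index`.
#' @param units Optional named character vector mapping component names to
#'   measurement units (e.g. `c(energy = "kcal")`).
#' @return A `recall_dataset` (a validated data frame).
#' @export
recall_dataset <- function(df, units = NULL) {
  required <- c("person_id", "day_index", "sex", "age", "component", "amount")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_ui("missing required columns: %s", paste(missing_cols, collapse = ", "),
            class = "recall_parse_error")
  }
  df$person_id <- as.character(df$person_id)
  df$day_index <- as.integer(df$day_index)
  df$component <- as.character(df$component)
  df$amount <- suppressWarnings(as.numeric(df$amount))  # non-numeric -> NA, caught below
  if (is.null(df$season)) df$season <- season_of_day(df$day_index)
  if (is.null(df$day_of_week)) df$day_of_week <- dow_of_day(df$day_index)
  if (is.null(df$is_weekend)) df$is_weekend <- df$day_of_week %in% c("Sat", "Sun")

  bad <- which(!is.finite(df$amount))
  if (length(bad)) {
    stop_ui("unparseable amount in row(s): %s", paste(utils::head(bad, 5), collapse = ", "),
            class = "recall_parse_error")
  }
  neg <- which(df$amount < 0)
  if (length(neg)) {
    stop_ui("negative amount in row(s): %s", paste(utils::head(neg, 5), collapse = ", "),
            class = "recall_validation_error")
  }
  if (any(df$day_index < 1)) {
    stop_ui("day_index must be a positive day number", class = "recall_validation_error")
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop_ui("sex must be 'male' or 'female'", class = "recall_validation_error")
  }
  bad_we <- df$is_weekend != (df$day_of_week %in% c("Sat", "Sun"))
  if (any(bad_we)) {
    stop_ui("is_weekend inconsistent with day_of_week in row(s): %s",
            paste(utils::head(which(bad_we), 5), collapse = ", "),
            class = "recall_validation_error")
  }
  key <- paste(df$person_id, df$component, df$day_index)
  if (anyDuplicated(key)) {
    stop_ui("duplicate (person, component, day_index) records",
            class = "recall_validation_error")
  }
  df <- df[order(df$component, df$person_id, df$day_index), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, units = units, class = c("recall_dataset", "data.frame"))
}

season_of_day <- function(day_index) {
  SEASONS[((as.integer(day_index) - 1L) %/% 7L) %% 4L + 1L]
}

dow_of_day <- function(day_index) {
  DAYS_OF_WEEK[(as.integer(day_index) - 1L) %% 7L + 1L]
}

#' @export
print.recall_dataset <- function(x, ...) {
  cat(sprintf("Recall dataset: %d persons, %d components, %d person-day records\n",
              length(unique(x$person_id)), length(unique(x$component)), nrow(x)))
  invisible(x)
}

#' Read a recall table from delimited text
#'
#' @param path Path to a delimited text file, one row per
#'   person-day-component.
#' @param schema Optional named character vector mapping canonical column
#'   names (`person_id`, `day_index`, `sex`, `age`, `component`, `amount`) to
#'   the column names used in the file.
#' @param sep Field separator (comma by default).
#' @param units Passed to [recall_dataset()].
#' @return A `recall_dataset`.
#' @export
read_recalls <- function(path, schema = NULL, sep = ",", units = NULL) {
  if (!file.exists(path)) {
    stop_ui("file not found: %s", path, class = "recall_parse_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        stop_ui("schema column '%s' (for '%s') not in file", src, canonical,
                class = "recall_parse_error")
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  recall_dataset(df, units = units)
}

#' Write a recall dataset to delimited text
#'
#' Inverse of [read_recalls()]: writes the canonical long layout so that a
#' read-back reproduces the table cell for cell.
#'
#' @param ds A `recall_dataset`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_recalls <- function(ds, path, sep = ",") {
  utils::write.table(as.data.frame(ds), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply participant exclusion filters
#'
#' Removes whole persons that completed fewer than `min_recalls` recall days
#' or reported an implausible daily energy intake on any day (outside
#' 600-4200 kcal for men, 400-3500 kcal for women, by default).
#'
#' @param ds A `recall_dataset` containing an energy component.
#' @param min_recalls Minimum number of completed recall days to retain a
#'   person.
#' @param energy_bounds Named list with `male` and `female` elements, each a
#'   length-2 numeric of (lower, upper) plausible daily energy intake.
#' @param energy_component Name of the energy component in the dataset.
#' @return A list with elements `dataset` (the filtered `recall_dataset`) and
#'   `report` (a data frame of excluded persons and reasons, with counts as
#'   attribute `counts`).
#' @export
apply_exclusions <- function(ds, min_recalls = 23,
                             energy_bounds = list(male = c(600, 4200),
                                                  female = c(400, 3500)),
                             energy_component = "energy") {
  if (!energy_component %in% ds$component) {
    stop_ui("dataset has no '%s' component; energy is required for exclusions",
            energy_component, class = "config_error")
  }
  # recall count: distinct surveyed days per person over all components
  day_key <- unique(ds[, c("person_id", "day_index")])
  n_days <- table(day_key$person_id)
  few <- names(n_days)[n_days < min_recalls]

  en <- ds[ds$component == energy_component, ]
  sex_of <- tapply(en$sex, en$person_id, function(s) s[[1]])
  lo <- vapply(sex_of, function(s) energy_bounds[[s]][1], numeric(1))
  hi <- vapply(sex_of, function(s) energy_bounds[[s]][2], numeric(1))
  rng <- do.call(rbind, tapply(en$amount, en$person_id, range, simplify = FALSE))
  implausible <- rownames(rng)[rng[, 1] < lo[rownames(rng)] | rng[, 2] > hi[rownames(rng)]]

  report <- rbind(
    if (length(few)) data.frame(person_id = few, reason = "too_few_recalls"),
    if (length(implausible)) data.frame(person_id = implausible,
                                        reason = "implausible_energy")
  )
  if (is.null(report)) report <- data.frame(person_id = character(), reason = character())
  drop <- unique(report$person_id)
  out <- ds[!ds$person_id %in% drop, , drop = FALSE]
  attr(report, "counts") <- c(
    too_few_recalls = length(few),
    implausible_energy = length(implausible),
    excluded = length(drop),
    retained = length(unique(out$person_id))
  )
  list(dataset = recall_dataset(as.data.frame(out), units = attr(ds, "units")),
       report = report)
}

#' Extract a short consecutive-day window from one season
#'
#' Selects, per person, up to three consecutive recall days within one
#' season's Monday-Sunday block.  The default rule picks the first
#' consecutive 3-day run containing exactly two weekdays and one weekend day
#' (Thursday-Friday-Saturday); a different start day can be forced with
#' `start_day`.  Persons missing some of the window's days keep whatever
#' subset exists (1 or 2 days); persons with no recalls in the season are
#' absent from the output and listed in attribute `dropped`.
#'
#' @param ds A `recall_dataset`.
#' @param season One of `"winter"`, `"spring"`, `"summer"`, `"autumn"`.
#' @param start_day Day of week starting the window (wrapping Sunday back to
#'   Monday within the season block); `NULL` (default) derives Thursday from
#'   the two-weekdays + one-weekend rule.
#' @param n_days Window length (default 3).
#' @return A `recall_dataset` restricted to the window.
#' @export
extract_window <- function(ds, season, start_day = NULL, n_days = 3) {
  season <- match.arg(season, SEASONS)
  if (is.null(start_day)) {
    # first run of 3 consecutive days in Mon..Sun with 2 weekdays + 1 weekend
    runs <- lapply(1:(7 - n_days + 1), function(i) DAYS_OF_WEEK[i:(i + n_days - 1)])
    ok <- vapply(runs, function(r) sum(r %in% c("Sat", "Sun")) == 1, logical(1))
    start_day <- runs[[which(ok)[1]]][1]
  }
  start_idx <- match(start_day, DAYS_OF_WEEK)
  if (is.na(start_idx)) {
    stop_ui("unknown start_day '%s'", start_day, class = "config_error")
  }
  # consecutive days of week, wrapping Sun -> Mon within the season block
  days <- DAYS_OF_WEEK[(start_idx - 1 + seq_len(n_days) - 1) %% 7 + 1]
  sub <- ds[ds$season == season & ds$day_of_week %in% days, , drop = FALSE]
  in_season <- unique(ds$person_id[ds$season == season])
  dropped <- setdiff(unique(ds$person_id), unique(sub$person_id))
  out <- recall_dataset(as.data.frame(sub), units = attr(ds, "units"))
  attr(out, "window") <- list(season = season, days = days)
  attr(out, "dropped") <- dropped
  attr(out, "no_recalls_in_season") <- setdiff(unique(ds$person_id), in_season)
  out
}

#' Descriptive statistics for one component
#'
#' Computes the descriptive profile used both to characterise a dataset and
#' to choose the NCI model variant: the overall mean, the SD/CV and
#' percentiles of the per-person mean intake (the empirical usual-intake
#' distribution; with several zero-intake days per person a daily-scale CV
#' would be dominated by consumption switching and could not match published
#' usual-intake descriptives), the variance ratio VR (within-person /
#' between-person variance of daily intakes, from a one-way
#' method-of-moments decomposition), the percentage of zero-intake recall
#' days, and the Spearman correlation between per-person consumption
#' probability and per-person consumption-day mean amount.
#'
#' @param ds A `recall_dataset`.
#' @param component Component name.
#' @param freq_measure For the Spearman correlation, whether a person's
#'   consumption propensity is the share of days with positive intake
#'   (`"frequency"`, default) or the count of consuming days (`"n_days"`);
#'   the two give identical correlations on balanced data.
#' @param vr_cap Upper cap for the reported VR (the between-person variance
#'   is floored at 1e-12, so VR can otherwise be astronomically large).
#' @param probs Percentile levels reported for the per-person means.
#' @return A `component_profile` list.
#' @export
describe_component <- function(ds, component,
                               freq_measure = c("frequency", "n_days"),
                               vr_cap = 100,
                               probs = c(5, 10, 25, 50, 75, 90, 95) / 100) {
  freq_measure <- match.arg(freq_measure)
  x <- ds[ds$component == component, , drop = FALSE]
  if (!nrow(x)) stop_ui("component '%s' not in dataset", component, class = "lookup_error")
  if (length(unique(x$person_id)) < 2) {
    stop_ui("need at least 2 persons to describe a component", class = "degenerate_error")
  }
  a <- x$amount
  person <- factor(x$person_id)
  person_mean <- tapply(a, person, mean)

  # one-way unbalanced ANOVA, method of moments
  n_i <- tabulate(person)
  k <- nlevels(person)
  N <- length(a)
  ssw <- sum((a - person_mean[person])^2)
  msw <- if (N - k > 0) ssw / (N - k) else 0
  grand <- mean(a)
  msb <- sum(n_i * (person_mean - grand)^2) / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  var_between <- max((msb - msw) / n0, 1e-12)
  vr <- min(msw / var_between, vr_cap)

  consuming <- a > 0
  freq <- tapply(consuming, person, if (freq_measure == "frequency") mean else sum)
  cons_mean <- tapply(ifelse(consuming, a, NA), person, mean, na.rm = TRUE)
  keep <- is.finite(cons_mean)
  if (any(a == 0) && sum(keep) >= 4 && stats::sd(freq[keep]) > 0 &&
      stats::sd(cons_mean[keep]) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(freq[keep], cons_mean[keep], method = "spearman"))
    spearman_r <- unname(ct$estimate)
    spearman_p <- ct$p.value
  } else {
    spearman_r <- NA_real_
    spearman_p <- NA_real_
  }

  structure(list(
    component = component,
    n_persons = k,
    n_days = N,
    mean = grand,
    sd = stats::sd(person_mean),
    cv_percent = if (grand > 0) 100 * stats::sd(person_mean) / grand else NA_real_,
    percentiles = stats::setNames(qtile(person_mean, probs), paste0("p", probs * 100)),
    var_within = msw,
    var_between = var_between,
    variance_ratio = vr,
    pct_zero = 100 * mean(a == 0),
    spearman_r = spearman_r,
    spearman_p = spearman_p
  ), class = "component_profile")
}

#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf("Component '%s': %d persons, %d recall-days\n", x$component,
              x$n_persons, x$n_days))
  cat(sprintf("  mean %.2f, SD %.2f, CV %.1f%%, VR %.2f, %% zero %.2f\n",
              x$mean, x$sd, x$cv_percent, x$variance_ratio, x$pct_zero))
  if (is.finite(x$spearman_r)) {
    cat(sprintf("  Spearman r(prob, amount) %.2f (p = %.3g)\n",
                x$spearman_r, x$spearman_p))
  }
  invisible(x)
}

#' Reference-standard usual intake from all available recalls
#'
#' The long-run "true" usual intake of each person: the arithmetic mean of
#' all of their available recall days for the component (23-28 days after
#' exclusions).
#'
#' @param ds A `recall_dataset` (after [apply_exclusions()]).
#' @param component Component name.
#' @return An `individual_estimates` data frame with columns `person_id` and
#'   `estimate`.
#' @export
true_usual_intake <- function(ds, component) {
  x <- ds[ds$component == component, , drop = FALSE]
  if (!nrow(x)) stop_ui("component '%s' not in dataset", component, class = "lookup_error")
  m <- tapply(x$amount, x$person_id, mean)
  individual_estimates(names(m), as.numeric(m), method = "28day",
                       component = component, season = NA_character_)
}

individual_estimates <- function(person_id, estimate, method, component,
                                 season = NA_character_) {
  stopifnot(all(estimate >= 0 | is.na(estimate)))
  structure(data.frame(person_id = as.character(person_id),
                       estimate = as.numeric(estimate),
                       stringsAsFactors = FALSE),
            method = method, component = component, season = season,
            class = c("individual_estimates", "data.frame"))
}
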