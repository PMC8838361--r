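#' Within-person short-window mean (the 3-day method)
#'
#' The traditional comparator: each person's usual intake is estimated by the
#' arithmetic mean of their available recall days in the window (1-3 days;
#' zero-intake days count as zeros).  Persons with no days in the window are
#' absent from the output.
#'
#' @param window A `recall_dataset` from [extract_window()].
#' @param component Component name.
#' @return An `individual_estimates` data frame.
#' @export
three_day_mean <- function(window, component) {
  x <- window[window$component == component, , drop = FALSE]
  if (!nrow(x)) stop_ui("component '%s' not in window", component, class = "lookup_error")
  m <- tapply(x$amount, x$person_id, mean)
  season <- if (length(unique(x$season)) == 1) x$season[[1]] else NA_character_
  individual_estimates(names(m), as.numeric(m), method = "3day",
                       component = component, season = season)
}

#' Naive group distribution of short-window means
#'
#' The group-level distribution of the 3-day method: mean and percentiles of
#' the per-person short-window means, with no measurement-error correction.
#'
#' @param est An `individual_estimates` from [three_day_mean()].
#' @return A `usual_intake_distribution`.
#' @export
naive_distribution <- function(est) {
  group_distribution(est)
}
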