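#' Kaplan-Meier curve of time to nonuse attrition
#'
#' Proportion of participants still logging in at least once per window,
#' by window index -- the reverse-sigmoidal shape characteristic of digital
#' intervention use (curiosity plateau, rejection phase, long tail of
#' consistent users).
#'
#' @param records Output of [attrition_records()].
#' @return A ggplot.
#' @export
plot_attrition_curve <- function(records) {
  sf <- survival::survfit(
    survival::Surv(records$time_months, records$event) ~ 1)
  df <- tibble(time = c(0, sf$time), surv = c(1, sf$surv))
  ggplot(df, aes(x = .data$time, y = .data$surv)) +
    geom_step(linewidth = 0.8) +
    scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%d%%", round(100 * x))) +
    labs(x = sprintf("Time (%d-day windows)", records$window_days[1]),
         y = "Free of nonuse attrition",
         title = "Time to first nonuse attrition") +
    theme_minimal()
}

#' Logins per window over follow-up
#'
#' Total logins per 30-day window across the cohort, the descriptive
#' engagement-over-time panel.
#'
#' @param logins Login events.
#' @param window_days Window length in days.
#' @return A ggplot.
#' @export
plot_logins_over_time <- function(logins, window_days = 30) {
  df <- logins %>%
    mutate(window = .data$day %/% window_days + 1) %>%
    count(.data$window)
  ggplot(df, aes(x = .data$window, y = .data$n)) +
    geom_col(fill = "grey35") +
    labs(x = sprintf("%d-day window", window_days), y = "Total logins",
         title = "Platform use over time") +
    theme_minimal()
}

#' Forest plot of adjusted 18-month change differences
#'
#' One panel per outcome; points are adjusted mean differences versus the
#' control group for the low / moderate / high engagement categories, with
#' 95% CIs.
#'
#' @param object An `eh_outcome_results` tibble from [run_all_outcomes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eh_outcome_results <- function(object, ...) {
  df <- object %>%
    mutate(group = factor(.data$group, levels = c("low", "moderate", "high")))
  ggplot(df, aes(x = .data$estimate, y = .data$group)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    geom_pointrange(aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    facet_wrap(~ .data$outcome, scales = "free_x") +
    labs(x = "Adjusted mean difference in 18-month change vs control",
         y = "Engagement category") +
    theme_minimal()
}

#' @rdname autoplot.eh_outcome_results
#' @param results An `eh_outcome_results` tibble.
#' @export
plot_outcome_forest <- function(results) {
  autoplot.eh_outcome_results(results)
}
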