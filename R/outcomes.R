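#' Reshape long outcome records to one row per participant
#'
#' @param outcomes Long tibble (`participant_id`, `timepoint`, `variable`,
#'   `value`) as produced by [sample_outcomes()] or read from
#'   `outcomes.csv`.
#' @return Wide tibble with `<variable>_baseline` / `<variable>_month18`
#'   columns.
#' @export
outcomes_wide <- function(outcomes) {
  outcomes %>%
    tidyr::pivot_wider(names_from = c("variable", "timepoint"),
                       values_from = "value",
                       names_glue = "{variable}_{timepoint}")
}

#' Pooled baseline standardisation constants
#'
#' Baseline mean and SD of each composite component over the supplied
#' (pooled, both-arm) analysis sample. These constants are what the
#' composite z-change is standardised against and are returned so any
#' report can restate them.
#'
#' @param wide Output of [outcomes_wide()].
#' @param components Component variables (default SBP, LDL, BMI).
#' @return Tibble: `variable`, `mean`, `sd`.
#' @export
standardization_constants <- function(wide,
                                      components = c("sbp", "ldl", "bmi")) {
  purrr::map(components, function(v) {
    x <- wide[[paste0(v, "_baseline")]]
    tibble(variable = v, mean = mean(x, na.rm = TRUE),
           sd = stats::sd(x, na.rm = TRUE))
  }) %>% bind_rows()
}

#' Composite cardiovascular z-score change
#'
#' For each component (SBP, LDL cholesterol, BMI) the 18-month change is
#' divided by the pooled baseline SD; the composite is the mean of the three
#' standardised changes. Lower values indicate improvement. Participants
#' missing any component at either timepoint get `NA` (and are excluded
#' from change models); the count is reported via a message.
#'
#' @param wide Output of [outcomes_wide()].
#' @param constants Optional [standardization_constants()] tibble; computed
#'   from `wide` (pooled) when omitted.
#' @return `wide` with `z_change_<component>` columns and
#'   `composite_z_change` appended.
#' @export
composite_z_change <- function(wide, constants = NULL) {
  components <- c("sbp", "ldl", "bmi")
  constants <- constants %||% standardization_constants(wide, components)
  if (any(constants$sd <= 0)) {
    abort_config("Standardisation SDs must be positive.", field = "constants")
  }
  z <- purrr::map(components, function(v) {
    sdv <- constants$sd[constants$variable == v]
    (wide[[paste0(v, "_month18")]] - wide[[paste0(v, "_baseline")]]) / sdv
  })
  names(z) <- paste0("z_change_", components)
  out <- bind_cols(wide, as_tibble(z))
  out$composite_z_change <- (out$z_change_sbp + out$z_change_ldl +
                               out$z_change_bmi) / 3
  n_miss <- sum(is.na(out$composite_z_change))
  if (n_miss > 0) {
    rlang::inform(sprintf(
      "%d participant(s) missing a composite component; composite set to NA.",
      n_miss))
  }
  attr(out, "constants") <- constants
  out
}

default_outcome_covariates <- function() {
  c("age", "sex", "education", "country", "sppb_lt10", "smoking",
    "lifestyle_stage", "computer_use", "cognition_z")
}

#' Adjusted 18-month change model for one outcome
#'
#' Ordinary least squares of the 18-month change on engagement group
#' (control as reference) and baseline covariates. The three group
#' coefficients are the adjusted mean differences versus control; the
#' overall dose-response p-value is the joint F-test of those three terms.
#' The baseline value of the outcome is added as a covariate iff its means
#' differ across the three engagement categories at p < .05 by one-way
#' ANOVA (`baseline_adjust = "auto"`).
#'
#' @param data One row per participant: `engagement_group` (factor with
#'   levels control, low, moderate, high), covariates, and either
#'   `<outcome>_baseline`/`<outcome>_month18` columns or a precomputed
#'   change column named `outcome`.
#' @param outcome Outcome variable stem (e.g. `"sbp"`) or the name of a
#'   precomputed change column (e.g. `"composite_z_change"`).
#' @param covariates Adjustment covariates (defaults to the published set:
#'   age, sex, education, country, physical function, smoking, lifestyle
#'   stage, computer use, cognition).
#' @param baseline_adjust `"auto"` (ANOVA-gated, default), `"always"`,
#'   `"never"`.
#' @param group Name of the grouping column.
#' @return An object of class `eh_change_fit`.
#' @export
fit_change_model <- function(data, outcome,
                             covariates = default_outcome_covariates(),
                             baseline_adjust = c("auto", "always", "never"),
                             group = "engagement_group") {
  baseline_adjust <- rlang::arg_match(baseline_adjust)
  g <- data[[group]]
  if (is.null(g)) abort_config("Missing grouping column.", field = group)
  g <- factor(as.character(g), levels = c("control", "low", "moderate", "high"))
  if (length(unique(stats::na.omit(as.character(g)))) < 2) {
    abort_fit("All participants share one group label; no contrast to estimate.")
  }

  has_change_col <- outcome %in% names(data)
  base_col <- paste0(outcome, "_baseline")
  if (has_change_col) {
    change <- data[[outcome]]
  } else {
    if (!all(c(base_col, paste0(outcome, "_month18")) %in% names(data))) {
      abort_config(paste0("No columns for outcome `", outcome, "`."),
                   field = outcome)
    }
    change <- data[[paste0(outcome, "_month18")]] - data[[base_col]]
  }

  df <- data %>%
    mutate(.change = change, .group = g) %>%
    select(".change", ".group", any_of(c(covariates, base_col)))

  adjust_baseline <- FALSE
  if (baseline_adjust == "always") adjust_baseline <- base_col %in% names(df)
  if (baseline_adjust == "auto" && base_col %in% names(df)) {
    eng <- df %>% filter(.data$.group != "control", !is.na(.data$.group))
    if (nrow(eng) > 3 && length(unique(as.character(eng$.group))) > 1) {
      g2 <- droplevels(eng$.group)
      pa <- stats::anova(stats::aov(eng[[base_col]] ~ g2))[1, "Pr(>F)"]
      adjust_baseline <- is.finite(pa) && pa < 0.05
    }
  }
  rhs <- c(".group", covariates, if (adjust_baseline) base_col)
  df <- df[stats::complete.cases(df[, c(".change", rhs)]), , drop = FALSE]

  fit <- stats::lm(stats::reformulate(rhs, response = ".change"), data = df)
  if (any(is.na(coef(fit)))) {
    abort_fit(paste0("Rank-deficient change model; collinear term(s): ",
                     paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
              class = "ehengage_singular_error")
  }
  red_terms <- setdiff(rhs, ".group")
  if (!length(red_terms)) red_terms <- "1"
  reduced <- stats::lm(stats::reformulate(red_terms, response = ".change"),
                       data = df)
  overall_p <- stats::anova(reduced, fit)[2, "Pr(>F)"]

  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  rows <- paste0(".group", c("low", "moderate", "high"))
  est <- tibble(
    group = c("low", "moderate", "high"),
    estimate = unname(cf[rows, "Estimate"]),
    std.error = unname(cf[rows, "Std. Error"]),
    conf.low = unname(ci[rows, 1]), conf.high = unname(ci[rows, 2]),
    p.value = unname(cf[rows, "Pr(>|t|)"]))

  structure(list(
    outcome = outcome,
    estimates = est,
    overall_p = overall_p,
    n = nrow(df),
    n_by_group = df %>% count(.data$.group, .drop = FALSE) %>%
      tidyr::pivot_wider(names_from = ".group", values_from = "n"),
    covariates = covariates,
    baseline_adjusted = adjust_baseline,
    lm = fit
  ), class = "eh_change_fit")
}

#' @export
print.eh_change_fit <- function(x, ...) {
  cat(sprintf("18-month change model for `%s` (n=%d, overall p=%.4g%s)\n",
              x$outcome, x$n, x$overall_p,
              if (x$baseline_adjusted) ", baseline-adjusted" else ""))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.eh_change_fit <- function(x, ...) {
  mutate(x$estimates, outcome = x$outcome, .before = 1)
}

#' @export
glance.eh_change_fit <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n, overall_p = x$overall_p,
         baseline_adjusted = x$baseline_adjusted)
}

#' Fit change models for every outcome
#'
#' Runs [fit_change_model()] for the composite z-score and each individual
#' outcome. Sign conventions: negative adjusted differences indicate
#' improvement for the composite, SBP, LDL, BMI, CAIDE and SCORE-OP;
#' positive differences indicate improvement for physical activity and
#' MEDAS.
#'
#' @inheritParams fit_change_model
#' @param outcomes Outcome stems to model.
#' @return A tibble of class `eh_outcome_results` (one row per outcome x
#'   engagement group) with attribute `fits` holding the individual
#'   `eh_change_fit` objects.
#' @export
run_all_outcomes <- function(data,
                             covariates = default_outcome_covariates(),
                             baseline_adjust = c("auto", "always", "never"),
                             outcomes = c("composite_z_change", "ldl", "sbp",
                                          "bmi", "phys_act", "medas",
                                          "caide", "score_op"),
                             group = "engagement_group") {
  baseline_adjust <- rlang::arg_match(baseline_adjust)
  fits <- purrr::map(outcomes, function(v) {
    fit_change_model(data, v, covariates = covariates,
                     baseline_adjust = baseline_adjust, group = group)
  })
  names(fits) <- outcomes
  out <- purrr::map(fits, function(f) {
    mutate(tidy(f), overall_p = f$overall_p, n = f$n,
           baseline_adjusted = f$baseline_adjusted)
  }) %>% bind_rows()
  attr(out, "fits") <- fits
  class(out) <- c("eh_outcome_results", class(out))
  out
}
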