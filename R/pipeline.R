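default_predictor_candidates <- function() {
  c("age", "sex", "education", "country", "living_with_partner",
    "cognition_z", "sppb_lt10", "depressive_symptoms", "hads_anxiety",
    "cvd_history", "diabetes", "hypertension", "dyslipidemia", "smoking",
    "physically_active", "obese", "medas", "pih", "lifestyle_stage",
    "computer_use")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("Pipeline failed at stage `", stage, "`: ",
                        conditionMessage(e)),
                 class = "ehengage_pipeline_error", stage = stage, parent = e)
  })
}

#' Run the full engagement analysis pipeline
#'
#' Orchestrates simulate (or load) -> engagement scoring -> nonuse
#' attrition -> ordinal predictor model -> early/late Cox models ->
#' dose-response outcome models, writing every stage artifact as plain
#' CSV/JSON into `out_dir` so any stage can be re-run standalone. A run
#' manifest records the seed, a configuration hash and the package version;
#' any stage failure aborts with the stage name while artifacts from the
#' stages already completed remain on disk.
#'
#' @param config An [sim_config()] for a simulated run, or `NULL` when
#'   reading prepared CSVs from `input_dir`. Exactly one of the two must be
#'   supplied.
#' @param input_dir Directory in the canonical CSV layout (see
#'   [read_usage_dir()]).
#' @param out_dir Output directory.
#' @param window_days Attrition window: 30 (monthly, default) or 42
#'   (6-week sensitivity).
#' @param scoring_variant `"cutpoints"` (published 0-2/3-5/6-7 mapping,
#'   default) or `"tertiles"` (equal-frequency sensitivity categorisation);
#'   both columns are always present in `engagement.csv`, the choice sets
#'   which one downstream models use.
#' @param candidates Candidate predictor terms for the ordinal and Cox
#'   models.
#' @param alpha_enter,alpha_stay,alpha_parallel Selection thresholds.
#' @param cut_months Early/late follow-up split (default 2).
#' @param ties Tie correction for Cox fits.
#' @param make_plots If `TRUE`, also writes attrition-curve and forest-plot
#'   PNGs.
#' @return Invisibly, a list with every stage result (`trial` or `inputs`,
#'   `engagement`, `attrition`, `predictors`, `survival`, `outcomes`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, out_dir,
                         window_days = 30,
                         scoring_variant = c("cutpoints", "tertiles"),
                         candidates = default_predictor_candidates(),
                         alpha_enter = 0.20, alpha_stay = 0.05,
                         alpha_parallel = 0.05, cut_months = 2,
                         ties = c("efron", "breslow"),
                         make_plots = FALSE) {
  scoring_variant <- rlang::arg_match(scoring_variant)
  ties <- rlang::arg_match(ties)
  if (is.null(config) == is.null(input_dir)) {
    abort_config("Supply exactly one of `config` or `input_dir`.",
                 field = "config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ehengage")),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) rlang::hash(unclass(config)) else
      rlang::hash(normalizePath(input_dir)),
    window_days = window_days, scoring_variant = scoring_variant,
    cut_months = cut_months, ties = ties)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- stage: inputs -------------------------------------------------------
  inputs <- pipeline_stage("simulate", {
    if (!is.null(config)) {
      trial <- simulate_trial(config)
      write_trial(trial, out_dir)
      list(participants = trial$participants, usage = trial$usage,
           outcomes = trial$outcomes)
    } else {
      read_usage_dir(input_dir)
    }
  })
  participants <- inputs$participants
  intervention <- filter(participants, .data$arm == "intervention")

  # --- stage: scoring ------------------------------------------------------
  engagement <- pipeline_stage("scoring", {
    eng <- summarize_usage(inputs$usage, participants = intervention) %>%
      score_engagement()
    readr::write_csv(eng, file.path(out_dir, "engagement.csv"))
    eng
  })

  # --- stage: attrition ----------------------------------------------------
  attrition <- pipeline_stage("attrition", {
    rec <- attrition_records(inputs$usage$logins, intervention,
                             window_days = window_days)
    readr::write_csv(rec, file.path(out_dir, "attrition.csv"))
    rec
  })

  model_group <- if (scoring_variant == "cutpoints") "category" else
    "category_tertile"
  model_data <- prep_model_data(
    intervention %>%
      left_join(select(engagement, "participant_id", outcome_cat =
                         all_of(model_group)),
                by = "participant_id") %>%
      mutate(outcome_cat = factor(as.character(.data$outcome_cat),
                                  levels = levels(engagement[[model_group]]),
                                  ordered = TRUE)))

  # --- stage: predictors (ordinal model) -----------------------------------
  predictors <- pipeline_stage("predictors", {
    fit <- select_predictors(model_data, outcome = "outcome_cat",
                             candidates = candidates,
                             alpha_enter = alpha_enter,
                             alpha_stay = alpha_stay,
                             alpha_parallel = alpha_parallel)
    tab <- tidy(fit, exponentiate = TRUE)
    readr::write_csv(tab, file.path(out_dir, "predictors_table.csv"))
    jsonlite::write_json(list(
      manifest = manifest,
      n = fit$n, n_dropped = fit$n_dropped, logLik = fit$logLik,
      constraint_map = as.list(fit$constraint_map),
      screen = attr(fit, "screen"),
      elimination = attr(fit, "elimination"),
      odds_ratios = tab),
      file.path(out_dir, "predictors_model.json"),
      auto_unbox = TRUE, digits = NA)
    fit
  })

  # --- stage: survival -----------------------------------------------------
  surv_models <- pipeline_stage("survival", {
    sd_all <- model_data %>%
      left_join(select(attrition, "participant_id", "time_months", "event"),
                by = "participant_id")
    spl <- split_followup(sd_all, cut_months = cut_months)
    early <- cox_backward_eliminate(
      spl$early, candidates, alpha = alpha_stay,
      time = "time_early", event = "event_early", ties = ties)
    late <- cox_backward_eliminate(
      spl$late, candidates, alpha = alpha_stay,
      time = "time_late", event = "event_late", entry = "entry", ties = ties)
    tab <- bind_rows(
      mutate(tidy(early, exponentiate = TRUE), period = "early", .before = 1),
      mutate(tidy(late, exponentiate = TRUE), period = "late", .before = 1))
    readr::write_csv(tab, file.path(out_dir, "survival_table.csv"))
    jsonlite::write_json(list(
      manifest = manifest,
      early = list(n = early$n, events = early$nevent,
                   hazard_ratios = tidy(early, exponentiate = TRUE),
                   ph_test = if (length(early$coefficients)) ph_test(early)),
      late = list(n = late$n, events = late$nevent,
                  hazard_ratios = tidy(late, exponentiate = TRUE),
                  ph_test = if (length(late$coefficients)) ph_test(late))),
      file.path(out_dir, "survival_models.json"),
      auto_unbox = TRUE, digits = NA)
    list(early = early, late = late, split = spl)
  })

  # --- stage: outcomes -----------------------------------------------------
  outcome_models <- pipeline_stage("outcomes", {
    if (is.null(inputs$outcomes)) {
      abort_config("No outcomes.csv available; cannot fit change models.",
                   field = "outcomes.csv")
    }
    wide <- composite_z_change(outcomes_wide(inputs$outcomes))
    adata <- prep_model_data(
      participants %>%
        left_join(select(engagement, "participant_id",
                         eng_cat = all_of(model_group)),
                  by = "participant_id") %>%
        mutate(engagement_group = ifelse(
          .data$arm == "control", "control", as.character(.data$eng_cat))) %>%
        left_join(wide, by = "participant_id"))
    if (scoring_variant == "tertiles") {
      adata$engagement_group <- dplyr::recode(
        adata$engagement_group, T1 = "low", T2 = "moderate", T3 = "high")
    }
    res <- run_all_outcomes(adata)
    readr::write_csv(res, file.path(out_dir, "outcome_models.csv"))
    res
  })

  # --- stage: report -------------------------------------------------------
  pipeline_stage("report", {
    cons <- classify_consistency(attrition)
    lines <- c(
      "Engagement analysis pipeline summary",
      sprintf("package %s | seed %s | config %s",
              manifest$package_version, manifest$seed, manifest$config_hash),
      "",
      sprintf("Participants: %d intervention / %d control",
              nrow(intervention), nrow(participants) - nrow(intervention)),
      sprintf("Median total logins (intervention): %g",
              stats::median(engagement$total_logins)),
      "",
      "Engagement categories:",
      sprintf("  %-9s %5d (%5.2f%%)",
              levels(engagement$category),
              tabulate(engagement$category, 3),
              100 * tabulate(engagement$category, 3) / nrow(engagement)),
      "",
      sprintf("Nonuse attrition (%d-day windows):", window_days),
      sprintf("  %-20s %5d (%5.2f%%)", cons$group, cons$n, 100 * cons$share),
      "",
      sprintf("Ordinal predictor model: n=%d, terms: %s",
              predictors$n,
              paste(predictors$term_labels, collapse = ", ")),
      sprintf("Early Cox model: n=%d, %d events, terms: %s",
              surv_models$early$n, surv_models$early$nevent,
              paste(surv_models$early$terms, collapse = ", ")),
      sprintf("Late Cox model: n=%d, %d events, terms: %s",
              surv_models$late$n, surv_models$late$nevent,
              paste(surv_models$late$terms, collapse = ", ")),
      "",
      "Adjusted 18-month change vs control (composite z):",
      sprintf("  %-9s %+.4f [%+.4f, %+.4f]",
              outcome_models$group[outcome_models$outcome == "composite_z_change"],
              outcome_models$estimate[outcome_models$outcome == "composite_z_change"],
              outcome_models$conf.low[outcome_models$outcome == "composite_z_change"],
              outcome_models$conf.high[outcome_models$outcome == "composite_z_change"]),
      sprintf("  overall dose-response p = %.4g",
              outcome_models$overall_p[outcome_models$outcome ==
                                         "composite_z_change"][1]))
    writeLines(lines, file.path(out_dir, "summary.txt"))
    if (make_plots) {
      ggplot2::ggsave(file.path(out_dir, "attrition_curve.png"),
                      plot_attrition_curve(attrition), width = 6, height = 4)
      ggplot2::ggsave(file.path(out_dir, "outcome_forest.png"),
                      autoplot(outcome_models), width = 7, height = 5)
    }
    NULL
  })

  invisible(list(inputs = inputs, engagement = engagement,
                 attrition = attrition, predictors = predictors,
                 survival = surv_models, outcomes = outcome_models,
                 manifest = manifest))
}
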