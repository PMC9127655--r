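#' Read the canonical usage-log CSV layout
#'
#' Expects `participants.csv`, `logins.csv`, `goals.csv`, `messages.csv`,
#' `measurements.csv`, `education.csv` and (optionally) `outcomes.csv` in
#' `dir`, as written by [write_trial()] or produced by an export of real
#' usage logs in the same schema.
#'
#' @param dir Directory path.
#' @return A list with `participants`, `usage` (list of event tibbles) and
#'   `outcomes` (or `NULL`).
#' @export
read_usage_dir <- function(dir) {
  need <- c("participants.csv", "logins.csv", "goals.csv", "messages.csv",
            "measurements.csv", "education.csv")
  missing_files <- need[!file.exists(file.path(dir, need))]
  if (length(missing_files)) {
    abort_config(paste0(
      "Input directory `", dir, "` is missing: ",
      paste(missing_files, collapse = ", "),
      ". Expected the canonical CSV layout (see ?write_trial)."),
      field = missing_files[1])
  }
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  participants <- rd("participants.csv") %>%
    mutate(
      sex = factor(.data$sex, levels = c("female", "male")),
      education = factor(.data$education, levels = c("low", "medium", "high"),
                         ordered = TRUE),
      country = factor(.data$country, levels = c("NL", "FR", "FI")),
      lifestyle_stage = factor(.data$lifestyle_stage,
                               levels = c("no_plans", "long_term_plans",
                                          "short_term_plans",
                                          "short_term_acting",
                                          "long_term_acting"), ordered = TRUE),
      computer_use = factor(.data$computer_use,
                            levels = c("none", "lt7h_week", "ge7h_week"),
                            ordered = TRUE),
      arm = factor(.data$arm, levels = c("intervention", "control")))
  outcomes <- NULL
  if (file.exists(file.path(dir, "outcomes.csv"))) outcomes <- rd("outcomes.csv")
  list(participants = participants,
       usage = list(logins = rd("logins.csv"), goals = rd("goals.csv"),
                    messages = rd("messages.csv"),
                    measurements = rd("measurements.csv"),
                    education = rd("education.csv")),
       outcomes = outcomes)
}

# Modelling functions use treatment contrasts; the roster stores ordinal
# covariates as ordered factors (which would otherwise get polynomial
# contrasts), so drop orderedness while keeping level order.
prep_model_data <- function(data) {
  ord <- vapply(data, is.ordered, logical(1))
  data[ord] <- lapply(data[ord], function(x) factor(x, ordered = FALSE))
  data
}
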