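#' Summarise raw platform usage per participant
#'
#' Collapses the event streams into per-participant totals: total logins
#' (platform and questionnaire-tagged alike -- the raw login count used for
#' scoring), platform/questionnaire breakdown, number of goals set, messages
#' sent, measurements entered and the fraction of education material read,
#' plus the any-use booleans that feed the composite score. Participants
#' present in `participants` but absent from every stream get all-zero rows.
#'
#' @param usage A list with tibbles `logins` (participant_id, day, purpose),
#'   `goals`, `messages`, `measurements`, `education`, as produced by
#'   [sample_usage_log()] or [read_usage_dir()].
#' @param participants Optional roster tibble defining the scoring universe
#'   (e.g. the intervention arm); if supplied, usage rows from other
#'   participants are dropped and missing participants appear with zeros.
#' @return A tibble, one row per participant.
#' @export
#' @examples
#' usage <- list(
#'   logins = tibble::tibble(participant_id = "A", day = c(1, 91),
#'                           purpose = c("platform", "questionnaire_only")),
#'   goals = tibble::tibble(participant_id = "A", day = 3,
#'                          health_factor = "weight"),
#'   messages = tibble::tibble(participant_id = character(), day = integer()),
#'   measurements = tibble::tibble(participant_id = character(),
#'                                 day = integer(), type = character()),
#'   education = tibble::tibble(participant_id = "A", fraction_read = 0.2))
#' summarize_usage(usage)
summarize_usage <- function(usage, participants = NULL) {
  need <- c("logins", "goals", "messages", "measurements", "education")
  miss <- setdiff(need, names(usage))
  if (length(miss)) {
    abort_config(paste0("`usage` is missing component(s): ",
                        paste(miss, collapse = ", ")), field = miss[1])
  }
  ids <- if (!is.null(participants)) {
    unique(participants$participant_id)
  } else {
    unique(unlist(lapply(usage[need], function(x) x$participant_id)))
  }
  universe <- tibble(participant_id = ids)
  cnt <- function(df, nm) {
    df %>% count(.data$participant_id, name = nm)
  }
  out <- universe %>%
    left_join(usage$logins %>%
                group_by(.data$participant_id) %>%
                summarise(total_logins = dplyr::n(),
                          platform_logins = sum(.data$purpose == "platform"),
                          questionnaire_logins =
                            sum(.data$purpose == "questionnaire_only")),
              by = "participant_id") %>%
    left_join(cnt(usage$goals, "n_goals"), by = "participant_id") %>%
    left_join(cnt(usage$messages, "n_messages"), by = "participant_id") %>%
    left_join(cnt(usage$measurements, "n_measurements"),
              by = "participant_id") %>%
    left_join(usage$education %>%
                group_by(.data$participant_id) %>%
                summarise(education_fraction_read =
                            max(.data$fraction_read, 0)),
              by = "participant_id") %>%
    mutate(across(c("total_logins", "platform_logins", "questionnaire_logins",
                    "n_goals", "n_messages", "n_measurements"),
                  ~ as.integer(tidyr::replace_na(.x, 0L))),
           education_fraction_read =
             tidyr::replace_na(.data$education_fraction_read, 0),
           any_message = .data$n_messages > 0,
           any_measurement = .data$n_measurements > 0,
           any_education = .data$education_fraction_read > 0)
  out
}

#' Login tertile cut points
#'
#' Empirical 1/3 and 2/3 quantiles (nearest rank) of total logins over the
#' supplied cohort -- by convention the whole intervention arm. The point
#' rule is `total <= cut1 -> 0`, `cut1 < total <= cut2 -> 1`,
#' `total > cut2 -> 2`, so ties at a cut fall into the lower tertile.
#'
#' @param summaries Output of [summarize_usage()] (needs >= 3 rows).
#' @param population Label recording which cohort the cuts come from.
#' @return An object of class `eh_tertiles` with `cut1`, `cut2`, `n`.
#' @export
#' @examples
#' s <- tibble::tibble(participant_id = letters[1:9], total_logins = 1:9)
#' login_tertiles(s)
login_tertiles <- function(summaries, population = "intervention") {
  x <- summaries$total_logins
  if (length(x) < 3) {
    abort_config("Tertiles require at least 3 participants.",
                 field = "summaries")
  }
  cuts <- nearest_rank(x, c(1 / 3, 2 / 3))
  if (cuts[1] == cuts[2] && cuts[2] == max(x)) {
    rlang::warn("All login totals equal; every participant falls in tertile 1.",
                class = "ehengage_degenerate_tertiles")
  }
  structure(list(cut1 = cuts[1], cut2 = cuts[2], n = length(x),
                 population = population),
            class = "eh_tertiles")
}

#' @export
print.eh_tertiles <- function(x, ...) {
  cat(sprintf("Login tertiles (%s, n=%d): cut1=%g, cut2=%g\n",
              x$population, x$n, x$cut1, x$cut2))
  invisible(x)
}

login_points <- function(total_logins, tertiles) {
  ifelse(total_logins <= tertiles$cut1, 0L,
         ifelse(total_logins <= tertiles$cut2, 1L, 2L))
}

#' Points for the number of goals set
#'
#' 0 goals scores 0, 1 goal scores 1, two or more score 2.
#'
#' @param n_goals Nonnegative integer vector.
#' @return Integer vector in 0..2.
#' @export
#' @examples
#' goal_points(c(0, 1, 7))
goal_points <- function(n_goals) {
  if (any(n_goals < 0, na.rm = TRUE)) {
    abort_config("`n_goals` must be nonnegative.", field = "n_goals")
  }
  pmin(as.integer(n_goals), 2L)
}

#' Complete the composite engagement score
#'
#' Adds the five component points (login tertile 0-2, goals 0-2, any
#' message 0/1, any measurement 0/1, any education read 0/1), the 0-7
#' composite score, its category (low 0-2, moderate 3-5, high 6-7) and the
#' tertile-based sensitivity categorisation (equal-frequency thirds of the
#' composite score distribution, nearest rank).
#'
#' @param summaries Output of [summarize_usage()] over the scoring cohort.
#' @param tertiles Optional [login_tertiles()]; computed from `summaries`
#'   when omitted. Supply explicitly when scoring a subset against cohort
#'   cuts.
#' @return `summaries` with point, score and category columns appended.
#' @export
#' @examples
#' usage <- list(
#'   logins = tibble::tibble(participant_id = rep(letters[1:9], 1:9),
#'                           day = 1, purpose = "platform"),
#'   goals = tibble::tibble(participant_id = "i", day = 1,
#'                          health_factor = "weight"),
#'   messages = tibble::tibble(participant_id = character(), day = integer()),
#'   measurements = tibble::tibble(participant_id = character(),
#'                                 day = integer(), type = character()),
#'   education = tibble::tibble(participant_id = character(),
#'                              fraction_read = double()))
#' score_engagement(summarize_usage(usage))
score_engagement <- function(summaries, tertiles = NULL) {
  tertiles <- tertiles %||% login_tertiles(summaries)
  out <- summaries %>%
    mutate(
      login_points = login_points(.data$total_logins, tertiles),
      goal_points = goal_points(.data$n_goals),
      message_point = as.integer(.data$any_message),
      measurement_point = as.integer(.data$any_measurement),
      education_point = as.integer(.data$any_education),
      composite_score = .data$login_points + .data$goal_points +
        .data$message_point + .data$measurement_point + .data$education_point,
      category = engagement_category(.data$composite_score)
    )
  scuts <- nearest_rank(out$composite_score, c(1 / 3, 2 / 3))
  out$category_tertile <- factor(
    ifelse(out$composite_score <= scuts[1], "T1",
           ifelse(out$composite_score <= scuts[2], "T2", "T3")),
    levels = c("T1", "T2", "T3"), ordered = TRUE)
  attr(out, "tertiles") <- tertiles
  out
}

#' Map a composite score to its engagement category
#'
#' @param score Integer vector in 0..7.
#' @return Ordered factor low < moderate < high (0-2 / 3-5 / 6-7).
#' @export
#' @examples
#' engagement_category(0:7)
engagement_category <- function(score) {
  if (any(score < 0 | score > 7, na.rm = TRUE)) {
    abort_config("Composite scores must lie in 0..7.", field = "score")
  }
  cut(score, breaks = c(-0.5, 2.5, 5.5, 7.5),
      labels = c("low", "moderate", "high"), ordered_result = TRUE)
}
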