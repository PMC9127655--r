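#' Qualifying login days
#'
#' Days of platform-purpose logins only. Questionnaire-only logins (adverse
#' event questionnaires, study evaluations) do not count as platform use:
#' a participant who logs in solely for those displays nonuse attrition.
#'
#' @param logins Tibble with `participant_id`, `day`, `purpose`.
#' @return The same tibble restricted to platform logins.
#' @export
qualifying_logins <- function(logins) {
  filter(logins, .data$purpose == "platform")
}

# Core window scan for one participant. Fixed consecutive windows of
# `window_days` anchored at day 0; a login at day d falls in window
# d %/% window_days + 1. The event time is the 1-based index of the first
# complete window containing no qualifying login; the trailing partial
# window is ignored.
first_empty_window <- function(days, followup_days, window_days) {
  n_win <- followup_days %/% window_days
  if (n_win < 1) {
    return(list(time = 0L, event = FALSE, followup_windows = 0L))
  }
  win <- days %/% window_days + 1L
  occupied <- tabulate(win[win <= n_win], nbins = n_win) > 0
  idx <- which(!occupied)
  if (length(idx)) {
    list(time = idx[1], event = TRUE, followup_windows = as.integer(n_win))
  } else {
    list(time = as.integer(n_win), event = FALSE,
         followup_windows = as.integer(n_win))
  }
}

# Sliding-gap sensitivity variant: the event occurs as soon as
# `window_days` pass with no qualifying login (counting from day 0 and from
# each login); reported on the same monthly index scale, i.e. the window
# containing the day the gap completes.
first_gap_event <- function(days, followup_days, window_days) {
  n_win <- followup_days %/% window_days
  if (n_win < 1) {
    return(list(time = 0L, event = FALSE, followup_windows = 0L))
  }
  pts <- sort(unique(c(0, days[days <= followup_days])))
  gaps_end <- c(pts[-1], followup_days)
  gap_from <- pts
  over <- which(gaps_end - gap_from > window_days)
  if (length(over)) {
    d <- gap_from[over[1]] + window_days
    t <- min(as.integer(d %/% window_days) + 1L, n_win)
    list(time = t, event = TRUE, followup_windows = as.integer(n_win))
  } else {
    list(time = as.integer(n_win), event = FALSE,
         followup_windows = as.integer(n_win))
  }
}

#' Time to first nonuse attrition
#'
#' Builds one record per participant: the index of the first 30-day (or
#' 42-day, for the 6-week sensitivity definition) window with no qualifying
#' platform login, an event indicator (censored at the end of individual
#' follow-up when no such window exists), and the attrition group -- `early`
#' (event in windows 1-2), `late` (window 3 on) or `consistent` (no event).
#'
#' @param logins Login events (`participant_id`, `day`, `purpose`).
#' @param participants Roster with `participant_id` and `followup_days`;
#'   every roster participant gets a record even with zero logins.
#' @param window_days Window length in days: 30 (default) or 42.
#' @param method `"fixed"` (consecutive windows anchored at day 0, default)
#'   or `"sliding"` (gap-based sensitivity variant).
#' @return Tibble: participant_id, window_days, time_months, event,
#'   followup_windows, group.
#' @export
#' @examples
#' logins <- tibble::tibble(participant_id = "A", day = c(5, 40),
#'                          purpose = "platform")
#' roster <- tibble::tibble(participant_id = "A", followup_days = 540)
#' attrition_records(logins, roster)
attrition_records <- function(logins, participants, window_days = 30,
                              method = c("fixed", "sliding")) {
  method <- rlang::arg_match(method)
  if (!window_days %in% c(30, 42)) {
    abort_config("`window_days` must be 30 or 42.", field = "window_days")
  }
  q <- qualifying_logins(logins)
  days_by_id <- split(q$day, q$participant_id)
  scan <- if (method == "fixed") first_empty_window else first_gap_event
  short <- 0L
  rec <- purrr::map(seq_len(nrow(participants)), function(i) {
    id <- participants$participant_id[i]
    r <- scan(days_by_id[[id]] %||% integer(), participants$followup_days[i],
              window_days)
    if (r$followup_windows == 0L) short <<- short + 1L
    tibble(participant_id = id, window_days = as.integer(window_days),
           time_months = r$time, event = r$event,
           followup_windows = r$followup_windows)
  }) %>% bind_rows()
  if (short > 0) {
    rlang::warn(sprintf(
      "%d participant(s) followed for less than one %d-day window; censored at 0.",
      short, window_days), class = "ehengage_short_followup")
  }
  rec %>%
    mutate(group = factor(
      ifelse(!.data$event, "consistent",
             ifelse(.data$time_months <= 2, "early", "late")),
      levels = c("early", "late", "consistent")))
}

#' Summarise attrition groups
#'
#' Counts and shares of early / late attrition and highly consistent users,
#' with the consistent users split into those covering the full 18 windows
#' and those who logged in every month they were enrolled but dropped out of
#' the study before 18 months.
#'
#' @param records Output of [attrition_records()].
#' @return A tibble with one row per group plus a `consistent_dropped` row.
#' @export
classify_consistency <- function(records) {
  n_total <- nrow(records)
  base <- records %>%
    count(.data$group, .drop = FALSE) %>%
    mutate(share = .data$n / n_total,
           group = as.character(.data$group))
  cd <- records %>%
    filter(.data$group == "consistent", .data$followup_windows < 18) %>%
    nrow()
  bind_rows(base,
            tibble(group = "consistent_dropped", n = cd,
                   share = cd / n_total))
}
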