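# Shared fixtures and independent oracles used across the test files.

empty_usage <- function() {
  list(
    logins = tibble::tibble(participant_id = character(), day = integer(),
                            purpose = character()),
    goals = tibble::tibble(participant_id = character(), day = integer(),
                           health_factor = character()),
    messages = tibble::tibble(participant_id = character(), day = integer()),
    measurements = tibble::tibble(participant_id = character(),
                                  day = integer(), type = character()),
    education = tibble::tibble(participant_id = character(),
                               fraction_read = double()))
}

usage_for <- function(id, login_days = integer(),
                      login_purpose = "platform",
                      goal_days = integer(), message_days = integer(),
                      measurement_days = integer(), fraction_read = 0) {
  u <- empty_usage()
  if (length(login_days)) {
    u$logins <- tibble::tibble(participant_id = id, day = login_days,
                               purpose = rep_len(login_purpose,
                                                 length(login_days)))
  }
  if (length(goal_days)) {
    u$goals <- tibble::tibble(participant_id = id, day = goal_days,
                              health_factor = "weight")
  }
  if (length(message_days)) {
    u$messages <- tibble::tibble(participant_id = id, day = message_days)
  }
  if (length(measurement_days)) {
    u$measurements <- tibble::tibble(participant_id = id,
                                     day = measurement_days, type = "weight")
  }
  if (fraction_read > 0) {
    u$education <- tibble::tibble(participant_id = id,
                                  fraction_read = fraction_read)
  }
  u
}

bind_usage <- function(...) {
  us <- list(...)
  out <- empty_usage()
  for (nm in names(out)) {
    out[[nm]] <- dplyr::bind_rows(lapply(us, `[[`, nm))
  }
  out
}

# Brute-force attrition oracle: literally check every window with any().
brute_attrition <- function(days, followup_days, window_days) {
  n_win <- followup_days %/% window_days
  if (n_win < 1) return(list(time = 0L, event = FALSE))
  for (k in seq_len(n_win)) {
    lo <- (k - 1) * window_days
    hi <- k * window_days
    if (!any(days >= lo & days < hi)) {
      return(list(time = k, event = TRUE))
    }
  }
  list(time = n_win, event = FALSE)
}

# Independent Cox partial log-likelihood: naive per-event loops written
# directly from the definition, no shared code with the package internals.
naive_cox_loglik <- function(beta, time, event, x, ties = "breslow",
                             entry = rep(0, length(time))) {
  x <- as.matrix(x)
  lp <- drop(x %*% beta)
  ll <- 0
  for (t in sort(unique(time[event]))) {
    deaths <- which(event & time == t)
    risk <- which(entry < t & time >= t)
    d <- length(deaths)
    ll <- ll + sum(lp[deaths])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(lp[risk])))
    } else {
      sr <- sum(exp(lp[risk]))
      sd_ <- sum(exp(lp[deaths]))
      for (l in seq_len(d) - 1) ll <- ll - log(sr - (l / d) * sd_)
    }
  }
  ll
}

small_cfg <- function(seed, ni = 120, nc = 80, ...) {
  sim_config(seed = seed, n_intervention = ni, n_control = nc, ...)
}

# Random login stream generator for property tests: mixes sparse and dense
# streams, with questionnaire logins interleaved.
random_log <- function(followup_days = sample(c(45, 200, 360, 548), 1)) {
  n_platform <- rpois(1, runif(1, 0, 25))
  days <- sort(sample(0:(followup_days - 1), n_platform, replace = TRUE))
  q_days <- seq(90, 540, by = 90)
  q_days <- q_days[q_days <= followup_days]
  list(platform = days, questionnaire = q_days, followup = followup_days)
}
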