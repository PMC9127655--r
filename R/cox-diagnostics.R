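#' Proportional-hazards diagnostic (Grambsch-Therneau score test)
#'
#' Tests, per covariate and globally, whether the scaled Schoenfeld
#' residuals drift with time -- the classical score test of the
#' proportional-hazards assumption. The default time transform is the
#' identity; a Kaplan-Meier transform (left-continuous survival estimate at
#' the event times) is available behind the `transform` flag.
#'
#' @param fit An [cox_fit()] object with at least 2 events and at least one
#'   covariate.
#' @param transform `"identity"` (default) or `"km"`.
#' @return A tibble with one row per coefficient plus a `GLOBAL` row:
#'   `term`, `chisq`, `df`, `p.value`.
#' @export
ph_test <- function(fit, transform = c("identity", "km")) {
  transform <- rlang::arg_match(transform)
  if (!inherits(fit, "eh_cox")) abort_fit("`fit` must come from cox_fit().")
  if (fit$nevent < 2) abort_fit("PH test requires at least 2 events.")
  if (!length(fit$coefficients)) abort_fit("PH test requires covariates.")

  sres <- fit$schoenfeld
  times <- fit$schoenfeld_time
  d <- nrow(sres)
  g <- if (transform == "identity") {
    times
  } else {
    sf <- survival::survfit(
      survival::Surv(fit$start_time, fit$stop_time, fit$event) ~ 1)
    # Left-continuous KM at each event time: 1 - S(t-).
    stp <- stats::stepfun(sf$time, c(1, sf$surv))
    1 - vapply(times, function(t) stp(t - 1e-9), numeric(1))
  }
  gc <- g - mean(g)
  sg2 <- sum(gc^2)
  V <- fit$vcov
  u <- drop(crossprod(sres, gc))                 # p-vector
  ustar <- d * drop(V %*% u)                     # scaled-residual projections
  per <- ustar^2 / (d * diag(V) * sg2)
  global <- d * drop(crossprod(u, V %*% u)) / sg2
  p <- length(u)
  tibble(
    term = c(names(fit$coefficients), "GLOBAL"),
    chisq = c(per, global),
    df = c(rep(1L, p), p),
    p.value = stats::pchisq(c(per, global), df = c(rep(1, p), p),
                            lower.tail = FALSE))
}

#' Split follow-up into early and late periods
#'
#' The published analysis splits follow-up at month 2 because proportional
#' hazards failed over the full period. The early dataset keeps every
#' participant, with events after `cut_months` censored at the cut; the late
#' dataset keeps only participants event-free through the cut (event or
#' censoring time at `cut_months + 1` or later), entering the risk set at
#' the cut (delayed entry, preserving the original month scale).
#'
#' @param records Attrition records (joined with covariates as needed):
#'   must contain `time_months` and `event`.
#' @param cut_months Split point in 30-day windows (default 2).
#' @return A list with tibbles `early` (extra columns `time_early`,
#'   `event_early`) and `late` (extra columns `entry`, `time_late`,
#'   `event_late`).
#' @export
split_followup <- function(records, cut_months = 2) {
  early <- records %>%
    mutate(time_early = pmin(.data$time_months, cut_months),
           event_early = .data$event & .data$time_months <= cut_months)
  late <- records %>%
    filter(.data$time_months >= cut_months + 1) %>%
    mutate(entry = cut_months, time_late = .data$time_months,
           event_late = .data$event)
  if (nrow(late) == 0) {
    rlang::warn("Late period is empty: the cut is at or beyond maximum follow-up.",
                class = "ehengage_empty_period_warning")
  }
  list(early = early, late = late)
}

#' Backward elimination for Cox models
#'
#' Same strategy as [backward_eliminate()] for the ordinal model: repeatedly
#' refit, removing the term with the largest joint Wald p-value above
#' `alpha` (categorical terms removed whole), until all remaining terms are
#' significant. When every term is removed the null model (no coefficients)
#' is returned with a warning.
#'
#' @inheritParams cox_fit
#' @param alpha Retention threshold (default 0.05).
#' @return The final `eh_cox`, with attribute `elimination`.
#' @export
cox_backward_eliminate <- function(data, terms, alpha = 0.05,
                                   time = "time_months", event = "event",
                                   entry = NULL, ties = c("efron", "breslow")) {
  ties <- rlang::arg_match(ties)
  path <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (!length(terms)) {
      rlang::warn("All terms eliminated; returning null Cox model.",
                  class = "ehengage_empty_model_warning")
      fit <- cox_fit(data, character(0), time = time, event = event,
                     entry = entry, ties = ties)
      break
    }
    fit <- cox_fit(data, terms, time = time, event = event, entry = entry,
                   ties = ties)
    pvals <- vapply(seq_along(terms), function(ti) {
      k <- which(fit$assign == ti)
      wald_chisq(fit$coefficients[k], fit$vcov[k, k, drop = FALSE])$p.value
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] > alpha) {
      path[[step]] <- tibble(step = step, dropped = terms[worst],
                             p.value = pvals[worst])
      terms <- terms[-worst]
    } else {
      break
    }
  }
  attr(fit, "elimination") <- bind_rows(path)
  fit
}
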