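#' Sample a synthetic baseline roster
#'
#' Draws the two-arm cohort: baseline covariates with the configured
#' marginals, a latent "digital literacy" factor tying together computer use,
#' education and cognition, individual follow-up duration, the latent
#' engagement propensity (planted covariate effects plus logistic-scale
#' noise), and the latent attrition class (early / late quitter or consistent
#' user) with its cessation window.
#'
#' Seeds the RNG from `config$seed`, so the same configuration always yields
#' a byte-identical roster.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with one row per participant. Columns `propensity`,
#'   `latent_class` and `cessation_window` are generator latents retained for
#'   self-consistency checks; they are not written by [write_trial()].
#' @export
#' @examples
#' sample_baseline(sim_config(seed = 1, n_intervention = 20, n_control = 10))
sample_baseline <- function(config) {
  stopifnot(inherits(config, "eh_sim_config"))
  set.seed(config$seed)
  cov <- config$covariates
  n <- config$n_intervention + config$n_control
  if (n == 0) abort_config("Empty cohort.", field = "n_intervention")

  arm <- factor(rep(c("intervention", "control"),
                    c(config$n_intervention, config$n_control)),
                levels = c("intervention", "control"))

  # Latent digital-literacy factor: shared standard-normal component so that
  # computer use, education and cognition are positively associated while
  # each keeps its configured marginal (thresholds on a standard normal).
  rho <- cov$digital_rho
  u <- rnorm(n)
  mix_latent <- function() rho * u + sqrt(1 - rho^2) * rnorm(n)
  cut_ordered <- function(z, probs, labels) {
    br <- c(-Inf, qnorm(cumsum(probs))[-length(probs)], Inf)
    factor(labels[findInterval(z, br)], levels = labels, ordered = TRUE)
  }

  education <- cut_ordered(mix_latent(), cov$education,
                           c("low", "medium", "high"))
  computer_use <- cut_ordered(mix_latent(), cov$computer_use,
                              c("none", "lt7h_week", "ge7h_week"))
  cognition_z <- cov$cognition$mean + cov$cognition$sd * mix_latent()

  age <- cov$age$min + stats::rgamma(n, shape = cov$age$shape,
                                     scale = cov$age$scale)
  lifestyle <- factor(
    sample(names(cov$lifestyle), n, replace = TRUE, prob = cov$lifestyle),
    levels = names(cov$lifestyle), ordered = TRUE)
  country <- factor(sample(names(cov$country), n, replace = TRUE,
                           prob = cov$country),
                    levels = c("NL", "FR", "FI"))

  dropout <- runif(n) < cov$dropout_prop
  followup_days <- ifelse(
    dropout,
    sample(seq(cov$dropout_min_day, config$max_followup_days - 1L), n,
           replace = TRUE),
    config$max_followup_days)

  roster <- tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    arm = arm,
    age = age,
    sex = factor(ifelse(runif(n) < cov$sex_male, "male", "female"),
                 levels = c("female", "male")),
    education = education,
    country = country,
    living_with_partner = runif(n) < cov$living_with_partner,
    cognition_z = cognition_z,
    sppb_lt10 = runif(n) < cov$sppb_lt10,
    depressive_symptoms = runif(n) < cov$depressive,
    hads_anxiety = pmin(21L, as.integer(round(
      stats::rgamma(n, shape = cov$hads$shape, scale = cov$hads$scale)))),
    cvd_history = runif(n) < cov$cvd,
    diabetes = runif(n) < cov$diabetes,
    hypertension = runif(n) < cov$hypertension,
    dyslipidemia = runif(n) < cov$dyslipidemia,
    smoking = runif(n) < cov$smoking,
    physically_active = runif(n) < cov$active,
    obese = runif(n) < cov$obese,
    medas = pmin(14L, pmax(0L, as.integer(round(
      rnorm(n, cov$medas$mean, cov$medas$sd))))),
    pih = pmin(cov$pih$max, pmax(0L, as.integer(round(
      cov$pih$max - stats::rgamma(n, shape = cov$pih$shape,
                                  scale = cov$pih$scale))))),
    lifestyle_stage = lifestyle,
    computer_use = computer_use,
    followup_days = as.integer(followup_days)
  )

  elo <- config$engagement_log_odds
  eta <- with(roster,
    elo["country_FR"] * (country == "FR") +
    elo["country_FI"] * (country == "FI") +
    elo["lifestyle_long_term_plans"] * (lifestyle_stage == "long_term_plans") +
    elo["lifestyle_short_term_plans"] * (lifestyle_stage == "short_term_plans") +
    elo["lifestyle_short_term_acting"] * (lifestyle_stage == "short_term_acting") +
    elo["lifestyle_long_term_acting"] * (lifestyle_stage == "long_term_acting") +
    elo["computer_lt7h_week"] * (computer_use == "lt7h_week") +
    elo["computer_ge7h_week"] * (computer_use == "ge7h_week") +
    elo["cognition_z"] * cognition_z +
    elo["sex_male"] * (sex == "male"))
  roster$propensity <- as.numeric(eta) + rnorm(n, sd = config$propensity_sd)

  eta_c <- roster$propensity - expected_propensity(config)
  mix <- config$attrition_mixture
  # Latent attrition score: higher propensity pushes towards consistent use.
  # Thresholding at the empirical quantiles of the score keeps the marginal
  # class shares at the configured mixture regardless of the covariate
  # distribution, while preserving the propensity-class association.
  G <- mix$eta_slope * eta_c + stats::rlogis(n)
  cuts <- stats::quantile(G, c(mix$early, mix$early + mix$late), type = 1,
                          names = FALSE)
  cls <- ifelse(G <= cuts[1], "early",
                ifelse(G <= cuts[2], "late", "consistent"))
  # Cessation window: the first 30-day window with no platform login.
  # Early quitters quit in window 1-2; late quitters from window 3 on, with a
  # geometric tail giving the KM curve its post-month-2 shoulder.
  cess <- rep(NA_integer_, n)
  cess[cls == "early"] <- sample(1:2, sum(cls == "early"), replace = TRUE)
  cess[cls == "late"] <- pmin(18L, 2L + 1L +
    stats::rgeom(sum(cls == "late"), prob = mix$late_geom_p))
  roster$latent_class <- cls
  roster$cessation_window <- cess
  roster
}

#' Sample usage logs for a roster
#'
#' Generates the event streams of the intervention platform: platform logins
#' (window-wise Poisson counts while the participant's latent class keeps
#' them active, at an intensity increasing with the planted engagement
#' propensity), questionnaire-only logins near each scheduled quarterly day,
#' goal-setting events with health-factor labels, coach messages, monitoring
#' measurements, and the fraction of education material read. Control-arm
#' participants produce sparse untagged platform logins only.
#'
#' Consumes the RNG stream; call `set.seed()` first (or use
#' [simulate_trial()], which seeds everything) for reproducibility.
#'
#' @param participants Roster from [sample_baseline()] (any subset of rows).
#' @param config The same [sim_config()] object.
#' @return A list of tibbles: `logins` (participant_id, day, purpose),
#'   `goals` (participant_id, day, health_factor), `messages`
#'   (participant_id, day), `measurements` (participant_id, day, type) and
#'   `education` (participant_id, fraction_read).
#' @export
sample_usage_log <- function(participants, config) {
  stopifnot(inherits(config, "eh_sim_config"))
  if (any(participants$followup_days <= 0 |
          participants$followup_days > config$max_followup_days)) {
    abort_config("`followup_days` out of bounds for this configuration.",
                 field = "followup_days")
  }
  usg <- config$usage
  w <- config$window_days
  eta_c <- participants$propensity - expected_propensity(config)

  int <- participants$arm == "intervention"
  n <- nrow(participants)
  n_windows <- pmin(18L, participants$followup_days %/% w)
  active <- ifelse(participants$latent_class == "consistent",
                   n_windows,
                   pmin(participants$cessation_window - 1L, n_windows))
  active[!int] <- 0L

  # Platform logins: >=1 per active window (zero-truncated Poisson) so the
  # latent cessation window is exactly the first empty window. Built as one
  # flat (participant-window) expansion rather than per-participant frames.
  mu_login <- exp(usg$login_base + usg$login_slope * eta_c)
  iw_part <- rep(seq_len(n), ifelse(int, pmax(active, 0L), 0L))
  iw_win <- sequence(ifelse(int, pmax(active, 0L), 0L))
  cnt <- 1L + rpois(length(iw_part), mu_login[iw_part])
  plat_part <- rep(iw_part, cnt)
  plat_day <- (rep(iw_win, cnt) - 1L) * w +
    sample(0:(w - 1L), sum(cnt), replace = TRUE)

  ctl_part <- rep(seq_len(n), ifelse(!int, pmax(n_windows, 0L), 0L))
  ctl_win <- sequence(ifelse(!int, pmax(n_windows, 0L), 0L))
  ccnt <- rpois(length(ctl_part), usg$control_login_mean)
  ctl_part2 <- rep(ctl_part, ccnt)
  ctl_day <- if (length(ctl_part2)) {
    (rep(ctl_win, ccnt) - 1L) * w + sample(0:(w - 1L), sum(ccnt),
                                           replace = TRUE)
  } else integer()

  # Questionnaire logins: near each scheduled day still inside follow-up.
  sched <- config$questionnaire_schedule_days
  jit <- config$questionnaire_jitter_days
  n_sched <- vapply(participants$followup_days,
                    function(f) sum(sched <= f), integer(1))
  n_sched[!int] <- 0L
  q_part <- rep(seq_len(n), n_sched)
  q_sched <- unlist(lapply(seq_len(n)[n_sched > 0],
                           function(i) sched[seq_len(n_sched[i])]))
  q_day <- if (length(q_part)) {
    pmax(0L, pmin(participants$followup_days[q_part],
                  q_sched + sample(seq(-jit, jit), length(q_part),
                                   replace = TRUE)))
  } else integer()

  logins <- tibble(
    participant_id = participants$participant_id[c(plat_part, ctl_part2,
                                                   q_part)],
    day = as.integer(c(plat_day, ctl_day, q_day)),
    purpose = rep(c("platform", "questionnaire_only"),
                  c(length(plat_part) + length(ctl_part2),
                    length(q_part)))) %>%
    arrange(.data$participant_id, .data$day)

  # Remaining components, intervention arm only. Counts scale with the
  # propensity and (weakly) with time on platform.
  idx <- which(int)
  dur <- ((active[idx] + 1) / 18)^0.25
  pid <- participants$participant_id[idx]
  fup <- participants$followup_days[idx]

  any_goal <- runif(length(idx)) <
    plogis(usg$goal_any_base + usg$goal_any_slope * eta_c[idx])
  n_goals <- ifelse(any_goal,
                    1L + rpois(length(idx),
                               exp(usg$goal_extra_base +
                                     usg$goal_extra_slope * eta_c[idx])),
                    0L)
  hf_levels <- c("weight", "physical_activity", "nutrition", "blood_pressure",
                 "cholesterol", "diabetes", "smoking", "other")
  hf_prob <- c(0.30, 0.25, 0.20, 0.10, 0.07, 0.04, 0.02, 0.02)
  goals <- tibble(
    participant_id = rep(pid, n_goals),
    day = as.integer(runif(sum(n_goals)) * pmin(120, rep(fup, n_goals))),
    health_factor = sample(hf_levels, sum(n_goals), TRUE, hf_prob))

  n_msg <- rpois(length(idx),
                 exp(usg$message_base + usg$message_slope * eta_c[idx]) * dur)
  messages <- tibble(
    participant_id = rep(pid, n_msg),
    day = as.integer(runif(sum(n_msg)) *
                       pmax(rep(pmax(active[idx], 1L) * w, n_msg) - 1L, 1L)))

  n_meas <- rpois(length(idx),
                  exp(usg$measurement_base + usg$measurement_slope * eta_c[idx]) * dur)
  meas_type <- c("physical_activity", "weight", "blood_pressure")
  measurements <- tibble(
    participant_id = rep(pid, n_meas),
    day = as.integer(runif(sum(n_meas)) *
                       pmax(rep(pmax(active[idx], 1L) * w, n_meas) - 1L, 1L)),
    type = sample(meas_type, sum(n_meas), TRUE, c(0.4, 0.3, 0.3)))

  any_edu <- runif(length(idx)) <
    plogis(usg$education_any_base + usg$education_any_slope * eta_c[idx])
  frac <- ifelse(any_edu,
                 rbeta(length(idx), usg$education_beta[1], usg$education_beta[2]),
                 0)
  education <- tibble(participant_id = pid, fraction_read = frac)

  list(logins = logins, goals = goals, messages = messages,
       measurements = measurements, education = education)
}

#' Sample baseline and 18-month outcomes
#'
#' Each outcome is generated as a baseline draw plus an 18-month change
#' composed of secular drift, linear covariate terms (age, sex, cognition,
#' smoking), the planted effect for the participant's engagement category
#' (zero for controls), and Gaussian noise. Values below physiologic floors
#' (SBP 70 mm Hg, BMI 14 kg/m^2, LDL 0.5 mmol/L, zero elsewhere) are
#' truncated with a warning.
#'
#' @param participants Roster rows.
#' @param category Character vector (length 1 or `nrow(participants)`) in
#'   `control`, `low`, `moderate`, `high`.
#' @param config The [sim_config()] object.
#' @return Long tibble: participant_id, timepoint (`baseline`/`month18`),
#'   variable, value.
#' @export
sample_outcomes <- function(participants, category, config) {
  stopifnot(inherits(config, "eh_sim_config"))
  n <- nrow(participants)
  category <- rep_len(as.character(category), n)
  bad <- setdiff(unique(category), c("control", "low", "moderate", "high"))
  if (length(bad)) {
    abort_config(paste0("Unknown engagement category: ",
                        paste(bad, collapse = ", ")), field = "category")
  }
  op <- config$outcome_params
  sl <- op$cov_slopes
  covterm <- sl$age * (participants$age - 70) +
    sl$sex_male * (participants$sex == "male") +
    sl$cognition_z * participants$cognition_z +
    sl$smoking * participants$smoking
  vars <- c("sbp", "ldl", "bmi", "phys_act", "medas", "caide", "score_op")
  n_trunc <- 0L
  out <- purrr::map(vars, function(v) {
    p <- op[[v]]
    base <- if (v == "medas") as.numeric(participants$medas) else
      rnorm(n, p$mean, p$sd)
    base <- pmax(base, p$floor)
    eff <- ifelse(category == "control", 0,
                  config$outcome_effects[v, ][category])
    # Covariate terms scaled to the outcome's SD so adjustment matters
    # comparably across outcomes.
    chg <- p$drift + covterm * p$sd / 16 + eff + rnorm(n, 0, p$noise)
    m18 <- base + chg
    k <- sum(m18 < p$floor)
    n_trunc <<- n_trunc + k
    m18 <- pmax(m18, p$floor)
    tibble(participant_id = rep(participants$participant_id, 2),
           timepoint = rep(c("baseline", "month18"), each = n),
           variable = v, value = c(base, m18))
  }) %>% bind_rows()
  if (n_trunc > 0) {
    rlang::warn(sprintf("%d outcome values truncated at physiologic floors.",
                        n_trunc), class = "ehengage_truncation_warning")
  }
  out
}

#' Simulate a complete synthetic trial
#'
#' Runs [sample_baseline()], [sample_usage_log()], scores intervention-arm
#' engagement with the package's own scoring pipeline to obtain each
#' participant's realized category, and then draws outcomes with the planted
#' category effects, so dose-response estimators downstream can be checked
#' against known truth. Fully determined by `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `eh_trial`: `participants`, `usage` (list of
#'   event tibbles), `engagement` (scored summaries, intervention arm),
#'   `outcomes`, and the `config`.
#' @export
#' @examples
#' trial <- simulate_trial(sim_config(seed = 1, n_intervention = 60,
#'                                    n_control = 40))
#' dplyr::count(trial$engagement, category)
simulate_trial <- function(config) {
  participants <- sample_baseline(config)
  usage <- sample_usage_log(participants, config)
  eng <- summarize_usage(usage,
                         participants = filter(participants,
                                               .data$arm == "intervention"))
  eng <- score_engagement(eng)
  category <- tibble(participant_id = participants$participant_id) %>%
    left_join(select(eng, "participant_id", "category"),
              by = "participant_id") %>%
    mutate(category = ifelse(is.na(.data$category), "control",
                             as.character(.data$category))) %>%
    pull(.data$category)
  outcomes <- sample_outcomes(participants, category, config)
  structure(list(participants = participants, usage = usage,
                 engagement = eng, outcomes = outcomes, config = config),
            class = "eh_trial")
}

#' Write a simulated trial to the canonical CSV layout
#'
#' Emits `participants.csv`, `logins.csv`, `goals.csv`, `messages.csv`,
#' `measurements.csv`, `education.csv` and `outcomes.csv` into `dir`.
#' Generator latents (propensity, latent class, cessation window) are
#' dropped: the written files follow the schema an analysis of real usage
#' logs would start from.
#'
#' @param trial An `eh_trial` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "eh_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- select(trial$participants, -any_of(c("propensity", "latent_class",
                                            "cessation_window")))
  readr::write_csv(p, file.path(dir, "participants.csv"))
  readr::write_csv(trial$usage$logins, file.path(dir, "logins.csv"))
  readr::write_csv(trial$usage$goals, file.path(dir, "goals.csv"))
  readr::write_csv(trial$usage$messages, file.path(dir, "messages.csv"))
  readr::write_csv(trial$usage$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(trial$usage$education, file.path(dir, "education.csv"))
  readr::write_csv(trial$outcomes, file.path(dir, "outcomes.csv"))
  invisible(dir)
}

#' Sample an ordered outcome from a (partial) proportional-odds model
#'
#' Draws Y with cumulative probabilities
#' `P(Y > j | x) = logistic(alpha_j + x' beta[, j])`, the exact data-
#' generating process of [gologit()]; used for planted-parameter recovery
#' and calibration studies. Supplying a `beta` matrix with equal columns
#' gives a proportional-odds truth; unequal columns plant a parallel-lines
#' violation. Covariate combinations implying decreasing category
#' probabilities (possible when columns differ) raise an error.
#'
#' @param X Numeric model matrix (no intercept column), n x p.
#' @param alpha Thresholds, length J-1, decreasing.
#' @param beta p x (J-1) coefficient matrix (or length-p vector, recycled
#'   across equations).
#' @param levels Outcome level labels (length J).
#' @return An ordered factor of length `nrow(X)`.
#' @export
sample_ordinal_outcome <- function(X, alpha,
                                   beta,
                                   levels = c("low", "moderate", "high")) {
  X <- as.matrix(X)
  nalpha <- length(alpha)
  if (length(levels) != nalpha + 1) {
    abort_config("`levels` must have length(alpha) + 1 entries.",
                 field = "levels")
  }
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = length(beta), ncol = nalpha)
  P <- vapply(seq_len(nalpha),
              function(j) plogis(alpha[j] + drop(X %*% beta[, j])),
              numeric(nrow(X)))
  catp <- cbind(1, P) - cbind(P, 0)
  if (any(catp < -1e-12)) {
    abort_config("Planted parameters imply negative category probabilities.",
                 field = "beta")
  }
  catp <- pmax(catp, 0)
  y <- vapply(seq_len(nrow(X)),
              function(i) sample.int(nalpha + 1, 1, prob = catp[i, ]),
              integer(1))
  factor(levels[y], levels = levels, ordered = TRUE)
}

#' Sample exponential survival times with a planted hazard ratio
#'
#' Event times from hazard `rate * exp(x' beta)` with administrative
#' censoring at `censor_time`; optionally rounded up to whole 30-day-window
#' indices to mimic the monthly attrition grid (heavy ties).
#'
#' @param X Numeric model matrix, n x p.
#' @param beta Length-p log hazard ratios.
#' @param rate Baseline hazard rate.
#' @param censor_time Administrative censoring time.
#' @param discretize If `TRUE`, report `ceiling(time)` (monthly grid).
#' @return Tibble with `time`, `event`.
#' @export
sample_survival_times <- function(X, beta, rate = 0.2, censor_time = 18,
                                  discretize = TRUE) {
  X <- as.matrix(X)
  t <- stats::rexp(nrow(X), rate = rate * exp(drop(X %*% beta)))
  event <- t <= censor_time
  t <- pmin(t, censor_time)
  if (discretize) t <- pmax(ceiling(t), 1)
  tibble(time = t, event = event)
}
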