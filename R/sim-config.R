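#' Configuration for the synthetic two-arm trial generator
#'
#' Builds the full parameter set that drives [simulate_trial()] and its
#' components. Defaults emulate an 18-month coach-supported eHealth lifestyle
#' trial in adults aged 65+ across the Netherlands, France and Finland:
#' roughly 1389 intervention and 1335 control participants, baseline covariate
#' marginals matching the published cohort description, a login process whose
#' Kaplan-Meier nonuse-attrition curve is reverse-sigmoidal (early/late/
#' consistent latent classes), scheduled quarterly questionnaire logins, an
#' engagement propensity driven by planted covariate odds ratios, and
#' 18-month outcome changes with a planted engagement-graded effect.
#'
#' All randomness is governed by `seed`; identical configurations produce
#' byte-identical output.
#'
#' @param seed Integer seed (mandatory).
#' @param n_intervention,n_control Arm sizes.
#' @param covariates Named list of marginal distribution parameters; see
#'   Details. Partial lists override defaults element-wise.
#' @param engagement_log_odds Named numeric vector of planted covariate
#'   effects on the latent engagement propensity (log odds-ratio scale).
#' @param propensity_sd SD of the latent propensity noise (logistic-scale
#'   individual heterogeneity).
#' @param attrition_mixture List with elements `early`, `late`, `consistent`
#'   (proportions summing to 1), `eta_slope` (how strongly propensity shifts
#'   class membership) and `late_geom_p` (geometric tail of late cessation
#'   months, giving the sigmoidal curve its shoulder).
#' @param usage Named list of usage-intensity parameters (Poisson log-means
#'   and propensity slopes for logins, goals, messages, measurements, and the
#'   education-read hurdle).
#' @param questionnaire_schedule_days Days on which an adverse-event
#'   questionnaire (or study evaluation) login is requested; default every 90
#'   days up to day 540.
#' @param questionnaire_jitter_days Maximum absolute jitter around scheduled
#'   questionnaire days (must be <= 7 to preserve the schedule property).
#' @param outcome_params Named list of per-outcome baseline means/SDs, secular
#'   drift, change-noise SDs and physiologic floors.
#' @param outcome_effects 7 x 3 numeric matrix (rows = outcomes, columns =
#'   `low`, `moderate`, `high`) of planted adjusted mean differences in
#'   18-month change versus control, on each outcome's natural scale.
#'
#' @details
#' `covariates` fields: `sex_male`, `education` (low/medium/high),
#' `country` (NL/FR/FI), `living_with_partner`, `age` (shifted-gamma:
#' `min`, `shape`, `scale`), `cognition` (`mean`, `sd`), `sppb_lt10`,
#' `depressive`, `hads` (gamma `shape`, `scale`, rounded, capped at 21),
#' `cvd`, `diabetes`, `hypertension`, `dyslipidemia`, `smoking`, `active`,
#' `obese`, `medas` (`mean`, `sd`, rounded into 0-14), `pih` (`max`,
#' `shape`, `scale`), `lifestyle` (5 ordered stages), `computer_use`
#' (none / <7 h/week / >=7 h/week), `digital_rho` (latent correlation tying
#' computer use, education and cognition together), `dropout_prop` and
#' `dropout_min_day` (early study dropout before day 548).
#'
#' The default planted composite-z effect is -0.08 (high), -0.04 (moderate),
#' 0.00 (low), entered on each component's scale as effect * baseline SD so
#' the implied composite-z contrast equals the planted value exactly.
#'
#' @return A list of class `eh_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_intervention = 50, n_control = 50)
#' cfg$attrition_mixture$early
sim_config <- function(seed,
                       n_intervention = 1389,
                       n_control = 1335,
                       covariates = list(),
                       engagement_log_odds = NULL,
                       propensity_sd = 1.0,
                       attrition_mixture = list(),
                       usage = list(),
                       questionnaire_schedule_days = seq(90, 540, by = 90),
                       questionnaire_jitter_days = 3,
                       outcome_params = list(),
                       outcome_effects = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_config("`seed` must be a single integer.", field = "seed")
  }

  cov_def <- list(
    sex_male = 0.527,
    education = c(low = 0.300, medium = 0.305, high = 0.395),
    country = c(NL = 0.552, FR = 0.128, FI = 0.320),
    living_with_partner = 0.725,
    age = list(min = 65, shape = 2, scale = 3.2),
    cognition = list(mean = 0, sd = 0.6),
    sppb_lt10 = 0.157,
    depressive = 0.086,
    hads = list(shape = 2, scale = 2.2),
    cvd = 0.305,
    diabetes = 0.213,
    hypertension = 0.833,
    dyslipidemia = 0.963,
    smoking = 0.069,
    active = 0.658,
    obese = 0.381,
    medas = list(mean = 6.1, sd = 2.0),
    pih = list(max = 96, shape = 2.5, scale = 4),
    lifestyle = c(no_plans = 0.072, long_term_plans = 0.104,
                  short_term_plans = 0.148, short_term_acting = 0.181,
                  long_term_acting = 0.495),
    computer_use = c(none = 0.031, lt7h_week = 0.566, ge7h_week = 0.403),
    digital_rho = 0.45,
    dropout_prop = 0.12,
    dropout_min_day = 30
  )
  cov <- utils::modifyList(cov_def, covariates)

  # Planted propensity effects on the log odds-ratio scale of the published
  # final engagement model: country, lifestyle-change stage, computer use,
  # plus a cognition effect. Sex is left null by default.
  elo_def <- c(
    country_FR = log(1.41), country_FI = log(1.55),
    lifestyle_long_term_plans = log(1.20),
    lifestyle_short_term_plans = log(2.25),
    lifestyle_short_term_acting = log(1.51),
    lifestyle_long_term_acting = log(2.02),
    computer_lt7h_week = log(5.39), computer_ge7h_week = log(6.58),
    cognition_z = log(1.65),
    sex_male = 0
  )
  elo <- elo_def
  if (!is.null(engagement_log_odds)) {
    elo[names(engagement_log_odds)] <- engagement_log_odds
  }

  mix_def <- list(early = 0.3348, late = 0.5378, consistent = 0.1274,
                  eta_slope = 0.8, late_geom_p = 0.45)
  mix <- utils::modifyList(mix_def, attrition_mixture)

  usage_def <- list(
    login_base = log(8),  login_slope = 0.30,   # extra platform logins / window
    # goals are a hurdle: coaches encourage one goal at baseline, so ~89%
    # set at least one; extra goals follow a Poisson tail
    goal_any_base = 2.1, goal_any_slope = 0.6,
    goal_extra_base = log(0.7), goal_extra_slope = 0.45,
    message_base = log(5), message_slope = 0.50,
    measurement_base = log(2.5), measurement_slope = 0.50,
    education_any_base = 0.9, education_any_slope = 0.60,
    education_beta = c(2, 4),
    control_login_mean = 0.7
  )
  usg <- utils::modifyList(usage_def, usage)

  out_def <- list(
    sbp      = list(mean = 147, sd = 16,  drift = -3.0, noise = 12,  floor = 70),
    ldl      = list(mean = 3.5, sd = 1.0, drift = -0.20, noise = 0.8, floor = 0.5),
    bmi      = list(mean = 28.3, sd = 4.2, drift = -0.10, noise = 1.5, floor = 14),
    phys_act = list(mean = 5.0, sd = 4.0, drift = -0.50, noise = 3.0, floor = 0),
    medas    = list(mean = 6.1, sd = 2.0, drift = 0.20, noise = 1.8, floor = 0),
    caide    = list(mean = 7.5, sd = 2.0, drift = 0.20, noise = 1.6, floor = 0),
    score_op = list(mean = 10.0, sd = 4.0, drift = 1.00, noise = 2.5, floor = 0),
    # Change-scale covariate slopes (kept linear in covariates that the
    # adjusted outcome models include, so planted effects stay estimable).
    cov_slopes = list(age = -0.05, sex_male = 0.4, cognition_z = -0.6,
                      smoking = 0.8)
  )
  outp <- utils::modifyList(out_def, outcome_params)

  if (is.null(outcome_effects)) {
    z <- c(low = 0, moderate = -0.04, high = -0.08)
    outcome_effects <- rbind(
      sbp      = z * outp$sbp$sd,
      ldl      = z * outp$ldl$sd,
      bmi      = z * outp$bmi$sd,
      phys_act = c(0, 0.3, 0.6),
      medas    = c(0, 0.15, 0.3),
      caide    = c(0, -0.1, -0.2),
      score_op = c(0, 0, 0)
    )
    colnames(outcome_effects) <- c("low", "moderate", "high")
  }

  cfg <- structure(list(
    seed = as.integer(seed),
    n_intervention = as.integer(n_intervention),
    n_control = as.integer(n_control),
    covariates = cov,
    engagement_log_odds = elo,
    propensity_sd = propensity_sd,
    attrition_mixture = mix,
    usage = usg,
    questionnaire_schedule_days = questionnaire_schedule_days,
    questionnaire_jitter_days = questionnaire_jitter_days,
    outcome_params = outp,
    outcome_effects = outcome_effects,
    max_followup_days = 548L,
    window_days = 30L
  ), class = "eh_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(p, field) {
    if (!is.numeric(p) || any(p < 0) || any(p > 1) || any(is.na(p))) {
      abort_config(sprintf("`%s` must be a probability in [0, 1].", field),
                   field = field)
    }
  }
  chk_simplex <- function(p, field) {
    chk_prob(p, field)
    if (abs(sum(p) - 1) > 1e-6) {
      abort_config(sprintf("`%s` proportions must sum to 1 (got %.4f).",
                           field, sum(p)), field = field)
    }
  }
  if (cfg$n_intervention < 0 || cfg$n_control < 0) {
    abort_config("Arm sizes must be nonnegative.", field = "n_intervention")
  }
  if (cfg$n_intervention + cfg$n_control <= 0) {
    abort_config("At least one participant is required across arms.",
                 field = "n_intervention")
  }
  cov <- cfg$covariates
  chk_simplex(cov$education, "education")
  chk_simplex(cov$country, "country")
  chk_simplex(cov$lifestyle, "lifestyle")
  chk_simplex(cov$computer_use, "computer_use")
  for (f in c("sex_male", "living_with_partner", "sppb_lt10", "depressive",
              "cvd", "diabetes", "hypertension", "dyslipidemia", "smoking",
              "active", "obese", "dropout_prop")) {
    chk_prob(cov[[f]], f)
  }
  mix <- cfg$attrition_mixture
  chk_simplex(c(mix$early, mix$late, mix$consistent), "attrition_mixture")
  if (mix$late_geom_p <= 0 || mix$late_geom_p >= 1) {
    abort_config("`attrition_mixture$late_geom_p` must be in (0, 1).",
                 field = "attrition_mixture")
  }
  for (v in c("sbp", "ldl", "bmi", "phys_act", "medas", "caide", "score_op")) {
    p <- cfg$outcome_params[[v]]
    if (p$sd <= 0 || p$noise <= 0) {
      abort_config(sprintf("Outcome `%s` requires positive sd and noise.", v),
                   field = v)
    }
  }
  if (cfg$questionnaire_jitter_days > 7) {
    abort_config("`questionnaire_jitter_days` must be <= 7.",
                 field = "questionnaire_jitter_days")
  }
  oe <- cfg$outcome_effects
  if (!is.matrix(oe) || nrow(oe) != 7 ||
      !identical(colnames(oe), c("low", "moderate", "high"))) {
    abort_config("`outcome_effects` must be a 7 x 3 matrix with columns low/moderate/high.",
                 field = "outcome_effects")
  }
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' Only scalar/vector fields are serialised; the file round-trips through
#' [sim_config()] so validation always applies on read.
#'
#' @param path File path.
#' @param cfg An `eh_sim_config` object.
#' @return `read_sim_config()` returns an `eh_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  oe <- y$outcome_effects
  if (!is.null(oe)) {
    oe <- do.call(rbind, oe)
    colnames(oe) <- c("low", "moderate", "high")
  }
  # YAML represents named vectors as maps; restore the vector fields.
  for (f in c("education", "country", "lifestyle", "computer_use")) {
    if (!is.null(y$covariates[[f]])) {
      y$covariates[[f]] <- unlist(y$covariates[[f]])
    }
  }
  if (!is.null(y$usage$education_beta)) {
    y$usage$education_beta <- unlist(y$usage$education_beta)
  }
  sim_config(
    seed = y$seed,
    n_intervention = y$n_intervention %||% 1389,
    n_control = y$n_control %||% 1335,
    covariates = y$covariates %||% list(),
    engagement_log_odds = unlist(y$engagement_log_odds),
    propensity_sd = y$propensity_sd %||% 1.0,
    attrition_mixture = y$attrition_mixture %||% list(),
    usage = y$usage %||% list(),
    questionnaire_schedule_days = y$questionnaire_schedule_days %||% seq(90, 540, 90),
    questionnaire_jitter_days = y$questionnaire_jitter_days %||% 3,
    outcome_params = y$outcome_params %||% list(),
    outcome_effects = oe
  )
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "eh_sim_config"))
  y <- unclass(cfg)
  y$outcome_effects <- lapply(seq_len(nrow(cfg$outcome_effects)), function(i) {
    as.numeric(cfg$outcome_effects[i, ])
  })
  names(y$outcome_effects) <- rownames(cfg$outcome_effects)
  # yaml drops names on atomic vectors; write the named ones as maps
  y$engagement_log_odds <- as.list(cfg$engagement_log_odds)
  for (f in c("education", "country", "lifestyle", "computer_use")) {
    y$covariates[[f]] <- as.list(cfg$covariates[[f]])
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

# Expected value of the planted linear predictor under the configured
# marginals; used to centre the propensity so intensity links have stable
# baselines regardless of the planted effect sizes.
expected_propensity <- function(cfg) {
  cov <- cfg$covariates
  elo <- cfg$engagement_log_odds
  sum(
    elo["country_FR"] * cov$country["FR"],
    elo["country_FI"] * cov$country["FI"],
    elo["lifestyle_long_term_plans"] * cov$lifestyle["long_term_plans"],
    elo["lifestyle_short_term_plans"] * cov$lifestyle["short_term_plans"],
    elo["lifestyle_short_term_acting"] * cov$lifestyle["short_term_acting"],
    elo["lifestyle_long_term_acting"] * cov$lifestyle["long_term_acting"],
    elo["computer_lt7h_week"] * cov$computer_use["lt7h_week"],
    elo["computer_ge7h_week"] * cov$computer_use["ge7h_week"],
    elo["cognition_z"] * cov$cognition$mean,
    elo["sex_male"] * cov$sex_male
  )
}
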