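test_that("same seed gives byte-identical rosters and trials", {
  cfg <- small_cfg(11)
  r1 <- sample_baseline(cfg)
  r2 <- sample_baseline(cfg)
  expect_identical(r1, r2)
  t1 <- suppressWarnings(simulate_trial(cfg))
  t2 <- suppressWarnings(simulate_trial(cfg))
  expect_identical(t1$usage, t2$usage)
  expect_identical(t1$outcomes, t2$outcomes)
  t3 <- suppressWarnings(simulate_trial(small_cfg(12)))
  expect_false(identical(t1$usage$logins, t3$usage$logins))
})

test_that("baseline marginals match the configured values within MC error", {
  cfg <- sim_config(seed = 5, n_intervention = 1389, n_control = 1335)
  roster <- sample_baseline(cfg)
  expect_equal(mean(roster$country == "FI"), 0.32, tolerance = 0.05)
  expect_equal(mean(roster$sex == "male"), 0.527, tolerance = 0.05)
  expect_equal(mean(roster$computer_use == "none"), 0.031, tolerance = 0.35)
  expect_equal(unname(table(roster$education) / nrow(roster))[1], 0.300,
               tolerance = 0.1)
  # documented association: computer use correlates with education/cognition
  expect_gt(cor(as.integer(roster$computer_use), as.integer(roster$education),
                method = "spearman"), 0.1)
  expect_gt(cor(as.integer(roster$computer_use), roster$cognition_z,
                method = "spearman"), 0.1)
  # attrition mixture shares are preserved by construction
  shares <- table(roster$latent_class) / nrow(roster)
  expect_equal(unname(shares[c("early", "late", "consistent")]),
               c(0.3348, 0.5378, 0.1274), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("usage logs respect latent class and the questionnaire schedule", {
  cfg <- small_cfg(21, ni = 200, nc = 0)
  set.seed(99)
  roster <- sample_baseline(cfg)
  usage <- sample_usage_log(roster, cfg)
  plat <- qualifying_logins(usage$logins)

  # consistent users with full follow-up: a platform login in every window
  full <- roster$participant_id[roster$latent_class == "consistent" &
                                  roster$followup_days == 548]
  for (id in head(full, 5)) {
    win <- unique(plat$day[plat$participant_id == id] %/% 30 + 1)
    expect_true(all(seq_len(18) %in% win))
  }

  # quitters: no platform login at or after the cessation window start
  quit <- roster[roster$latent_class != "consistent", ]
  for (i in head(seq_len(nrow(quit)), 20)) {
    d <- plat$day[plat$participant_id == quit$participant_id[i]]
    expect_false(any(d >= (quit$cessation_window[i] - 1) * 30))
  }

  # schedule property: a questionnaire login within 7 days of each scheduled
  # day still inside follow-up
  q <- usage$logins[usage$logins$purpose == "questionnaire_only", ]
  for (id in head(roster$participant_id, 25)) {
    fup <- roster$followup_days[roster$participant_id == id]
    sched <- cfg$questionnaire_schedule_days
    sched <- sched[sched <= fup]
    qd <- q$day[q$participant_id == id]
    expect_true(all(vapply(sched, function(s) any(abs(qd - s) <= 7),
                           logical(1))))
  }
})

test_that("planted computer-use effect lowers composite scores for non-users", {
  cfg <- sim_config(seed = 31, n_intervention = 400, n_control = 0,
                    covariates = list(computer_use = c(none = 0.5,
                                                       lt7h_week = 0.25,
                                                       ge7h_week = 0.25)))
  trial <- suppressWarnings(simulate_trial(cfg))
  d <- dplyr::left_join(trial$engagement,
                        trial$participants[, c("participant_id",
                                               "computer_use")],
                        by = "participant_id")
  m_none <- mean(d$composite_score[d$computer_use == "none"])
  m_hi <- mean(d$composite_score[d$computer_use == "ge7h_week"])
  expect_gt(m_hi, m_none)

  # doubling the planted log-odds widens the gap
  cfg2 <- sim_config(seed = 31, n_intervention = 400, n_control = 0,
                     covariates = list(computer_use = c(none = 0.5,
                                                        lt7h_week = 0.25,
                                                        ge7h_week = 0.25)),
                     engagement_log_odds = c(
                       computer_lt7h_week = 2 * log(5.39),
                       computer_ge7h_week = 2 * log(6.58)))
  trial2 <- suppressWarnings(simulate_trial(cfg2))
  d2 <- dplyr::left_join(trial2$engagement,
                         trial2$participants[, c("participant_id",
                                                 "computer_use")],
                         by = "participant_id")
  gap1 <- m_hi - m_none
  gap2 <- mean(d2$composite_score[d2$computer_use == "ge7h_week"]) -
    mean(d2$composite_score[d2$computer_use == "none"])
  expect_gt(gap2, gap1)
})

test_that("outcome generation plants the category effect and truncates at floors", {
  cfg <- small_cfg(41, ni = 2000, nc = 0)
  set.seed(7)
  roster <- sample_baseline(cfg)
  # null configuration: zero planted effects => no between-category gap
  cfg0 <- sim_config(seed = 41, n_intervention = 2000, n_control = 0,
                     outcome_effects = matrix(
                       0, 7, 3,
                       dimnames = list(c("sbp", "ldl", "bmi", "phys_act",
                                         "medas", "caide", "score_op"),
                                       c("low", "moderate", "high"))))
  o_hi <- suppressWarnings(sample_outcomes(roster, "high", cfg0))
  o_lo <- suppressWarnings(sample_outcomes(roster, "low", cfg0))
  w_hi <- outcomes_wide(o_hi); w_lo <- outcomes_wide(o_lo)
  d_hi <- mean(w_hi$sbp_month18 - w_hi$sbp_baseline)
  d_lo <- mean(w_lo$sbp_month18 - w_lo$sbp_baseline)
  expect_equal(d_hi - d_lo, 0, tolerance = 1.5)

  # planted composite effect: realized z-change gap ~ -0.08
  set.seed(8)
  o_hi <- suppressWarnings(sample_outcomes(roster, "high", cfg))
  o_ct <- suppressWarnings(sample_outcomes(roster, "control", cfg))
  z_hi <- composite_z_change(outcomes_wide(o_hi))
  cons <- attr(z_hi, "constants")
  z_ct <- composite_z_change(outcomes_wide(o_ct), constants = cons)
  gap <- mean(z_hi$composite_z_change) - mean(z_ct$composite_z_change)
  expect_lt(abs(gap - (-0.08)), 0.025)

  # extreme noise hits the physiologic floor with a warning
  cfg_x <- sim_config(seed = 43, n_intervention = 50, n_control = 0,
                      outcome_params = list(bmi = list(mean = 16, sd = 1,
                                                       drift = -8, noise = 6,
                                                       floor = 14)))
  r_x <- sample_baseline(cfg_x)
  expect_warning(o_x <- sample_outcomes(r_x, "low", cfg_x),
                 class = "ehengage_truncation_warning")
  w_x <- outcomes_wide(o_x)
  expect_true(all(w_x$bmi_month18 >= 14))

  expect_error(sample_outcomes(roster, "extreme", cfg),
               class = "ehengage_config_error")
})
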