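wide_fixture <- function(n = 200, seed = 61, effects = c(low = 0,
                                                         moderate = -0.04,
                                                         high = -0.08)) {
  set.seed(seed)
  g <- sample(c("control", "low", "moderate", "high"), n, TRUE)
  sbp0 <- rnorm(n, 147, 16); ldl0 <- rnorm(n, 3.5, 1); bmi0 <- rnorm(n, 28, 4.2)
  eff <- ifelse(g == "control", 0, effects[g])
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    engagement_group = g,
    age = rnorm(n, 70, 4), sex = factor(sample(c("f", "m"), n, TRUE)),
    cognition_z = rnorm(n),
    sbp_baseline = sbp0, sbp_month18 = sbp0 + rnorm(n, -2, 10) + eff * 16,
    ldl_baseline = ldl0, ldl_month18 = ldl0 + rnorm(n, 0, 0.7) + eff * 1,
    bmi_baseline = bmi0, bmi_month18 = bmi0 + rnorm(n, 0, 1.4) + eff * 4.2)
}

test_that("composite z change matches its arithmetic definition", {
  w <- tibble::tibble(
    participant_id = c("a", "b"),
    sbp_baseline = c(140, 150), sbp_month18 = c(140, 142),
    ldl_baseline = c(3, 4), ldl_month18 = c(3, 4),
    bmi_baseline = c(27, 30), bmi_month18 = c(27, 30))
  cons <- tibble::tibble(variable = c("sbp", "ldl", "bmi"),
                         mean = c(145, 3.5, 28.5), sd = c(16, 1, 4))
  z <- composite_z_change(w, constants = cons)
  # no change at all -> 0
  expect_equal(z$composite_z_change[1], 0)
  # SBP -8 with SD 16, others unchanged -> -0.5 / 3
  expect_equal(z$composite_z_change[2], -0.5 / 3)

  # pooled mean composite change equals the mean of the component z-changes
  w2 <- wide_fixture(150)
  z2 <- composite_z_change(w2)
  expect_equal(mean(z2$composite_z_change),
               mean((mean(z2$z_change_sbp) + mean(z2$z_change_ldl) +
                       mean(z2$z_change_bmi)) / 3),
               tolerance = 1e-12)

  # a missing component leaves the composite undefined with a message
  w$ldl_month18[2] <- NA
  expect_message(z3 <- composite_z_change(w, constants = cons), "missing")
  expect_true(is.na(z3$composite_z_change[2]))
  cons$sd[1] <- 0
  expect_error(composite_z_change(w, constants = cons),
               class = "ehengage_config_error")
})

test_that("change-model coefficients agree with a normal-equations oracle", {
  w <- wide_fixture(50)
  w <- composite_z_change(w)
  fit <- fit_change_model(w, "composite_z_change",
                          covariates = c("age", "sex", "cognition_z"),
                          baseline_adjust = "never")
  g <- factor(w$engagement_group, levels = c("control", "low", "moderate",
                                             "high"))
  Xo <- cbind(1, g == "low", g == "moderate", g == "high", w$age,
              w$sex == "m", w$cognition_z)
  yo <- w$composite_z_change
  bo <- solve(t(Xo) %*% Xo, t(Xo) %*% yo)
  expect_equal(fit$estimates$estimate, bo[2:4], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("group contrasts are location-invariant and reduce to raw means when unadjusted", {
  w <- composite_z_change(wide_fixture(300, seed = 67))
  f1 <- fit_change_model(w, "composite_z_change",
                         covariates = c("age", "sex", "cognition_z"))
  w2 <- dplyr::mutate(w, composite_z_change = composite_z_change + 5)
  f2 <- fit_change_model(w2, "composite_z_change",
                         covariates = c("age", "sex", "cognition_z"))
  expect_equal(f1$estimates$estimate, f2$estimates$estimate,
               tolerance = 1e-10)

  # with no covariates the group coefficients are raw mean differences
  f0 <- fit_change_model(w, "composite_z_change", covariates = character(0),
                         baseline_adjust = "never")
  raw <- tapply(w$composite_z_change, w$engagement_group, mean)
  expect_equal(f0$estimates$estimate[f0$estimates$group == "high"],
               unname(raw["high"] - raw["control"]), tolerance = 1e-10)
})

test_that("degenerate grouping and collinear covariates raise errors", {
  w <- composite_z_change(wide_fixture(60))
  w$engagement_group <- "high"
  expect_error(fit_change_model(w, "composite_z_change",
                                covariates = character(0)),
               "one group label")
  w2 <- composite_z_change(wide_fixture(60))
  w2$dup <- w2$age
  expect_error(fit_change_model(w2, "composite_z_change",
                                covariates = c("age", "dup")),
               class = "ehengage_singular_error")
})

test_that("baseline adjustment is gated on the across-category ANOVA", {
  w <- composite_z_change(wide_fixture(400, seed = 71))
  # force a baseline imbalance across engagement categories
  w$sbp_baseline <- w$sbp_baseline +
    ifelse(w$engagement_group == "high", 12, 0)
  f_auto <- fit_change_model(w, "sbp", covariates = c("age"),
                             baseline_adjust = "auto")
  expect_true(f_auto$baseline_adjusted)
  f_bal <- fit_change_model(composite_z_change(wide_fixture(400, seed = 76)),
                            "sbp", covariates = c("age"),
                            baseline_adjust = "auto")
  expect_false(f_bal$baseline_adjusted)
  expect_false(fit_change_model(w, "sbp", covariates = c("age"),
                                baseline_adjust = "never")$baseline_adjusted)
})

test_that("null and planted configurations behave as expected across the outcome table", {
  # null: no planted effects; estimates near zero
  w0 <- composite_z_change(wide_fixture(2000, seed = 73,
                                        effects = c(low = 0, moderate = 0,
                                                    high = 0)))
  f0 <- fit_change_model(w0, "composite_z_change",
                         covariates = c("age", "sex", "cognition_z"))
  expect_lt(max(abs(f0$estimates$estimate)), 0.08)
  expect_gt(f0$overall_p, 0.001)

  # planted gradient at trial scale: recovered with correct signs
  trial <- suppressWarnings(simulate_trial(sim_config(seed = 75)))
  adata <- ehengage:::prep_model_data(
    trial$participants %>%
      dplyr::left_join(dplyr::select(trial$engagement, participant_id,
                                     category),
                       by = "participant_id") %>%
      dplyr::mutate(engagement_group = ifelse(arm == "control", "control",
                                              as.character(category))) %>%
      dplyr::left_join(composite_z_change(outcomes_wide(trial$outcomes)),
                       by = "participant_id"))
  res <- run_all_outcomes(adata)
  cz <- res[res$outcome == "composite_z_change", ]
  expect_equal(nrow(cz), 3)
  hi <- cz[cz$group == "high", ]
  expect_lt(hi$estimate, 0)
  expect_true(hi$conf.low < -0.08 & -0.08 < hi$conf.high)
  # dose-response ordering of the point estimates
  expect_lt(hi$estimate, cz$estimate[cz$group == "low"])
  # single-outcome call gives a single-fit table
  res1 <- run_all_outcomes(adata, outcomes = "composite_z_change")
  expect_equal(nrow(res1), 3)
  expect_s3_class(autoplot(res), "ggplot")
})
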