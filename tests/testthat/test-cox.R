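test_that("two-subject partial likelihood matches the analytic closed form", {
  d <- tibble::tibble(time = c(1, 2), event = c(TRUE, FALSE), x = c(1, 0))
  for (b in c(-1.3, 0, 0.7, 2.4)) {
    # single event, subject with x=1 at risk with subject with x=0:
    # l(b) = b - log(e^b + 1)
    expect_equal(cox_partial_loglik(d, "x", b, time = "time",
                                    event = "event"),
                 b - log(exp(b) + 1), tolerance = 1e-10)
    expect_equal(cox_partial_loglik(d, "x", b, time = "time",
                                    event = "event", ties = "breslow"),
                 b - log(exp(b) + 1), tolerance = 1e-10)
  }
})

test_that("partial likelihood equals brute-force risk-set enumeration on tiny data", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    d <- tibble::tibble(
      time = sample(1:4, n, replace = TRUE),
      event = runif(n) < 0.7,
      x1 = rnorm(n), x2 = runif(n) < 0.5)
    if (sum(d$event) == 0) next
    b <- rnorm(2, sd = 0.7)
    for (tie in c("breslow", "efron")) {
      expect_equal(
        cox_partial_loglik(d, c("x1", "x2"), b, time = "time",
                           event = "event", ties = tie),
        naive_cox_loglik(b, d$time, d$event, cbind(d$x1, d$x2), ties = tie),
        tolerance = 1e-10)
    }
  }
})

test_that("coefficients agree with the survival package on tied monthly data", {
  set.seed(53)
  n <- 500
  d <- tibble::tibble(
    x1 = rnorm(n),
    x2 = factor(sample(c("none", "lt7", "ge7"), n, TRUE,
                       prob = c(0.2, 0.45, 0.35)),
                levels = c("none", "lt7", "ge7")))
  X <- cbind(d$x1, d$x2 == "lt7", d$x2 == "ge7")
  s <- sample_survival_times(X, beta = c(0.4, log(0.46), log(0.44)),
                             rate = 0.25)
  d$time <- s$time; d$event <- s$event
  for (tie in c("efron", "breslow")) {
    fit <- cox_fit(d, c("x1", "x2"), time = "time", event = "event",
                   ties = tie)
    ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = d,
                           ties = tie)
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-4)
    expect_equal(unname(sqrt(diag(fit$vcov))),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
  }

  # delayed entry agrees with survival's counting-process formulation
  d$entry <- ifelse(d$time > 2, 2, 0)
  dl <- d[d$time > 2, ]
  fit <- cox_fit(dl, c("x1", "x2"), time = "time", event = "event",
                 entry = "entry")
  ref <- survival::coxph(survival::Surv(entry, time, event) ~ x1 + x2,
                         data = dl, ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
})

test_that("degenerate survival inputs are rejected or flagged", {
  d <- tibble::tibble(time = 1:4, event = FALSE, x = rnorm(4))
  expect_error(cox_fit(d, "x", time = "time", event = "event"),
               "No events")
  # perfect separation: the only event has the uniquely largest covariate,
  # with a gap small enough that the likelihood keeps climbing past the cap
  d2 <- tibble::tibble(time = c(1, 2, 3, 4), event = c(TRUE, FALSE, FALSE, FALSE),
                       x = c(0.8, 0, 0, 0))
  expect_warning(fit <- cox_fit(d2, "x", time = "time", event = "event"),
                 class = "ehengage_separation_warning")
  expect_true(fit$capped)
  # null model (no terms) is allowed
  d3 <- tibble::tibble(time = c(1, 2), event = c(TRUE, TRUE))
  f0 <- cox_fit(d3, character(0), time = "time", event = "event")
  expect_equal(length(f0$coefficients), 0)
})

test_that("follow-up split produces the published bookkeeping", {
  rec <- tibble::tibble(
    participant_id = c("a", "b", "c", "d"),
    time_months = c(1, 3, 18, 2), event = c(TRUE, TRUE, FALSE, FALSE),
    followup_windows = c(18, 18, 18, 2))
  spl <- split_followup(rec, cut_months = 2)
  # early: everyone, events only in months 1-2
  expect_equal(nrow(spl$early), 4)
  expect_equal(spl$early$time_early, c(1, 2, 2, 2))
  expect_equal(spl$early$event_early, c(TRUE, FALSE, FALSE, FALSE))
  # late: only those event-free through month 2 (b and c)
  expect_setequal(spl$late$participant_id, c("b", "c"))
  expect_equal(unique(spl$late$entry), 2)
  expect_warning(split_followup(rec, cut_months = 20),
                 class = "ehengage_empty_period_warning")
})

test_that("planted hazard ratio is recovered and split halves agree for a constant effect", {
  set.seed(55)
  n <- 1200
  x <- runif(n) < 0.5
  s <- sample_survival_times(cbind(x), beta = log(0.46), rate = 0.3)
  d <- tibble::tibble(time = s$time, event = s$event, x = x)
  fit <- cox_fit(d, "x", time = "time", event = "event")
  ci <- tidy(fit, exponentiate = TRUE)
  expect_equal(ci$estimate, 0.46, tolerance = 0.2)
  expect_true(ci$conf.low < 0.46 && 0.46 < ci$conf.high)

  # a time-constant effect gives compatible early/late estimates
  rec <- dplyr::rename(d, time_months = time)
  spl <- split_followup(rec, cut_months = 2)
  f_e <- cox_fit(spl$early, "x", time = "time_early", event = "event_early")
  f_l <- cox_fit(spl$late, "x", time = "time_late", event = "event_late",
                 entry = "entry")
  se <- sqrt(diag(f_e$vcov) + diag(f_l$vcov))
  expect_lt(abs(f_e$coefficients - f_l$coefficients) / se, 3)
})

test_that("PH score test is calibrated under H0 and powerful under violation", {
  set.seed(57)
  # calibration: modest replicate count; the full calibration runs in the
  # acceptance suite
  p_null <- replicate(60, {
    n <- 300
    x <- rnorm(n)
    s <- sample_survival_times(cbind(x), beta = 0.5, rate = 0.25)
    d <- tibble::tibble(time = s$time, event = s$event, x = x)
    ph_test(cox_fit(d, "x", time = "time", event = "event"))$p.value[1]
  })
  expect_gt(mean(p_null < 0.05), 0)   # not degenerate at 0
  expect_lt(mean(p_null < 0.05), 0.15)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)

  # power: effect switches sign at month 2 (the published violation pattern)
  set.seed(58)
  p_alt <- replicate(20, {
    n <- 1000
    x <- runif(n) < 0.5
    t1 <- sample_survival_times(cbind(x), beta = 1.2, rate = 0.35,
                                censor_time = 2)
    t2 <- sample_survival_times(cbind(x), beta = -1.2, rate = 0.25,
                                censor_time = 16)
    time <- ifelse(t1$event, t1$time, 2 + t2$time)
    event <- t1$event | t2$event
    d <- tibble::tibble(time = time, event = event, x = x)
    ph_test(cox_fit(d, "x", time = "time", event = "event"))$p.value[1]
  })
  expect_gt(mean(p_alt < 0.05), 0.8)

  d1 <- tibble::tibble(time = c(1, 2), event = c(TRUE, FALSE), x = c(1, 0))
  expect_error(ph_test(cox_fit(d1, "x", time = "time", event = "event")),
               "at least 2 events")
})

test_that("Cox backward elimination keeps period-specific planted effects", {
  set.seed(59)
  n <- 1500
  x <- runif(n) < 0.4     # planted only in the early period
  z <- rnorm(n)           # pure noise
  t1 <- sample_survival_times(cbind(x), beta = log(0.4), rate = 0.35,
                              censor_time = 2)
  t2 <- sample_survival_times(cbind(x), beta = 0, rate = 0.25,
                              censor_time = 16)
  rec <- tibble::tibble(
    time_months = ifelse(t1$event, t1$time, 2 + t2$time),
    event = t1$event | t2$event, x = x, z = z)
  spl <- split_followup(rec, cut_months = 2)
  f_e <- cox_backward_eliminate(spl$early, c("x", "z"),
                                time = "time_early", event = "event_early")
  expect_true("x" %in% f_e$terms)
  expect_false("z" %in% f_e$terms)
  f_l <- suppressWarnings(cox_backward_eliminate(
    spl$late, c("x", "z"), time = "time_late", event = "event_late",
    entry = "entry"))
  expect_false("x" %in% f_l$terms)
})
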