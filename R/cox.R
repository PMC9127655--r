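#' Cox proportional-hazards regression for nonuse attrition
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with analytic
#' gradient and information, supporting Breslow and Efron tie corrections
#' (Efron is the default: the monthly attrition grid produces heavy ties)
#' and delayed entry via `entry` (used by the late-period model, where risk
#' begins at the split month and the original time scale is retained).
#'
#' @param data Data frame holding times, events and covariates.
#' @param terms Character vector of covariate term labels; may be empty, in
#'   which case the null model (no coefficients) is returned.
#' @param time,event,entry Column names of the stop time, the event
#'   indicator, and (optionally) the delayed-entry time.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param gtol Gradient-norm convergence tolerance.
#' @return An object of class `eh_cox`.
#' @export
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, TRUE, FALSE),
#'                     x = c(1, 0, 1, 0))
#' cox_fit(d, "x", time = "time", event = "event")
cox_fit <- function(data, terms, time = "time_months", event = "event",
                    entry = NULL, ties = c("efron", "breslow"),
                    gtol = 1e-6) {
  ties <- rlang::arg_match(ties)
  keep_cols <- c(time, event, entry, all.vars(stats::reformulate(
    if (length(terms)) terms else "1")))
  cc <- stats::complete.cases(data[, intersect(keep_cols, names(data))])
  d <- data[cc, , drop = FALSE]
  n_dropped <- nrow(data) - nrow(d)

  stop_t <- as.numeric(d[[time]])
  ev <- as.logical(d[[event]])
  start_t <- if (is.null(entry)) rep(0, nrow(d)) else as.numeric(d[[entry]])
  if (any(start_t >= stop_t)) {
    abort_fit("Entry times must precede stop times.")
  }
  nevent <- sum(ev)
  if (nevent == 0) abort_fit("No events; cannot fit a Cox model.")

  if (length(terms)) {
    tt <- stats::terms(stats::reformulate(terms))
    mm <- stats::model.matrix(tt, d)
    X <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    assign <- attr(mm, "assign")[colnames(mm) != "(Intercept)"]
    v <- apply(X, 2, stats::var)
    if (any(v == 0)) {
      abort_fit(paste0("Term(s) with zero variance: ",
                       paste(colnames(X)[v == 0], collapse = ", ")),
                class = "ehengage_degenerate_term")
    }
    if (qr(X)$rank < ncol(X)) {
      abort_fit("Design matrix is rank deficient (collinear terms).",
                class = "ehengage_singular_error")
    }
  } else {
    X <- matrix(numeric(0), nrow(d), 0)
    assign <- integer(0)
  }
  p <- ncol(X)

  ll_parts <- function(beta, want = c("ll", "grad", "info")) {
    lp <- if (p) drop(X %*% beta) else rep(0, nrow(d))
    w <- exp(lp)
    ll <- 0; U <- numeric(p); Imat <- matrix(0, p, p)
    for (t in sort(unique(stop_t[ev]))) {
      risk <- start_t < t & stop_t >= t
      D <- ev & stop_t == t
      dsz <- sum(D)
      S0r <- sum(w[risk])
      S1r <- if (p) colSums(X[risk, , drop = FALSE] * w[risk]) else numeric(0)
      S2r <- if (p) crossprod(X[risk, , drop = FALSE],
                              X[risk, , drop = FALSE] * w[risk]) else
        matrix(0, 0, 0)
      ll <- ll + sum(lp[D])
      if (p) U <- U + colSums(X[D, , drop = FALSE])
      if (ties == "breslow") {
        ll <- ll - dsz * log(S0r)
        if (p) {
          xb <- S1r / S0r
          U <- U - dsz * xb
          Imat <- Imat + dsz * (S2r / S0r - tcrossprod(xb))
        }
      } else {
        S0d <- sum(w[D])
        S1d <- if (p) colSums(X[D, , drop = FALSE] * w[D]) else numeric(0)
        S2d <- if (p) crossprod(X[D, , drop = FALSE],
                                X[D, , drop = FALSE] * w[D]) else
          matrix(0, 0, 0)
        for (l in seq_len(dsz) - 1L) {
          phi <- S0r - (l / dsz) * S0d
          ll <- ll - log(phi)
          if (p) {
            Z <- (S1r - (l / dsz) * S1d) / phi
            M <- (S2r - (l / dsz) * S2d) / phi
            U <- U - Z
            Imat <- Imat + (M - tcrossprod(Z))
          }
        }
      }
    }
    list(ll = ll, U = U, I = Imat)
  }

  loglik_null <- ll_parts(rep(0, p))$ll
  beta <- rep(0, p)
  capped <- FALSE
  if (p) {
    ll0 <- loglik_null
    for (it in seq_len(50)) {
      parts <- ll_parts(beta)
      if (sqrt(sum(parts$U^2)) < gtol) break
      step <- tryCatch(solve(parts$I, parts$U), error = function(e) NULL)
      if (is.null(step)) {
        abort_fit("Singular information in Cox fit.",
                  class = "ehengage_singular_error")
      }
      lambda <- 1
      repeat {
        cand <- beta + lambda * step
        if (ll_parts(cand)$ll >= parts$ll - 1e-12 || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      beta <- beta + lambda * step
      if (any(abs(beta) > 15)) {
        rlang::warn("Monotone partial likelihood (perfect separation); coefficient capped.",
                    class = "ehengage_separation_warning")
        beta <- pmin(pmax(beta, -15), 15)
        capped <- TRUE
        break
      }
    }
    parts <- ll_parts(beta)
    if (!capped && sqrt(sum(parts$U^2)) >= gtol) {
      abort_fit("Cox model did not converge.",
                class = "ehengage_convergence_error", last_iterate = beta)
    }
    V <- solve_or_abort(parts$I, "information matrix")
    loglik <- parts$ll
  } else {
    V <- matrix(numeric(0), 0, 0)
    loglik <- loglik_null
  }
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  # Schoenfeld residuals (Breslow weighting) for the PH diagnostic: one row
  # per event, x_i minus the risk-set weighted mean at the event time.
  sres <- NULL; sres_time <- NULL
  if (p && nevent) {
    lp <- drop(X %*% beta); w <- exp(lp)
    rows <- which(ev)
    ord <- rows[order(stop_t[rows])]
    sres <- matrix(0, length(ord), p, dimnames = list(NULL, colnames(X)))
    sres_time <- stop_t[ord]
    for (k in seq_along(ord)) {
      t <- stop_t[ord[k]]
      risk <- start_t < t & stop_t >= t
      xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sum(w[risk])
      sres[k, ] <- X[ord[k], ] - xbar
    }
  }

  structure(list(
    coefficients = beta, vcov = V,
    loglik = loglik, loglik_null = loglik_null,
    n = nrow(d), nevent = nevent, n_dropped = n_dropped,
    ties = ties, terms = terms, assign = assign,
    capped = capped,
    schoenfeld = sres, schoenfeld_time = sres_time,
    stop_time = stop_t, start_time = start_t, event = ev
  ), class = "eh_cox")
}

#' Cox partial log-likelihood at a given coefficient vector
#'
#' Evaluates (without maximising) the partial log-likelihood of the model in
#' `terms` at `beta`; useful for closed-form verification on tiny data.
#'
#' @inheritParams cox_fit
#' @param beta Numeric coefficient vector.
#' @return The partial log-likelihood value.
#' @export
cox_partial_loglik <- function(data, terms, beta, time = "time_months",
                               event = "event", entry = NULL,
                               ties = c("efron", "breslow")) {
  ties <- rlang::arg_match(ties)
  recompute_partial_loglik(beta, data, terms, time, event, entry, ties)
}

recompute_partial_loglik <- function(beta, data, terms, time, event,
                                     entry, ties) {
  d <- data[stats::complete.cases(
    data[, intersect(c(time, event, entry,
                       all.vars(stats::reformulate(terms))), names(data))]), ]
  mm <- stats::model.matrix(stats::reformulate(terms), d)
  X <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  stop_t <- as.numeric(d[[time]]); ev <- as.logical(d[[event]])
  start_t <- if (is.null(entry)) rep(0, nrow(d)) else as.numeric(d[[entry]])
  lp <- drop(X %*% beta); w <- exp(lp)
  ll <- 0
  for (t in sort(unique(stop_t[ev]))) {
    risk <- start_t < t & stop_t >= t
    D <- ev & stop_t == t
    dsz <- sum(D)
    S0r <- sum(w[risk]); S0d <- sum(w[D])
    ll <- ll + sum(lp[D])
    if (ties == "breslow") {
      ll <- ll - dsz * log(S0r)
    } else {
      for (l in seq_len(dsz) - 1L) ll <- ll - log(S0r - (l / dsz) * S0d)
    }
  }
  ll
}

#' @export
print.eh_cox <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n=%d, events=%d, partial logLik=%.3f\n",
              x$ties, x$n, x$nevent, x$loglik))
  if (length(x$coefficients)) print(round(exp(x$coefficients), 4))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `eh_cox`.
#' @param exponentiate Report hazard ratios instead of log hazards.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble of coefficients with Wald CIs.
#' @export
tidy.eh_cox <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  if (!length(x$coefficients)) {
    return(tibble(term = character(), estimate = double(),
                  std.error = double(), statistic = double(),
                  p.value = double(), conf.low = double(),
                  conf.high = double()))
  }
  se <- sqrt(diag(x$vcov))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se))),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se))
  if (exponentiate) {
    out <- mutate(out, across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @export
glance.eh_cox <- function(x, ...) {
  tibble(n = x$n, nevent = x$nevent, loglik = x$loglik,
         loglik_null = x$loglik_null, ties = x$ties,
         capped = x$capped)
}
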