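#' Generalized ordered logit (partial proportional odds) regression
#'
#' Fits the cumulative-logit model `P(Y > j | x) = logistic(alpha_j + x'b_j)`
#' for an ordered outcome with J levels (j = 1..J-1) by maximising the
#' multinomial likelihood. Each model term is either `parallel` -- one
#' coefficient shared across all cumulative splits, as in standard
#' proportional-odds regression -- or `free`, with a separate coefficient per
#' split. With every term parallel the model is ordinary proportional-odds
#' logistic regression; with every term free it is the fully unconstrained
#' generalized ordered logit, whose fitted cumulative probabilities are not
#' forced to be ordered, so negative fitted category probabilities raise a
#' warning rather than an error.
#'
#' Optimisation is quasi-Newton (BFGS with the analytic gradient) followed by
#' Newton polishing against a finite-difference Hessian of the analytic
#' gradient, to a gradient-norm tolerance `gtol`. The covariance matrix is
#' the inverse observed information at the optimum.
#'
#' @param formula Model formula; the response must be an ordered factor (or
#'   coercible) with every level observed.
#' @param data Data frame; rows with missing values are dropped
#'   (complete-case analysis) and the dropped count recorded.
#' @param constraints Named character vector mapping term labels to
#'   `"parallel"` or `"free"`. Unnamed terms default to `parallel`.
#' @param parallel Shortcut: `TRUE` (all terms parallel, default) or `FALSE`
#'   (all free). Ignored when `constraints` is supplied.
#' @param start Optional starting parameter vector (advanced use).
#' @param gtol Gradient-norm convergence tolerance.
#' @param maxit Maximum BFGS iterations.
#' @return An object of class `eh_gologit`; see [tidy.eh_gologit()].
#' @export
#' @examples
#' d <- tibble::tibble(
#'   y = ordered(rep(c("low", "moderate", "high"), c(30, 50, 20)),
#'               levels = c("low", "moderate", "high")),
#'   x = rnorm(100))
#' fit <- gologit(y ~ x, d)
#' tidy(fit, exponentiate = TRUE)
gologit <- function(formula, data, constraints = NULL, parallel = TRUE,
                    start = NULL, gtol = 1e-6, maxit = 500) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  n_dropped <- nrow(data) - nrow(mf)
  y <- stats::model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  J <- nlevels(y)
  if (J < 3) {
    abort_fit("The outcome must have at least 3 observed ordered levels.")
  }
  tt <- attr(mf, "terms")
  mm <- stats::model.matrix(tt, mf)
  keep <- colnames(mm) != "(Intercept)"
  X <- mm[, keep, drop = FALSE]
  assign <- attr(mm, "assign")[keep]
  term_labels <- attr(tt, "term.labels")

  if (ncol(X) > 0) {
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
  }

  cmap <- build_constraint_map(term_labels, constraints, parallel)
  fit <- gologit_fit_core(X, as.integer(y), J, assign, term_labels, cmap,
                          start = start, gtol = gtol, maxit = maxit)
  fit$y_levels <- levels(y)
  fit$formula <- formula
  fit$xlevels <- stats::.getXlevels(tt, mf)
  fit$n_dropped <- n_dropped
  fit$call <- match.call()
  fit
}

build_constraint_map <- function(term_labels, constraints, parallel) {
  cmap <- stats::setNames(
    rep(if (isTRUE(parallel)) "parallel" else "free", length(term_labels)),
    term_labels)
  if (!is.null(constraints)) {
    unknown <- setdiff(names(constraints), term_labels)
    if (length(unknown)) {
      abort_fit(paste0("Constraint for unknown term(s): ",
                       paste(unknown, collapse = ", ")))
    }
    bad <- setdiff(constraints, c("parallel", "free"))
    if (length(bad)) {
      abort_fit("Constraints must be \"parallel\" or \"free\".")
    }
    cmap[names(constraints)] <- constraints
  }
  cmap
}

# Parameter layout: theta = (alpha_1..alpha_{J-1}, betas). A parallel column
# contributes one beta; a free column J-1 (one per cumulative split).
# idx[c, j] gives the theta position of column c in equation j.
gologit_layout <- function(ncolX, J, assign, cmap, term_labels, colnames_X) {
  nalpha <- J - 1L
  idx <- matrix(0L, nrow = ncolX, ncol = nalpha)
  names_beta <- character(0)
  pos <- nalpha
  for (cc in seq_len(ncolX)) {
    trm <- term_labels[assign[cc]]
    if (cmap[trm] == "parallel") {
      pos <- pos + 1L
      idx[cc, ] <- pos
      names_beta <- c(names_beta, colnames_X[cc])
    } else {
      idx[cc, ] <- pos + seq_len(nalpha)
      pos <- pos + nalpha
      names_beta <- c(names_beta, paste0(colnames_X[cc], ":eq", seq_len(nalpha)))
    }
  }
  list(idx = idx, npar = pos,
       names = c(paste0("alpha_", seq_len(nalpha)), names_beta))
}

gologit_fit_core <- function(X, y, J, assign, term_labels, cmap,
                             start = NULL, gtol = 1e-6, maxit = 500) {
  n <- length(y)
  if (any(tabulate(y, J) == 0)) {
    abort_fit("Every outcome level must be observed at least once.")
  }
  nalpha <- J - 1L
  lay <- gologit_layout(ncol(X), J, assign, cmap, term_labels, colnames(X))
  npar <- lay$npar
  idx <- lay$idx
  eps <- 1e-12

  # Cumulative linear predictors eta[, j] = alpha_j + X beta_j.
  etas <- function(theta) {
    E <- matrix(theta[seq_len(nalpha)], n, nalpha, byrow = TRUE)
    if (ncol(X) > 0) {
      for (j in seq_len(nalpha)) {
        E[, j] <- E[, j] + drop(X %*% theta[idx[, j]])
      }
    }
    E
  }
  catprob <- function(P) {
    # P = plogis(eta); category prob for observed y.
    Pfull <- cbind(1, P, 0)
    Pfull[cbind(seq_len(n), y)] - Pfull[cbind(seq_len(n), y + 1L)]
  }
  # In the unconstrained model the category probability of an observation
  # can be driven <= 0 during optimisation. Below `eps` the log-likelihood
  # is extended linearly (slope `pen`), which repels iterates from the
  # infeasible region with a gradient consistent with the objective; at an
  # interior optimum every observed category probability is positive, so
  # the extension never affects the reported fit.
  pen <- 1e6
  nll <- function(theta) {
    pr <- catprob(plogis(etas(theta)))
    -sum(log(pmax(pr, eps))) + pen * sum(pmax(eps - pr, 0))
  }
  grad <- function(theta) {
    P <- plogis(etas(theta))
    pr <- catprob(P)
    wgt <- ifelse(pr > eps, 1 / pr, pen)
    g <- numeric(npar)
    # d log P(Y = k) / d eta_j is nonzero only for j = k-1 (upper bound of
    # the category) and j = k (lower bound).
    G <- matrix(0, n, nalpha)
    dP <- P * (1 - P)
    for (j in seq_len(nalpha)) {
      up <- y == j + 1L   # eta_j enters positively: P(Y=k) = p_{k-1} - p_k
      dn <- y == j
      G[up, j] <- dP[up, j] * wgt[up]
      G[dn, j] <- G[dn, j] - dP[dn, j] * wgt[dn]
    }
    g[seq_len(nalpha)] <- colSums(G)
    if (ncol(X) > 0) {
      B <- crossprod(X, G)            # p x (J-1)
      for (cc in seq_len(ncol(X))) {
        for (j in seq_len(nalpha)) {
          g[idx[cc, j]] <- g[idx[cc, j]] + B[cc, j]
        }
      }
    }
    -g
  }

  if (is.null(start)) {
    cum <- rev(cumsum(rev(tabulate(y, J))))[-1] / n   # P(Y > j)
    start <- c(qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3)), rep(0, npar - nalpha))
  }
  if (length(start) != npar) {
    abort_fit("`start` has the wrong length for this constraint map.")
  }

  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  # Newton polish to the gradient-norm tolerance.
  converged <- FALSE
  for (it in seq_len(40)) {
    g <- grad(theta)
    if (sqrt(sum(g^2)) < gtol) { converged <- TRUE; break }
    H <- fd_hessian(grad, theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    f0 <- nll(theta)
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      if (nll(cand) <= f0 + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6) break
    theta <- theta - lambda * step
  }
  g <- grad(theta)
  if (!converged && sqrt(sum(g^2)) >= gtol) {
    abort_fit("Generalized ordered logit did not converge.",
              class = "ehengage_convergence_error",
              last_iterate = theta, gradient_norm = sqrt(sum(g^2)))
  }

  beta_part <- theta[-seq_len(nalpha)]
  if (length(beta_part) && any(abs(beta_part) > 15)) {
    rlang::warn("Possible separation: |coefficient| > 15.",
                class = "ehengage_separation_warning")
  }
  P <- plogis(etas(theta))
  all_pr <- cbind(1, P)[, seq_len(J), drop = FALSE] - cbind(P, 0)
  if (any(all_pr < -1e-8)) {
    rlang::warn("Negative fitted category probabilities (unconstrained gologit).",
                class = "ehengage_negative_prob_warning")
  }

  H <- fd_hessian(grad, theta)
  V <- solve_or_abort(H, "observed information")
  names(theta) <- lay$names
  dimnames(V) <- list(lay$names, lay$names)

  structure(list(
    coefficients = theta,
    alpha = theta[seq_len(nalpha)],
    vcov = V,
    logLik = -nll(theta),
    n = n, J = J,
    constraint_map = cmap,
    term_labels = term_labels,
    assign = assign,
    coef_index = idx,
    X = X, y = y,
    gtol = gtol,
    converged = TRUE,
    iterations = opt$counts[["function"]]
  ), class = "eh_gologit")
}

# Refit the stored design under a different constraint map, warm-starting
# from the current estimates where the layouts overlap.
gologit_refit <- function(fit, cmap) {
  lay_new <- gologit_layout(ncol(fit$X), fit$J, fit$assign, cmap,
                            fit$term_labels, colnames(fit$X))
  start <- numeric(lay_new$npar)
  nalpha <- fit$J - 1L
  start[seq_len(nalpha)] <- fit$alpha
  for (cc in seq_len(ncol(fit$X))) {
    for (j in seq_len(nalpha)) {
      start[lay_new$idx[cc, j]] <- fit$coefficients[fit$coef_index[cc, j]]
    }
  }
  out <- gologit_fit_core(fit$X, fit$y, fit$J, fit$assign, fit$term_labels,
                          cmap, start = start, gtol = fit$gtol)
  out$y_levels <- fit$y_levels
  out$formula <- fit$formula
  out
}

theta_indices_for_term <- function(fit, term) {
  ti <- match(term, fit$term_labels)
  if (is.na(ti)) abort_fit(paste0("Unknown term: ", term))
  cols <- which(fit$assign == ti)
  sort(unique(as.vector(fit$coef_index[cols, , drop = FALSE])))
}

#' Joint Wald test that all of a term's coefficients are zero
#'
#' For a categorical term this is the overall test across all its contrasts,
#' in every cumulative equation where the term appears.
#'
#' @param fit An `eh_gologit`.
#' @param term Term label as it appears in the model formula.
#' @return A list with `statistic`, `df`, `p.value`.
#' @export
wald_term <- function(fit, term) {
  k <- theta_indices_for_term(fit, term)
  wald_chisq(fit$coefficients[k], fit$vcov[k, k, drop = FALSE])
}

#' Wald test of the parallel-lines (proportional odds) assumption
#'
#' Tests H0: the term's coefficients are equal across all cumulative splits.
#' If the term is parallel in `fit`, the model is refit internally with that
#' term freed (all other constraints unchanged) and the test computed there.
#' For a categorical term the test is joint across its contrasts; df is
#' (number of contrast columns) x (J - 2).
#'
#' @param fit An `eh_gologit`.
#' @param term Term label.
#' @return A list with `statistic`, `df`, `p.value` and the freed `fit`.
#' @export
wald_parallel_lines <- function(fit, term) {
  if (!term %in% fit$term_labels) abort_fit(paste0("Unknown term: ", term))
  if (fit$constraint_map[term] == "parallel") {
    cmap <- fit$constraint_map
    cmap[term] <- "free"
    fit <- gologit_refit(fit, cmap)
  }
  ti <- match(term, fit$term_labels)
  cols <- which(fit$assign == ti)
  nalpha <- fit$J - 1L
  ncontrast <- length(cols) * (nalpha - 1L)
  C <- matrix(0, ncontrast, length(fit$coefficients))
  r <- 0L
  for (cc in cols) {
    for (j in seq_len(nalpha - 1L)) {
      r <- r + 1L
      C[r, fit$coef_index[cc, j]] <- 1
      C[r, fit$coef_index[cc, j + 1L]] <- -1
    }
  }
  est <- drop(C %*% fit$coefficients)
  V <- C %*% fit$vcov %*% t(C)
  res <- wald_chisq(est, V)
  res$fit <- fit
  res
}

#' @export
print.eh_gologit <- function(x, ...) {
  cat(sprintf(
    "Generalized ordered logit: n=%d, J=%d, logLik=%.3f\n",
    x$n, x$J, x$logLik))
  if (length(x$term_labels)) {
    cat("Constraints:",
        paste(sprintf("%s[%s]", x$term_labels,
                      substr(x$constraint_map[x$term_labels], 1, 4)),
              collapse = " "), "\n")
  }
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a generalized ordered logit fit
#'
#' @param x An `eh_gologit`.
#' @param exponentiate If `TRUE`, report odds ratios (and CIs) instead of
#'   log-odds coefficients; thresholds are never exponentiated.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `equation` (`"all"` for parallel terms and
#'   thresholds per split), `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.eh_gologit <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  nalpha <- x$J - 1L
  nm <- names(x$coefficients)
  equation <- c(paste0("eq", seq_len(nalpha)),
                ifelse(grepl(":eq[0-9]+$", nm[-seq_len(nalpha)]),
                       sub("^.*:(eq[0-9]+)$", "\\1", nm[-seq_len(nalpha)]),
                       "all"))
  term <- c(nm[seq_len(nalpha)],
            sub(":eq[0-9]+$", "", nm[-seq_len(nalpha)]))
  out <- tibble(
    term = term, equation = equation,
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$coefficients / se))),
    conf.low = unname(x$coefficients - z * se),
    conf.high = unname(x$coefficients + z * se))
  if (exponentiate) {
    thr <- seq_len(nalpha)
    out <- out %>%
      mutate(across(c("estimate", "conf.low", "conf.high"),
                    ~ ifelse(dplyr::row_number() %in% thr, .x, exp(.x))))
  }
  out
}

#' @export
glance.eh_gologit <- function(x, ...) {
  tibble(n = x$n, logLik = x$logLik, df = length(x$coefficients),
         n_free_terms = sum(x$constraint_map == "free"),
         converged = x$converged)
}
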