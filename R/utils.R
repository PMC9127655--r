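# Internal helpers shared across modules.

# Nearest-rank (type-1) empirical quantile. Used for login tertiles and the
# tertile-based sensitivity categorisation so that cut points are always
# observed values.
nearest_rank <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 1, names = FALSE)
}

# Stop with a classed condition so callers/tests can distinguish
# configuration errors from numerical failures.
abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "ehengage_config_error", field = field)
}

abort_fit <- function(msg, ..., class = "ehengage_fit_error") {
  rlang::abort(msg, class = class, ...)
}

# Finite-difference Jacobian of an analytic gradient; used to obtain the
# observed information for models fit by quasi-Newton. Central differences,
# step scaled to parameter magnitude.
fd_hessian <- function(grad_fn, theta, h = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    hk <- h * (1 + abs(theta[k]))
    up <- theta; up[k] <- up[k] + hk
    dn <- theta; dn[k] <- dn[k] - hk
    H[, k] <- (grad_fn(up) - grad_fn(dn)) / (2 * hk)
  }
  (H + t(H)) / 2
}

# Safe solve that reports singularity as a fit error naming the offender.
solve_or_abort <- function(A, what = "information matrix") {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) {
    abort_fit(paste0("Singular ", what, "; check for collinear or constant terms."),
              class = "ehengage_singular_error")
  }
  out
}

wald_chisq <- function(est, V) {
  stat <- drop(crossprod(est, solve_or_abort(V, "covariance sub-block") %*% est))
  df <- length(est)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
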