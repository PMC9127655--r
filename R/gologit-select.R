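#' Bivariate screening of candidate predictors
#'
#' Fits each candidate alone (with thresholds, parallel coefficient) against
#' the ordinal outcome and retains it when the overall Wald p-value is below
#' `alpha`. This is the entry step of the published modelling strategy:
#' variables associated with engagement at the .2 level enter the initial
#' multivariate model.
#'
#' @param outcome Name of the ordered outcome column.
#' @param candidates Character vector of candidate term labels.
#' @param data Data frame.
#' @param alpha Entry threshold (default 0.20).
#' @return Tibble with `term`, `p.value`, `retained`.
#' @export
bivariate_screen <- function(outcome, candidates, data, alpha = 0.20) {
  if (!length(candidates)) {
    return(tibble(term = character(), p.value = double(),
                  retained = logical()))
  }
  res <- purrr::map(candidates, function(cand) {
    fit <- gologit(stats::reformulate(cand, response = outcome), data,
                   parallel = TRUE)
    tibble(term = cand, p.value = wald_term(fit, cand)$p.value)
  }) %>% bind_rows()
  mutate(res, retained = .data$p.value < alpha)
}

# Derive the constraint map for a set of terms: a term is freed when the
# parallel-lines Wald test rejects at alpha_parallel.
derive_constraints <- function(base_fit, alpha_parallel) {
  cmap <- stats::setNames(rep("parallel", length(base_fit$term_labels)),
                          base_fit$term_labels)
  for (trm in base_fit$term_labels) {
    p <- tryCatch(wald_parallel_lines(base_fit, trm)$p.value,
                  error = function(e) NA_real_)
    if (!is.na(p) && p < alpha_parallel) cmap[trm] <- "free"
  }
  cmap
}

#' Manual backward elimination for the generalized ordered logit
#'
#' Starting from `formula`, repeatedly refits the model and removes the term
#' with the largest overall Wald p-value exceeding `alpha_stay` (categorical
#' terms are removed whole), until every remaining term is significant. At
#' each refit the constraint map is re-derived: a term gets split-specific
#' coefficients iff its parallel-lines Wald test rejects at
#' `alpha_parallel`. Deterministic given the data.
#'
#' @param formula Initial model formula.
#' @param data Data frame (complete cases are used).
#' @param alpha_stay Retention threshold (default 0.05).
#' @param alpha_parallel Threshold for freeing a term from the parallel-lines
#'   constraint (default 0.05).
#' @param retest_parallel If `FALSE`, the constraint map is derived once from
#'   the initial model and kept fixed during elimination.
#' @return The final `eh_gologit`, with attribute `elimination` (a tibble of
#'   the removal path) and `screen` left untouched for callers to add.
#' @export
backward_eliminate <- function(formula, data, alpha_stay = 0.05,
                               alpha_parallel = 0.05,
                               retest_parallel = TRUE) {
  response <- all.vars(formula)[1]
  terms_now <- attr(stats::terms(formula, data = data), "term.labels")
  path <- list()
  cmap_fixed <- NULL
  step <- 0L
  repeat {
    step <- step + 1L
    if (!length(terms_now)) {
      rlang::warn("All terms eliminated; returning intercept-only model.",
                  class = "ehengage_empty_model_warning")
      fit <- gologit(stats::reformulate("1", response = response), data)
      break
    }
    f <- stats::reformulate(terms_now, response = response)
    base <- gologit(f, data, parallel = TRUE)
    if (retest_parallel || is.null(cmap_fixed)) {
      cmap <- derive_constraints(base, alpha_parallel)
      if (!retest_parallel) cmap_fixed <- cmap
    } else {
      cmap <- cmap_fixed[terms_now]
    }
    fit <- if (all(cmap == "parallel")) base else gologit(f, data, constraints = cmap)
    pvals <- purrr::map_dbl(terms_now, ~ wald_term(fit, .x)$p.value)
    worst <- which.max(pvals)
    if (pvals[worst] > alpha_stay) {
      path[[step]] <- tibble(step = step, dropped = terms_now[worst],
                             p.value = pvals[worst])
      terms_now <- terms_now[-worst]
    } else {
      break
    }
  }
  attr(fit, "elimination") <- bind_rows(path)
  fit
}

#' Full predictor-selection workflow for engagement
#'
#' Convenience wrapper reproducing the published strategy end to end:
#' bivariate screening at `alpha_enter`, then backward elimination with
#' per-step parallel-lines testing.
#'
#' @param data Data frame with the ordered outcome and candidate columns.
#' @param outcome Ordered outcome column name.
#' @param candidates Candidate term labels.
#' @param alpha_enter Bivariate entry threshold (default 0.20).
#' @param alpha_stay Backward-elimination retention threshold (default 0.05).
#' @param alpha_parallel Parallel-lines relaxation threshold (default 0.05).
#' @return The final `eh_gologit` with attributes `screen` and `elimination`.
#' @export
select_predictors <- function(data, outcome = "category",
                              candidates,
                              alpha_enter = 0.20, alpha_stay = 0.05,
                              alpha_parallel = 0.05) {
  scr <- bivariate_screen(outcome, candidates, data, alpha = alpha_enter)
  kept <- scr$term[scr$retained]
  fit <- if (!length(kept)) {
    rlang::warn("No candidate passed bivariate screening.",
                class = "ehengage_empty_model_warning")
    gologit(stats::reformulate("1", response = outcome), data)
  } else {
    backward_eliminate(stats::reformulate(kept, response = outcome), data,
                       alpha_stay = alpha_stay,
                       alpha_parallel = alpha_parallel)
  }
  attr(fit, "screen") <- scr
  fit
}
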