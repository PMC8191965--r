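#' Logistic model of wellbeing maintenance
#'
#' Fits a binomial logistic regression of the maintained/deprived
#' classification on socio-economic covariates by maximum likelihood
#' (via [stats::glm()]), and assembles the conventional reporting table:
#' per-term coefficient B, standard error, Wald statistic, df, p-value,
#' odds ratio Exp(B) and its 95% confidence interval, together with the
#' model-level Nagelkerke pseudo R-squared and the classification accuracy
#' at a 0.5 probability cutoff.
#'
#' Categorical covariates are expanded against their declared reference
#' level (e.g. income reference "LOW" for less than $600, gender reference
#' "Man"); multi-level factors additionally get a joint Wald test with
#' df = levels - 1. For single-df terms `Wald = (B/SE)^2` and
#' `CI = exp(B +/- 1.96 SE)` exactly.
#'
#' Perfect or quasi-complete separation is detected (fitted probabilities
#' numerically 0/1 or exploding coefficients) and reported with an explicit
#' warning and a `separation` flag rather than a silent non-convergence.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param outcome Name of the 0/1 outcome column (default `"maintained"`).
#' @param terms Character vector of covariate names entering the model.
#' @param reference Named list of reference levels for factor terms,
#'   e.g. `list(income_group = "LOW", gender = "Man")`.
#' @param conf_level Confidence level for the odds-ratio interval.
#' @param cutoff Probability cutoff for classification accuracy.
#' @return A `wc_fit` list: `terms` (coefficient tibble), `term_tests`
#'   (joint Wald tests, one row per model term), `nagelkerke`, `accuracy`
#'   (percent), `n`, `loglik`, `loglik_null`, `separation`, and the
#'   underlying `glm` object as `fit`.
#' @export
fit_maintenance_model <- function(data, outcome = "maintained", terms,
                                  reference = list(), conf_level = 0.95,
                                  cutoff = 0.5) {
  data <- as.data.frame(data)
  missing_terms <- setdiff(c(outcome, terms), names(data))
  if (length(missing_terms)) {
    wc_abort(sprintf("model columns not found: %s",
                     paste(missing_terms, collapse = ", ")),
             class = "wellcount_input_error")
  }
  data <- data[stats::complete.cases(data[c(outcome, terms)]), , drop = FALSE]
  y <- data[[outcome]]
  check_binary(y, "outcome")
  if (length(unique(y)) < 2) {
    wc_abort("outcome is constant; the model is not identified")
  }
  if (nrow(data) < length(terms) + 1) {
    wc_abort("fewer rows than model parameters")
  }
  for (nm in names(reference)) {
    if (nm %in% terms && is.factor(data[[nm]])) {
      data[[nm]] <- stats::relevel(droplevels(data[[nm]]), ref = reference[[nm]])
    }
  }

  form <- stats::reformulate(terms, response = outcome)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  V <- stats::vcov(fit)
  B <- stats::coef(fit)
  SE <- sqrt(diag(V))
  if (any(abs(B) > 15) || any(SE > 50)) separation <- TRUE
  if (separation) {
    warning(rlang::warning_cnd(
      class = "wellcount_separation_warning",
      message = paste("possible complete or quasi-complete separation:",
                      "coefficient estimates are unreliable")))
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coef_tbl <- tibble::tibble(
    term = names(B), B = unname(B), SE = unname(SE),
    Wald = unname((B / SE)^2), df = 1L,
    p = unname(stats::pchisq((B / SE)^2, df = 1, lower.tail = FALSE)),
    ExpB = unname(exp(B)),
    CI_lower = unname(exp(B - z * SE)),
    CI_upper = unname(exp(B + z * SE))
  )

  # joint Wald tests per model term (df = number of dummy columns)
  assign_idx <- attr(stats::model.matrix(fit), "assign")
  term_labels <- attr(stats::terms(fit), "term.labels")
  term_tests <- dplyr::bind_rows(lapply(seq_along(term_labels), function(i) {
    idx <- which(assign_idx == i)
    b <- B[idx]
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    tibble::tibble(term = term_labels[i], Wald = W, df = length(idx),
                   p = stats::pchisq(W, df = length(idx), lower.tail = FALSE))
  }))

  ll1 <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(stats::reformulate("1", response = outcome),
                     family = stats::binomial(), data = data)
  ll0 <- as.numeric(stats::logLik(fit0))
  p_hat <- stats::fitted(fit)

  structure(
    list(terms = coef_tbl, term_tests = term_tests,
         nagelkerke = nagelkerke_r2(ll0, ll1, nrow(data)),
         accuracy = classification_rate(p_hat, y, cutoff),
         n = nrow(data), loglik = ll1, loglik_null = ll0,
         separation = separation, fit = fit),
    class = "wc_fit"
  )
}

#' @export
print.wc_fit <- function(x, ...) {
  cat("<wc_fit> binomial logistic regression, n =", x$n, "\n")
  print(as.data.frame(x$terms), digits = 3)
  cat(sprintf("Nagelkerke R2 = %.3f; correctly classifies %.1f%% of cases\n",
              x$nagelkerke, x$accuracy))
  if (x$separation) cat("warning: separation detected\n")
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' The Cox-Snell likelihood-ratio measure rescaled to a 0-1 range:
#' `[1 - exp(2 (ll0 - ll1) / n)] / [1 - exp(2 ll0 / n)]`, where `ll0` and
#' `ll1` are the null and fitted log-likelihoods.
#'
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param loglik_model Log-likelihood of the fitted model
#'   (`>= loglik_null`).
#' @param n Number of observations.
#' @return Value in `[0, 1]`, or `NA` when the null likelihood is already 1
#'   (denominator 0).
#' @examples
#' nagelkerke_r2(-100, -60, 150)
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  if (n < 1) wc_abort("n must be >= 1", class = "wellcount_range_error")
  if (loglik_model < loglik_null - 1e-8) {
    wc_abort("model log-likelihood below the null log-likelihood")
  }
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom == 0) return(NA_real_)
  (1 - exp(2 * (loglik_null - loglik_model) / n)) / denom
}

#' Classification accuracy at a probability cutoff
#'
#' @param prob Fitted probabilities in `[0, 1]`.
#' @param outcome Observed 0/1 outcomes.
#' @param cutoff Probability cutoff (default 0.5).
#' @return Percent of cases whose predicted class (`prob >= cutoff`) matches
#'   the outcome.
#' @examples
#' classification_rate(c(0.9, 0.9), c(1, 0))  # 50
#' @export
classification_rate <- function(prob, outcome, cutoff = 0.5) {
  if (any(prob < 0 | prob > 1)) {
    wc_abort("probabilities must lie in [0, 1]", class = "wellcount_range_error")
  }
  check_binary(outcome, "outcome")
  100 * mean((prob >= cutoff) == (outcome == 1))
}
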