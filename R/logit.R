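# Age-adjusted binary logistic biomarker models: per-marker odds ratios with
# Wald intervals (exp(beta -/+ 1.96*SEM)), in-sample concordance index,
# delta-C against the base model, and likelihood-ratio tests of nested
# models.  Plain maximum likelihood (no penalization); quasi-separation is
# detected and flagged, not corrected.

#' Fit a binary logistic regression
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of
#' `y ~ covariates + markers`.  Standard errors come from the
#' observed-information matrix.  Quasi-separation (diverging coefficients or
#' fitted probabilities at the 0/1 boundary) sets `converged = FALSE` with a
#' warning rather than an error.
#'
#' @param y binary outcome: logical, 0/1, or a 2-level factor (second level
#'   is the event).
#' @param data data.frame holding covariates and markers.
#' @param covariates character, adjustment columns (default `"age"`).
#' @param markers character, marker columns (may be empty for the base
#'   model).
#' @return object of class `logit_result`: `coefficients` data.frame
#'   (`term`, `beta`, `sem`, `or_value`, `ci_low`, `ci_high`, `p_value` —
#'   Wald), `c_index`, `log_likelihood`, `n`, `converged`, `terms`.
#' @export
fit_logistic <- function(y, data, covariates = "age", markers = character()) {
  yb <- coerce_binary(y)
  if (length(unique(yb)) < 2) stop("outcome has a single class")
  vars <- c(covariates, markers)
  stopifnot(all(vars %in% names(data)) || length(vars) == 0)
  df <- data.frame(.y = yb, data[vars], check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", if (length(vars))
    paste(sprintf("`%s`", vars), collapse = " + ") else "1"))
  qr_x <- qr(stats::model.matrix(fml, df))
  if (qr_x$rank < ncol(qr_x$qr)) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(qr_x$qr)[-seq_len(qr_x$rank)], collapse = ", "))
  }
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  sem <- sqrt(diag(stats::vcov(fit)))
  converged <- fit$converged && !warned_sep && all(abs(beta) < 15)
  if (!converged) {
    warning("model did not converge cleanly (possible quasi-separation)")
  }
  orci <- t(vapply(seq_along(beta), function(i)
    unlist(odds_ratio_ci(beta[i], sem[i])), numeric(3)))
  coefs <- data.frame(
    term = names(beta), beta = unname(beta), sem = unname(sem),
    or_value = orci[, 1], ci_low = orci[, 2], ci_high = orci[, 3],
    p_value = 2 * stats::pnorm(-abs(beta / sem)),
    stringsAsFactors = FALSE)
  structure(
    list(coefficients = coefs,
         c_index = concordance_index(yb, stats::fitted(fit)),
         log_likelihood = as.numeric(stats::logLik(fit)),
         n = length(yb), converged = converged,
         terms = vars, fitted = stats::fitted(fit)),
    class = "logit_result")
}

coerce_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2) stop("outcome must have exactly 2 classes")
    y <- droplevels(y)
    as.integer(y == levels(y)[2])
  } else if (is.logical(y)) {
    as.integer(y)
  } else {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1))) stop("numeric outcome must be coded 0/1")
    as.integer(y)
  }
}

#' @export
print.logit_result <- function(x, ...) {
  cat("logistic model (", paste(x$terms, collapse = " + "), "), n = ", x$n,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  cat(sprintf("  C-index %.3f, log-likelihood %.2f\n", x$c_index, x$log_likelihood))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Odds ratio with Wald 95% confidence interval
#'
#' `OR = exp(beta)`; the interval is the exponential image of
#' `beta -/+ 1.96 * SEM`.
#'
#' @param beta log-odds coefficient.
#' @param sem its standard error (non-negative).
#' @return list with `or_value`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(beta, sem) {
  stopifnot(sem >= 0)
  list(or_value = exp(beta),
       ci_low = exp(beta - 1.96 * sem),
       ci_high = exp(beta + 1.96 * sem))
}

#' Concordance index (Harrell's C for binary outcomes)
#'
#' Over all case-control pairs, the fraction in which the case has the
#' higher risk score, counting ties as one half.  Computed from midranks, so
#' it is exact and O(n log n), and invariant under any strictly increasing
#' transform of the scores.
#'
#' @param y binary outcome (see [fit_logistic()] for accepted codings).
#' @param risk_scores numeric vector.
#' @return scalar in \[0, 1\].
#' @export
concordance_index <- function(y, risk_scores) {
  yb <- coerce_binary(y)
  if (length(unique(yb)) < 2) stop("both classes must be present")
  n1 <- sum(yb == 1); n0 <- sum(yb == 0)
  r <- rank(risk_scores)  # midranks handle ties as 1/2
  (sum(r[yb == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare nested logistic models
#'
#' Likelihood-ratio test `2 * (ll_extended - ll_base)` on a chi-squared
#' reference with as many degrees of freedom as added terms, plus the
#' C-index difference.
#'
#' @param base,extended `logit_result` objects fitted on the same samples;
#'   `base`'s terms must be a subset of `extended`'s.
#' @return list of class `model_comparison`: `delta_c`, `lr_chi2`, `df`,
#'   `p_value`, plus the two C-indexes.
#' @export
compare_models <- function(base, extended) {
  if (!all(base$terms %in% extended$terms)) {
    stop("models are not nested: base terms must be a subset of extended terms")
  }
  if (base$n != extended$n) stop("models were fitted on different sample counts")
  df <- length(extended$terms) - length(base$terms)
  lr <- 2 * (extended$log_likelihood - base$log_likelihood)
  structure(
    list(delta_c = extended$c_index - base$c_index,
         lr_chi2 = lr, df = df,
         p_value = if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE) else NA_real_,
         c_base = base$c_index, c_extended = extended$c_index),
    class = "model_comparison")
}

#' Step-by-step marker table for one outcome contrast
#'
#' Builds the standard biomarker-panel report: one row per single marker
#' (outcome ~ age + marker, with beta, SEM, OR, 95% CI, Wald p, C-index and
#' delta-C against the covariates-only model) and, from the second marker
#' on, one row per cumulative combination (combined C-index, delta-C against
#' the previous combination, likelihood-ratio chi-squared and its p).
#'
#' @param y binary outcome.
#' @param data data.frame with covariate and marker columns.
#' @param markers character, ordered marker names (order defines the
#'   cumulative additions).
#' @param covariates adjustment columns, default `"age"`.
#' @return data.frame with columns `model`, `type` (single/combined),
#'   `beta`, `sem`, `or_value`, `ci_low`, `ci_high`, `wald_p`, `c_index`,
#'   `delta_c`, `lr_chi2`, `lr_p`, `converged`.  A failing single-marker fit
#'   yields a row with `NA` statistics rather than aborting the table.
#' @export
stepwise_marker_table <- function(y, data, markers, covariates = "age") {
  stopifnot(length(markers) >= 1)
  base <- fit_logistic(y, data, covariates, character())
  rows <- list()
  prev <- base
  for (k in seq_along(markers)) {
    mk <- markers[k]
    single <- tryCatch(
      suppressWarnings(fit_logistic(y, data, covariates, mk)),
      error = function(e) NULL)
    if (is.null(single)) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = mk, type = "single", beta = NA_real_, sem = NA_real_,
        or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        wald_p = NA_real_, c_index = NA_real_, delta_c = NA_real_,
        lr_chi2 = NA_real_, lr_p = NA_real_, converged = FALSE,
        stringsAsFactors = FALSE)
    } else {
      co <- single$coefficients[single$coefficients$term == mk, ]
      rows[[length(rows) + 1L]] <- data.frame(
        model = mk, type = "single", beta = co$beta, sem = co$sem,
        or_value = co$or_value, ci_low = co$ci_low, ci_high = co$ci_high,
        wald_p = co$p_value, c_index = single$c_index,
        delta_c = single$c_index - base$c_index,
        lr_chi2 = NA_real_, lr_p = NA_real_, converged = single$converged,
        stringsAsFactors = FALSE)
    }
    if (k >= 2) {
      combo <- tryCatch(
        suppressWarnings(fit_logistic(y, data, covariates, markers[seq_len(k)])),
        error = function(e) NULL)
      if (is.null(combo)) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = paste(markers[seq_len(k)], collapse = " + "),
          type = "combined", beta = NA_real_, sem = NA_real_,
          or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          wald_p = NA_real_, c_index = NA_real_, delta_c = NA_real_,
          lr_chi2 = NA_real_, lr_p = NA_real_, converged = FALSE,
          stringsAsFactors = FALSE)
      } else {
        cmp <- compare_models(prev, combo)
        rows[[length(rows) + 1L]] <- data.frame(
          model = paste(markers[seq_len(k)], collapse = " + "),
          type = "combined", beta = NA_real_, sem = NA_real_,
          or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          wald_p = NA_real_, c_index = combo$c_index, delta_c = cmp$delta_c,
          lr_chi2 = cmp$lr_chi2, lr_p = cmp$p_value,
          converged = combo$converged, stringsAsFactors = FALSE)
        prev <- combo
      }
    } else {
      if (!is.null(single)) prev <- single
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
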