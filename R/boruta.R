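# All-relevant feature selection with shadow attributes.  Each iteration
# appends a permuted ("shadow") copy of every undecided feature to the
# design, grows a random forest, and scores each real feature's normalized
# permutation importance (mean decrease in accuracy divided by its standard
# error over trees) against the best shadow.  Features that beat the best
# shadow significantly more often than chance (binomial test, Bonferroni
# over the undecided set) are Confirmed; significantly less often, Rejected;
# the rest stay Tentative.  Tentative features are never force-resolved.

#' Adjust protein values for covariates by per-assay linear regression
#'
#' For each assay, fits ordinary least squares of NPX on an intercept plus
#' the covariates over the non-missing samples and returns the residuals.
#' Missing cells stay missing.  Sex is coded as an indicator (M = 1).
#' Constant covariates are dropped from the design with a warning.
#'
#' @param m an [npx_matrix].
#' @param info a [sample_info] data.frame aligned with `m`'s samples.
#' @param covariates character, columns of `info` to adjust for; default
#'   `c("age", "sex")`.
#' @return an [npx_matrix] whose values are the per-assay residuals.
#' @export
residualize_covariates <- function(m, info, covariates = c("age", "sex")) {
  stopifnot(identical(info$sample_id, m$sample_ids))
  design <- list(`(Intercept)` = rep(1, nrow(m$values)))
  for (v in covariates) {
    col <- info[[v]]
    if (is.factor(col) || is.character(col)) {
      f <- droplevels(factor(col))
      if (nlevels(f) < 2) {
        warning("covariate '", v, "' is constant; dropped from the design")
        next
      }
      col <- as.numeric(f == levels(f)[2])
    }
    if (anyNA(col)) stop("covariate '", v, "' has missing values")
    if (stats::sd(col) == 0) {
      warning("covariate '", v, "' is constant; dropped from the design")
      next
    }
    design[[v]] <- as.numeric(col)
  }
  X <- do.call(cbind, design)
  out <- m$values
  for (j in seq_len(ncol(out))) {
    obs <- which(!is.na(out[, j]))
    if (length(obs) <= ncol(X)) {
      stop("assay '", m$assays$name[j], "': too few observed values to adjust")
    }
    fit <- stats::lm.fit(X[obs, , drop = FALSE], out[obs, j])
    out[obs, j] <- fit$residuals
  }
  m$values <- out
  m
}

#' Replace missing values by per-assay medians (rough fix)
#'
#' Median imputation in the style of `randomForest::na.roughfix`: each
#' missing numeric entry becomes the median of its assay's non-missing
#' values.
#'
#' @param m an [npx_matrix] or plain numeric matrix.
#' @return complete object of the same kind.
#' @export
roughfix_missing <- function(m) {
  is_npx <- inherits(m, "npx_matrix")
  x <- if (is_npx) m$values else as.matrix(m)
  all_miss <- colSums(!is.na(x)) == 0
  if (any(all_miss)) {
    stop("assay(s) with all values missing: ",
         paste(colnames(x)[all_miss], collapse = ", "))
  }
  for (j in which(colSums(is.na(x)) > 0)) {
    x[is.na(x[, j]), j] <- stats::median(x[, j], na.rm = TRUE)
  }
  if (is_npx) { m$values <- x; return(m) }
  x
}

#' Shadow-feature all-relevant selection
#'
#' @param X complete numeric matrix, samples x features (adjust covariates
#'   and rough-fix missing values first).
#' @param y binary outcome, one value per sample (factor or coercible).
#' @param max_runs iteration cap, default 500; at least 8 (binomial
#'   decisions are impossible below that).
#' @param alpha significance level of the binomial decision tests, default
#'   0.05, Bonferroni-corrected over the currently undecided features.
#' @param ntree trees per forest, default 500.
#' @param mtry features tried per split; default `floor(sqrt(p))` over the
#'   real + shadow design.
#' @param seed integer seed governing shadows and forests.
#' @param verbose emit per-iteration progress messages.
#' @return object of class `boruta_state`: `decisions` (named character,
#'   Confirmed/Tentative/Rejected), `hit_counts`, `n_completed_iterations`,
#'   `importance_history` (iterations x features, NA once rejected),
#'   `shadow_history` (per-iteration min/mean/max shadow Z), `alpha`,
#'   `max_runs`, `seed`.
#' @export
boruta_select <- function(X, y, max_runs = 500, alpha = 0.05,
                          ntree = 500, mtry = NULL, seed = 1L,
                          verbose = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must be binary (exactly 2 classes)")
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  if (max_runs < 8) stop("max_runs must be at least 8 for binomial decisions")
  if (anyNA(X)) stop("X must be complete; run roughfix_missing() first")
  p <- ncol(X)
  features <- colnames(X)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  decisions <- stats::setNames(rep("Tentative", p), features)
  hit_counts <- stats::setNames(rep(0L, p), features)
  imp_history <- list()
  shadow_history <- list()
  iter <- 0L
  while (iter < max_runs && any(decisions == "Tentative")) {
    iter <- iter + 1L
    # Rejected features leave the design; Confirmed ones stay in the forest
    # (they keep absorbing the signal, so chance correlations in undecided
    # features are not inflated), but only Tentative features accumulate
    # hits and face decisions.  Shadows are fresh permuted copies of EVERY
    # original feature, so the max-shadow benchmark keeps the strength of
    # the full null ensemble for the whole run; a shadow pool that shrank
    # with the active set would let late survivors clear an ever-lower bar.
    active <- which(decisions != "Rejected")
    und <- which(decisions == "Tentative")
    real <- X[, active, drop = FALSE]
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(X))
    design <- cbind(real, shadow)
    m_try <- if (is.null(mtry)) max(1L, floor(sqrt(ncol(design)))) else mtry
    rf <- randomForest::randomForest(design, y, ntree = ntree, mtry = m_try,
                                     importance = TRUE)
    z <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    z[!is.finite(z)] <- 0  # constant importance across trees has no Z
    z_active <- z[seq_along(active)]
    z_shadow <- z[-seq_along(active)]
    zmax_shadow <- max(z_shadow)
    und_pos <- match(und, active)
    hits <- z_active[und_pos] > zmax_shadow
    hit_counts[und] <- hit_counts[und] + as.integer(hits)

    row <- rep(NA_real_, p)
    row[active] <- z_active
    imp_history[[iter]] <- row
    shadow_history[[iter]] <- c(min = min(z_shadow), mean = mean(z_shadow),
                                max = zmax_shadow)

    # Bonferroni over the full feature set (constant multiplier p): decided
    # features keep their hit history, so every feature's binomial test is
    # corrected against the same family.  A multiplier that shrank with the
    # undecided set would make confirmation ever easier late in a run.
    p_hi <- stats::pbinom(hit_counts[und] - 1L, iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hit_counts[und], iter, 0.5)
    confirm <- p_hi * p < alpha
    reject <- p_lo * p < alpha
    decisions[und[confirm]] <- "Confirmed"
    decisions[und[reject]] <- "Rejected"
    if (verbose) {
      message(sprintf("iteration %d: %d confirmed, %d rejected, %d tentative",
                      iter, sum(decisions == "Confirmed"),
                      sum(decisions == "Rejected"),
                      sum(decisions == "Tentative")))
    }
  }
  hist_mat <- do.call(rbind, imp_history)
  colnames(hist_mat) <- features
  shadow_df <- as.data.frame(do.call(rbind, shadow_history))
  structure(
    list(features = features, decisions = decisions, hit_counts = hit_counts,
         n_completed_iterations = iter, importance_history = hist_mat,
         shadow_history = shadow_df, alpha = alpha, max_runs = max_runs,
         seed = seed),
    class = "boruta_state")
}

#' @export
print.boruta_state <- function(x, ...) {
  tab <- table(factor(x$decisions, levels = c("Confirmed", "Tentative", "Rejected")))
  cat("boruta_state: ", x$n_completed_iterations, " iterations; ",
      tab["Confirmed"], " confirmed, ", tab["Tentative"], " tentative, ",
      tab["Rejected"], " rejected\n", sep = "")
  invisible(x)
}

#' Variable-importance chart table
#'
#' Per-feature min, mean and max importance Z over the iterations the
#' feature participated in, with its decision, sorted by mean Z descending;
#' a summary row for the shadow attributes (min of per-iteration minima,
#' mean of means, max of maxima) is appended last.
#'
#' @param state a `boruta_state`.
#' @return data.frame with columns `feature`, `decision`, `min_z`, `mean_z`,
#'   `max_z`; the final row has feature `"shadow"` and decision `"Shadow"`.
#' @export
importance_chart_table <- function(state) {
  if (state$n_completed_iterations < 1) stop("no completed iterations")
  h <- state$importance_history
  rows <- data.frame(
    feature = state$features,
    decision = unname(state$decisions),
    min_z = apply(h, 2, min, na.rm = TRUE),
    mean_z = apply(h, 2, mean, na.rm = TRUE),
    max_z = apply(h, 2, max, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rows <- rows[order(-rows$mean_z), ]
  sh <- state$shadow_history
  rows <- rbind(rows, data.frame(
    feature = "shadow", decision = "Shadow",
    min_z = min(sh$min), mean_z = mean(sh$mean), max_z = max(sh$max),
    stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' Group-wise mean NPX of confirmed biomarkers (Cleveland summary)
#'
#' For each confirmed feature, the arithmetic mean of the raw
#' (un-residualized) NPX per study group, optionally joined with q-values
#' from a [volcano_table()] of the same contrast.
#'
#' @param m an [npx_matrix] of raw NPX values.
#' @param labels group label per sample.
#' @param confirmed character vector of confirmed feature names.
#' @param volcano optional data.frame from [volcano_table()]; its `q_value`
#'   is joined by assay name.
#' @return data.frame with one row per (feature, group): `feature`, `group`,
#'   `mean_npx`, and `q_value` if a volcano table was given.  Empty
#'   `confirmed` yields an empty table.
#' @export
cleveland_summary <- function(m, labels, confirmed, volcano = NULL) {
  labels <- as.character(labels)
  if (!length(confirmed)) {
    out <- data.frame(feature = character(), group = character(),
                      mean_npx = numeric(), stringsAsFactors = FALSE)
    if (!is.null(volcano)) out$q_value <- numeric()
    return(out)
  }
  missing_feat <- setdiff(confirmed, m$assays$name)
  if (length(missing_feat)) {
    stop("confirmed feature(s) not in matrix: ", paste(missing_feat, collapse = ", "))
  }
  groups <- unique(labels)
  rows <- expand.grid(feature = confirmed, group = groups,
                      stringsAsFactors = FALSE)
  rows$mean_npx <- mapply(function(f, g) {
    j <- match(f, m$assays$name)
    mean(m$values[labels == g, j], na.rm = TRUE)
  }, rows$feature, rows$group)
  if (!is.null(volcano)) {
    rows$q_value <- volcano$q_value[match(rows$feature, volcano$assay)]
  }
  rows[order(rows$feature, rows$group), , drop = FALSE]
}
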