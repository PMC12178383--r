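# Per-protein Welch two-sample tests with Benjamini-Hochberg FDR control and
# volcano-style classification.  Because NPX is log2-scale, the mean NPX
# difference between two groups is the log2 fold change.  Missing values are
# excluded pairwise per assay; no imputation is done for testing.

#' Welch two-sample t-test
#'
#' Unequal-variance t-test of `y` against `x`.  The estimate is
#' `mean(y) - mean(x)`; degrees of freedom follow Welch-Satterthwaite; the
#' p-value is two-sided.
#'
#' @param x,y numeric vectors (group 1, group 2); `NA`s dropped; each group
#'   needs at least 2 values.
#' @return list with `estimate`, `t`, `df`, `p_value`.
#' @export
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 non-missing values")
  }
  fit <- stats::t.test(y, x, var.equal = FALSE)
  list(estimate = unname(mean(y) - mean(x)),
       t = unname(fit$statistic),
       df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) with monotonicity enforcement,
#' capped at 1.  Missing p-values propagate to missing q-values and do not
#' count toward the family size.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
adjust_fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Volcano table: per-assay differential abundance between two groups
#'
#' One Welch test per assay of `group2` against `group1`, BH-adjusted across
#' all testable assays of this contrast (each contrast is its own FDR
#' family).  Direction classes at `q_threshold`: `up_in_group2` when the
#' estimate (group2 - group1 mean NPX) is positive and q below threshold,
#' `up_in_group1` when negative, `ns` otherwise.  Low-detection flags on the
#' matrix are carried through.
#'
#' @param m an [npx_matrix].
#' @param labels group label per sample.
#' @param group1,group2 labels of the contrast.
#' @param q_threshold significance cutoff on the q-value, default 0.05.
#' @return data.frame with one row per assay: `assay`, `panel`, `estimate`,
#'   `t`, `df`, `p_value`, `q_value`, `direction_class`,
#'   `flagged_low_detection`.  Assays with fewer than 2 values in a group get
#'   `NA` statistics and class `ns`, with a warning.
#' @export
volcano_table <- function(m, labels, group1, group2, q_threshold = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m$values))
  i1 <- labels == group1; i2 <- labels == group2
  if (!any(i1) || !any(i2)) stop("both contrast groups must be present")
  n_assay <- ncol(m$values)
  est <- tval <- dfv <- pv <- rep(NA_real_, n_assay)
  skipped <- character()
  for (j in seq_len(n_assay)) {
    x <- m$values[i1, j]; y <- m$values[i2, j]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      skipped <- c(skipped, m$assays$name[j])
      next
    }
    w <- welch_test(x, y)
    est[j] <- w$estimate; tval[j] <- w$t; dfv[j] <- w$df; pv[j] <- w$p_value
  }
  if (length(skipped)) {
    warning(length(skipped), " assay(s) skipped (fewer than 2 values per group): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  }
  qv <- adjust_fdr_bh(pv)
  cls <- rep("ns", n_assay)
  sig <- !is.na(qv) & qv < q_threshold
  cls[sig & est > 0] <- "up_in_group2"
  cls[sig & est < 0] <- "up_in_group1"
  data.frame(
    assay = m$assays$name, panel = m$assays$panel,
    estimate = est, t = tval, df = dfv, p_value = pv, q_value = qv,
    direction_class = cls,
    flagged_low_detection = m$assays$name %in% m$low_detection_flagged,
    stringsAsFactors = FALSE)
}

#' Demographic comparisons across diagnosis groups
#'
#' Chi-squared test of independence (no continuity correction) for
#' categorical variables and Kruskal-Wallis H for continuous variables, with
#' per-group medians and ranges.  Groups lacking data for a continuous
#' variable are dropped from that variable's test.
#'
#' @param info a [sample_info] data.frame; extra continuous columns (e.g.
#'   tryptase) may be present.
#' @param continuous character vector of continuous column names, default
#'   `"age"`.
#' @param categorical character vector of categorical column names, default
#'   `"sex"`.
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, plus a `summary` string of per-group
#'   medians (ranges) or counts.
#' @export
compare_demographics <- function(info, continuous = "age", categorical = "sex") {
  g <- droplevels(factor(info$diagnosis))
  if (nlevels(g) < 2) stop("need at least 2 diagnosis groups")
  rows <- list()
  for (v in categorical) {
    x <- factor(info[[v]])
    tab <- table(x, g)
    if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
      warning("variable '", v, "': empty row/column in contingency table")
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected == 0)) warning("variable '", v, "': expected cell count 0")
    rows[[v]] <- data.frame(
      variable = v, test = "chi-squared",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value,
      summary = paste(vapply(levels(g), function(l) {
        paste0(l, "=", paste(table(x[g == l]), collapse = ":"))
      }, character(1)), collapse = "; "),
      stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x <- info[[v]]
    keep <- !is.na(x)
    gg <- droplevels(g[keep])
    if (nlevels(gg) < 2) {
      warning("variable '", v, "': fewer than 2 groups with data; skipped")
      next
    }
    kt <- stats::kruskal.test(x[keep], gg)
    rows[[v]] <- data.frame(
      variable = v, test = "kruskal-wallis",
      statistic = unname(kt$statistic), df = unname(kt$parameter),
      p_value = kt$p.value,
      summary = paste(vapply(levels(gg), function(l) {
        xi <- x[keep][gg == l]
        sprintf("%s=%.1f (%.1f-%.1f)", l, stats::median(xi), min(xi), max(xi))
      }, character(1)), collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
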