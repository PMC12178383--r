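test_that("logistic fit recovers parameters and its own likelihood", {
  set.seed(30)
  n <- 5000
  x <- rnorm(n)
  p <- plogis(-1 + 0.8 * x)
  y <- rbinom(n, 1, p)
  fit <- fit_logistic(y, data.frame(x = x), covariates = character(),
                      markers = "x")
  b <- fit$coefficients
  expect_lt(abs(b$beta[b$term == "x"] - 0.8), 0.1)
  expect_lt(abs(b$beta[b$term == "(Intercept)"] - (-1)), 0.1)
  # log-likelihood is the Bernoulli log-likelihood at the fitted probabilities
  ll <- sum(y * log(fit$fitted) + (1 - y) * log(1 - fit$fitted))
  expect_lt(abs(fit$log_likelihood - ll), 1e-8)
  expect_true(fit$converged)
})

test_that("an uninformative marker yields an odds ratio of 1", {
  v <- rnorm(20)
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(y, data.frame(m = c(v, v)), covariates = character(),
                      markers = "m")
  co <- fit$coefficients
  expect_lt(abs(co$beta[co$term == "m"]), 1e-6)
  expect_lt(abs(co$or_value[co$term == "m"] - 1), 1e-6)
})

test_that("degenerate designs are refused or flagged", {
  y <- rep(c(0, 1), each = 10)
  expect_error(fit_logistic(rep(1, 20), data.frame(x = rnorm(20)),
                            covariates = character(), markers = "x"),
               "single class")
  d <- data.frame(a = rnorm(20))
  d$b <- 2 * d$a
  expect_error(fit_logistic(y, d, covariates = character(),
                            markers = c("a", "b")), "rank deficient")
  # perfect separation: flagged, not an error
  sep <- data.frame(x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_warning(fs <- fit_logistic(y, sep, covariates = character(),
                                    markers = "x"), "converge")
  expect_false(fs$converged)
})

test_that("odds ratio and CI are the exp-image of beta +/- 1.96 SEM", {
  r <- odds_ratio_ci(0, 0.5)
  expect_equal(r$or_value, 1)
  expect_equal(r$ci_low * r$ci_high, 1, tolerance = 1e-12)  # symmetric in log
  r2 <- odds_ratio_ci(1.2, 0.3)
  expect_equal(r2$ci_low, exp(1.2 - 1.96 * 0.3))
  expect_equal(r2$ci_high, exp(1.2 + 1.96 * 0.3))
  expect_error(odds_ratio_ci(1, -0.1))
})

test_that("concordance index equals exhaustive pair counting", {
  # perfect separation and all-ties anchors
  expect_equal(concordance_index(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(concordance_index(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
    expect_identical(concordance_index(y, s), cindex_brute_force(y, s))
  }
  # invariant under strictly increasing transforms
  y <- rep(c(0, 1), 15)
  s <- rnorm(30)
  expect_equal(concordance_index(y, s), concordance_index(y, exp(s)))
  expect_equal(concordance_index(y, s), concordance_index(y, rank(s)))
})

test_that("nested model comparison computes delta-C and the LR test", {
  set.seed(32)
  n <- 500
  age <- runif(n, 30, 85)
  m1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.03 * age + 1.0 * m1))
  d <- data.frame(age = age, m1 = m1, noise = rnorm(n))
  base <- fit_logistic(y, d, "age", character())
  ext <- fit_logistic(y, d, "age", "m1")
  cmp <- compare_models(base, ext)
  expect_equal(cmp$df, 1)
  expect_gt(cmp$lr_chi2, 0)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$delta_c, ext$c_index - base$c_index, tolerance = 1e-12)
  # identity comparison
  same <- compare_models(base, base)
  expect_equal(same$delta_c, 0)
  expect_equal(same$lr_chi2, 0, tolerance = 1e-10)
  # non-nested models refuse
  other <- fit_logistic(y, d, "noise", character())
  expect_error(compare_models(ext, other), "not nested")
  # nested LR is non-negative
  ext2 <- fit_logistic(y, d, "age", c("m1", "noise"))
  expect_gte(compare_models(ext, ext2)$lr_chi2, -1e-8)
})

test_that("adding an informative marker is detected with high power", {
  set.seed(33)
  hits <- replicate(10, {
    n <- 500
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * x))
    d <- data.frame(x = x)
    base <- fit_logistic(y, d, character(), character())
    ext <- fit_logistic(y, d, character(), "x")
    compare_models(base, ext)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise marker table has the single + cumulative layout", {
  set.seed(34)
  n <- 200
  age <- runif(n, 30, 85)
  m1 <- rnorm(n); m2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + 0.02 * age + 0.9 * m1 + 0.9 * m2))
  d <- data.frame(age = age, m1 = m1, m2 = m2, m3 = rnorm(n))
  tab <- stepwise_marker_table(y, d, c("m1", "m2", "m3"))
  expect_equal(nrow(tab), 3 + 2)  # singles + cumulative combos
  expect_equal(tab$type, c("single", "single", "combined", "single", "combined"))
  singles <- tab[tab$type == "single", ]
  expect_false(anyNA(singles$beta))
  expect_true(all(is.na(tab$beta[tab$type == "combined"])))
  combo12 <- tab$c_index[tab$model == "m1 + m2"]
  expect_gte(combo12, max(singles$c_index[singles$model %in% c("m1", "m2")]) - 1e-9)
  expect_false(anyNA(tab$lr_chi2[tab$type == "combined"]))

  # a perfectly separating marker is flagged, table still emitted
  d$sep <- ifelse(y == 1, 10, -10) + rnorm(n, sd = 0.01)
  tab2 <- suppressWarnings(stepwise_marker_table(y, d, c("sep", "m1")))
  expect_false(tab2$converged[tab2$model == "sep"])
  expect_equal(nrow(tab2), 3)
})
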