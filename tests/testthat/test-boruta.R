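test_that("covariate residualization has the OLS orthogonality properties", {
  # covariate orthogonal to the centered response leaves it unchanged
  x <- c(1, 2, 3, 4)
  v <- c(1, -1, -1, 1)  # orthogonal to centered x, mean zero
  m <- make_npx(matrix(x, ncol = 1))
  info <- sample_info(m$sample_ids, rep("ISM", 4), age = v + 2, sex = rep("F", 4))
  expect_warning(r <- residualize_covariates(m, info), "constant")  # sex constant
  expect_lt(max(abs(r$values[, 1] - (x - mean(x)))), 1e-10)

  # response built from age: residuals uncorrelated with age, mean zero
  set.seed(20)
  n <- 50
  age <- runif(n, 25, 85)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  vals <- matrix(0.5 * age + rnorm(n * 3), n, 3)
  m2 <- make_npx(vals)
  info2 <- sample_info(m2$sample_ids, rep("ISM", n), age, sex)
  r2 <- residualize_covariates(m2, info2)
  for (j in 1:3) {
    expect_lt(abs(cor(r2$values[, j], age)), 1e-10)
    expect_lt(abs(mean(r2$values[, j])), 1e-10)
  }
  # missing cells stay missing
  vals[3, 2] <- NA
  m3 <- make_npx(vals)
  r3 <- residualize_covariates(m3, info2)
  expect_true(is.na(r3$values[3, 2]))
  expect_equal(sum(is.na(r3$values)), 1L)
})

test_that("rough-fix imputation fills per-assay medians", {
  expect_equal(roughfix_missing(matrix(c(1, 2, NA, 4), 4, 1))[3, 1], 2)
  expect_equal(roughfix_missing(matrix(c(1, 2, 3, 4, NA), 5, 1))[5, 1], 2.5)
  x <- matrix(rnorm(12), 4, 3)
  expect_identical(roughfix_missing(x), x)
  x[, 2] <- NA
  colnames(x) <- c("a", "bad", "c")
  expect_error(roughfix_missing(x), "bad")
})

test_that("shadow-feature selection recovers a planted feature", {
  set.seed(21)
  n <- 60
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 21), n, 21, dimnames = list(NULL, paste0("F", 1:21)))
  X[, 1] <- as.numeric(y == "B") + rnorm(n, sd = 0.1)
  st <- boruta_select(X, y, max_runs = 40, ntree = 300, seed = 1)
  expect_equal(unname(st$decisions["F1"]), "Confirmed")
  expect_false(any(st$decisions[-1] == "Confirmed"))
  # state invariants
  expect_true(all(st$hit_counts <= st$n_completed_iterations))
  expect_setequal(names(st$decisions), colnames(X))  # shadows never decided
  expect_true(all(st$decisions %in% c("Confirmed", "Tentative", "Rejected")))
  expect_equal(nrow(st$importance_history), st$n_completed_iterations)
  expect_equal(nrow(st$shadow_history), st$n_completed_iterations)
})

test_that("selection is reproducible for a fixed seed", {
  set.seed(22)
  n <- 40
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("F", 1:8)))
  X[, 1] <- as.numeric(y == "B") * 2 + rnorm(n, sd = 0.3)
  a <- boruta_select(X, y, max_runs = 15, ntree = 100, seed = 5)
  b <- boruta_select(X, y, max_runs = 15, ntree = 100, seed = 5)
  expect_identical(a$decisions, b$decisions)
  expect_identical(a$importance_history, b$importance_history)
  expect_identical(a$shadow_history, b$shadow_history)
})

test_that("selection rejects invalid inputs", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(boruta_select(X, rep("a", 10)), "binary")
  expect_error(boruta_select(X, factor(rep(c("a", "b", "c"), c(4, 4, 2)))),
               "binary")
  expect_error(boruta_select(X, factor(rep(c("a", "b"), each = 5)),
                             max_runs = 5), "at least 8")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(boruta_select(Xna, factor(rep(c("a", "b"), each = 5))),
               "complete")
})

test_that("a full run of hits confirms under the Bonferroni rule", {
  # consistency of the decision arithmetic: a feature beating the best
  # shadow in all of 12 iterations among 50 candidates satisfies
  # 0.5^12 * 50 < 0.05, i.e. must be Confirmed
  expect_lt(pbinom(11, 12, 0.5, lower.tail = FALSE) * 50, 0.05)
  # and empirically: a dominant feature is confirmed within ~12 iterations
  set.seed(23)
  n <- 60
  y <- factor(rep(c("A", "B"), each = n / 2))
  X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("F", 1:50)))
  X[, 1] <- as.numeric(y == "B") + rnorm(n, sd = 0.05)
  st <- boruta_select(X, y, max_runs = 20, ntree = 300, seed = 2)
  expect_equal(unname(st$decisions["F1"]), "Confirmed")
  # confirmation at the earliest iteration the all-hits binomial allows:
  # hits accrue only while undecided, so the count equals that iteration
  expect_gte(unname(st$hit_counts["F1"]), 10)
  expect_lte(unname(st$hit_counts["F1"]), st$n_completed_iterations)
})

test_that("importance chart summarizes per-feature Z and appends the shadow row", {
  state <- structure(list(
    features = c("f1", "f2"),
    decisions = c(f1 = "Confirmed", f2 = "Rejected"),
    hit_counts = c(f1 = 3L, f2 = 0L),
    n_completed_iterations = 3L,
    importance_history = matrix(c(5, 6, 7, -1, NA, NA), ncol = 2,
                                dimnames = list(NULL, c("f1", "f2"))),
    shadow_history = data.frame(min = c(-2, -1, -1.5), mean = c(0, 0.5, 0.25),
                                max = c(1, 2, 1.5)),
    alpha = 0.05, max_runs = 10, seed = 1), class = "boruta_state")
  tab <- importance_chart_table(state)
  expect_equal(nrow(tab), 3L)  # 2 features + shadow summary
  expect_equal(tab$feature, c("f1", "f2", "shadow"))
  expect_equal(tab[tab$feature == "f1", c("min_z", "mean_z", "max_z")],
               data.frame(min_z = 5, mean_z = 6, max_z = 7, row.names = 1L))
  expect_equal(tab[tab$feature == "f2", "mean_z"], -1)  # single iteration
  expect_equal(tab[tab$feature == "shadow", "max_z"], 2)
  expect_equal(tab[tab$feature == "shadow", "min_z"], -2)
})

test_that("Cleveland summary reports group means of raw NPX", {
  co <- generate_cohort(small_cohort(seed = 33, shift = 2))
  m <- resolve_duplicate_assays(co$npx)
  lab <- as.character(co$info$diagnosis)
  v <- volcano_table(m, lab, "ISM", "AdvSM")
  cs <- cleveland_summary(m, lab, c("PROT002", "PROT005"), v)
  expect_equal(nrow(cs), 2 * length(unique(lab)))
  # means match direct averaging
  j <- match("PROT005", m$assays$name)
  direct <- mean(m$values[lab == "ISM", j], na.rm = TRUE)
  expect_equal(cs$mean_npx[cs$feature == "PROT005" & cs$group == "ISM"],
               direct, tolerance = 1e-12)
  # planted AdvSM shift shows up in the group means
  expect_gt(cs$mean_npx[cs$feature == "PROT002" & cs$group == "AdvSM"],
            cs$mean_npx[cs$feature == "PROT002" & cs$group == "ISM"])
  # q-values joined by assay
  expect_equal(cs$q_value[cs$feature == "PROT002"][1],
               v$q_value[v$assay == "PROT002"])
  # empty confirmed set: empty table, no error
  empty <- cleveland_summary(m, lab, character())
  expect_equal(nrow(empty), 0L)
})
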