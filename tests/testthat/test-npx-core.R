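test_that("long-format reader assembles the wide matrix", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "SampleID,Assay,Panel,NPX,LOD",
    "s1,A,P,1.5,0",
    "s1,B,P,2.5,0",
    "s2,A,P,3.5,0",
    "s2,B,P,4.5,0"), path)
  m <- read_npx_long(path)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_false(anyNA(m$values))
  expect_equal(m$values["s2", "B"], 4.5)

  # omitting one (sample, assay) pair leaves exactly that cell missing
  writeLines(c(
    "SampleID,Assay,Panel,NPX,LOD",
    "s1,A,P,1.5,0",
    "s1,B,P,2.5,0",
    "s2,A,P,3.5,0"), path)
  m <- read_npx_long(path)
  expect_true(is.na(m$values["s2", "B"]))
  expect_equal(sum(is.na(m$values)), 1L)

  # duplicate (sample, assay, panel) rows are a parse error with the row
  writeLines(c(
    "SampleID,Assay,Panel,NPX,LOD",
    "s1,A,P,1.5,0",
    "s1,A,P,1.6,0"), path)
  expect_error(read_npx_long(path), "duplicate.*row")
  writeLines("SampleID,Assay,NPX", path)
  expect_error(read_npx_long(path), "lacks column")
})

test_that("duplicate assay resolution keeps the better-detected copy", {
  vals <- cbind(rep(1, 10), rep(1, 10), rep(1, 10))
  blod <- cbind(c(rep(TRUE, 4), rep(FALSE, 6)),   # 0.40 below LOD
                c(TRUE, rep(FALSE, 9)),           # 0.10 below LOD
                rep(FALSE, 10))
  m <- npx_matrix(vals,
                  data.frame(name = c("X", "X", "Y"),
                             panel = c("P1", "P2", "P1"),
                             lod = 0, stringsAsFactors = FALSE),
                  below_lod = blod)
  r <- resolve_duplicate_assays(m)
  expect_equal(nrow(r$assays), 2L)
  expect_equal(r$assays$panel[r$assays$name == "X"], "P2")
  # retained values untouched
  expect_equal(unname(r$values), unname(vals[, c(2, 3)]))

  # no duplicates: identity
  m2 <- make_npx(matrix(rnorm(20), 5, 4))
  expect_identical(resolve_duplicate_assays(m2), m2)

  # exact tie resolved to the lexicographically first panel, with a warning
  blod_tie <- cbind(c(TRUE, rep(FALSE, 9)), c(TRUE, rep(FALSE, 9)),
                    rep(FALSE, 10))
  mt <- npx_matrix(vals,
                   data.frame(name = c("X", "X", "Y"),
                              panel = c("Pb", "Pa", "P1"),
                              lod = 0, stringsAsFactors = FALSE),
                   below_lod = blod_tie)
  expect_warning(rt <- resolve_duplicate_assays(mt), "tie")
  expect_equal(rt$assays$panel[rt$assays$name == "X"], "Pa")
})

test_that("low-detection flagging uses a strict 20% boundary", {
  vals <- matrix(1, 100, 3, dimnames = list(NULL, c("a21", "a20", "ok")))
  blod <- cbind(c(rep(TRUE, 21), rep(FALSE, 79)),
                c(rep(TRUE, 20), rep(FALSE, 80)),
                rep(FALSE, 100))
  m <- npx_matrix(vals, data.frame(name = colnames(vals), panel = "P", lod = 0),
                  below_lod = blod)
  fl <- flag_low_detection(m)
  expect_true("a21" %in% fl)
  expect_false("a20" %in% fl)
  # monotone in threshold: lower threshold flags a superset
  fl10 <- flag_low_detection(m, threshold = 0.10)
  expect_true(all(fl %in% fl10))
  # stored on the matrix by the annotator
  m2 <- annotate_low_detection(m)
  expect_equal(m2$low_detection_flagged, "a21")
  # fractions computed over non-missing values only
  vals2 <- vals; vals2[51:100, 1] <- NA
  blod2 <- blod; blod2[51:100, 1] <- FALSE
  m3 <- npx_matrix(vals2, m$assays, below_lod = blod2)
  fr <- attr(flag_low_detection(m3), "fractions")
  expect_equal(unname(fr["a21"]), 21 / 50)
})

test_that("low-detection flagging in a censored synthetic cohort", {
  cfg <- cohort_config(group_sizes = c(ISM = 120), n_panels = 1,
                       assays_per_panel = 5,
                       lod_quantile = c(PROT001 = 0.30),
                       missing_rate = 0, qc_fail_count = 0, seed = 5)
  co <- generate_cohort(cfg)
  fl <- flag_low_detection(co$npx)
  expect_true("PROT001" %in% fl)
})

test_that("iterative PCA imputation recovers low-rank structure", {
  # complete matrix: identity
  x <- matrix(rnorm(50), 10, 5)
  out <- impute_iterative_pca(x)
  expect_identical(unname(out[, ]), unname(x))

  # rank-1 completion: a deleted entry of an outer product is recovered
  u <- c(1, 2, 3, 4, 5, 6)
  v <- c(2, -1, 0.5, 3)
  r1 <- u %*% t(v)
  holed <- r1; holed[2, 3] <- NA
  rec <- impute_iterative_pca(holed, ncp = 1, tol = 1e-14)
  expect_lt(abs(rec[2, 3] - r1[2, 3]), 1e-6)
  expect_true(attr(rec, "converged"))
  # observed entries bit-identical
  obs <- !is.na(holed)
  expect_identical(rec[obs], r1[obs])

  # MCAR on rank-2 + noise: beats column-mean imputation
  set.seed(42)
  n <- 60; p <- 20
  truth <- matrix(rnorm(n * 2), n, 2) %*% matrix(rnorm(2 * p), 2, p) +
    matrix(rnorm(n * p, sd = 0.1), n, p)
  holes <- matrix(runif(n * p) < 0.05, n, p)
  xm <- truth; xm[holes] <- NA
  imp <- impute_iterative_pca(xm, ncp = 2)
  colmean <- xm
  for (j in seq_len(p)) colmean[is.na(xm[, j]), j] <- mean(xm[, j], na.rm = TRUE)
  rmse <- function(a) sqrt(mean((a[holes] - truth[holes])^2))
  expect_lt(rmse(imp), rmse(colmean))
})

test_that("imputation guards degenerate inputs", {
  x <- matrix(rnorm(20), 5, 4)
  x[, 2] <- NA
  expect_error(impute_iterative_pca(x), "all values missing")
  x2 <- matrix(rnorm(20), 5, 4)
  x2[1, 1] <- NA
  expect_warning(impute_iterative_pca(x2, ncp = 2, max_iter = 1, tol = 1e-30),
                 "did not converge")
})
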