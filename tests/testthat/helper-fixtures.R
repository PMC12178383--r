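# shared fixtures and independent oracles

# quick NPX matrix from a plain values matrix (one panel, LOD -Inf)
make_npx <- function(values, panel = "P1", lod = rep(-Inf, ncol(values)),
                     names = colnames(values)) {
  if (is.null(names)) names <- paste0("A", seq_len(ncol(values)))
  npx_matrix(values,
             data.frame(name = names, panel = panel, lod = lod,
                        stringsAsFactors = FALSE))
}

# brute-force Benjamini-Hochberg: for each p, the smallest alpha at which the
# step-up rule p_(i) <= i * alpha / m rejects it
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p of the i-th smallest: min over j >= i of m * p_(j) / j
    js <- seq.int(i, m)
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

# exhaustive O(n^2) concordance: fraction of case-control pairs with the case
# scoring higher, ties counting one half
cindex_brute_force <- function(y, s) {
  cases <- which(y == 1); controls <- which(y == 0)
  tot <- 0
  for (i in cases) for (j in controls) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Welch statistics straight from the textbook formulas
welch_by_hand <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(estimate = mean(y) - mean(x), t = t, df = df,
       p = 2 * pt(-abs(t), df))
}

# small synthetic cohort shared by several tests: 2 panels x 12 assays with
# the duplicate, a planted AdvSM signature on three assays
small_cohort <- function(seed = 11, shift = 2) {
  cohort_config(
    group_sizes = c(ISM = 30, AdvSM = 12, PCV = 20),
    n_panels = 2, assays_per_panel = 12,
    effect_table = data.frame(
      assay = c("PROT002", "PROT003", "PROT004"),
      diagnosis = "AdvSM", shift = shift, stringsAsFactors = FALSE),
    missing_rate = 0.02, qc_fail_count = 2, seed = seed)
}
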