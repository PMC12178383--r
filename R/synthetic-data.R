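# Synthetic cohorts with the statistical structure the pipeline assumes:
# multi-panel NPX with a cross-panel duplicate assay, below-LOD censoring,
# MCAR missingness, QC-failed-but-retained samples, age confounding between
# diagnosis groups, and (separately) a cell-type-labelled expression matrix
# with planted marker genes.

#' Configuration for a synthetic NPX cohort
#'
#' Defaults emulate a mastocytosis/polycythemia-vera study cohort: four
#' diagnosis groups of 16/80/12/60 samples, three 92-assay panels with one
#' protein (IL6) measured on two panels, group-wise age confounding, and
#' five QC-failed samples that are flagged but retained.
#'
#' @param group_sizes named integer vector, samples per diagnosis group.
#' @param n_panels number of panels.
#' @param assays_per_panel assays per panel.
#' @param duplicated_assay name of the one assay present on two panels.
#' @param effect_table data.frame with columns `assay`, `diagnosis`, `shift`:
#'   mean NPX shifts (log2 scale) added on top of the assay baseline for the
#'   given group.  Empty by default (null cohort).
#' @param baseline_mean_sd length-2 numeric: mean and SD of the
#'   once-per-cohort assay-level baseline means (NPX units).
#' @param noise_sd within-assay between-sample SD (NPX units).
#' @param lod_quantile per-assay limit of detection expressed as a quantile
#'   of that assay's baseline distribution.  Scalar (recycled) or named
#'   vector; names are assay names, with the duplicated assay addressable as
#'   `"<name>@<panel>"` to give its two copies different censoring.  The
#'   default censors most assays lightly (2%), a block of assays heavily
#'   (30%, so they exceed the 20% low-detection flag threshold), and the
#'   duplicated assay asymmetrically (5% on its first panel, 35% on its
#'   last), so the duplicate-resolution rule always has a strict winner.
#' @param missing_rate fraction of cells made missing completely at random.
#' @param qc_fail_count number of samples flagged as QC failures (retained).
#' @param age_params per-group list of `c(median, min, max)` ages in years.
#' @param sex_ratio per-group fraction of female samples.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(CM = 16, ISM = 80, AdvSM = 12, PCV = 60),
                          n_panels = 3,
                          assays_per_panel = 92,
                          duplicated_assay = "IL6",
                          effect_table = NULL,
                          baseline_mean_sd = c(4, 2),
                          noise_sd = 1,
                          lod_quantile = NULL,
                          missing_rate = 0.02,
                          qc_fail_count = 5,
                          age_params = list(CM = c(45, 24, 78), ISM = c(59, 25, 89),
                                            AdvSM = c(72, 49, 76), PCV = c(72, 34, 90)),
                          sex_ratio = c(CM = 9 / 16, ISM = 54 / 80,
                                        AdvSM = 5 / 12, PCV = 39 / 60),
                          seed = 1L) {
  if (is.null(effect_table)) {
    effect_table <- data.frame(assay = character(), diagnosis = character(),
                               shift = numeric(), stringsAsFactors = FALSE)
  }
  cfg <- list(group_sizes = group_sizes, n_panels = n_panels,
              assays_per_panel = assays_per_panel,
              duplicated_assay = duplicated_assay,
              effect_table = effect_table,
              baseline_mean_sd = baseline_mean_sd, noise_sd = noise_sd,
              lod_quantile = lod_quantile, missing_rate = missing_rate,
              qc_fail_count = qc_fail_count, age_params = age_params,
              sex_ratio = sex_ratio, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$group_sizes < 1)) stop("group_sizes: all group sizes must be >= 1")
  if (is.null(names(cfg$group_sizes)) ||
      !all(names(cfg$group_sizes) %in% diagnosis_levels())) {
    stop("group_sizes: names must be diagnosis labels (",
         paste(diagnosis_levels(), collapse = ", "), ")")
  }
  if (cfg$n_panels < 1) stop("n_panels: must be >= 1")
  if (cfg$assays_per_panel < 1) stop("assays_per_panel: must be >= 1")
  et <- cfg$effect_table
  if (!all(c("assay", "diagnosis", "shift") %in% names(et))) {
    stop("effect_table: needs columns assay, diagnosis, shift")
  }
  if (nrow(et) && any(!is.finite(et$shift))) stop("effect_table: shifts must be finite")
  if (!is.null(cfg$lod_quantile) &&
      (any(cfg$lod_quantile < 0) || any(cfg$lod_quantile >= 1))) {
    stop("lod_quantile: must lie in [0, 1)")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate: must lie in [0, 1)")
  }
  if (cfg$qc_fail_count < 0 || cfg$qc_fail_count > sum(cfg$group_sizes)) {
    stop("qc_fail_count: must be between 0 and the cohort size")
  }
  for (g in names(cfg$group_sizes)) {
    ap <- cfg$age_params[[g]]
    if (is.null(ap) || length(ap) != 3 || ap[2] > ap[1] || ap[1] > ap[3]) {
      stop("age_params: group '", g, "' needs c(median, min, max) with min <= median <= max")
    }
    sr <- cfg$sex_ratio[[g]]
    if (is.null(sr) || sr < 0 || sr > 1) stop("sex_ratio: group '", g, "' needs a fraction in [0, 1]")
  }
  invisible(cfg)
}

# triangular(min, mode, max) sampling by inverse CDF; the mode is solved so
# the distribution's median matches the printed group median.
rtriangular_from_median <- function(n, med, lo, hi) {
  if (lo == hi) return(rep(lo, n))
  mid <- (lo + hi) / 2
  mode <- if (med >= mid) lo + 2 * (med - lo)^2 / (hi - lo)
          else hi - 2 * (hi - med)^2 / (hi - lo)
  mode <- min(max(mode, lo), hi)
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
}

panel_names <- function(n_panels) {
  base <- c("Cardiovascular II", "Cardiovascular III", "Immune Response")
  if (n_panels <= length(base)) base[seq_len(n_panels)]
  else c(base, paste0("Panel ", seq.int(length(base) + 1, n_panels)))
}

# Assay layout: panel p gets `assays_per_panel` proteins; the duplicated
# assay sits on the first and last panel (when n_panels >= 2), so total
# columns = n_panels * assays_per_panel while unique names = that - 1.
build_assay_layout <- function(cfg) {
  pn <- panel_names(cfg$n_panels)
  total <- cfg$n_panels * cfg$assays_per_panel
  n_unique <- if (cfg$n_panels >= 2) total - 1L else total
  base_names <- sprintf("PROT%03d", seq_len(n_unique - 1L))
  nm <- character(total)
  panel <- rep(pn, each = cfg$assays_per_panel)
  k <- 1L
  for (i in seq_len(total)) {
    p <- (i - 1L) %/% cfg$assays_per_panel + 1L
    j <- (i - 1L) %% cfg$assays_per_panel + 1L
    if (j == 1L && (p == 1L || (p == cfg$n_panels && cfg$n_panels >= 2))) {
      nm[i] <- cfg$duplicated_assay
    } else {
      nm[i] <- base_names[k]
      k <- k + 1L
    }
  }
  data.frame(name = nm, panel = panel, stringsAsFactors = FALSE)
}

default_lod_quantiles <- function(cfg, layout) {
  q <- rep(0.02, nrow(layout))
  names(q) <- layout$name
  # a block of heavily censored assays so the >20% low-detection flag has
  # real members in the default cohort
  heavy <- grep("^PROT00[1-9]$|^PROT010$", layout$name)
  q[heavy] <- 0.30
  if (cfg$n_panels >= 2) {
    dup <- which(layout$name == cfg$duplicated_assay)
    q[dup[1]] <- 0.05
    q[dup[length(dup)]] <- 0.35
  }
  q
}

#' Generate a synthetic NPX cohort
#'
#' Draws NPX values as an assay-specific Gaussian baseline (assay means drawn
#' once per cohort) plus the configured group mean shifts, censors values
#' below each assay's LOD (flagged, never removed), applies MCAR missingness,
#' flags exactly `qc_fail_count` samples as QC failures (retained), and draws
#' ages from per-group triangular distributions matching the configured
#' (median, min, max).
#'
#' @param config a [cohort_config()].
#' @return list with elements `npx` (an [npx_matrix]) and `info`
#'   (a [sample_info] data.frame).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  withr_seed <- cfg$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  layout <- build_assay_layout(cfg)
  p <- nrow(layout)
  mu <- stats::rnorm(p, cfg$baseline_mean_sd[1], cfg$baseline_mean_sd[2])

  shift <- matrix(0, n, p)
  et <- cfg$effect_table
  if (nrow(et)) {
    for (r in seq_len(nrow(et))) {
      cols <- which(layout$name == et$assay[r])
      rows <- which(groups == et$diagnosis[r])
      if (!length(cols)) stop("effect_table: unknown assay '", et$assay[r], "'")
      shift[rows, cols] <- shift[rows, cols] + et$shift[r]
    }
  }
  vals <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
  vals <- sweep(vals, 2, mu, `+`) + shift

  q <- cfg$lod_quantile
  if (is.null(q)) {
    q <- default_lod_quantiles(cfg, layout)
  } else if (length(q) == 1L && is.null(names(q))) {
    q <- stats::setNames(rep(q, p), layout$name)
  } else {
    qq <- stats::setNames(rep(0.02, p), layout$name)
    key <- paste0(layout$name, "@", layout$panel)
    for (nmq in names(q)) {
      hit <- if (grepl("@", nmq, fixed = TRUE)) which(key == nmq)
             else which(layout$name == nmq)
      if (!length(hit)) stop("lod_quantile: unknown assay '", nmq, "'")
      qq[hit] <- q[[nmq]]
    }
    q <- qq
  }
  lod <- stats::qnorm(as.numeric(q), mean = mu, sd = cfg$noise_sd)
  lod[as.numeric(q) == 0] <- -Inf

  # the two copies of the duplicated assay must differ in realized below-LOD
  # fraction so duplicate resolution has a strict winner
  if (cfg$n_panels >= 2) {
    dup <- which(layout$name == cfg$duplicated_assay)
    frac <- vapply(dup, function(j) mean(vals[, j] < lod[j]), numeric(1))
    guard <- 0L
    while (length(unique(frac)) == 1L && guard < 50L) {
      j <- dup[length(dup)]
      nxt <- sort(vals[, j])[min(n, sum(vals[, j] < lod[j]) + 1L)]
      lod[j] <- nxt + 1e-9
      frac <- vapply(dup, function(k) mean(vals[, k] < lod[k]), numeric(1))
      guard <- guard + 1L
    }
  }

  miss <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
  vals[miss] <- NA_real_

  assays <- data.frame(name = layout$name, panel = layout$panel, lod = lod,
                       stringsAsFactors = FALSE)
  m <- npx_matrix(vals, assays, sample_ids = ids)

  age <- numeric(n)
  sex <- character(n)
  for (g in names(cfg$group_sizes)) {
    idx <- which(groups == g)
    ap <- cfg$age_params[[g]]
    age[idx] <- round(rtriangular_from_median(length(idx), ap[1], ap[2], ap[3]), 1)
    nf <- round(cfg$sex_ratio[[g]] * length(idx))
    sx <- c(rep("F", nf), rep("M", length(idx) - nf))
    sex[idx] <- sample(sx)
  }
  qc <- rep(TRUE, n)
  if (cfg$qc_fail_count > 0) qc[sample.int(n, cfg$qc_fail_count)] <- FALSE
  info <- sample_info(ids, groups, age, sex, qc)
  list(npx = m, info = info, seed = cfg$seed)
}

# save/restore the RNG state so generators are pure functions of their config
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- single-cell fixture ---------------------------------------------------

#' Configuration for a synthetic annotated single-cell matrix
#'
#' Emulates a normalized, log-transformed bone-marrow mononuclear-cell
#' expression matrix with cell-type annotations and planted marker genes
#' (e.g. tryptase in mast cells), for exercising the dot-plot summarization.
#'
#' @param cell_types character vector of cell-type labels.
#' @param cells_per_type cells simulated per type.
#' @param n_genes total genes; names are `GENE001`... unless overridden by
#'   marker names.
#' @param marker_plan data.frame with columns `gene`, `cell_type`, `fold`:
#'   each marker's mean expression is multiplied by `fold` in its type.
#' @param dropout_rate fraction of entries zeroed at random.
#' @param seed integer seed.
#' @return list of class `single_cell_config`.
#' @export
single_cell_config <- function(cell_types = c("mast cells", "basophils", "monocytes",
                                              "neutrophils", "NK/T cells",
                                              "B cells/progenitors"),
                               cells_per_type = 100,
                               n_genes = 40,
                               marker_plan = data.frame(
                                 gene = c("TPSAB1", "MILR1", "GRN", "LAG3"),
                                 cell_type = c("mast cells", "mast cells",
                                               "neutrophils", "NK/T cells"),
                                 fold = c(10, 4, 4, 4),
                                 stringsAsFactors = FALSE),
                               dropout_rate = 0.3,
                               seed = 1L) {
  cfg <- list(cell_types = cell_types, cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes), marker_plan = marker_plan,
              dropout_rate = dropout_rate, seed = as.integer(seed))
  if (cfg$cells_per_type < 1) stop("cells_per_type: must be >= 1")
  if (!all(marker_plan$cell_type %in% cell_types)) {
    stop("marker_plan: unknown cell type(s): ",
         paste(setdiff(marker_plan$cell_type, cell_types), collapse = ", "))
  }
  if (nrow(marker_plan) > cfg$n_genes) stop("marker_plan: more markers than genes")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stop("dropout_rate: must lie in [0, 1)")
  class(cfg) <- "single_cell_config"
  cfg
}

#' Generate a synthetic annotated single-cell expression matrix
#'
#' Expression is non-negative on a normalized-log-like scale: per-gene base
#' means drawn once, half-normal per-cell noise, marker genes elevated by
#' their configured fold in their designated type, and dropout zeros injected
#' at `dropout_rate`.
#'
#' @param config a [single_cell_config()].
#' @return list with `expression` (genes x cells matrix) and `cell_types`
#'   (character vector, one label per column).
#' @export
generate_single_cell <- function(config = single_cell_config()) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  markers <- cfg$marker_plan$gene
  if (anyDuplicated(markers)) stop("marker_plan: duplicated marker gene")
  filler <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  genes <- c(markers, setdiff(filler, markers))[seq_len(cfg$n_genes)]
  if (!all(markers %in% genes)) stop("marker gene not in gene list")

  types <- rep(cfg$cell_types, each = cfg$cells_per_type)
  n_cells <- length(types)
  base <- stats::runif(cfg$n_genes, 0.2, 1.5)
  names(base) <- genes

  mu <- matrix(rep(base, n_cells), nrow = cfg$n_genes)
  for (r in seq_len(nrow(cfg$marker_plan))) {
    g <- match(cfg$marker_plan$gene[r], genes)
    cells <- which(types == cfg$marker_plan$cell_type[r])
    mu[g, cells] <- mu[g, cells] * cfg$marker_plan$fold[r]
  }
  expr <- abs(matrix(stats::rnorm(cfg$n_genes * n_cells, sd = 0.3),
                     cfg$n_genes, n_cells)) + mu
  drop <- matrix(stats::runif(cfg$n_genes * n_cells) < cfg$dropout_rate,
                 cfg$n_genes, n_cells)
  expr[drop] <- 0
  dimnames(expr) <- list(genes, sprintf("CELL%04d", seq_len(n_cells)))
  list(expression = expr, cell_types = types, seed = cfg$seed)
}
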