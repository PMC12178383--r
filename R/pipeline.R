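# End-to-end orchestration: import (or simulate) -> preprocessing ->
# PCA/permutation -> volcano -> shadow-feature selection -> logistic marker
# table -> optional single-cell linkage, writing plain CSV/JSON artifacts
# plus a reproducibility manifest.

#' Pipeline run configuration
#'
#' @param npx_path,meta_path long-format NPX CSV and metadata CSV; leave
#'   `NULL` to run on a synthetic cohort.
#' @param synthetic a [cohort_config()] used when no input paths are given.
#' @param contrasts list of `c(group_a, group_b)` pairs.  The default
#'   mirrors the standard subtype comparisons (ISM vs AdvSM, ISM vs PCV,
#'   AdvSM vs PCV); CM samples ride through import and PCA but join no
#'   contrast.
#' @param q_threshold volcano significance cutoff.
#' @param n_perm,pca_dims permutation-test settings.
#' @param boruta_max_runs,boruta_ntree selection settings (smaller than the
#'   defaults of [boruta_select()] keep full runs fast; raise for final
#'   analyses).
#' @param n_markers number of top confirmed features carried into the
#'   logistic table per contrast (markers may also be fixed via `markers`,
#'   a named list keyed by "A_vs_B").
#' @param markers optional named list of fixed marker vectors per contrast.
#' @param sc_matrix,sc_annotation optional single-cell input paths.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(npx_path = NULL, meta_path = NULL,
                       synthetic = cohort_config(),
                       contrasts = list(c("ISM", "AdvSM"), c("ISM", "PCV"),
                                        c("AdvSM", "PCV")),
                       q_threshold = 0.05,
                       n_perm = 999, pca_dims = c(1, 2),
                       boruta_max_runs = 100, boruta_ntree = 300,
                       n_markers = 5, markers = NULL,
                       sc_matrix = NULL, sc_annotation = NULL,
                       seed = 1L) {
  for (ct in contrasts) {
    if (!all(ct %in% diagnosis_levels())) {
      stop("contrast groups must come from: ",
           paste(diagnosis_levels(), collapse = ", "))
    }
  }
  structure(
    list(npx_path = npx_path, meta_path = meta_path, synthetic = synthetic,
         contrasts = contrasts, q_threshold = q_threshold, n_perm = n_perm,
         pca_dims = pca_dims, boruta_max_runs = boruta_max_runs,
         boruta_ntree = boruta_ntree, n_markers = n_markers, markers = markers,
         sc_matrix = sc_matrix, sc_annotation = sc_annotation,
         seed = as.integer(seed)),
    class = "run_config")
}

stage_seed <- function(seed, stage) {
  # distinct, stable sub-seeds per stage, kept within 32-bit range
  (seed * 1000L + stage) %% .Machine$integer.max
}

#' Run the full biomarker-discovery analysis
#'
#' Imports (or simulates) the cohort, resolves cross-panel duplicates, flags
#' low-detection assays, writes the demographics table, imputes for PCA, and
#' per contrast emits: PCA scores and centroids, the permutation-test JSON,
#' the volcano CSV, the shadow-feature decisions CSV and the stepwise
#' logistic marker table.  A manifest JSON records seeds, settings, a config
#' hash and any stage failure; a stage failure preserves the artifacts
#' already written.
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory, created if needed.
#' @return invisibly, a list with the manifest and the in-memory results.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = tempfile("npxbio_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "npxbio",
                   version = as.character(utils::packageVersion("npxbio")),
                   seed = config$seed, settings = config_settings(config),
                   config_hash = config_hash(config),
                   warnings = character(), failed_stage = NULL)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- list(stage = name, message = conditionMessage(e))
      NULL
    })
  }

  cohort <- stage("import", {
    if (!is.null(config$npx_path)) {
      list(npx = read_npx_long(config$npx_path),
           info = read_sample_info(config$meta_path))
    } else {
      cfg <- config$synthetic
      cfg$seed <- stage_seed(config$seed, 1L)
      generate_cohort(cfg)
    }
  })
  if (is.null(cohort)) return(finish_run(manifest, results, out_dir))

  m <- stage("preprocess", {
    m <- resolve_duplicate_assays(cohort$npx)
    annotate_low_detection(m)
  })
  if (is.null(m)) return(finish_run(manifest, results, out_dir))
  if (sum(!cohort$info$qc_pass) > 0) {
    manifest$warnings <- c(manifest$warnings,
                           sprintf("%d QC-failed sample(s) retained",
                                   sum(!cohort$info$qc_pass)))
  }
  if (length(m$low_detection_flagged)) {
    manifest$warnings <- c(manifest$warnings,
                           sprintf("%d assay(s) flagged >20%% below LOD",
                                   length(m$low_detection_flagged)))
  }

  stage("demographics", {
    demo <- compare_demographics(cohort$info)
    utils::write.csv(demo, file.path(out_dir, "demographics.csv"), row.names = FALSE)
    results$demographics <- demo
  })

  imputed <- stage("impute", impute_iterative_pca(m))
  if (is.null(imputed)) return(finish_run(manifest, results, out_dir))

  labels <- as.character(cohort$info$diagnosis)
  for (ci in seq_along(config$contrasts)) {
    ct <- config$contrasts[[ci]]
    tag <- paste0(ct[1], "_vs_", ct[2])
    res <- stage(paste0("contrast:", tag), {
      keep <- labels %in% ct
      sub_vals <- imputed$values[keep, , drop = FALSE]
      sub_labels <- labels[keep]
      pca <- run_pca(sub_vals)
      cent <- group_centroids(pca, sub_labels, config$pca_dims)
      perm <- permutation_centroid_test(
        pca, sub_labels, ct[1], ct[2], n_perm = config$n_perm,
        dims = config$pca_dims, seed = stage_seed(config$seed, 10L + ci))
      utils::write.csv(
        data.frame(sample_id = rownames(pca$scores), group = sub_labels,
                   pca$scores[, config$pca_dims, drop = FALSE]),
        file.path(out_dir, paste0("pca_scores_", tag, ".csv")), row.names = FALSE)
      utils::write.csv(data.frame(group = rownames(cent), cent),
                       file.path(out_dir, paste0("pca_centroids_", tag, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(contrast = ct, observed_distance = perm$observed_distance,
             p_value = perm$p_value, n_perm = perm$n_perm, dims = perm$dims,
             seed = perm$seed),
        file.path(out_dir, paste0("permutation_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)

      volcano <- volcano_table(m, labels, ct[1], ct[2], config$q_threshold)
      utils::write.csv(volcano, file.path(out_dir, paste0("volcano_", tag, ".csv")),
                       row.names = FALSE)

      adj <- residualize_covariates(
        subset_npx(m, keep), subset_info(cohort$info, keep))
      Xb <- roughfix_missing(adj)$values
      bor <- boruta_select(Xb, factor(sub_labels),
                           max_runs = config$boruta_max_runs,
                           ntree = config$boruta_ntree,
                           seed = stage_seed(config$seed, 20L + ci))
      chart <- importance_chart_table(bor)
      utils::write.csv(
        data.frame(feature = bor$features, decision = unname(bor$decisions),
                   hit_count = unname(bor$hit_counts),
                   n_iter = bor$n_completed_iterations),
        file.path(out_dir, paste0("boruta_decisions_", tag, ".csv")),
        row.names = FALSE)

      confirmed_sorted <- chart$feature[chart$decision == "Confirmed"]
      clev <- cleveland_summary(m, labels, confirmed_sorted, volcano)
      utils::write.csv(clev, file.path(out_dir, paste0("cleveland_", tag, ".csv")),
                       row.names = FALSE)

      mk <- if (!is.null(config$markers[[tag]])) config$markers[[tag]]
            else utils::head(confirmed_sorted, config$n_markers)
      logit_tab <- NULL
      if (length(mk)) {
        dat <- data.frame(age = cohort$info$age[keep],
                          Xmat_to_df(imputed$values[keep, mk, drop = FALSE]),
                          check.names = FALSE)
        yb <- factor(sub_labels, levels = c(ct[2], ct[1]))  # first-listed group = 1
        logit_tab <- stepwise_marker_table(yb, dat, mk)
        utils::write.csv(logit_tab, file.path(out_dir, paste0("logit_", tag, ".csv")),
                         row.names = FALSE)
      }
      list(pca = pca, centroids = cent, permutation = perm, volcano = volcano,
           boruta = bor, importance_chart = chart, cleveland = clev,
           markers = mk, logit = logit_tab)
    })
    if (!is.null(res)) results[[tag]] <- res
    if (!is.null(manifest$failed_stage)) break
  }

  if (!is.null(config$sc_matrix) && is.null(manifest$failed_stage)) {
    stage("sc_linkage", {
      sc <- read_annotated_expression(config$sc_matrix, config$sc_annotation)
      summ <- celltype_dot_stats(sc$expression, sc$cell_types)
      utils::write.csv(celltype_summary_table(summ),
                       file.path(out_dir, "celltype_summary.csv"), row.names = FALSE)
      results$sc <- summ
    })
  }
  finish_run(manifest, results, out_dir)
}

subset_npx <- function(m, keep) {
  npx_matrix(m$values[keep, , drop = FALSE], m$assays,
             sample_ids = m$sample_ids[keep],
             below_lod = m$below_lod[keep, , drop = FALSE],
             low_detection_flagged = m$low_detection_flagged)
}

subset_info <- function(info, keep) {
  out <- info[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

Xmat_to_df <- function(x) {
  df <- as.data.frame(x)
  names(df) <- colnames(x)
  df
}

config_settings <- function(config) {
  s <- unclass(config)
  s$synthetic <- if (!is.null(s$synthetic)) unclass(s$synthetic) else NULL
  s
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_settings(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

finish_run <- function(manifest, results, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}
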