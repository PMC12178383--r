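# PCA on scaled NPX data, group centroids (arithmetic means of scores), and
# a permutation test of centroid separation: the observed Euclidean distance
# between two group centroids in score space is ranked within a null built by
# reshuffling the group labels over the pooled samples.

#' Principal component analysis of a complete NPX matrix
#'
#' Thin wrapper over [stats::prcomp()] returning scores, loadings and
#' explained variances in one object.  Scaling uses the n-1 sample SD
#' (prcomp convention).  The matrix must be complete — impute first.
#'
#' @param m an [npx_matrix] with no missing values, or a plain numeric matrix.
#' @param center,scale logical, passed to [stats::prcomp()]; default both
#'   `TRUE` (PCA on scaled data).
#' @return object of class `pca_model` with fields `scores` (samples x
#'   components), `loadings` (assays x components), `explained_variance`
#'   (per-component variances, non-increasing), `center`, `scale`.
#' @export
run_pca <- function(m, center = TRUE, scale = TRUE) {
  x <- if (inherits(m, "npx_matrix")) m$values else as.matrix(m)
  if (anyNA(x)) stop("matrix has missing values; run impute_iterative_pca() first")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance assay(s) cannot be scaled: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  fit <- stats::prcomp(x, center = center, scale. = scale)
  structure(
    list(scores = fit$x, loadings = fit$rotation,
         explained_variance = fit$sdev^2,
         center = fit$center, scale = fit$scale),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  ev <- x$explained_variance
  cat("pca_model: ", nrow(x$scores), " samples, ", length(ev), " components\n",
      sep = "")
  cat("  variance explained (first 5): ",
      paste(sprintf("%.1f%%", 100 * ev[seq_len(min(5, length(ev)))] / sum(ev)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Group centroids in PCA score space
#'
#' Centroids are the plain arithmetic means of each group's score vectors,
#' restricted to the requested components.
#'
#' @param model a `pca_model` from [run_pca()].
#' @param labels vector of group labels, one per sample (row of scores).
#' @param dims integer vector of component indices, default `c(1, 2)`.
#' @return matrix, one row per group label, columns = `dims`.
#' @export
group_centroids <- function(model, labels, dims = c(1, 2)) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(model$scores))
  s <- model$scores[, dims, drop = FALSE]
  groups <- unique(labels)
  if (any(!table(labels) >= 1)) stop("empty group")
  out <- t(vapply(groups, function(g) colMeans(s[labels == g, , drop = FALSE]),
                  numeric(length(dims))))
  rownames(out) <- groups
  colnames(out) <- colnames(model$scores)[dims]
  out
}

#' Permutation test of centroid separation between two groups
#'
#' The observed statistic is the Euclidean distance between the two group
#' centroids in the `dims`-dimensional score plane.  The null distribution
#' reshuffles the two group labels over the pooled samples (group sizes
#' preserved) and recomputes the distance on the fixed score matrix — PCA is
#' label-blind, so it is not refit per permutation.  The p-value uses the
#' add-one rule `(1 + #(null >= observed)) / (1 + n_perm)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`.
#'
#' @param model a `pca_model`.
#' @param labels group labels, one per sample; samples outside the two tested
#'   groups are excluded.
#' @param group_a,group_b the two labels to test.
#' @param n_perm number of permutations, default 9999; at least 99.
#' @param dims score components used, default `c(1, 2)` (the plotted plane).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permutation_result` with `observed_distance`,
#'   `null_distances`, `p_value`, `n_perm`, `dims`, `seed`.
#' @export
permutation_centroid_test <- function(model, labels, group_a, group_b,
                                      n_perm = 9999, dims = c(1, 2), seed = 1L) {
  labels <- as.character(labels)
  if (n_perm < 99) stop("n_perm must be at least 99 for usable p resolution")
  keep <- labels %in% c(group_a, group_b)
  s <- model$scores[keep, dims, drop = FALSE]
  lab <- labels[keep]
  na <- sum(lab == group_a); nb <- sum(lab == group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  if (min(na, nb) == 1) warning("a tested group has a single sample")

  cdist <- function(idx_a) {
    ca <- colMeans(s[idx_a, , drop = FALSE])
    cb <- colMeans(s[-idx_a, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }
  observed <- cdist(which(lab == group_a))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm),
                  function(i) cdist(sample.int(na + nb, na)),
                  numeric(1))
  p <- (1 + sum(nulls >= observed)) / (1 + n_perm)
  structure(
    list(observed_distance = observed, null_distances = nulls, p_value = p,
         n_perm = n_perm, dims = dims, seed = seed,
         groups = c(group_a, group_b), group_sizes = c(na, nb)),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation test of centroid separation (", x$groups[1], " vs ",
      x$groups[2], ")\n", sep = "")
  cat(sprintf("  observed distance %.3f on PC%s; p = %.4g (%d permutations)\n",
              x$observed_distance, paste(x$dims, collapse = ","),
              x$p_value, x$n_perm))
  invisible(x)
}
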