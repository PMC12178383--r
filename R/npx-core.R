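# ---- NpxMatrix -------------------------------------------------------------

#' Construct an NPX matrix object
#'
#' An `npx_matrix` bundles a samples x assays table of NPX values (log2
#' normalized protein expression) with its missingness structure, a
#' below-LOD mask and the set of assays flagged for low detection (the
#' double-dagger set).  Assay identity is the (name, panel) pair: the same
#' protein can appear on two panels before duplicate resolution.
#'
#' @param values numeric matrix, samples in rows, assays in columns; `NA`
#'   encodes a missing measurement.
#' @param assays data.frame with columns `name`, `panel`, `lod` (one row per
#'   column of `values`).
#' @param sample_ids character vector of row identities.
#' @param below_lod logical matrix of the same shape as `values`; `TRUE`
#'   marks a value reported below the assay's limit of detection.  Missing
#'   cells must carry `FALSE`.  If `NULL`, derived as `values < lod`.
#' @param low_detection_flagged character vector of assay names carrying the
#'   low-detection annotation.
#' @return an object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, assays, sample_ids = rownames(values),
                       below_lod = NULL, low_detection_flagged = character()) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  stopifnot(is.data.frame(assays), all(c("name", "panel", "lod") %in% names(assays)))
  if (nrow(assays) != ncol(values)) {
    stop("assays table has ", nrow(assays), " rows but values has ",
         ncol(values), " columns")
  }
  if (anyDuplicated(assays[c("name", "panel")])) {
    stop("duplicated (name, panel) pair in assay table")
  }
  if (is.null(below_lod)) {
    below_lod <- sweep(values, 2, assays$lod, `<`)
    below_lod[is.na(below_lod)] <- FALSE
  }
  below_lod <- as.matrix(below_lod)
  stopifnot(identical(dim(below_lod), dim(values)))
  if (any(below_lod & is.na(values))) {
    stop("missing entries cannot carry a below-LOD flag")
  }
  if (!all(low_detection_flagged %in% assays$name)) {
    stop("low_detection_flagged contains unknown assay names")
  }
  rownames(values) <- sample_ids
  colnames(values) <- assays$name
  dimnames(below_lod) <- dimnames(values)
  structure(
    list(values = values, assays = assays, sample_ids = sample_ids,
         below_lod = below_lod,
         low_detection_flagged = unique(low_detection_flagged)),
    class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat("npx_matrix: ", length(x$sample_ids), " samples x ", nrow(x$assays),
      " assays (", length(unique(x$assays$panel)), " panels)\n", sep = "")
  cat("  missing: ", sum(is.na(x$values)),
      " values; below LOD: ", sum(x$below_lod), " values\n", sep = "")
  if (length(x$low_detection_flagged)) {
    cat("  low-detection flagged assays: ",
        length(x$low_detection_flagged), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Per-sample metadata table
#'
#' Validates and normalizes a sample-information data.frame: diagnosis from
#' the closed vocabulary (CM, ISM, AdvSM, PCV), positive age in years, sex
#' F/M, and the QC-pass flag (QC-failed samples are retained in all analyses,
#' only flagged).
#'
#' @param sample_id character vector.
#' @param diagnosis character or factor, values among CM/ISM/AdvSM/PCV.
#' @param age numeric, years, strictly positive.
#' @param sex character, "F" or "M".
#' @param qc_pass logical, default all `TRUE`.
#' @return data.frame of class `sample_info`.
#' @export
sample_info <- function(sample_id, diagnosis, age, sex,
                        qc_pass = rep(TRUE, length(sample_id))) {
  diagnosis <- as.character(diagnosis)
  bad <- setdiff(unique(diagnosis), diagnosis_levels())
  if (length(bad)) stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be finite and > 0")
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  out <- data.frame(sample_id = as.character(sample_id),
                    diagnosis = factor(diagnosis, levels = diagnosis_levels()),
                    age = as.numeric(age), sex = factor(sex, levels = c("F", "M")),
                    qc_pass = as.logical(qc_pass),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_info", class(out))
  out
}

#' Diagnosis vocabulary
#'
#' @return character vector of the recognized diagnosis labels.
#' @export
diagnosis_levels <- function() c("CM", "ISM", "AdvSM", "PCV")

# ---- I/O -------------------------------------------------------------------

#' Read a long-format NPX CSV
#'
#' The canonical long format has one row per (sample, assay, panel)
#' measurement with columns `SampleID`, `Assay`, `Panel`, `NPX`, and either a
#' logical `BelowLOD` column or a numeric `LOD` column from which the flag is
#' derived (`NPX < LOD`).  Absent (sample, assay) pairs become missing cells.
#' Lines starting with `#` (the writer's seed header) are skipped.
#'
#' @param path CSV file path.
#' @return an [npx_matrix].
#' @export
read_npx_long <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("SampleID", "Assay", "Panel", "NPX")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("NPX file lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(c("BelowLOD", "LOD") %in% names(df))) {
    stop("NPX file needs a BelowLOD or LOD column")
  }
  key <- paste(df$SampleID, df$Assay, df$Panel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, assay, panel) row at line ",
         which(duplicated(key))[1] + 1L)
  }
  samples <- unique(df$SampleID)
  adf <- unique(df[c("Assay", "Panel")])
  adf <- adf[order(match(adf$Assay, df$Assay)), , drop = FALSE]
  if ("LOD" %in% names(df)) {
    lodmap <- df[!duplicated(paste(df$Assay, df$Panel, sep = "\r")), ]
    adf$lod <- lodmap$LOD[match(paste(adf$Assay, adf$Panel, sep = "\r"),
                                paste(lodmap$Assay, lodmap$Panel, sep = "\r"))]
  } else {
    adf$lod <- -Inf
  }
  assays <- data.frame(name = adf$Assay, panel = adf$Panel, lod = adf$lod,
                       stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, nrow = length(samples), ncol = nrow(assays),
                 dimnames = list(samples, assays$name))
  blod <- matrix(FALSE, nrow = length(samples), ncol = nrow(assays))
  i <- match(df$SampleID, samples)
  j <- match(paste(df$Assay, df$Panel, sep = "\r"),
             paste(assays$name, assays$panel, sep = "\r"))
  vals[cbind(i, j)] <- df$NPX
  if ("BelowLOD" %in% names(df)) {
    blod[cbind(i, j)] <- as.logical(df$BelowLOD) & !is.na(df$NPX)
  } else {
    blod[cbind(i, j)] <- !is.na(df$NPX) & df$NPX < assays$lod[j]
  }
  blod[is.na(vals)] <- FALSE
  npx_matrix(vals, assays, sample_ids = samples, below_lod = blod)
}

#' Read a sample metadata CSV
#'
#' Expects columns `SampleID`, `Diagnosis`, `Age`, `Sex` and optionally
#' `QC_Pass` (default `TRUE`).
#'
#' @param path CSV file path.
#' @return a [sample_info] data.frame.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("SampleID", "Diagnosis", "Age", "Sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata file lacks column(s): ", paste(miss, collapse = ", "))
  qc <- if ("QC_Pass" %in% names(df)) as.logical(df$QC_Pass) else rep(TRUE, nrow(df))
  sample_info(df$SampleID, df$Diagnosis, df$Age, df$Sex, qc)
}

#' Write an NPX matrix as long-format CSV
#'
#' Emits the canonical long format read back by [read_npx_long()]; missing
#' cells are simply not written.  A `# seed:` header records provenance when
#' given.
#'
#' @param m an [npx_matrix].
#' @param path output CSV path.
#' @param seed optional integer recorded in the header comment.
#' @export
write_npx_long <- function(m, path, seed = NULL) {
  idx <- which(!is.na(m$values), arr.ind = TRUE)
  df <- data.frame(
    SampleID = m$sample_ids[idx[, 1]],
    Assay = m$assays$name[idx[, 2]],
    Panel = m$assays$panel[idx[, 2]],
    NPX = m$values[idx],
    LOD = m$assays$lod[idx[, 2]],
    BelowLOD = m$below_lod[idx],
    stringsAsFactors = FALSE)
  df <- df[order(match(df$SampleID, m$sample_ids), df$Panel, df$Assay), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata CSV
#'
#' @param info a [sample_info] data.frame.
#' @param path output CSV path.
#' @param seed optional integer recorded in the header comment.
#' @export
write_sample_info <- function(info, path, seed = NULL) {
  df <- data.frame(SampleID = info$sample_id, Diagnosis = as.character(info$diagnosis),
                   Age = info$age, Sex = as.character(info$sex),
                   QC_Pass = info$qc_pass, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# ---- preprocessing rules ---------------------------------------------------

#' Resolve assays measured on more than one panel
#'
#' When the same protein is measured on two panels, the copy detected below
#' the limit of detection in the greater fraction of (non-missing) samples is
#' dropped and the better-detected copy kept.  An exact tie keeps the copy
#' from the lexicographically first panel, with a warning.
#'
#' @param m an [npx_matrix].
#' @return an [npx_matrix] with unique assay names across panels.
#' @export
resolve_duplicate_assays <- function(m) {
  dup_names <- unique(m$assays$name[duplicated(m$assays$name)])
  if (!length(dup_names)) return(m)
  drop <- integer()
  for (nm in dup_names) {
    cols <- which(m$assays$name == nm)
    frac <- vapply(cols, function(j) {
      obs <- !is.na(m$values[, j])
      if (!any(obs)) return(NA_real_)
      mean(m$below_lod[obs, j])
    }, numeric(1))
    if (length(unique(frac)) == 1L) {
      keep <- cols[order(m$assays$panel[cols])][1]
      warning("below-LOD fraction tie for assay '", nm,
              "'; keeping the copy from panel '",
              m$assays$panel[keep], "'")
    } else {
      keep <- cols[which.min(frac)]
    }
    drop <- c(drop, setdiff(cols, keep))
  }
  keep_cols <- setdiff(seq_len(nrow(m$assays)), drop)
  npx_matrix(m$values[, keep_cols, drop = FALSE],
             m$assays[keep_cols, , drop = FALSE],
             sample_ids = m$sample_ids,
             below_lod = m$below_lod[, keep_cols, drop = FALSE],
             low_detection_flagged = intersect(m$low_detection_flagged,
                                               m$assays$name[keep_cols]))
}

#' Flag assays with low detection
#'
#' Returns (and stores on the matrix) the names of assays whose fraction of
#' below-LOD values among non-missing measurements strictly exceeds
#' `threshold`.  Values are never removed: flagged assays stay in the data as
#' a conservative measure and downstream results carry the flag.
#'
#' @param m an [npx_matrix].
#' @param threshold fraction in (0, 1); default 0.20.
#' @return character vector of flagged assay names, with the per-assay
#'   below-LOD fractions as attribute `"fractions"`.  Assign it back with
#'   [annotate_low_detection()] to store the set on the matrix.
#' @export
flag_low_detection <- function(m, threshold = 0.20) {
  frac <- vapply(seq_len(ncol(m$values)), function(j) {
    obs <- !is.na(m$values[, j])
    if (!any(obs)) return(NA_real_)
    mean(m$below_lod[obs, j])
  }, numeric(1))
  names(frac) <- m$assays$name
  if (anyNA(frac)) {
    warning(sum(is.na(frac)), " assay(s) with all values missing excluded from flagging")
  }
  flagged <- unique(m$assays$name[!is.na(frac) & frac > threshold])
  attr(flagged, "fractions") <- frac
  flagged
}

#' Store the low-detection flag set on an NPX matrix
#'
#' Convenience wrapper: computes [flag_low_detection()] and records the
#' result in the matrix's `low_detection_flagged` field.
#'
#' @inheritParams flag_low_detection
#' @return the matrix with the flag set stored.
#' @export
annotate_low_detection <- function(m, threshold = 0.20) {
  m$low_detection_flagged <- as.character(flag_low_detection(m, threshold))
  m
}

#' Impute missing NPX values by iterative PCA
#'
#' EM-style low-rank completion: missing cells start at their column means,
#' then the matrix is repeatedly centered (and optionally scaled), projected
#' on its leading `ncp` singular directions, and only the missing cells are
#' overwritten with the reconstruction, until the sum of squared change in
#' the imputed cells falls below `tol`.  Observed values are never altered.
#'
#' @param m an [npx_matrix] or a plain numeric matrix with `NA`s.
#' @param ncp reconstruction rank, default 2.
#' @param max_iter iteration cap, default 1000.
#' @param tol convergence tolerance on the imputed cells, default 1e-8.
#' @param scale logical; also divide by column SDs inside the iteration.
#' @return object like `m` with no missing values; attribute `converged`
#'   (logical) and `iterations` record the fit.
#' @export
impute_iterative_pca <- function(m, ncp = 2, max_iter = 1000, tol = 1e-8,
                                 scale = FALSE) {
  is_npx <- inherits(m, "npx_matrix")
  x <- if (is_npx) m$values else as.matrix(m)
  stopifnot(ncp >= 1)
  miss <- is.na(x)
  if (!any(miss)) {
    out <- x
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    if (is_npx) { m$values <- x; attr(m, "converged") <- TRUE; return(m) }
    return(out)
  }
  if (any(colSums(!miss) == 0)) stop("assay with all values missing cannot be imputed")
  mu0 <- colMeans(x, na.rm = TRUE)
  x[miss] <- mu0[col(x)[miss]]
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ctr <- colMeans(x)
    scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
    scl[scl == 0] <- 1
    z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
    sv <- svd(z, nu = ncp, nv = ncp)
    d <- sv$d[seq_len(ncp)]
    recon <- sv$u %*% (d * t(sv$v))
    recon <- sweep(sweep(recon, 2, scl, `*`), 2, ctr, `+`)
    delta <- sum((recon[miss] - x[miss])^2)
    x[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) warning("iterative PCA imputation did not converge in ",
                          max_iter, " iterations")
  if (is_npx) {
    m$values <- x
    attr(m, "converged") <- converged
    attr(m, "iterations") <- it
    return(m)
  }
  attr(x, "converged") <- converged
  attr(x, "iterations") <- it
  x
}
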