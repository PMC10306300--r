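# Platform-specific preprocessing: extreme-outlier fences, immunoassay
# fit-range resolution, metabolite zero replacement and median
# normalization, and covariate adjustment.

#' Flag extreme outliers per karyotype and per analyte
#'
#' Classifies extreme outliers with Tukey-style fences at `k` times the
#' interquartile range: within each karyotype stratum of each analyte, a
#' value is flagged when it lies below `Q1 - k*IQR` or above `Q3 + k*IQR`
#' (default `k = 3`). Quartiles use linear interpolation between order
#' statistics (R's type 7). The classification is a single pass: fences are
#' computed once from all non-missing values and are not recomputed after
#' exclusion. Strata with fewer than 4 non-missing values are left
#' untouched with a warning.
#'
#' @param panel An [analyte_panel()] or analyte x sample matrix.
#' @param metadata Cohort metadata with `sample_id` and `karyotype`.
#' @param k Fence multiplier on the IQR.
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#' @return An `outlier_mask`: list with `mask` (logical analyte x sample
#'   matrix, `TRUE` = excluded) and `stats` (tibble of per-stratum Q1, Q3,
#'   IQR and fences).
#' @export
exclude_extreme_outliers <- function(panel, metadata, k = 3, quantile_type = 7) {
  x <- .panel_values(panel)
  .assert_scalar_number(k, "k", lower = 0)
  meta <- .match_samples(x, metadata)
  kar <- as.character(meta$karyotype)
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  stats_rows <- list()
  small <- 0L
  for (g in unique(kar)) {
    cols <- which(kar == g)
    xs <- x[, cols, drop = FALSE]
    for (a in seq_len(nrow(x))) {
      v <- xs[a, ]
      nn <- sum(is.finite(v))
      if (nn < 4L) { small <- small + 1L; next }
      q <- quantile(v[is.finite(v)], c(0.25, 0.75), names = FALSE,
                    type = quantile_type)
      iqr <- q[2] - q[1]
      lo <- q[1] - k * iqr
      hi <- q[2] + k * iqr
      out <- is.finite(v) & (v < lo | v > hi)
      mask[a, cols[out]] <- TRUE
      stats_rows[[length(stats_rows) + 1L]] <- tibble(
        analyte = rownames(x)[a], karyotype = g,
        q1 = q[1], q3 = q[2], iqr = iqr, lower = lo, upper = hi,
        n = nn, n_excluded = sum(out))
    }
  }
  if (small > 0L) {
    warn(sprintf("%d analyte/karyotype strata had < 4 non-missing values; no exclusion applied there", small))
  }
  structure(list(mask = mask,
                 stats = if (length(stats_rows)) dplyr::bind_rows(stats_rows) else tibble()),
            class = "outlier_mask")
}

#' @rdname exclude_extreme_outliers
#' @param mask An `outlier_mask` from [exclude_extreme_outliers()].
#' @return `apply_outlier_mask()` returns the panel (or matrix) with
#'   flagged values set to missing.
#' @export
apply_outlier_mask <- function(panel, mask) {
  x <- .panel_values(panel)
  if (!identical(dim(x), dim(mask$mask))) abort("mask does not match panel shape")
  x[mask$mask] <- NA_real_
  if (is_analyte_panel(panel)) { panel$values <- x; panel } else x
}

#' Resolve immunoassay out-of-range values and average duplicate wells
#'
#' Replaces values below the fit-curve range by the minimum, and values
#' above by the maximum, calculated in-range concentration of that analyte
#' on the same plate; then averages duplicate wells per sample. Analytes
#' with more than `flag_threshold` of wells outside the fit range are
#' flagged (and retained). In-range values pass through bit-identical. If
#' every well of an analyte on a plate is out of range, the analyte stays
#' missing on that plate and a warning is raised.
#'
#' @param panel An immunoassay [analyte_panel()] with per-well `sample_id`,
#'   `plate` and `flags`.
#' @param flag_threshold Out-of-range fraction above which an analyte is
#'   flagged (default 0.10).
#' @return An [analyte_panel()] with one column per sample and
#'   `flagged_analytes` filled in.
#' @export
resolve_out_of_range <- function(panel, flag_threshold = 0.1) {
  if (!is_analyte_panel(panel) || panel$platform != "immunoassay") {
    abort("`panel` must be an immunoassay analyte_panel")
  }
  if (is.null(panel$plate)) abort("immunoassay panel must carry plate IDs")
  if (is.null(panel$flags)) abort("immunoassay panel must carry fit-range flags")
  wells <- panel$values
  flags <- panel$flags
  plates <- unique(panel$plate)
  unresolved <- 0L
  for (pl in plates) {
    cols <- which(panel$plate == pl)
    for (a in seq_len(nrow(wells))) {
      fl <- flags[a, cols]
      inr <- fl == "in_range" & is.finite(wells[a, cols])
      oor <- fl %in% c("below_range", "above_range")
      if (!any(oor)) next
      if (!any(inr)) { unresolved <- unresolved + 1L; next }
      lo <- min(wells[a, cols][inr])
      hi <- max(wells[a, cols][inr])
      below <- cols[fl == "below_range"]
      above <- cols[fl == "above_range"]
      wells[a, below] <- lo
      wells[a, above] <- hi
    }
  }
  if (unresolved > 0L) {
    warn(sprintf("%d analyte/plate combinations had all wells out of range; left missing", unresolved))
  }
  samples <- unique(panel$sample_id)
  out <- matrix(NA_real_, nrow(wells), length(samples),
                dimnames = list(rownames(wells), samples))
  for (s in seq_along(samples)) {
    cols <- which(panel$sample_id == samples[s])
    v <- wells[, cols, drop = FALSE]
    out[, s] <- rowMeans(v, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  oor_frac <- rowMeans(matrix(flags %in% c("below_range", "above_range"),
                              nrow(flags)))
  flagged <- rownames(wells)[oor_frac > flag_threshold]
  analyte_panel(out, platform = "immunoassay", flagged_analytes = flagged)
}

#' Metabolite zero replacement and median normalization
#'
#' Replaces reported zero intensities with a random draw from
#' `Uniform(0, 0.5 * m)` where `m` is the smallest nonzero intensity of
#' that metabolite, then rescales each sample by
#' `global median / sample median` so that, after normalization, every
#' sample's median equals the global median of the (zero-replaced) raw
#' matrix. Replacement draws are reproducible from `seed`. Metabolites
#' with no nonzero values are set entirely missing with a warning; a
#' sample whose median is 0 is an error.
#'
#' @param panel A metabolomics [analyte_panel()] or matrix of nonnegative
#'   intensities.
#' @param seed Seed for the zero-replacement draws.
#' @return The normalized panel (same type as the input).
#' @export
normalize_metabolites <- function(panel, seed = 1L) {
  x <- .panel_values(panel)
  if (is_analyte_panel(panel) && panel$platform != "metabolomics") {
    abort("`panel` must be a metabolomics panel")
  }
  if (any(x < 0, na.rm = TRUE)) abort("intensities must be nonnegative")
  set.seed(.assert_count(seed, "seed", min = 0L))
  all_zero <- 0L
  for (a in seq_len(nrow(x))) {
    v <- x[a, ]
    zero <- which(is.finite(v) & v == 0)
    if (!length(zero)) next
    nz <- v[is.finite(v) & v > 0]
    if (!length(nz)) {
      x[a, ] <- NA_real_
      all_zero <- all_zero + 1L
      next
    }
    x[a, zero] <- runif(length(zero), 0, 0.5 * min(nz))
  }
  if (all_zero > 0L) {
    warn(sprintf("%d metabolites had no nonzero values; left missing", all_zero))
  }
  global_median <- median(x, na.rm = TRUE)
  sample_median <- apply(x, 2, median, na.rm = TRUE)
  if (any(!is.na(sample_median) & sample_median == 0)) {
    abort("sample with median intensity 0; cannot normalize")
  }
  x <- sweep(x, 2, global_median / sample_median, "*")
  if (is_analyte_panel(panel)) { panel$values <- x; panel } else x
}

#' Adjust a feature matrix for nuisance covariates
#'
#' Per feature, fits a linear model containing the nuisance covariates plus
#' a protected karyotype term, and subtracts only the fitted nuisance
#' contributions (with nuisance regressors centered, so the grand level and
#' the protected group contrast are retained). The operation is idempotent.
#' Missing covariates and rank-deficient designs are errors; the error for
#' a rank-deficient design names the collinear columns.
#'
#' @param features Numeric feature x sample matrix (e.g. log2 expression or
#'   log2 abundances). Missing feature values are tolerated per feature.
#' @param metadata Cohort metadata with `sample_id` plus all model columns.
#' @param nuisance Nuisance covariate names (default `age`, `sex`, `source`).
#' @param protect Protected covariates kept in the model but never removed
#'   (default `karyotype`).
#' @return The adjusted matrix, same shape and dimnames.
#' @export
adjust_covariates <- function(features, metadata,
                              nuisance = c("age", "sex", "source"),
                              protect = "karyotype") {
  x <- .panel_values(features)
  meta <- .match_samples(x, metadata)
  vars <- c(protect, nuisance)
  missing_vars <- setdiff(vars, names(meta))
  if (length(missing_vars)) {
    abort(sprintf("metadata lacks model columns: %s", paste(missing_vars, collapse = ", ")))
  }
  mm <- meta[vars]
  if (anyNA(mm)) abort("missing covariate values are not allowed")
  form <- stats::reformulate(vars)
  X <- model.matrix(form, data = mm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("rank-deficient design; collinear columns: %s",
                  paste(dropped, collapse = ", ")))
  }
  nuis_cols <- which(attr(X, "assign") %in% which(vars %in% nuisance))
  Xn_centered <- scale(X[, nuis_cols, drop = FALSE], center = TRUE, scale = FALSE)
  adj <- x
  complete_rows <- !apply(x, 1, anyNA)
  fit_block <- function(Y) {
    B <- qr.coef(qrX, t(Y))           # p x features
    Y - t(Xn_centered %*% B[nuis_cols, , drop = FALSE])
  }
  if (any(complete_rows)) {
    adj[complete_rows, ] <- fit_block(x[complete_rows, , drop = FALSE])
  }
  for (a in which(!complete_rows)) {
    ok <- is.finite(x[a, ])
    if (sum(ok) <= ncol(X)) next
    Xi <- X[ok, , drop = FALSE]
    qi <- qr(Xi)
    if (qi$rank < ncol(Xi)) next
    b <- qr.coef(qi, x[a, ok])
    Xc <- scale(Xi[, nuis_cols, drop = FALSE], center = TRUE, scale = FALSE)
    adj[a, ok] <- x[a, ok] - drop(Xc %*% b[nuis_cols])
  }
  if (is_analyte_panel(features)) { features$values <- adj; features } else adj
}
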