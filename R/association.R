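# Association screens relating IFN scores and karyotype to the omics
# layers. Every screen returns the common AssociationResult shape
# (feature, kind, estimate, p, q, n) with BH adjustment computed within
# that screen alone.

.association_result <- function(feature, kind, estimate, p, n) {
  tibble(feature = feature, kind = kind, estimate = estimate,
         p = p, q = .bh(p), n = n)
}

#' Spearman correlation screen
#'
#' Correlates a per-sample variable (typically the IFN score) with every
#' feature of a layer using average-rank Spearman rho on pairwise-complete
#' observations, with the t-approximation for p-values and BH adjustment
#' across the screen. Constant features get a missing rho and are excluded
#' from the BH family.
#'
#' @param scores Tibble with `sample_id` and a numeric column (default
#'   `ifn_score`), or a named numeric vector.
#' @param features Feature x sample matrix or [analyte_panel()].
#' @param score_col Name of the score column.
#' @param min_n Minimum paired observations per feature (default 4).
#' @return An association tibble with `kind = "spearman_rho"`.
#' @export
spearman_screen <- function(scores, features, score_col = "ifn_score",
                            min_n = 4L) {
  x <- .panel_values(features)
  s <- if (is.data.frame(scores)) setNames(scores[[score_col]], scores$sample_id) else scores
  common <- intersect(colnames(x), names(s))
  if (length(common) < min_n) abort("fewer than `min_n` samples shared between scores and features")
  x <- x[, common, drop = FALSE]
  s <- s[common]
  res <- apply(x, 1, function(v) {
    ok <- is.finite(v) & is.finite(s)
    n <- sum(ok)
    if (n < min_n) return(c(NA_real_, NA_real_, n))
    if (var(v[ok]) == 0 || var(s[ok]) == 0) return(c(NA_real_, NA_real_, n))
    rho <- cor(rank(v[ok]), rank(s[ok]))   # average-rank Spearman
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    c(rho, 2 * pt(-abs(tt), n - 2), n)
  })
  .association_result(rownames(x), "spearman_rho",
                      unname(res[1, ]), unname(res[2, ]),
                      as.integer(res[3, ]))
}

#' Differential abundance by log2-scale linear models
#'
#' Per analyte, fits `log2(abundance) ~ karyotype + age + sex + source`
#' and reports the karyotype coefficient as the log2 fold change, with
#' Wald p-values and BH adjustment across analytes. Analytes constant
#' across samples are dropped with a warning. Nonpositive abundances are
#' an error: out-of-range and outlier handling must happen upstream.
#'
#' @param panel An [analyte_panel()] or positive analyte x sample matrix
#'   (missing allowed for excluded values).
#' @param metadata Cohort metadata (`sample_id`, `karyotype`, covariates).
#' @param covariates Covariates beside karyotype.
#' @return An association tibble with `kind = "log2fc"`.
#' @export
differential_abundance <- function(panel, metadata,
                                   covariates = c("age", "sex", "source")) {
  x <- .panel_values(panel)
  if (any(x <= 0, na.rm = TRUE)) {
    abort("nonpositive abundances reached differential_abundance; QC contract violated")
  }
  meta <- .match_samples(x, metadata)
  form <- stats::reformulate(c("karyotype", covariates))
  X <- model.matrix(form, data = meta)
  kcol <- grep("^karyotype", colnames(X))[1]
  est <- p <- rep(NA_real_, nrow(x))
  nn <- integer(nrow(x))
  dropped <- 0L
  for (a in seq_len(nrow(x))) {
    ok <- is.finite(x[a, ])
    nn[a] <- sum(ok)
    if (nn[a] <= ncol(X)) next
    v <- log2(x[a, ok])
    if (var(v) == 0) { dropped <- dropped + 1L; next }
    Xi <- X[ok, , drop = FALSE]
    qi <- qr(Xi)
    if (qi$rank < ncol(Xi)) next
    b <- qr.coef(qi, v)
    r <- v - drop(Xi %*% b)
    df <- nn[a] - qi$rank
    se <- sqrt(sum(r^2) / df * chol2inv(qr.R(qi))[kcol, kcol])
    est[a] <- b[kcol]
    p[a] <- 2 * pt(-abs(b[kcol] / se), df)
  }
  if (dropped > 0L) {
    warn(sprintf("%d analytes constant across samples were dropped", dropped))
  }
  .association_result(rownames(x), "log2fc", est, p, nn)
}

#' Beta-regression screen on cell-cluster frequencies
#'
#' Per cell cluster, fits a beta regression of relative frequency on a
#' predictor (IFN score or karyotype) with `age` and `sex` adjustment and
#' a logit link, and reports `exp(predictor coefficient)` as the fold
#' change per predictor unit, with BH adjustment across clusters.
#' Outlier exclusion (3x IQR per karyotype per cluster) is expected to
#' have been applied upstream via [exclude_extreme_outliers()].
#' Non-converged fits are excluded from the BH family with a warning.
#'
#' @param cells Cluster x sample matrix of relative frequencies in (0, 1)
#'   (missing allowed for excluded values).
#' @param predictor Either a scores tibble (see [spearman_screen()]) or
#'   the string `"karyotype"`.
#' @param metadata Cohort metadata.
#' @param covariates Adjustment covariates (default `age`, `sex`).
#' @param boundary_correction Passed to [fit_beta_regression()].
#' @return An association tibble with `kind = "fold_change_per_unit"`.
#' @export
beta_screen <- function(cells, predictor, metadata,
                        covariates = c("age", "sex"),
                        boundary_correction = FALSE) {
  x <- .panel_values(cells)
  meta <- .match_samples(x, metadata)
  if (is.character(predictor) && length(predictor) == 1L && predictor == "karyotype") {
    pred <- as.numeric(meta$karyotype == "T21")
    pred_name <- "karyotype"
  } else {
    s <- if (is.data.frame(predictor)) setNames(predictor$ifn_score, predictor$sample_id) else predictor
    pred <- unname(s[colnames(x)])
    pred_name <- "ifn_score"
  }
  if (all(!is.finite(pred)) || var(pred, na.rm = TRUE) == 0) {
    abort("predictor is constant; no identifiable slope")
  }
  df <- data.frame(pred = pred, as.data.frame(meta)[covariates])
  X <- model.matrix(~ ., data = df)
  pcol <- which(colnames(X) == "pred")
  est <- p <- rep(NA_real_, nrow(x))
  nn <- integer(nrow(x))
  nonconv <- 0L
  skipped <- 0L
  for (a in seq_len(nrow(x))) {
    y <- x[a, ]
    ok <- is.finite(y) & is.finite(pred)
    nn[a] <- sum(ok)
    if (all(y[ok] == 0)) { skipped <- skipped + 1L; next }
    if (nn[a] <= ncol(X) + 1L) next
    fit <- tryCatch(
      fit_beta_regression(y[ok], X[ok, , drop = FALSE],
                          boundary_correction = boundary_correction),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$converged) { nonconv <- nonconv + 1L; next }
    est[a] <- exp(fit$coefficients[pcol])
    p[a] <- fit$p.value[pcol]
  }
  if (skipped > 0L) warn(sprintf("%d all-zero clusters skipped", skipped))
  if (nonconv > 0L) warn(sprintf("%d non-converged beta fits excluded", nonconv))
  out <- .association_result(rownames(x), "fold_change_per_unit", est, p, nn)
  out$predictor <- pred_name
  out
}
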