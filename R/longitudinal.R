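# Longitudinal on/off-drug case analysis: per-feature on/off fold
# changes, cohort reference bands, and score-trajectory classification.

#' Per-feature on/off-drug fold changes
#'
#' For each feature (restricted to `genes` when supplied, e.g. the
#' non-chr21 ISG universe), computes the log2 fold change of on-drug over
#' off-drug draws as the difference of mean log2 values (a geometric-mean
#' ratio on the raw scale; set `log_scale = FALSE` for arithmetic means),
#' a two-sided Mann-Whitney p across draws, and BH q across features. A
#' status with a single draw yields fold changes but missing p-values,
#' with a warning.
#'
#' @param series An `ifn_series` from [generate_longitudinal_subject()],
#'   or a list with `expression` (feature x draw matrix) and `draws`
#'   (tibble with `draw`, `status` in off/on).
#' @param genes Optional feature subset.
#' @param log_scale Contrast means of log2 values (default) or of raw
#'   values.
#' @return A tibble: `feature`, `log2fc_on_off`, `p`, `q`.
#' @export
on_off_fold_changes <- function(series, genes = NULL, log_scale = TRUE) {
  x <- series$expression
  status <- series$draws$status
  if (!all(c("off", "on") %in% as.character(status))) {
    abort("both on and off draws are required")
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) abort(sprintf("features missing from series: %s",
                                    paste(head(miss, 5), collapse = ", ")))
    x <- x[genes, , drop = FALSE]
  }
  if (any(x <= 0, na.rm = TRUE)) abort("feature values must be positive")
  on <- as.character(status) == "on"
  single <- sum(on) < 2L || sum(!on) < 2L
  if (single) warn("a status has a single draw; p-values are undefined and reported missing")
  lx <- log2(x)
  fc <- rowMeans(lx[, on, drop = FALSE]) - rowMeans(lx[, !on, drop = FALSE])
  if (!log_scale) {
    fc <- log2(rowMeans(x[, on, drop = FALSE]) / rowMeans(x[, !on, drop = FALSE]))
  }
  p <- if (single) rep(NA_real_, nrow(x)) else
    apply(lx, 1, function(v) .mann_whitney(v[on], v[!on]))
  tibble(feature = rownames(x), log2fc_on_off = unname(fc),
         p = unname(p), q = .bh(p))
}

#' Cohort reference bands for IFN scores
#'
#' Per karyotype group, the median and quartiles of cohort IFN scores
#' (package quantile convention), used as the reference ranges against
#' which a longitudinal subject's draws are positioned.
#'
#' @param cohort_scores Scores tibble (`sample_id`, `ifn_score`).
#' @param metadata Cohort metadata with `sample_id`, `karyotype`.
#' @return A tibble: `karyotype`, `q1`, `median`, `q3`, `n`.
#' @export
reference_bands <- function(cohort_scores, metadata) {
  meta <- metadata[match(cohort_scores$sample_id, metadata$sample_id), ]
  groups <- unique(as.character(meta$karyotype))
  if (length(groups) < 2L) abort("both karyotype groups must be present")
  rows <- lapply(groups, function(g) {
    v <- cohort_scores$ifn_score[meta$karyotype == g]
    v <- v[is.finite(v)]
    if (!length(v)) abort(sprintf("empty karyotype group: %s", g))
    q <- .quartiles(v)
    tibble(karyotype = g, q1 = q[1], median = q[2], q3 = q[3], n = length(v))
  })
  dplyr::bind_rows(rows)
}

#' Score a longitudinal series against frozen reference statistics
#'
#' @param series An `ifn_series`.
#' @param ref A frozen [reference_stats()] object from the cross-sectional
#'   cohort (the series is never scored against its own draws).
#' @param log2_scale,pseudocount Transform applied before scoring; must
#'   match the convention under which `ref` was computed.
#' @return The series' scores joined to its draw table: `draw`, `time`,
#'   `status`, `ifn_score`.
#' @export
score_series <- function(series, ref, log2_scale = TRUE, pseudocount = 0.5) {
  x <- if (log2_scale) log2(series$expression + pseudocount) else series$expression
  sc <- compute_ifn_score(x, ref)
  dplyr::bind_cols(series$draws, sc["ifn_score"])
}

#' Classify a score trajectory against cohort reference bands
#'
#' Labels each draw by its position relative to the euploid-control and
#' T21 interquartile ranges (control IQR takes precedence where the two
#' overlap), tests on-drug versus off-drug scores with a two-sided
#' Mann-Whitney U, and flags whether the on-drug median falls below the
#' off-drug median.
#'
#' @param scored_series Tibble from [score_series()] (`draw`, `time`,
#'   `status`, `ifn_score`).
#' @param bands Reference bands from [reference_bands()].
#' @return An `ifn_trajectory`: list with `draws` (classified tibble),
#'   `on_vs_off_p`, `on_median`, `off_median`, `on_below_off`, `bands`.
#' @export
score_trajectory_report <- function(scored_series, bands) {
  if (missing(bands) || is.null(bands)) abort("reference bands are required")
  need <- c("control", "T21")
  if (!all(need %in% bands$karyotype)) abort("bands must cover control and T21")
  ctrl <- bands[bands$karyotype == "control", ]
  t21 <- bands[bands$karyotype == "T21", ]
  cls <- vapply(scored_series$ifn_score, function(v) {
    if (v >= ctrl$q1 && v <= ctrl$q3) "within_control_range"
    else if (v >= t21$q1 && v <= t21$q3) "within_t21_range"
    else if (v < ctrl$q1) "below_control_range"
    else if (v > t21$q3) "above_t21_range"
    else "between_ranges"
  }, character(1))
  on <- scored_series$ifn_score[scored_series$status == "on"]
  off <- scored_series$ifn_score[scored_series$status == "off"]
  structure(list(
    draws = dplyr::mutate(scored_series, classification = cls),
    on_vs_off_p = .mann_whitney(on, off),
    on_median = median(on), off_median = median(off),
    on_below_off = median(on) < median(off),
    bands = bands
  ), class = "ifn_trajectory")
}

#' @export
print.ifn_trajectory <- function(x, ...) {
  cat(sprintf("<ifn_trajectory> on median %.2f vs off median %.2f (on %s off; Mann-Whitney p = %.3g)\n",
              x$on_median, x$off_median,
              if (x$on_below_off) "below" else "not below", x$on_vs_off_p))
  print(table(x$draws$classification))
  invisible(x)
}

#' @method autoplot ifn_trajectory
#' @export
autoplot.ifn_trajectory <- function(object, ...) {
  b <- object$bands
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$time, y = .data$ifn_score,
                               colour = .data$status)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = b$q1[b$karyotype == "control"],
                      ymax = b$q3[b$karyotype == "control"],
                      alpha = 0.15, fill = "grey40") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = b$q1[b$karyotype == "T21"],
                      ymax = b$q3[b$karyotype == "T21"],
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::geom_hline(yintercept = b$median, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::labs(x = "draw", y = "IFN score",
                  title = "IFN score trajectory vs cohort reference bands") +
    ggplot2::theme_minimal()
}
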