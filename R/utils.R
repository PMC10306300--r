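# Internal helpers shared across modules.

# Quantile convention used throughout (fences, reference bands): linear
# interpolation between order statistics, R's type 7 default.
.quartiles <- function(x, type = 7) {
  x <- x[is.finite(x)]
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = type)
}

# Benjamini-Hochberg within one screen; NAs excluded from the denominator.
.bh <- function(p) stats::p.adjust(p, method = "BH")

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# Align a feature-by-sample matrix with a metadata table on sample IDs.
.match_samples <- function(mat, metadata) {
  if (is.null(colnames(mat))) abort("feature matrix must have sample IDs as column names")
  idx <- match(colnames(mat), metadata$sample_id)
  if (anyNA(idx)) {
    abort(sprintf(
      "samples missing from metadata: %s",
      paste(head(colnames(mat)[is.na(idx)], 5), collapse = ", ")
    ))
  }
  metadata[idx, , drop = FALSE]
}

# Two-sided Mann-Whitney U; exact for small tie-free samples, normal
# approximation with tie correction otherwise (stats::wilcox.test policy).
.mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}
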