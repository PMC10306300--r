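# Consensus clustering (Monti resampling scheme): repeated subsampled
# hierarchical clustering with 1 - Pearson correlation distance; the
# consensus matrix records how often each sample pair co-clusters when
# co-sampled, and the consensus-CDF area curve drives cluster-number
# selection.

.pearson_dist <- function(x) {
  as.dist(1 - cor(x))
}

# Area under the empirical CDF of the off-diagonal consensus values
# (Monti's A(k)): sum over sorted unique values of (x_i - x_{i-1}) * CDF(x_{i-1}).
.consensus_auc <- function(cm) {
  v <- sort(cm[lower.tri(cm)])
  xs <- unique(c(0, v, 1))
  cdf <- ecdf(v)
  sum(diff(xs) * cdf(head(xs, -1L)))
}

#' Consensus clustering of samples on marker profiles
#'
#' For each resampling repetition, subsamples a fraction of the samples,
#' computes 1 - Pearson correlation distances between their marker
#' profiles, cuts an agglomerative hierarchical tree at each `k`, and
#' accumulates co-clustering counts. The consensus matrix entry (i, j) is
#' the number of times i and j clustered together divided by the number of
#' times both were sampled. Final labels at each k come from hierarchical
#' clustering of 1 - consensus. With `reps = 1` and `item_fraction = 1`
#' the consensus entries are exactly the 0/1 co-membership of a single
#' hierarchical cut.
#'
#' @param marker_z Marker x sample matrix (typically per-marker z-scores
#'   of the T21 samples). Zero-variance markers are dropped with a warning.
#' @param k_range Candidate cluster numbers (each must be < n samples).
#' @param reps Number of subsampling repetitions.
#' @param item_fraction Fraction of samples drawn per repetition.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param seed Seed for the resampling stream.
#' @return An `ifn_consensus`: list with `consensus` (list of sample x
#'   sample matrices per k), `labels` (list per k), `summary` (tibble: k,
#'   auc, delta_area), and the resampling log. Supports [tidy()] and
#'   [autoplot()].
#' @export
consensus_cluster <- function(marker_z, k_range = 2:7, reps = 100L,
                              item_fraction = 0.8, linkage = "average",
                              seed = 1L) {
  x <- .panel_values(marker_z)
  reps <- .assert_count(reps, "reps", min = 1L)
  .assert_scalar_number(item_fraction, "item_fraction", lower = 0.1, upper = 1)
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    abort("k_range must lie within [2, n - 1]")
  }
  keep <- apply(x, 1, function(v) isTRUE(var(v) > 0))
  if (any(!keep)) {
    warn(sprintf("%d zero-variance markers dropped", sum(!keep)))
    x <- x[keep, , drop = FALSE]
  }
  set.seed(.assert_count(seed, "seed", min = 0L))
  m <- max(2L, floor(item_fraction * n))
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  co_sampled <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    hc <- hclust(.pearson_dist(x[, idx, drop = FALSE]), method = linkage)
    for (k in k_range) {
      if (k >= length(idx)) next
      lab <- cutree(hc, k = k)
      same <- outer(lab, lab, "==")
      ck <- conn[[as.character(k)]]
      ck[idx, idx] <- ck[idx, idx] + same
      conn[[as.character(k)]] <- ck
    }
  }
  consensus <- lapply(conn, function(ck) {
    cm <- ifelse(co_sampled > 0, ck / co_sampled, 0)
    diag(cm) <- 1
    dimnames(cm) <- list(colnames(x), colnames(x))
    cm
  })
  labels <- lapply(seq_along(k_range), function(i) {
    cm <- consensus[[i]]
    hc <- hclust(as.dist(1 - cm), method = linkage)
    setNames(cutree(hc, k = k_range[i]), colnames(x))
  })
  names(labels) <- as.character(k_range)
  auc <- vapply(consensus, .consensus_auc, numeric(1))
  delta <- c(auc[1], diff(auc) / head(auc, -1L))
  structure(list(
    consensus = consensus, labels = labels,
    summary = tibble(k = k_range, auc = unname(auc), delta_area = unname(delta)),
    resampling = list(reps = reps, item_fraction = item_fraction,
                      linkage = linkage, seed = seed)
  ), class = "ifn_consensus")
}

#' @export
print.ifn_consensus <- function(x, ...) {
  cat(sprintf("<ifn_consensus> %d samples, k in {%s}, %d reps at fraction %.2f (%s linkage)\n",
              nrow(x$consensus[[1]]), paste(x$summary$k, collapse = ", "),
              x$resampling$reps, x$resampling$item_fraction,
              x$resampling$linkage))
  print(x$summary)
  invisible(x)
}

#' @method tidy ifn_consensus
#' @export
tidy.ifn_consensus <- function(x, ...) x$summary

#' Choose the cluster number from the consensus delta-area curve
#'
#' Returns the largest k reached before the relative gain in consensus-CDF
#' area first falls below `gain_threshold`: i.e. the smallest k whose
#' successor adds less than the threshold. If every gain stays above the
#' threshold the maximum k is returned with a warning (no plateau).
#'
#' @param result An [consensus_cluster()] result, or a tibble with `k`
#'   and `delta_area`.
#' @param gain_threshold Relative area-gain threshold (default 0.05).
#' @return The chosen k (integer).
#' @export
select_k_delta_area <- function(result, gain_threshold = 0.05) {
  s <- if (inherits(result, "ifn_consensus")) result$summary else as_tibble(result)
  if (nrow(s) < 3L) abort("at least 3 k values are required")
  .assert_scalar_number(gain_threshold, "gain_threshold", lower = 0)
  gains <- s$delta_area
  below <- which(gains < gain_threshold)
  if (!length(below)) {
    warn("consensus area gains never plateau; returning the maximum k")
    return(max(s$k))
  }
  i <- below[1]
  if (i == 1L) s$k[1] else s$k[i - 1L]
}

#' @method autoplot ifn_consensus
#' @export
autoplot.ifn_consensus <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$k, y = .data$delta_area)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "relative consensus area gain",
                  title = "Consensus clustering delta-area curve") +
    ggplot2::theme_minimal()
}
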