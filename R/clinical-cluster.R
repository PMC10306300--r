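# Mixed-data clinical stratification: Gower distance over condition flags
# plus the IFN score, PAM (k-medoids) clustering with silhouette-based k
# selection, observed/expected condition enrichment with Fisher tests, and
# score comparisons across groups.

#' Gower distance for mixed clinical records
#'
#' Pairwise dissimilarity averaging per-variable contributions: binary
#' variables contribute simple matching (0 if equal, 1 otherwise -
#' co-absence counts as agreement, matching the symmetric treatment of
#' condition flags); numeric variables contribute `|x_i - x_j| / range`.
#' Unknown (NA) values are excluded pairwise from the average. Distances
#' lie in \[0, 1\] with a zero diagonal; the triangle inequality is not
#' guaranteed.
#'
#' @param records Data frame: logical columns (condition flags) and/or
#'   numeric columns (e.g. IFN score). A `sample_id` column, if present,
#'   is used for dimnames.
#' @return A symmetric n x n distance matrix.
#' @export
gower_distance <- function(records) {
  records <- as.data.frame(records)
  ids <- if ("sample_id" %in% names(records)) records$sample_id else rownames(records)
  records$sample_id <- NULL
  if (!ncol(records)) abort("no usable variables in `records`")
  n <- nrow(records)
  num <- sum_d <- matrix(0, n, n)
  for (v in names(records)) {
    x <- records[[v]]
    if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1, NA)))) {
      x <- as.numeric(x)
      d <- abs(outer(x, x, "-"))     # simple matching for binaries
      d[d > 0] <- 1
    } else if (is.numeric(x)) {
      rng <- diff(range(x, na.rm = TRUE))
      d <- if (rng > 0) abs(outer(x, x, "-")) / rng else matrix(0, n, n)
    } else {
      d <- 1 - outer(as.character(x), as.character(x), "==")
      storage.mode(d) <- "numeric"
    }
    ok <- !is.na(d)
    d[!ok] <- 0
    sum_d <- sum_d + d
    num <- num + ok
  }
  if (any(num == 0 & row(num) != col(num))) {
    abort("some record pairs share no non-missing variables")
  }
  out <- sum_d / pmax(num, 1)
  diag(out) <- 0
  dimnames(out) <- list(ids, ids)
  out
}

# Total distance of every point to its nearest medoid.
.pam_cost <- function(D, medoids) {
  sum(apply(D[medoids, , drop = FALSE], 2, min))
}

# One steepest-descent SWAP pass to convergence from a given medoid set.
.pam_swap <- function(D, medoids) {
  n <- nrow(D)
  cost <- .pam_cost(D, medoids)
  repeat {
    best <- list(delta = 0, mi = NULL)
    others <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      rest <- medoids[-mi]
      d_rest <- if (length(rest)) apply(D[rest, , drop = FALSE], 2, min) else rep(Inf, n)
      for (j in others) {
        delta <- sum(pmin(d_rest, D[j, ])) - cost
        if (delta < best$delta - 1e-12) best <- list(delta = delta, mi = mi, j = j)
      }
    }
    if (is.null(best$mi)) break
    medoids[best$mi] <- best$j
    cost <- cost + best$delta
  }
  list(medoids = sort(medoids), cost = cost)
}

#' PAM (k-medoids) clustering from a distance matrix
#'
#' Partitioning around medoids: a greedy BUILD phase selects k initial
#' medoids, then a steepest-descent SWAP phase exchanges a medoid for a
#' non-medoid whenever that lowers the total distance of points to their
#' nearest medoid, until no swap improves. Because single-swap descent can
#' terminate in a local optimum of the k-medoids objective, the SWAP phase
#' is additionally restarted from `restarts` seeded random medoid sets and
#' the lowest-cost solution is kept (ties broken toward the lexically
#' smallest medoid set, so the result is deterministic given the seed).
#'
#' @param dist Symmetric nonnegative distance matrix with zero diagonal.
#' @param k Number of clusters (1 <= k <= n).
#' @param restarts Number of additional random initializations of the
#'   SWAP phase beyond the BUILD start.
#' @param seed Seed for the restart initializations.
#' @return A list: `labels` (cluster of each point, numbered by medoid
#'   order), `medoids` (indices), `cost` (total within-cluster distance
#'   to medoid).
#' @export
pam_cluster <- function(dist, k, restarts = 20L, seed = 1L) {
  D <- as.matrix(dist)
  n <- nrow(D)
  k <- .assert_count(k, "k", min = 1L)
  restarts <- .assert_count(restarts, "restarts")
  if (k > n) abort("k cannot exceed the number of points")
  if (any(abs(diag(D)) > 1e-12) || any(D < -1e-12)) {
    abort("`dist` must be nonnegative with a zero diagonal")
  }
  if (max(abs(D - t(D))) > 1e-8) abort("`dist` must be symmetric")
  # BUILD: start with the most central point, then greedily add the point
  # giving the largest cost reduction.
  medoids <- which.min(colSums(D))
  while (length(medoids) < k) {
    dmin <- apply(D[medoids, , drop = FALSE], 2, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(dmin - D[j, ], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }
  best <- .pam_swap(D, unname(medoids))
  if (restarts > 0L && k < n) {
    set.seed(.assert_count(seed, "seed", min = 0L))
    for (r in seq_len(restarts)) {
      cand <- .pam_swap(D, sort(sample.int(n, k)))
      if (cand$cost < best$cost - 1e-12 ||
          (abs(cand$cost - best$cost) <= 1e-12 &&
           paste(cand$medoids, collapse = ",") < paste(best$medoids, collapse = ","))) {
        best <- cand
      }
    }
  }
  medoids <- unname(best$medoids)
  assign_idx <- apply(D[medoids, , drop = FALSE], 2, which.min)
  labels <- as.integer(assign_idx)
  names(labels) <- rownames(D)
  list(labels = labels, medoids = medoids, cost = .pam_cost(D, medoids))
}

#' Average silhouette widths and k selection
#'
#' Runs [pam_cluster()] for each candidate k and computes the average
#' silhouette width `s(i) = (b - a) / max(a, b)`, where `a` is the mean
#' distance of point i to its own cluster and `b` the smallest mean
#' distance to another cluster; members of singleton clusters get
#' `s(i) = 0` by convention (with a warning). Returns the k with the
#' highest average width.
#'
#' @param dist Distance matrix.
#' @param k_range Candidate cluster numbers, within \[2, n - 1\].
#' @return A list: `k` (chosen), `widths` (tibble: k, avg_width),
#'   `clusterings` (list of [pam_cluster()] results per k).
#' @export
silhouette_select_k <- function(dist, k_range = 2:6) {
  D <- as.matrix(dist)
  n <- nrow(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    abort("k_range must lie within [2, n - 1]")
  }
  clusterings <- lapply(k_range, function(k) pam_cluster(D, k))
  widths <- vapply(clusterings, function(cl) mean(silhouette_widths(D, cl$labels)),
                   numeric(1))
  names(clusterings) <- as.character(k_range)
  list(k = k_range[which.max(widths)],
       widths = tibble(k = k_range, avg_width = widths),
       clusterings = clusterings)
}

#' @rdname silhouette_select_k
#' @param labels Integer cluster labels.
#' @return `silhouette_widths()` returns the per-point silhouette values.
#' @export
silhouette_widths <- function(dist, labels) {
  D <- as.matrix(dist)
  n <- nrow(D)
  s <- numeric(n)
  sizes <- table(labels)
  if (any(sizes == 1L)) warn("singleton cluster: its members get silhouette 0")
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Condition enrichment across clinical clusters
#'
#' For each condition (pre-filtered to at least `min_cases` cases and
#' controls), computes the observed/expected case ratio per cluster -
#' expected counts assume equal occurrence rates across clusters - and a
#' two-sided Fisher exact test on the k x 2 cluster-by-status table
#' (exact enumeration for k = 2; Monte-Carlo p with `fisher_b` draws for
#' k > 2), with BH adjustment across conditions.
#'
#' @param labels Cluster labels (named by sample, or aligned with rows of
#'   `conditions`).
#' @param conditions Data frame of logical condition flags (NA = unknown).
#' @param min_cases Minimum cases and controls per condition.
#' @param fisher_b Monte-Carlo draws for k > 2 Fisher tests.
#' @param seed Seed for Monte-Carlo Fisher tests.
#' @return A `condition_enrichment`: list with `oe` (tibble: condition,
#'   cluster, observed, expected, oe_ratio) and `tests` (tibble:
#'   condition, odds_ratio, p, q). Supports [tidy()].
#' @export
condition_enrichment <- function(labels, conditions, min_cases = 10L,
                                 fisher_b = 10000L, seed = 1L) {
  conditions <- as.data.frame(conditions)
  conditions$sample_id <- NULL
  if (length(labels) != nrow(conditions)) {
    abort("labels and conditions must cover the same samples")
  }
  labs <- as.integer(factor(labels))
  ks <- sort(unique(labs))
  oe_rows <- list(); test_rows <- list()
  set.seed(.assert_count(seed, "seed", min = 0L))
  for (cn in names(conditions)) {
    fl <- as.logical(conditions[[cn]])
    ok <- !is.na(fl)
    n_cases <- sum(fl[ok]); n_ctrl <- sum(!fl[ok])
    if (n_cases == 0L) abort(sprintf("condition %s has zero cases; pre-filtering contract violated", cn))
    if (n_cases < min_cases || n_ctrl < min_cases) next
    tab <- table(factor(labs[ok], levels = ks), factor(fl[ok], levels = c(FALSE, TRUE)))
    rate <- n_cases / sum(ok)
    for (g in seq_along(ks)) {
      csize <- sum(tab[g, ])
      expected <- csize * rate
      oe_rows[[length(oe_rows) + 1L]] <- tibble(
        condition = cn, cluster = ks[g],
        observed = as.integer(tab[g, "TRUE"]), expected = expected,
        oe_ratio = if (expected > 0) tab[g, "TRUE"] / expected else NA_real_)
    }
    ft <- if (length(ks) == 2L) {
      fisher.test(tab)
    } else {
      fisher.test(tab, simulate.p.value = TRUE, B = fisher_b)
    }
    test_rows[[length(test_rows) + 1L]] <- tibble(
      condition = cn,
      odds_ratio = if (length(ks) == 2L) unname(ft$estimate) else NA_real_,
      p = ft$p.value)
  }
  if (!length(test_rows)) abort("no conditions passed the case/control filter")
  tests <- dplyr::bind_rows(test_rows)
  tests$q <- .bh(tests$p)
  structure(list(oe = dplyr::bind_rows(oe_rows), tests = tests,
                 min_cases = min_cases),
            class = "condition_enrichment")
}

#' @export
print.condition_enrichment <- function(x, ...) {
  cat(sprintf("<condition_enrichment> %d conditions, %d clusters\n",
              nrow(x$tests), length(unique(x$oe$cluster))))
  print(x$tests)
  invisible(x)
}

#' @method tidy condition_enrichment
#' @export
tidy.condition_enrichment <- function(x, ...) {
  dplyr::left_join(x$oe, x$tests, by = "condition")
}

#' Compare IFN scores across clusters or case/control groups
#'
#' Two-sided Mann-Whitney U tests of score distributions: for cluster
#' labels, each cluster against the reference cluster; for a data frame of
#' condition flags, cases against controls per condition. BH adjustment is
#' applied across the comparisons made. Empty groups are skipped with a
#' warning.
#'
#' @param scores Scores tibble (`sample_id`, `ifn_score`) or named vector.
#' @param groups Cluster labels (vector, compared to `reference`) or a
#'   data frame of logical condition flags.
#' @param reference Reference cluster label (default: first level).
#' @return A tibble: `comparison`, `n1`, `n2`, `median_diff`, `p`, `q`.
#' @export
compare_scores_across_groups <- function(scores, groups, reference = NULL) {
  s <- if (is.data.frame(scores)) setNames(scores$ifn_score, scores$sample_id) else scores
  rows <- list()
  if (is.data.frame(groups)) {
    conds <- as.data.frame(groups)
    ids <- conds$sample_id %||% names(s)
    conds$sample_id <- NULL
    sv <- unname(s[ids])
    for (cn in names(conds)) {
      fl <- as.logical(conds[[cn]])
      x <- sv[which(fl)]; y <- sv[which(!fl)]
      if (!length(x) || !length(y)) { warn(sprintf("%s: empty group; skipped", cn)); next }
      rows[[length(rows) + 1L]] <- tibble(
        comparison = cn, n1 = length(x), n2 = length(y),
        median_diff = median(x, na.rm = TRUE) - median(y, na.rm = TRUE),
        p = .mann_whitney(x, y))
    }
  } else {
    labs <- groups
    ids <- names(labs) %||% names(s)
    sv <- unname(s[ids])
    lv <- sort(unique(labs))
    if (is.null(reference)) reference <- lv[1]
    for (g in setdiff(lv, reference)) {
      x <- sv[labs == g]; y <- sv[labs == reference]
      if (!length(x) || !length(y)) { warn("empty group; skipped"); next }
      rows[[length(rows) + 1L]] <- tibble(
        comparison = sprintf("cluster %s vs %s", g, reference),
        n1 = length(x), n2 = length(y),
        median_diff = median(x, na.rm = TRUE) - median(y, na.rm = TRUE),
        p = .mann_whitney(x, y))
    }
  }
  if (!length(rows)) abort("no comparisons could be made")
  out <- dplyr::bind_rows(rows)
  out$q <- .bh(out$p)
  out
}

#' Clinical stratification end to end
#'
#' Builds the mixed record table (condition flags plus IFN score), computes
#' Gower distances, selects k by average silhouette width over `k_range`,
#' clusters with PAM, and runs condition enrichment and score comparisons.
#'
#' @param scores Scores tibble (`sample_id`, `ifn_score`).
#' @param conditions Data frame with `sample_id` and logical condition
#'   columns (typically the T21 samples' metadata condition flags).
#' @param k_range Candidate cluster numbers.
#' @param min_cases Condition filter (cases and controls).
#' @param include_score Include the IFN score as a numeric Gower variable.
#' @return A `clinical_strata`: labels, chosen k, silhouette widths,
#'   medoid sample IDs, [condition_enrichment()] result and score
#'   comparisons.
#' @export
stratify_clinical <- function(scores, conditions, k_range = 2:6,
                              min_cases = 10L, include_score = TRUE) {
  conds <- as.data.frame(conditions)
  if (!"sample_id" %in% names(conds)) abort("`conditions` needs a sample_id column")
  s <- setNames(scores$ifn_score, scores$sample_id)
  conds <- conds[conds$sample_id %in% names(s), , drop = FALSE]
  cond_cols <- names(conds)[vapply(conds, is.logical, logical(1))]
  # Pre-filter conditions on case/control counts.
  keep <- vapply(cond_cols, function(cn) {
    fl <- conds[[cn]]
    sum(fl, na.rm = TRUE) >= min_cases && sum(!fl, na.rm = TRUE) >= min_cases
  }, logical(1))
  cond_cols <- cond_cols[keep]
  if (!length(cond_cols)) abort("no conditions pass the case/control filter")
  records <- conds[c("sample_id", cond_cols)]
  if (include_score) records$ifn_score <- unname(s[records$sample_id])
  D <- gower_distance(records)
  sel <- silhouette_select_k(D, k_range)
  cl <- sel$clusterings[[as.character(sel$k)]]
  enrich <- condition_enrichment(cl$labels, conds[cond_cols],
                                 min_cases = min_cases)
  score_tests <- compare_scores_across_groups(
    scores[match(records$sample_id, scores$sample_id), ], cl$labels)
  structure(list(
    labels = cl$labels, k = sel$k, widths = sel$widths,
    medoids = records$sample_id[cl$medoids],
    enrichment = enrich, score_tests = score_tests,
    distance = D
  ), class = "clinical_strata")
}

#' @export
print.clinical_strata <- function(x, ...) {
  cat(sprintf("<clinical_strata> k = %d (silhouette-selected), sizes: %s\n",
              x$k, paste(table(x$labels), collapse = "/")))
  print(x$score_tests)
  invisible(x)
}
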