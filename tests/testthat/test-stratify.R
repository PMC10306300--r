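# Unsupervised stratification: consensus clustering, delta-area k
# selection, Gower/PAM/silhouette with exhaustive oracles, and the
# enrichment and score tests.

test_that("degenerate consensus run reproduces a plain hierarchical cut", {
  set.seed(50)
  z <- generate_marker_subtypes(n_per_group = 6, n_groups = 3, n_markers = 12,
                                seed = 50)
  res <- consensus_cluster(z, k_range = 2:4, reps = 1, item_fraction = 1,
                           seed = 1)
  hc <- hclust(as.dist(1 - cor(z)), method = "average")
  for (k in 2:4) {
    cm <- res$consensus[[as.character(k)]]
    expect_true(all(cm %in% c(0, 1)))
    lab <- cutree(hc, k = k)
    expect_equal(unname(cm[upper.tri(cm)]),
                 unname(outer(lab, lab, "==")[upper.tri(cm)] + 0))
    # Final labels recover the same partition.
    expect_equal(mclust::adjustedRandIndex(res$labels[[as.character(k)]], lab), 1)
  }
})

test_that("two well-separated clouds give a binary consensus and exact recovery", {
  z <- generate_marker_subtypes(n_per_group = 10, n_groups = 2, n_markers = 10,
                                shift = 5, noise_sd = 0.8, seed = 51)
  res <- consensus_cluster(z, k_range = 2:4, reps = 50, seed = 3)
  cm <- res$consensus[["2"]]
  expect_true(all(cm >= 0 & cm <= 1))
  expect_true(all(cm %in% c(0, 1)))
  expect_equal(mclust::adjustedRandIndex(res$labels[["2"]],
                                         attr(z, "labels")), 1)
  # Equivariance: permuting samples permutes the consensus identically.
  perm <- sample(ncol(z))
  res_p <- consensus_cluster(z[, perm], k_range = 2:4, reps = 50, seed = 3)
  expect_equal(res_p$consensus[["2"]][colnames(z)[perm], colnames(z)[perm]],
               cm[colnames(z)[perm], colnames(z)[perm]])
})

test_that("consensus matrices are symmetric with unit diagonal", {
  z <- generate_marker_subtypes(n_per_group = 6, n_groups = 3, seed = 52)
  res <- consensus_cluster(z, k_range = 2:5, reps = 20, seed = 9)
  for (cm in res$consensus) {
    expect_equal(cm, t(cm), tolerance = 1e-12)
    expect_equal(unname(diag(cm)), rep(1, ncol(z)))
  }
  expect_error(consensus_cluster(z, k_range = 2:50), "k_range")
  zz <- rbind(z, flat = rep(1, ncol(z)))
  expect_warning(consensus_cluster(zz, k_range = 2:3, reps = 2, seed = 1),
                 "zero-variance")
})

test_that("the delta-area rule applies threshold arithmetic as stated", {
  s <- tibble::tibble(k = 2:5, auc = NA_real_,
                      delta_area = c(0.30, 0.20, 0.02, 0.01))
  expect_equal(select_k_delta_area(s, gain_threshold = 0.05), 3)
  # All gains above threshold: maximum k with a warning.
  s2 <- tibble::tibble(k = 2:5, auc = NA_real_,
                       delta_area = c(0.3, 0.2, 0.2, 0.2))
  expect_warning(k <- select_k_delta_area(s2, gain_threshold = 0.05), "plateau")
  expect_equal(k, 5)
  expect_error(select_k_delta_area(s[1:2, ]), "3 k values")
})

test_that("planted five-subtype panels select k = 5 with perfect recovery", {
  picks <- vapply(1:5, function(s) {
    z <- generate_marker_subtypes(seed = 500 + s)
    res <- consensus_cluster(z, k_range = 2:8, reps = 50, seed = 500 + s)
    k <- select_k_delta_area(res)
    ari <- mclust::adjustedRandIndex(res$labels[[as.character(k)]],
                                     attr(z, "labels"))
    c(k, ari)
  }, numeric(2))
  expect_true(all(picks[1, ] == 5))
  expect_true(all(picks[2, ] == 1))
})

test_that("Gower distances match hand-computed values", {
  rec <- data.frame(
    b1 = c(TRUE, FALSE), b2 = c(TRUE, TRUE), score = c(2, 7))
  # Contributions: b1 -> 1, b2 -> 0, numeric |2-7|/5 = 1 => (1 + 0 + 1)/3.
  D <- gower_distance(rec)
  expect_equal(D[1, 2], (1 + 0 + 1) / 3)
  # Worked 3-variable toy: two binaries (one equal), numeric differing by
  # 5 on a range of 10 -> (0 + 1 + 0.5)/3 = 0.5.
  rec2 <- data.frame(b1 = c(TRUE, TRUE, TRUE), b2 = c(TRUE, FALSE, TRUE),
                     num = c(0, 5, 10))
  D2 <- gower_distance(rec2)
  expect_equal(D2[1, 2], (0 + 1 + 0.5) / 3)
  # Identical records are at distance 0; all-different binaries at 1.
  expect_equal(D2[1, 1], 0)
  rec3 <- data.frame(b1 = c(TRUE, FALSE), b2 = c(FALSE, TRUE))
  expect_equal(gower_distance(rec3)[1, 2], 1)
  # NAs are excluded pairwise.
  rec4 <- data.frame(b1 = c(TRUE, NA), b2 = c(TRUE, FALSE), num = c(1, 3))
  D4 <- gower_distance(rec4)
  expect_equal(D4[1, 2], (1 + abs(1 - 3) / 2) / 2)
  rec5 <- data.frame(b1 = c(TRUE, NA), b2 = c(NA, FALSE))
  expect_error(gower_distance(rec5), "no non-missing")
})

test_that("Gower distances agree with the reference implementation", {
  set.seed(53)
  rec <- data.frame(
    c1 = sample(c(TRUE, FALSE), 20, replace = TRUE),
    c2 = sample(c(TRUE, FALSE, NA), 20, replace = TRUE),
    s = rnorm(20))
  D <- gower_distance(rec)
  rec_f <- rec
  rec_f$c1 <- factor(rec_f$c1); rec_f$c2 <- factor(rec_f$c2)
  ref <- as.matrix(cluster::daisy(rec_f, metric = "gower"))
  expect_equal(unname(D), unname(ref), tolerance = 1e-10)
})

brute_force_pam <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[med, , drop = FALSE], 2, min))
    if (cost < best - 1e-12) best <- cost
  }
  best
}

test_that("PAM reaches the exhaustive optimum on all small instances", {
  set.seed(54)
  for (trial in 1:12) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    D <- as.matrix(dist(pts))
    for (k in 2:min(4, n - 1)) {
      fit <- pam_cluster(D, k)
      expect_equal(fit$cost, brute_force_pam(D, k), tolerance = 1e-10)
    }
  }
})

test_that("PAM separates the line toy and handles k = n", {
  x <- c(0, 1, 10, 11)
  D <- as.matrix(dist(x))
  fit <- pam_cluster(D, 2)
  expect_equal(unname(fit$labels), c(1, 1, 2, 2))
  expect_equal(fit$cost, 2)
  fit_n <- pam_cluster(D, 4)
  expect_equal(fit_n$cost, 0)
  expect_equal(sort(fit_n$medoids), 1:4)
  expect_error(pam_cluster(D, 5), "exceed")
})

test_that("PAM cost matches the reference implementation on larger instances", {
  set.seed(55)
  pts <- matrix(rnorm(2 * 40), 40, 2)
  D <- as.matrix(dist(pts))
  for (k in 2:4) {
    fit <- pam_cluster(D, k)
    ref <- cluster::pam(as.dist(D), k = k)
    # Both are local optima of the same objective; ours must be at least
    # as good as or equal to the reference solution.
    ref_cost <- sum(apply(D[ref$id.med, , drop = FALSE], 2, min))
    expect_lte(fit$cost, ref_cost + 1e-8)
  }
})

test_that("silhouette widths match the direct formula and the reference", {
  # Hand-computable 4-point instance: pairs {0, 1} and {10, 11}.
  x <- c(0, 1, 10, 11)
  D <- as.matrix(dist(x))
  labels <- c(1, 1, 2, 2)
  s <- silhouette_widths(D, labels)
  # For point 1: a = 1, b = (10 + 11)/2 = 10.5, s = (10.5 - 1)/10.5.
  expect_equal(s[1], (10.5 - 1) / 10.5)
  ref <- cluster::silhouette(labels, as.dist(D))
  expect_equal(s, unname(ref[, "sil_width"]), tolerance = 1e-12)
  expect_warning(sel <- silhouette_select_k(D, k_range = 2:3), "singleton")
  expect_equal(sel$k, 2)
  expect_gt(max(sel$widths$avg_width), 0.85)
})

test_that("uniform random distances give near-zero silhouettes", {
  set.seed(56)
  n <- 40
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.5, 1)
  D <- D + t(D)
  sel <- silhouette_select_k(D, k_range = 2:4)
  expect_lt(max(abs(sel$widths$avg_width)), 0.15)
})

test_that("condition enrichment arithmetic and Fisher exactness hold", {
  labels <- rep(1:2, each = 100)
  cond <- data.frame(c1 = c(rep(TRUE, 10), rep(FALSE, 90),
                            rep(TRUE, 30), rep(FALSE, 70)))
  enr <- condition_enrichment(labels, cond)
  oe <- enr$oe
  expect_equal(oe$expected, c(20, 20))
  expect_equal(oe$oe_ratio, c(0.5, 1.5))
  # Size-weighted O/E averages to 1.
  expect_equal(sum(oe$oe_ratio * c(100, 100)) / 200, 1)
  # Fisher p equals the hypergeometric enumeration for [[10,0],[0,10]].
  labels2 <- rep(1:2, each = 10)
  cond2 <- data.frame(c1 = c(rep(TRUE, 10), rep(FALSE, 10)))
  enr2 <- condition_enrichment(labels2, cond2)
  p_exact <- 2 * choose(10, 10) * choose(10, 0) / choose(20, 10)
  expect_equal(enr2$tests$p, p_exact, tolerance = 1e-12)
  # Proportional split: O/E = 1 everywhere, p = 1.
  cond3 <- data.frame(c1 = rep(c(TRUE, FALSE), 100))
  enr3 <- condition_enrichment(rep(1:2, each = 100), cond3)
  expect_equal(enr3$oe$oe_ratio, c(1, 1))
  expect_equal(enr3$tests$p, 1)
  expect_error(condition_enrichment(labels, data.frame(c1 = rep(FALSE, 200))),
               "zero cases")
})

test_that("score comparisons use the exact Mann-Whitney distribution", {
  s <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                      ifn_score = c(1, 2, 3, 4, 5, 6))
  labels <- setNames(c(1, 1, 1, 2, 2, 2), s$sample_id)
  res <- compare_scores_across_groups(s, labels)
  # U = 0; exact two-sided p = 2 * (1 / choose(6, 3)) = 0.1.
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # Identical groups: p = 1.
  s2 <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                       ifn_score = rep(c(1, 2, 3), 2))
  res2 <- compare_scores_across_groups(s2, labels)
  expect_equal(res2$p, 1)
  # Case/control comparisons per condition with BH across conditions.
  cond <- data.frame(sample_id = s$sample_id,
                     cA = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     cB = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  res3 <- compare_scores_across_groups(s, cond)
  expect_equal(nrow(res3), 2)
  expect_equal(res3$q, p.adjust(res3$p, "BH"))
})

test_that("power of the score comparison increases with the group shift", {
  set.seed(57)
  power_at <- function(shift) {
    mean(vapply(1:40, function(i) {
      x <- rnorm(15); y <- rnorm(15) + shift
      s <- tibble::tibble(sample_id = sprintf("s%d", 1:30),
                          ifn_score = c(x, y))
      labels <- setNames(rep(1:2, each = 15), s$sample_id)
      compare_scores_across_groups(s, labels)$p < 0.05
    }, logical(1)))
  }
  p <- vapply(c(0, 1, 2), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_lt(p[1], 0.2)
  expect_gt(p[3], 0.9)
})

test_that("clinical stratification separates high- and low-activity samples", {
  coh <- generate_cohort(small_config(
    seed = 58, n_t21 = 150L, n_control = 50L,
    condition_baseline = qlogis(0.3)))
  de <- differential_expression(coh$expression, coh$metadata)
  sig <- select_isg_signature(de, coh$gene_info)
  sc <- score_cohort(coh$expression, coh$metadata, sig)
  t21 <- coh$metadata$karyotype == "T21"
  strat <- stratify_clinical(sc$scores[t21, ],
                             coh$metadata[t21, ], k_range = 2:4)
  expect_s3_class(strat, "clinical_strata")
  expect_true(all(strat$labels %in% seq_len(strat$k)))
  expect_equal(tidy(strat$enrichment)$condition %in%
                 names(coh$truth$condition_enrichment),
               rep(TRUE, nrow(tidy(strat$enrichment))))
})
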