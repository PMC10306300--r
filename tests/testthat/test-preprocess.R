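# Platform QC: outlier fences, fit-range resolution, metabolite
# normalization and covariate adjustment.

test_that("outlier fences flag exactly the fence-violating points", {
  meta <- toy_metadata(5, n_t21 = 5)
  x <- matrix(c(1, 2, 3, 4, 100), nrow = 1,
              dimnames = list("a1", meta$sample_id))
  m <- exclude_extreme_outliers(x, meta)
  # Q1 = 2, Q3 = 4, IQR = 2, fences [-4, 10]: only 100 is out.
  expect_identical(unname(m$mask[1, ]), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(m$stats$q1, 2)
  expect_equal(m$stats$q3, 4)
  expect_equal(m$stats$upper, 10)
  # Mirror symmetry of the rule.
  xm <- matrix(c(-100, -4, -3, -2, -1), nrow = 1,
               dimnames = list("a1", meta$sample_id))
  mm <- exclude_extreme_outliers(xm, meta)
  expect_identical(unname(mm$mask[1, ]), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # Constant vector: fences collapse onto the constant, nothing excluded.
  xc <- matrix(rep(7, 5), nrow = 1, dimnames = list("a1", meta$sample_id))
  expect_false(any(exclude_extreme_outliers(xc, meta)$mask))
})

test_that("outlier masking is stratified by karyotype and respects [Q1, Q3]", {
  set.seed(42)
  meta <- toy_metadata(60, n_t21 = 30)
  x <- matrix(rnorm(5 * 60), 5, 60,
              dimnames = list(sprintf("a%d", 1:5), meta$sample_id))
  x[1, 1] <- 50    # extreme in the T21 stratum only
  m <- exclude_extreme_outliers(x, meta)
  expect_true(m$mask[1, 1])
  # No value inside its stratum's [Q1, Q3] is ever flagged.
  for (g in c("T21", "control")) {
    cols <- meta$karyotype == g
    for (a in 1:5) {
      q <- quantile(x[a, cols], c(0.25, 0.75))
      inside <- cols & x[a, ] >= q[1] & x[a, ] <= q[2]
      expect_false(any(m$mask[a, inside]))
    }
  }
  masked <- apply_outlier_mask(x, m)
  expect_true(is.na(masked[1, 1]))
  expect_identical(masked[!m$mask], x[!m$mask])
})

test_that("small strata are skipped with a warning", {
  meta <- toy_metadata(5, n_t21 = 2)   # control stratum has 3 samples
  x <- matrix(rnorm(5), 1, 5, dimnames = list("a1", meta$sample_id))
  expect_warning(m <- exclude_extreme_outliers(x, meta), "4 non-missing")
})

make_well_panel <- function(values, flags, samples, plates) {
  analyte_panel(values, platform = "immunoassay", sample_id = samples,
                plate = plates, flags = flags)
}

test_that("out-of-range values are replaced per plate and duplicates averaged", {
  # One analyte, one plate, three samples in duplicate.
  vals <- matrix(c(2, 4, 0.9, 0.7, NA, 1.5), nrow = 1,
                 dimnames = list("cyt", sprintf("w%d", 1:6)))
  flags <- matrix(c("in_range", "in_range", "in_range", "in_range",
                    "below_range", "in_range"), nrow = 1,
                  dimnames = dimnames(vals))
  panel <- make_well_panel(vals, flags, rep(c("s1", "s2", "s3"), each = 2),
                           rep("plate_1", 6))
  out <- resolve_out_of_range(panel)
  # Duplicate wells (2, 4) average to 3.
  expect_equal(out$values["cyt", "s1"], 3)
  expect_equal(out$values["cyt", "s2"], 0.8)
  # Below-range replaced by the plate's in-range minimum 0.7, then averaged.
  expect_equal(out$values["cyt", "s3"], (0.7 + 1.5) / 2)
  # In-range values untouched bit for bit.
  expect_identical(out$values["cyt", "s2"], (0.9 + 0.7) / 2)
  # 1/6 wells out of range: below the 10% threshold? 16.7% -> flagged.
  expect_identical(out$flagged_analytes, "cyt")
})

test_that("the >10% out-of-range flag rule uses the stated threshold", {
  n <- 20
  vals <- matrix(runif(n, 1, 2), nrow = 1,
                 dimnames = list("cyt", sprintf("w%d", 1:n)))
  flags <- matrix("in_range", 1, n, dimnames = dimnames(vals))
  flags[1, 1:3] <- "below_range"   # 3/20 = 15% > 10%
  vals[1, 1:3] <- NA
  panel <- make_well_panel(vals, flags, sprintf("s%d", 1:n), rep("plate_1", n))
  expect_identical(resolve_out_of_range(panel)$flagged_analytes, "cyt")
  flags[1, 1:3] <- "in_range"; flags[1, 1:2] <- "below_range"  # 10% exactly
  vals[1, 1:2] <- NA; vals[1, 3] <- 1.5
  panel <- make_well_panel(vals, flags, sprintf("s%d", 1:n), rep("plate_1", n))
  expect_length(resolve_out_of_range(panel)$flagged_analytes, 0L)
})

test_that("a plate with every well out of range stays missing with a warning", {
  vals <- matrix(NA_real_, 1, 4, dimnames = list("cyt", sprintf("w%d", 1:4)))
  flags <- matrix("below_range", 1, 4, dimnames = dimnames(vals))
  panel <- make_well_panel(vals, flags, c("s1", "s1", "s2", "s2"),
                           rep("plate_1", 4))
  expect_warning(out <- resolve_out_of_range(panel), "all wells out of range")
  expect_true(all(is.na(out$values)))
})

test_that("metabolite normalization equalizes sample medians and replaces zeros", {
  set.seed(7)
  x <- matrix(2^runif(200, 5, 10), 10, 20,
              dimnames = list(sprintf("m%d", 1:10), sprintf("s%d", 1:20)))
  x[1, 1] <- 0
  x[3, c(2, 5)] <- 0
  norm <- normalize_metabolites(x, seed = 3)
  expect_true(all(norm > 0))
  # Every sample median equals the global median of the zero-replaced matrix.
  set.seed(3)
  raw <- x
  for (a in seq_len(nrow(raw))) {
    z <- which(raw[a, ] == 0)
    if (length(z)) raw[a, z] <- runif(length(z), 0, 0.5 * min(raw[a, raw[a, ] > 0]))
  }
  g <- median(raw)
  expect_equal(unname(apply(norm, 2, median)), rep(g, 20), tolerance = 1e-12)
  # Zero replacement draws from (0, 0.5 * min nonzero of the metabolite).
  expect_gt(raw[1, 1], 0)
  expect_lt(raw[1, 1], 0.5 * min(x[1, x[1, ] > 0]))
})

test_that("zero-replacement bounds follow the per-metabolite minimum", {
  x <- matrix(c(0, 4, 8), 1, 3, dimnames = list("m1", c("s1", "s2", "s3")))
  reps <- vapply(1:50, function(s) {
    set.seed(s)
    z <- which(x[1, ] == 0)
    u <- runif(length(z), 0, 0.5 * min(x[1, x[1, ] > 0]))
    u
  }, numeric(1))
  expect_true(all(reps > 0 & reps < 2))
})

test_that("normalization is idempotent on a zero-free matrix and exact on equal medians", {
  set.seed(9)
  x <- matrix(2^runif(60, 4, 8), 6, 10,
              dimnames = list(sprintf("m%d", 1:6), sprintf("s%d", 1:10)))
  n1 <- normalize_metabolites(x, seed = 1)
  n2 <- normalize_metabolites(n1, seed = 2)
  expect_equal(n1, n2, tolerance = 1e-12)
  # All-equal sample medians: returned unchanged.
  xe <- sweep(x, 2, apply(x, 2, median), "/")
  expect_equal(normalize_metabolites(xe, seed = 1), xe, tolerance = 1e-12)
})

test_that("all-zero metabolites are left missing with a warning", {
  x <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("s1", "s2", "s3")))
  expect_warning(out <- normalize_metabolites(x, seed = 1), "no nonzero")
  expect_true(all(is.na(out["m1", ])))
  expect_true(all(out["m2", ] > 0))
})

test_that("covariate adjustment removes nuisance effects and keeps protected ones", {
  set.seed(11)
  n <- 600
  meta <- toy_metadata(n, n_t21 = 300)
  base <- matrix(rnorm(20 * n, 5, 0.3), 20, n,
                 dimnames = list(sprintf("f%d", 1:20), meta$sample_id))
  delta_sex <- 2
  delta_kar <- 3
  x <- base +
    delta_sex * matrix(as.numeric(meta$sex == "M"), 20, n, byrow = TRUE) +
    delta_kar * matrix(as.numeric(meta$karyotype == "T21"), 20, n, byrow = TRUE)
  adj <- adjust_covariates(x, meta, nuisance = c("age", "sex", "source"),
                           protect = "karyotype")
  sex_gap <- rowMeans(adj[, meta$sex == "M"]) - rowMeans(adj[, meta$sex == "F"])
  kar_gap <- rowMeans(adj[, meta$karyotype == "T21"]) -
    rowMeans(adj[, meta$karyotype == "control"])
  expect_lt(max(abs(sex_gap)), 0.05 * delta_sex)
  expect_gt(min(kar_gap), 0.95 * delta_kar)
  # Idempotence.
  adj2 <- adjust_covariates(adj, meta)
  expect_equal(adj2, adj, tolerance = 1e-10)
})

test_that("adjustment leaves covariate-free data essentially unchanged", {
  set.seed(12)
  n <- 2000
  meta <- toy_metadata(n, n_t21 = 1000)
  x <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("f%d", 1:5), meta$sample_id))
  adj <- adjust_covariates(x, meta)
  expect_equal(mean(abs(adj - x)), 0, tolerance = 0.1)
  expect_equal(unname(rowMeans(adj)), unname(rowMeans(x)), tolerance = 1e-8)
})

test_that("adjustment matches an independent batch-removal implementation", {
  set.seed(13)
  n <- 120
  meta <- toy_metadata(n, n_t21 = 60)
  x <- matrix(rnorm(8 * n, 6, 1), 8, n,
              dimnames = list(sprintf("f%d", 1:8), meta$sample_id)) +
    1.5 * matrix(as.numeric(meta$sex == "M"), 8, n, byrow = TRUE)
  adj <- adjust_covariates(x, meta, nuisance = "sex", protect = "karyotype")
  ref <- limma::removeBatchEffect(
    x, batch = meta$sex,
    design = model.matrix(~ karyotype, data = meta))
  # Both remove the sex effect; they may differ by a per-feature constant.
  d <- adj - ref
  expect_lt(max(apply(d, 1, sd)), 1e-8)
})

test_that("rank-deficient designs fail loudly, naming the collinear columns", {
  meta <- toy_metadata(30)
  meta$dup <- meta$age
  x <- matrix(rnorm(60), 2, 30,
              dimnames = list(c("f1", "f2"), meta$sample_id))
  expect_error(adjust_covariates(x, meta, nuisance = c("age", "dup")),
               "collinear.*dup|dup.*collinear")
  meta2 <- meta
  meta2$age[1] <- NA
  expect_error(adjust_covariates(x, meta2, nuisance = "age"), "missing covariate")
})
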