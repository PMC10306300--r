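# Shared fixtures: small cohort configurations used across test files.

small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_t21 = 60L, n_control = 40L,
    n_genes = 300L, n_chr21_genes = 30L,
    n_isg_true = 10L, n_isg_weak = 30L, n_isg_chr21 = 2L,
    n_proteins = 30L, n_cytokines = 12L, n_metabolites = 20L,
    n_cell_clusters = 8L, n_conditions = 6L,
    seed = seed
  ), list(...))
  do.call(cohort_config, args)
}

# The signature-recovery study conditions: 300 T21 / 100 control, 2000
# genes, 18 planted ISGs at strong latent-driven elevation.
recovery_config <- function(seed = 1L, ...) {
  cohort_config(seed = seed, ...)
}

# Metadata table for ad-hoc matrices.
toy_metadata <- function(n, n_t21 = floor(n / 2), seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    karyotype = factor(rep(c("T21", "control"), c(n_t21, n - n_t21)),
                       levels = c("control", "T21")),
    age = runif(n, 10, 60),
    sex = factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M")),
    source = factor(sample(c("site_A", "site_B"), n, replace = TRUE),
                    levels = c("site_A", "site_B"))
  )
}
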