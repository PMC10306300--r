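#' Configuration for the synthetic multi-omics cohort generator
#'
#' Bundles every knob of the simulated cross-sectional cohort: sample sizes,
#' gene-panel layout, the latent interferon (IFN) activity model, per-layer
#' effect sizes and noise levels, and the master seed. Defaults describe a
#' T21-vs-euploid cohort in which chr21 genes carry a ~1.5x dosage effect,
#' a core set of 18 interferon-stimulated genes (ISGs) is strongly induced
#' in proportion to latent IFN activity, a broader ISG universe is weakly
#' induced, and downstream analyte / cell-composition / condition layers
#' load on the same latent axis.
#'
#' Effect maps (`analyte_effects`, `cytokine_effects`, `metabolite_effects`,
#' `cell_cluster_effects`, `condition_enrichment`) are named numeric vectors
#' of per-feature slopes on latent activity (log2 scale for abundances,
#' logit scale for cell frequencies and condition odds). Names must match
#' generated feature names; unknown names are an error at generation time.
#'
#' @param n_t21,n_control Number of T21 and euploid control samples.
#' @param n_genes Total genes in the expression matrix.
#' @param n_chr21_genes Genes assigned to chr21 (triplicated in T21).
#' @param n_isg_true Strongly induced non-chr21 ISGs (the planted signature).
#' @param n_isg_weak Weakly induced non-chr21 ISGs (completes the ISG
#'   universe; with the defaults, 18 + 120 = 138 non-chr21 ISGs).
#' @param n_isg_chr21 Strongly induced chr21 ISGs (IFNAR2/MX1/MX2 analogues,
#'   present to exercise the chr21 exclusion rule).
#' @param dosage_fold Multiplicative chr21 gene-dosage effect in T21.
#' @param isg_effect,isg_weak_effect log2-expression slope per unit latent
#'   activity for strong and weak ISGs.
#' @param t21_shift Mean latent-activity elevation in T21 (control mean 0).
#' @param latent_sd Within-karyotype SD of latent activity.
#' @param expr_noise_sd Residual log2-expression SD.
#' @param expr_age_sd,expr_sex_sd SDs of per-gene age slopes (per year) and
#'   sex offsets on log2 expression.
#' @param n_proteins,protein_noise_sd,analyte_effects Proteomics layer:
#'   panel size, residual log2 SD, named slope map (default: 12 proteins at
#'   slope 0.4).
#' @param n_cytokines,cytokine_noise_sd,cytokine_effects Immunoassay layer
#'   (default effects: 6 cytokines at slope 0.4).
#' @param n_plates,duplicate_sd,oor_frac,n_oor_heavy,oor_frac_heavy
#'   Immunoassay plate structure: number of plates, log2 SD between
#'   duplicate wells, fraction of wells outside the fit-curve range for a
#'   typical analyte, and the number/fraction for deliberately flag-heavy
#'   analytes (exercising the 10 percent flag rule).
#' @param n_metabolites,metabolite_noise_sd,metabolite_effects,zero_frac
#'   Metabolomics layer. The panel always contains `kynurenine` and
#'   `tryptophan` (default slopes +0.3 and -0.2, so the kyn/trp ratio rises
#'   with IFN activity); `zero_frac` is the fraction of intensities reported
#'   as zero (exercising zero replacement).
#' @param n_cell_clusters,cell_noise_sd,cell_cluster_effects Immune-cell
#'   composition layer: cluster count, logit noise SD, named logit slopes
#'   (default: two clusters at +0.3, two at -0.3).
#' @param n_conditions,condition_baseline,condition_enrichment Clinical
#'   condition flags: number of conditions, baseline log-odds, named
#'   log-odds slopes on latent activity (default: half the conditions at
#'   slope 0.8, the rest 0).
#' @param age_range,sex_prob,source_probs Covariate distributions: uniform
#'   age range in years, probability of female sex, named sampling-site
#'   probabilities.
#' @param seed Master seed; all layers draw from sub-streams derived from it.
#'
#' @return A `cohort_config` list, validated.
#' @seealso [generate_cohort()], [generate_longitudinal_subject()]
#' @export
cohort_config <- function(n_t21 = 300L, n_control = 100L,
                          n_genes = 2000L, n_chr21_genes = 100L,
                          n_isg_true = 18L, n_isg_weak = 120L, n_isg_chr21 = 3L,
                          dosage_fold = 1.5,
                          isg_effect = 0.9, isg_weak_effect = 0.25,
                          t21_shift = 1, latent_sd = 1,
                          expr_noise_sd = 0.5,
                          expr_age_sd = 0.002, expr_sex_sd = 0.05,
                          n_proteins = 80L, protein_noise_sd = 0.4,
                          analyte_effects = NULL,
                          n_cytokines = 30L, cytokine_noise_sd = 0.4,
                          cytokine_effects = NULL,
                          n_plates = 4L, duplicate_sd = 0.1,
                          oor_frac = 0.04, n_oor_heavy = 2L, oor_frac_heavy = 0.25,
                          n_metabolites = 60L, metabolite_noise_sd = 0.4,
                          metabolite_effects = NULL, zero_frac = 0.05,
                          n_cell_clusters = 15L, cell_noise_sd = 0.3,
                          cell_cluster_effects = NULL,
                          n_conditions = 8L, condition_baseline = stats::qlogis(0.3),
                          condition_enrichment = NULL,
                          age_range = c(6, 60), sex_prob = 0.5,
                          source_probs = c(site_A = 0.7, site_B = 0.3),
                          seed = 1L) {
  cfg <- list(
    n_t21 = .assert_count(n_t21, "n_t21"),
    n_control = .assert_count(n_control, "n_control"),
    n_genes = .assert_count(n_genes, "n_genes", min = 1L),
    n_chr21_genes = .assert_count(n_chr21_genes, "n_chr21_genes"),
    n_isg_true = .assert_count(n_isg_true, "n_isg_true"),
    n_isg_weak = .assert_count(n_isg_weak, "n_isg_weak"),
    n_isg_chr21 = .assert_count(n_isg_chr21, "n_isg_chr21"),
    dosage_fold = .assert_scalar_number(dosage_fold, "dosage_fold", lower = 1e-12),
    isg_effect = .assert_scalar_number(isg_effect, "isg_effect", lower = 0),
    isg_weak_effect = .assert_scalar_number(isg_weak_effect, "isg_weak_effect", lower = 0),
    t21_shift = .assert_scalar_number(t21_shift, "t21_shift"),
    latent_sd = .assert_scalar_number(latent_sd, "latent_sd", lower = 0),
    expr_noise_sd = .assert_scalar_number(expr_noise_sd, "expr_noise_sd", lower = 0),
    expr_age_sd = .assert_scalar_number(expr_age_sd, "expr_age_sd", lower = 0),
    expr_sex_sd = .assert_scalar_number(expr_sex_sd, "expr_sex_sd", lower = 0),
    n_proteins = .assert_count(n_proteins, "n_proteins"),
    protein_noise_sd = .assert_scalar_number(protein_noise_sd, "protein_noise_sd", lower = 0),
    analyte_effects = analyte_effects,
    n_cytokines = .assert_count(n_cytokines, "n_cytokines"),
    cytokine_noise_sd = .assert_scalar_number(cytokine_noise_sd, "cytokine_noise_sd", lower = 0),
    cytokine_effects = cytokine_effects,
    n_plates = .assert_count(n_plates, "n_plates", min = 1L),
    duplicate_sd = .assert_scalar_number(duplicate_sd, "duplicate_sd", lower = 0),
    oor_frac = .assert_scalar_number(oor_frac, "oor_frac", lower = 0, upper = 0.9),
    n_oor_heavy = .assert_count(n_oor_heavy, "n_oor_heavy"),
    oor_frac_heavy = .assert_scalar_number(oor_frac_heavy, "oor_frac_heavy", lower = 0, upper = 0.9),
    n_metabolites = .assert_count(n_metabolites, "n_metabolites", min = 2L),
    metabolite_noise_sd = .assert_scalar_number(metabolite_noise_sd, "metabolite_noise_sd", lower = 0),
    metabolite_effects = metabolite_effects,
    zero_frac = .assert_scalar_number(zero_frac, "zero_frac", lower = 0, upper = 0.5),
    n_cell_clusters = .assert_count(n_cell_clusters, "n_cell_clusters", min = 2L),
    cell_noise_sd = .assert_scalar_number(cell_noise_sd, "cell_noise_sd", lower = 0),
    cell_cluster_effects = cell_cluster_effects,
    n_conditions = .assert_count(n_conditions, "n_conditions"),
    condition_baseline = .assert_scalar_number(condition_baseline, "condition_baseline"),
    condition_enrichment = condition_enrichment,
    age_range = age_range,
    sex_prob = .assert_scalar_number(sex_prob, "sex_prob", lower = 0, upper = 1),
    source_probs = source_probs,
    seed = .assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_chr21_genes > cfg$n_genes) {
    abort("n_chr21_genes cannot exceed n_genes")
  }
  if (cfg$n_isg_true + cfg$n_isg_weak > cfg$n_genes - cfg$n_chr21_genes) {
    abort("n_isg_true + n_isg_weak cannot exceed the number of non-chr21 genes")
  }
  if (cfg$n_isg_chr21 > cfg$n_chr21_genes) {
    abort("n_isg_chr21 cannot exceed n_chr21_genes")
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2]) {
    abort("age_range must be an increasing pair of ages")
  }
  if (is.null(names(cfg$source_probs)) || any(cfg$source_probs < 0)) {
    abort("source_probs must be a named nonnegative vector")
  }
  if (cfg$n_oor_heavy > cfg$n_cytokines) abort("n_oor_heavy cannot exceed n_cytokines")
  # Fill default effect maps (done here so names validate against sizes).
  feat <- .feature_names(cfg)
  if (is.null(cfg$analyte_effects)) {
    cfg$analyte_effects <- setNames(
      rep(0.4, min(12L, cfg$n_proteins)), head(feat$proteins, 12L))
  }
  if (is.null(cfg$cytokine_effects)) {
    cfg$cytokine_effects <- setNames(
      rep(0.4, min(6L, cfg$n_cytokines)), head(feat$cytokines, 6L))
  }
  if (is.null(cfg$metabolite_effects)) {
    cfg$metabolite_effects <- c(kynurenine = 0.3, tryptophan = -0.2)
  }
  if (is.null(cfg$cell_cluster_effects)) {
    k <- min(4L, cfg$n_cell_clusters)
    cfg$cell_cluster_effects <- setNames(
      rep(c(0.3, -0.3), length.out = k), head(feat$cell_clusters, k))
  }
  if (is.null(cfg$condition_enrichment)) {
    n_inf <- ceiling(cfg$n_conditions / 2)
    cfg$condition_enrichment <- setNames(
      c(rep(0.8, n_inf), rep(0, cfg$n_conditions - n_inf)), feat$conditions)
  }
  for (m in c("analyte_effects", "cytokine_effects", "metabolite_effects",
              "cell_cluster_effects", "condition_enrichment")) {
    v <- cfg[[m]]
    if (length(v) && (is.null(names(v)) || !is.numeric(v))) {
      abort(sprintf("`%s` must be a named numeric vector", m))
    }
  }
  structure(cfg, class = "cohort_config")
}

# Canonical feature names for each layer, derived from panel sizes only.
.feature_names <- function(cfg) {
  mets <- c("kynurenine", "tryptophan")
  if (cfg$n_metabolites > 2L) {
    mets <- c(mets, sprintf("met_%03d", 3:cfg$n_metabolites))
  }
  list(
    genes = sprintf("g%04d", seq_len(cfg$n_genes)),
    proteins = sprintf("prot_%03d", seq_len(cfg$n_proteins)),
    cytokines = sprintf("cyt_%02d", seq_len(cfg$n_cytokines)),
    metabolites = mets,
    cell_clusters = sprintf("cl_%02d", seq_len(cfg$n_cell_clusters)),
    conditions = sprintf("cond_%d", seq_len(cfg$n_conditions))
  )
}

# Seed sub-streams: one generator state per layer so adding features to one
# layer never perturbs another.
.substream <- function(seed, k) {
  set.seed((seed * 131L + k) %% .Machine$integer.max)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d T21 / %d control; %d genes (%d chr21, ISGs: %d strong + %d weak + %d chr21)\n",
    x$n_t21, x$n_control, x$n_genes, x$n_chr21_genes,
    x$n_isg_true, x$n_isg_weak, x$n_isg_chr21))
  cat(sprintf("  dosage_fold %.3g, isg_effect %.3g, t21_shift %.3g, latent_sd %.3g, seed %d\n",
              x$dosage_fold, x$isg_effect, x$t21_shift, x$latent_sd, x$seed))
  invisible(x)
}
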