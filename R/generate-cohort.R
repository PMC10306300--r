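# Synthetic cohort generation. Expression is generated on the log2 scale
# (Gaussian noise) and exponentiated to RPKM-like values, so configured
# effects are multiplicative fold changes on the linear scale. Latent IFN
# activity is Normal(mu_karyotype, latent_sd) with mu_T21 > mu_control.

# Gene-level model parameters, drawn from their own sub-stream so that
# generate_cohort() and generate_longitudinal_subject() with the same
# config share an identical gene panel.
.gene_model <- function(cfg) {
  feat <- .feature_names(cfg)
  genes <- feat$genes
  .substream(cfg$seed, 1L)
  chr <- rep("other", cfg$n_genes)
  chr[seq_len(cfg$n_chr21_genes)] <- "chr21"
  non21 <- which(chr != "chr21")
  strong <- sort(sample(non21, cfg$n_isg_true))
  weak <- sort(sample(setdiff(non21, strong), cfg$n_isg_weak))
  isg21 <- head(which(chr == "chr21"), cfg$n_isg_chr21)
  isg_effect <- numeric(cfg$n_genes)
  isg_effect[strong] <- cfg$isg_effect
  isg_effect[weak] <- cfg$isg_weak_effect
  isg_effect[isg21] <- cfg$isg_effect
  list(
    genes = genes,
    chr = chr,
    is_isg = seq_len(cfg$n_genes) %in% c(strong, weak, isg21),
    isg_effect = isg_effect,
    planted = genes[strong],
    weak = genes[weak],
    chr21_isgs = genes[isg21],
    baseline = runif(cfg$n_genes, 2, 8),
    age_slope = rnorm(cfg$n_genes, 0, cfg$expr_age_sd),
    sex_effect = rnorm(cfg$n_genes, 0, cfg$expr_sex_sd)
  )
}

# Log2 expression for a set of samples given latent activity and covariates.
.expression_log2 <- function(cfg, gm, latent, is_t21, age, sex_f) {
  n <- length(latent)
  mu <- matrix(gm$baseline, nrow = cfg$n_genes, ncol = n)
  mu <- mu + log2(cfg$dosage_fold) * (gm$chr == "chr21") %o% as.numeric(is_t21)
  mu <- mu + gm$isg_effect %o% latent
  mu <- mu + gm$age_slope %o% (age - mean(cfg$age_range))
  mu <- mu + gm$sex_effect %o% (as.numeric(sex_f) - 0.5)
  mu + matrix(rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd), cfg$n_genes, n)
}

.check_effect_names <- function(map, universe, what) {
  bad <- setdiff(names(map), universe)
  if (length(bad)) {
    abort(sprintf("%s names unknown features: %s", what,
                  paste(head(bad, 5), collapse = ", ")))
  }
}

.effect_vector <- function(map, universe) {
  out <- setNames(numeric(length(universe)), universe)
  out[names(map)] <- map
  out
}

#' Generate a synthetic cross-sectional multi-omics cohort
#'
#' Simulates every input layer of the IFN-score analysis with a shared
#' latent per-individual IFN-activity variable: a gene-by-sample RPKM-like
#' expression matrix with chr21 dosage and planted ISG induction, a plasma
#' proteomics panel, an immunoassay cytokine panel with plates, duplicate
#' wells and fit-range flags, a metabolite panel with reported zeros, a
#' compositional immune-cell frequency table (softmax of Gaussian logits,
#' so per-cluster logit slopes are exact), and per-sample metadata with
#' clinical condition flags whose log-odds load on latent activity.
#'
#' The latent activity is returned under `$truth` for truth-recovery tests
#' only; no analysis stage consumes it.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ifn_cohort`: a list with elements
#'   `expression` (gene x sample matrix), `gene_info` (tibble: gene, chr,
#'   is_isg), `proteomics`, `immunoassay`, `metabolites` ([analyte_panel()]
#'   objects), `cells` (cluster x sample frequency matrix, columns sum to
#'   1), `metadata` (tibble with karyotype, age, sex, source and logical
#'   condition columns), and `truth` (latent state and planted features).
#' @examples
#' coh <- generate_cohort(cohort_config(n_t21 = 30, n_control = 20,
#'   n_genes = 200, n_chr21_genes = 20, n_isg_weak = 30, seed = 7))
#' coh
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config else do.call(cohort_config, config)
  if (cfg$n_t21 < 1L || cfg$n_control < 1L) {
    abort("both karyotype groups need at least one sample")
  }
  feat <- .feature_names(cfg)
  .check_effect_names(cfg$analyte_effects, feat$proteins, "analyte_effects")
  .check_effect_names(cfg$cytokine_effects, feat$cytokines, "cytokine_effects")
  .check_effect_names(cfg$metabolite_effects, feat$metabolites, "metabolite_effects")
  .check_effect_names(cfg$cell_cluster_effects, feat$cell_clusters, "cell_cluster_effects")
  .check_effect_names(cfg$condition_enrichment, feat$conditions, "condition_enrichment")

  gm <- .gene_model(cfg)
  n <- cfg$n_t21 + cfg$n_control
  sample_id <- sprintf("S%04d", seq_len(n))
  karyotype <- factor(rep(c("T21", "control"), c(cfg$n_t21, cfg$n_control)),
                      levels = c("control", "T21"))

  # Covariates and latent IFN activity.
  .substream(cfg$seed, 2L)
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- factor(ifelse(runif(n) < cfg$sex_prob, "F", "M"), levels = c("F", "M"))
  source <- factor(sample(names(cfg$source_probs), n, replace = TRUE,
                          prob = cfg$source_probs),
                   levels = names(cfg$source_probs))
  latent <- rnorm(n, mean = ifelse(karyotype == "T21", cfg$t21_shift, 0),
                  sd = cfg$latent_sd)

  # Expression layer.
  .substream(cfg$seed, 3L)
  expr <- 2^.expression_log2(cfg, gm, latent, karyotype == "T21", age, sex == "M")
  dimnames(expr) <- list(gm$genes, sample_id)

  # Proteomics layer (relative fluorescence-like positive values).
  .substream(cfg$seed, 4L)
  p_eff <- .effect_vector(cfg$analyte_effects, feat$proteins)
  prot <- 2^(matrix(runif(cfg$n_proteins, 4, 10), cfg$n_proteins, n) +
             p_eff %o% latent +
             matrix(rnorm(cfg$n_proteins * n, 0, cfg$protein_noise_sd),
                    cfg$n_proteins, n))
  dimnames(prot) <- list(feat$proteins, sample_id)
  proteomics <- analyte_panel(prot, platform = "proteomics")

  # Immunoassay layer: duplicate wells on plates, with fit-range flags.
  .substream(cfg$seed, 5L)
  c_eff <- .effect_vector(cfg$cytokine_effects, feat$cytokines)
  conc <- matrix(runif(cfg$n_cytokines, 1, 8), cfg$n_cytokines, n) +
    c_eff %o% latent +
    matrix(rnorm(cfg$n_cytokines * n, 0, cfg$cytokine_noise_sd),
           cfg$n_cytokines, n)
  plate_of_sample <- sprintf("plate_%d", ((seq_len(n) - 1L) %% cfg$n_plates) + 1L)
  wells <- 2^(conc[, rep(seq_len(n), each = 2L), drop = FALSE] +
              matrix(rnorm(cfg$n_cytokines * 2L * n, 0, cfg$duplicate_sd),
                     cfg$n_cytokines, 2L * n))
  well_sample <- rep(sample_id, each = 2L)
  well_plate <- rep(plate_of_sample, each = 2L)
  colnames(wells) <- sprintf("%s_w%d", well_sample, rep(1:2, n))
  rownames(wells) <- feat$cytokines
  frac <- rep(cfg$oor_frac, cfg$n_cytokines)
  frac[seq_len(cfg$n_oor_heavy)] <- cfg$oor_frac_heavy
  flags <- matrix("in_range", cfg$n_cytokines, 2L * n,
                  dimnames = dimnames(wells))
  for (i in seq_len(cfg$n_cytokines)) {
    if (frac[i] <= 0) next
    lo <- quantile(wells[i, ], frac[i] / 2, type = 7)
    hi <- quantile(wells[i, ], 1 - frac[i] / 2, type = 7)
    flags[i, wells[i, ] < lo] <- "below_range"
    flags[i, wells[i, ] > hi] <- "above_range"
  }
  wells[flags != "in_range"] <- NA_real_
  immunoassay <- analyte_panel(wells, platform = "immunoassay",
                               sample_id = well_sample, plate = well_plate,
                               flags = flags)

  # Metabolomics layer with reported zeros.
  .substream(cfg$seed, 6L)
  m_eff <- .effect_vector(cfg$metabolite_effects, feat$metabolites)
  mets <- 2^(matrix(runif(cfg$n_metabolites, 10, 20), cfg$n_metabolites, n) +
             m_eff %o% latent +
             matrix(rnorm(cfg$n_metabolites * n, 0, cfg$metabolite_noise_sd),
                    cfg$n_metabolites, n))
  mets[matrix(runif(length(mets)) < cfg$zero_frac, nrow(mets))] <- 0
  dimnames(mets) <- list(feat$metabolites, sample_id)
  metabolites <- analyte_panel(mets, platform = "metabolomics")

  # Immune-cell composition: softmax of Gaussian logits.
  .substream(cfg$seed, 7L)
  cl_eff <- .effect_vector(cfg$cell_cluster_effects, feat$cell_clusters)
  logits <- matrix(rnorm(cfg$n_cell_clusters, 0, 1), cfg$n_cell_clusters, n) +
    cl_eff %o% latent +
    matrix(rnorm(cfg$n_cell_clusters * n, 0, cfg$cell_noise_sd),
           cfg$n_cell_clusters, n)
  cells <- apply(logits, 2, function(l) { e <- exp(l - max(l)); e / sum(e) })
  dimnames(cells) <- list(feat$cell_clusters, sample_id)

  # Clinical condition flags: Bernoulli with logit linear in latent activity.
  .substream(cfg$seed, 8L)
  cond_eff <- .effect_vector(cfg$condition_enrichment, feat$conditions)
  conditions <- vapply(feat$conditions, function(cn) {
    runif(n) < plogis(cfg$condition_baseline + cond_eff[cn] * latent)
  }, logical(n))

  metadata <- tibble(
    sample_id = sample_id, karyotype = karyotype,
    age = age, sex = sex, source = source
  )
  metadata <- dplyr::bind_cols(metadata, as_tibble(conditions))

  structure(list(
    expression = expr,
    gene_info = tibble(gene = gm$genes, chr = gm$chr, is_isg = gm$is_isg),
    proteomics = proteomics,
    immunoassay = immunoassay,
    metabolites = metabolites,
    cells = cells,
    metadata = metadata,
    truth = list(
      latent = tibble(sample_id = sample_id, latent = latent),
      planted_isgs = gm$planted,
      weak_isgs = gm$weak,
      chr21_isgs = gm$chr21_isgs,
      analyte_effects = cfg$analyte_effects,
      cytokine_effects = cfg$cytokine_effects,
      metabolite_effects = cfg$metabolite_effects,
      cell_cluster_effects = cfg$cell_cluster_effects,
      condition_enrichment = cfg$condition_enrichment,
      config = cfg
    )
  ), class = "ifn_cohort")
}

#' @export
print.ifn_cohort <- function(x, ...) {
  n <- nrow(x$metadata)
  cat(sprintf("<ifn_cohort> %d samples (%d T21 / %d control)\n", n,
              sum(x$metadata$karyotype == "T21"),
              sum(x$metadata$karyotype == "control")))
  cat(sprintf("  expression: %d genes; proteomics: %d; immunoassay: %d; metabolites: %d; cell clusters: %d\n",
              nrow(x$expression), nrow(x$proteomics$values),
              nrow(x$immunoassay$values), nrow(x$metabolites$values),
              nrow(x$cells)))
  invisible(x)
}

#' Generate a longitudinal on/off-drug subject
#'
#' Simulates repeated blood draws from one T21 individual with high latent
#' IFN activity who intermittently takes a JAK inhibitor. Off-drug draws
#' are sampled at the subject's latent activity; on-drug draws shrink the
#' ISG component of expression toward the euploid-control mean by fraction
#' `drug_effect` (so `drug_effect = 1` places expected on-drug ISG
#' expression at the control mean, and `drug_effect = 0` makes on and off
#' draws identically distributed). The gene panel is identical to the
#' cohort generated from the same `config`, so draws can be scored against
#' that cohort's frozen reference statistics.
#'
#' @param config A [cohort_config()] (shared with the cross-sectional cohort).
#' @param n_on,n_off Number of on-drug and off-drug draws (default 7 and 4).
#' @param drug_effect Fractional shrinkage of ISG induction while on drug,
#'   in \[0, 1\].
#' @param subject_latent Latent IFN activity of the subject; default is
#'   `t21_shift + 1.5 * latent_sd` (upper range of the T21 distribution).
#' @return An `ifn_series`: list with `expression` (gene x draw matrix),
#'   `draws` (tibble: draw, time, status), `subject_latent`, `drug_effect`
#'   and `gene_info`.
#' @export
generate_longitudinal_subject <- function(config, n_on = 7L, n_off = 4L,
                                          drug_effect = 0.8,
                                          subject_latent = NULL) {
  cfg <- if (inherits(config, "cohort_config")) config else do.call(cohort_config, config)
  n_on <- .assert_count(n_on, "n_on", min = 1L)
  n_off <- .assert_count(n_off, "n_off", min = 1L)
  .assert_scalar_number(drug_effect, "drug_effect", lower = 0, upper = 1)
  gm <- .gene_model(cfg)
  if (is.null(subject_latent)) {
    subject_latent <- cfg$t21_shift + 1.5 * cfg$latent_sd
  }
  n <- n_on + n_off
  # Off draws spread across the series (treatment interruptions).
  off_pos <- unique(round(seq(1, n, length.out = n_off)))
  while (length(off_pos) < n_off) {
    off_pos <- sort(unique(c(off_pos, setdiff(seq_len(n), off_pos)[1])))
  }
  status <- rep("on", n)
  status[off_pos] <- "off"
  status <- factor(status, levels = c("off", "on"))

  .substream(cfg$seed, 9L)
  eff_latent <- ifelse(status == "on",
                       subject_latent * (1 - drug_effect), subject_latent)
  mu <- matrix(gm$baseline, cfg$n_genes, n) +
    log2(cfg$dosage_fold) * (gm$chr == "chr21") %o% rep(1, n) +
    gm$isg_effect %o% eff_latent
  expr <- 2^(mu + matrix(rnorm(cfg$n_genes * n, 0, cfg$expr_noise_sd),
                         cfg$n_genes, n))
  draw_id <- sprintf("draw_%02d", seq_len(n))
  dimnames(expr) <- list(gm$genes, draw_id)
  structure(list(
    expression = expr,
    draws = tibble(draw = draw_id, time = seq_len(n), status = status),
    subject_latent = subject_latent,
    drug_effect = drug_effect,
    gene_info = tibble(gene = gm$genes, chr = gm$chr, is_isg = gm$is_isg)
  ), class = "ifn_series")
}

#' @export
print.ifn_series <- function(x, ...) {
  cat(sprintf("<ifn_series> %d draws (%d on / %d off drug), drug_effect %.2f\n",
              nrow(x$draws), sum(x$draws$status == "on"),
              sum(x$draws$status == "off"), x$drug_effect))
  invisible(x)
}

#' Generate a marker panel with planted sample subtypes
#'
#' Simulates an inflammatory-marker z-score matrix in which samples fall
#' into `n_groups` discrete subtypes, each elevating its own block of
#' markers. Used to exercise consensus clustering and cluster-number
#' selection on data with a known partition.
#'
#' @param n_per_group Samples per subtype.
#' @param n_groups Number of planted subtypes.
#' @param n_markers Number of markers (split into `n_groups` blocks).
#' @param shift Mean elevation (in noise SDs) of a subtype's marker block.
#' @param noise_sd Residual SD.
#' @param seed Seed.
#' @return A marker x sample matrix with attribute `"labels"` holding the
#'   planted subtype of each sample.
#' @export
generate_marker_subtypes <- function(n_per_group = 12L, n_groups = 5L,
                                     n_markers = 25L, shift = 4,
                                     noise_sd = 1, seed = 1L) {
  n_per_group <- .assert_count(n_per_group, "n_per_group", min = 2L)
  n_groups <- .assert_count(n_groups, "n_groups", min = 2L)
  n_markers <- .assert_count(n_markers, "n_markers", min = n_groups)
  set.seed(seed)
  n <- n_per_group * n_groups
  labels <- rep(seq_len(n_groups), each = n_per_group)
  block <- cut(seq_len(n_markers), n_groups, labels = FALSE)
  mu <- vapply(labels, function(g) ifelse(block == g, shift, 0), numeric(n_markers))
  z <- mu + matrix(rnorm(n_markers * n, 0, noise_sd), n_markers, n)
  dimnames(z) <- list(sprintf("marker_%02d", seq_len(n_markers)),
                      sprintf("S%03d", seq_len(n)))
  attr(z, "labels") <- labels
  z
}
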