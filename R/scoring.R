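# The IFN score: per-sample sum of signature-gene z-scores, with z
# computed against the mean and SD of the euploid-control samples on
# covariate-adjusted expression.

#' Reference statistics for IFN scoring
#'
#' Computes, per signature gene, the mean and sample SD (n - 1 denominator)
#' of adjusted expression over the euploid control samples. Genes with zero
#' SD across controls are dropped with a warning and recorded. The result
#' can be frozen (see [write_reference_stats()]) and reused to score
#' external samples - e.g. a longitudinal subject - on the cohort's scale.
#'
#' @param adjusted_expr Gene x sample matrix on the adjustment scale used
#'   for scoring (default workflow: age/sex-adjusted `log2(RPKM + 0.5)`).
#' @param control_ids Sample IDs of the euploid controls (at least 2).
#' @param signature An [select_isg_signature()] result, or a character
#'   vector of gene IDs.
#' @return An `ifn_reference`: list with `stats` (tibble: gene, mean, sd),
#'   `n_controls` and `dropped` genes.
#' @export
reference_stats <- function(adjusted_expr, control_ids, signature) {
  genes <- if (is.character(signature)) signature else signature$gene
  if (length(genes) == 0L) abort("signature contains no genes")
  missing_genes <- setdiff(genes, rownames(adjusted_expr))
  if (length(missing_genes)) {
    abort(sprintf("signature genes missing from matrix: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  control_ids <- intersect(control_ids, colnames(adjusted_expr))
  if (length(control_ids) < 2L) abort("at least 2 control samples are required")
  x <- adjusted_expr[genes, control_ids, drop = FALSE]
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  dropped <- genes[s == 0 | !is.finite(s)]
  if (length(dropped)) {
    warn(sprintf("%d signature genes constant across controls were dropped: %s",
                 length(dropped), paste(head(dropped, 5), collapse = ", ")))
  }
  keep <- setdiff(genes, dropped)
  structure(list(stats = tibble(gene = keep, mean = unname(m[keep]),
                                sd = unname(s[keep])),
                 n_controls = length(control_ids), dropped = dropped),
            class = "ifn_reference")
}

#' @export
print.ifn_reference <- function(x, ...) {
  cat(sprintf("<ifn_reference> %d genes, %d control samples%s\n",
              nrow(x$stats), x$n_controls,
              if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped)) else ""))
  invisible(x)
}

#' Compute per-sample IFN scores
#'
#' The IFN score of a sample is the sum over signature genes of
#' `z(g, s) = (x(g, s) - mean_g) / sd_g`, with `mean_g` and `sd_g` the
#' euploid-control reference statistics. A sample sitting at the control
#' mean on every gene scores 0; a sample one control-SD above the mean on
#' every gene scores `+n_genes`. Any sample on the same adjusted scale can
#' be scored, including external or longitudinal draws.
#'
#' @param adjusted_expr Gene x sample matrix on the reference's scale.
#' @param ref An [reference_stats()] result.
#' @return A tibble: `sample_id`, `ifn_score`, `n_genes`.
#' @export
compute_ifn_score <- function(adjusted_expr, ref) {
  genes <- ref$stats$gene
  missing_genes <- setdiff(genes, rownames(adjusted_expr))
  if (length(missing_genes)) {
    abort(sprintf("signature genes missing from matrix: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  x <- adjusted_expr[genes, , drop = FALSE]
  z <- (x - ref$stats$mean) / ref$stats$sd
  tibble(sample_id = colnames(adjusted_expr),
         ifn_score = unname(colSums(z)),
         n_genes = length(genes))
}

#' Adjust, reference and score a cohort in one step
#'
#' Convenience wrapper for the standard scoring path: log2-transform
#' expression, adjust for nuisance covariates with the karyotype term
#' protected, compute control reference statistics for the signature, and
#' score every sample.
#'
#' @param expr Gene x sample RPKM-like matrix.
#' @param metadata Cohort metadata (`sample_id`, `karyotype`, covariates).
#' @param signature Signature genes (see [reference_stats()]).
#' @param nuisance Nuisance covariates for [adjust_covariates()].
#' @param log2_scale Score on `log2(x + pseudocount)` (default) or on the
#'   linear scale when `FALSE`.
#' @param pseudocount Pseudocount for the log2 transform.
#' @return A list: `scores` (tibble), `reference` (`ifn_reference`),
#'   `adjusted` (the adjusted matrix).
#' @export
score_cohort <- function(expr, metadata, signature,
                         nuisance = c("age", "sex"),
                         log2_scale = TRUE, pseudocount = 0.5) {
  x <- if (log2_scale) log2(expr + pseudocount) else expr
  adjusted <- adjust_covariates(x, metadata, nuisance = nuisance,
                                protect = "karyotype")
  controls <- metadata$sample_id[metadata$karyotype == "control"]
  ref <- reference_stats(adjusted, controls, signature)
  list(scores = compute_ifn_score(adjusted, ref), reference = ref,
       adjusted = adjusted)
}

#' Kynurenine / tryptophan ratio
#'
#' Per-sample ratio of kynurenine to tryptophan intensities, a standard
#' readout of IFN-inducible IDO1-driven tryptophan catabolism. The ratio is
#' invariant to any per-sample scaling applied to both metabolites. Missing
#' if either metabolite is missing; nonpositive tryptophan yields a missing
#' ratio with a warning.
#'
#' @param metabolites A metabolomics [analyte_panel()] or matrix.
#' @param kyn,trp Row names of the two metabolites.
#' @return A tibble: `sample_id`, `kyn_trp_ratio`.
#' @export
kyn_trp_ratio <- function(metabolites, kyn = "kynurenine", trp = "tryptophan") {
  x <- .panel_values(metabolites)
  miss <- setdiff(c(kyn, trp), rownames(x))
  if (length(miss)) {
    abort(sprintf("metabolites not in panel: %s", paste(miss, collapse = ", ")))
  }
  k <- x[kyn, ]
  t <- x[trp, ]
  bad <- is.finite(t) & t <= 0
  if (any(bad)) {
    warn(sprintf("%d samples have nonpositive tryptophan; ratio set missing", sum(bad)))
    t[bad] <- NA_real_
  }
  tibble(sample_id = colnames(x), kyn_trp_ratio = unname(k / t))
}

#' Serialize reference statistics to JSON
#'
#' @param ref An `ifn_reference`.
#' @param path File path.
#' @export
write_reference_stats <- function(ref, path) {
  jsonlite::write_json(list(stats = ref$stats, n_controls = ref$n_controls,
                            dropped = ref$dropped),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stats = as_tibble(x$stats), n_controls = x$n_controls,
                 dropped = as.character(x$dropped %||% character())),
            class = "ifn_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
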