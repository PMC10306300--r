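# ISG signature derivation: differential expression in T21 vs control,
# then filtering on fold change, significance, ISG membership and chr21
# exclusion.

#' Per-gene differential expression between karyotype groups
#'
#' Fits, per gene, an ordinary linear model on `log2(RPKM + pseudocount)`
#' with karyotype plus `age` and `sex` as covariates, and tests the
#' karyotype coefficient with a Wald t-test. The karyotype coefficient is
#' reported as the log2 fold change (T21 over control). P-values are
#' Benjamini-Hochberg adjusted across genes; genes with zero variance get
#' a missing p-value and are excluded from the BH denominator.
#'
#' This is a Gaussian working model on abundance-scale data, used where a
#' count-level negative-binomial model would require read counts.
#'
#' @param expr Nonnegative gene x sample expression matrix (RPKM-like).
#' @param metadata Cohort metadata with `sample_id`, `karyotype` (levels
#'   `control`, `T21`), `age`, `sex`.
#' @param covariates Covariate columns included alongside karyotype.
#' @param pseudocount Added before the log2 transform.
#' @return A tibble: `gene`, `log2fc`, `se`, `p`, `q`.
#' @export
differential_expression <- function(expr, metadata,
                                    covariates = c("age", "sex"),
                                    pseudocount = 0.5) {
  if (any(expr < 0, na.rm = TRUE)) abort("expression must be nonnegative")
  meta <- .match_samples(expr, metadata)
  if (length(unique(meta$karyotype)) < 2L) {
    abort("both karyotype groups must be present")
  }
  y <- log2(expr + pseudocount)
  X <- model.matrix(stats::reformulate(c("karyotype", covariates)),
                    data = meta)
  kcol <- grep("^karyotype", colnames(X))[1]
  qrX <- qr(X)
  B <- qr.coef(qrX, t(y))                       # p x genes
  res <- t(y) - X %*% B
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  XtXinv_kk <- chol2inv(qr.R(qrX))[kcol, kcol]
  est <- B[kcol, ]
  se <- sqrt(sigma2 * XtXinv_kk)
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- apply(y, 1, function(v) var(v) == 0 || !is.finite(var(v)))
  p[zero_var] <- NA_real_
  est[zero_var] <- 0
  tibble(gene = rownames(expr), log2fc = unname(est), se = unname(se),
         p = unname(p), q = .bh(p))
}

#' Select the ISG score signature
#'
#' Filters a differential-expression table to the interferon-stimulated
#' genes that define the IFN score: linear fold change at least `fc_min`
#' (elevated only - negative fold changes never qualify), `q < q_max`,
#' annotated ISG, and not on the excluded chromosome (chr21, whose genes
#' are elevated by dosage rather than IFN signaling). The result is
#' deterministic and sorted by gene ID. An empty selection is returned
#' with a warning, not an error.
#'
#' Relaxing `fc_min` reproduces the broader signature variants (e.g. all
#' elevated non-chr21 ISGs) used for robustness checks.
#'
#' @param de Differential-expression tibble from [differential_expression()].
#' @param annotations Gene annotation table with `gene`, `chr`, `is_isg`.
#' @param fc_min Minimum linear fold change (default 1.5).
#' @param q_max FDR threshold (default 0.1).
#' @param exclude_chr Chromosome whose genes are excluded (default "chr21").
#' @return An `isg_signature`: tibble of `gene`, `log2fc`, `q`, with the
#'   thresholds recorded as attributes.
#' @export
select_isg_signature <- function(de, annotations, fc_min = 1.5, q_max = 0.1,
                                 exclude_chr = "chr21") {
  .assert_scalar_number(fc_min, "fc_min", lower = 1e-12)
  .assert_scalar_number(q_max, "q_max", lower = 0, upper = 1)
  need <- c("gene", "chr", "is_isg")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` must provide gene, chr and is_isg")
  }
  ann <- annotations[match(de$gene, annotations$gene), ]
  keep <- !is.na(de$q) & de$q < q_max &
    de$log2fc >= log2(fc_min) &
    !is.na(ann$is_isg) & ann$is_isg &
    !is.na(ann$chr) & ann$chr != exclude_chr
  sig <- de[keep, c("gene", "log2fc", "q")]
  sig <- sig[order(sig$gene), ]
  if (nrow(sig) == 0L) warn("no genes passed the signature thresholds")
  structure(as_tibble(sig), class = c("isg_signature", class(as_tibble(sig))),
            fc_min = fc_min, q_max = q_max, exclude_chr = exclude_chr)
}

#' @export
print.isg_signature <- function(x, ...) {
  cat(sprintf("<isg_signature> %d genes (FC >= %.3g, q < %.3g, excluding %s)\n",
              nrow(x), attr(x, "fc_min"), attr(x, "q_max"), attr(x, "exclude_chr")))
  NextMethod()
}

#' @method glance isg_signature
#' @export
glance.isg_signature <- function(x, ...) {
  tibble(n_genes = nrow(x), fc_min = attr(x, "fc_min"),
         q_max = attr(x, "q_max"), exclude_chr = attr(x, "exclude_chr"))
}
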