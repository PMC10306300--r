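# Preranked gene set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score (weight exponent 1) with a gene-label permutation null.
# Ranking metrics in the standard workflow: RNA log2 fold change,
# proteomics log2FC * -log10(p), or Spearman rho.

# Enrichment score from sorted hit positions. Between hits the running sum
# decreases linearly, so its extremes occur just after (D) or just before
# (d) a hit; ES is the extreme of larger magnitude.
.gsea_es <- function(hit_idx, w_hits, n_genes) {
  nh <- length(hit_idx)
  phit <- cumsum(w_hits) / sum(w_hits)
  pmiss <- (hit_idx - seq_len(nh)) / (n_genes - nh)
  d_after <- phit - pmiss
  d_before <- c(0, phit[-nh]) - pmiss
  hi <- max(d_after)
  lo <- min(d_before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Computes, per gene set, the weighted Kolmogorov-Smirnov running-sum
#' enrichment score (ES, weight exponent 1) on a ranked gene list, a
#' gene-label permutation null, a normalized enrichment score
#' `NES = ES / mean(|same-sign null ES|)`, permutation p-values and BH q
#' across sets, plus the leading-edge genes. Ties in the ranking are
#' broken by gene ID so results are deterministic; the permutation stream
#' is seeded.
#'
#' @param ranking Named numeric vector (gene -> ranking metric), no
#'   missing values.
#' @param gene_sets Named list of gene ID vectors (e.g. from [read_gmt()]).
#' @param n_perm Number of gene-label permutations per set.
#' @param seed Seed for the permutation stream.
#' @param min_size,max_size Gene sets with fewer/more members present in
#'   the ranking are skipped.
#' @return A tibble: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (list column).
#' @export
preranked_gsea <- function(ranking, gene_sets, n_perm = 10000L, seed = 1L,
                           min_size = 3L, max_size = 500L) {
  if (anyNA(ranking)) abort("ranking must have no missing values")
  if (is.null(names(ranking))) abort("ranking must be named by gene")
  n_perm <- .assert_count(n_perm, "n_perm", min = 1L)
  ord <- order(-ranking, names(ranking))   # ties broken by stable gene ID
  r <- ranking[ord]
  genes <- names(r)
  n <- length(r)
  absr <- abs(r)
  set.seed(.assert_count(seed, "seed", min = 0L))
  rows <- purrr::map(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    sz <- length(members)
    if (sz < min_size || sz > max_size || sz >= n) return(NULL)
    hit_idx <- sort(match(members, genes))
    es <- .gsea_es(hit_idx, absr[hit_idx], n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sort(sample.int(n, sz))
      .gsea_es(idx, absr[idx], n)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    # Leading edge: hits at or before (after, for negative ES) the extremum.
    nh <- length(hit_idx)
    phit <- cumsum(absr[hit_idx]) / sum(absr[hit_idx])
    pmiss <- (hit_idx - seq_len(nh)) / (n - nh)
    if (es >= 0) {
      peak <- which.max(phit - pmiss)
      le <- genes[hit_idx[seq_len(peak)]]
    } else {
      trough <- which.min(c(0, phit[-nh]) - pmiss)
      le <- genes[hit_idx[hit_idx >= hit_idx[trough]]]
    }
    tibble(set = nm, size = sz, es = es, nes = nes, p = p,
           leading_edge = list(le))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(set = character(), size = integer(), es = numeric(),
                  nes = numeric(), p = numeric(), q = numeric(),
                  leading_edge = list()))
  }
  out$q <- .bh(out$p)
  out[, c("set", "size", "es", "nes", "p", "q", "leading_edge")]
}

#' Read gene sets in GMT format
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of gene ID vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
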