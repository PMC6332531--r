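#' Upper-tail hypergeometric overrepresentation probability
#'
#' Probability of observing `hits` or more gene-set members in a module
#' of `module_size` proteins drawn from a background of
#' `background_size` proteins of which `geneset_size` belong to the set:
#'
#'   `P(X >= t) = sum_{i=t}^{n} C(T, i) C(N-T, n-i) / C(N, n)`
#'
#' Computed through the hypergeometric distribution function, which works
#' in log space and stays stable for large backgrounds.
#'
#' @param hits Observed overlap t, `0 <= t <= min(n, T)` (vectorized).
#' @param module_size Module size n.
#' @param geneset_size Gene-set size T.
#' @param background_size Background size N (all proteins in the analyzed
#'   network).
#' @return Upper-tail probability in (0, 1\].
#' @examples
#' hypergeom_test(2, 3, 4, 10)  # 40/120
#' @export
hypergeom_test <- function(hits, module_size, geneset_size, background_size) {
  ok <- hits >= 0 & hits <= module_size & module_size <= background_size &
    geneset_size <= background_size & hits <= geneset_size
  if (!all(ok)) rlang::abort("inconsistent hypergeometric counts")
  stats::phyper(hits - 1, geneset_size, background_size - geneset_size,
                module_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-module gene-set enrichment
#'
#' Tests every module for overrepresentation of `gene_set` against a
#' background of `background_size` proteins, then BH-adjusts across
#' modules.
#'
#' @param mods A `module_set` (or tibble with `module_id` and `members`).
#' @param gene_set Character vector of gene/protein IDs (pre-mapped to
#'   the network's ID space).
#' @param background_size Background N; conventionally the number of
#'   proteins in the analyzed network.
#' @param cutoff Significance cutoff on the adjusted value (default
#'   0.01); significance is strict (`p_adj < cutoff`).
#' @return Tibble: `module_id`, `n` (module size), `t` (hits), `p_raw`,
#'   `p_adj`, `significant`.
#' @export
module_enrichment <- function(mods, gene_set, background_size,
                              cutoff = 0.01) {
  if (nrow(mods) == 0) rlang::abort("empty module set")
  gene_set <- unique(gene_set)
  Tn <- length(gene_set)
  n <- lengths(mods$members)
  t <- vapply(mods$members, function(m) length(intersect(m, gene_set)),
              integer(1))
  if (any(n > background_size) || Tn > background_size) {
    rlang::abort("background smaller than a module or the gene set")
  }
  p_raw <- hypergeom_test(t, n, Tn, background_size)
  p_adj <- bh_adjust(p_raw)
  tibble::tibble(
    module_id = mods$module_id, n = n, t = t,
    p_raw = p_raw, p_adj = p_adj, significant = p_adj < cutoff
  )
}

#' Overrepresentation score and gene-coverage summary for a module set
#'
#' Runs [module_enrichment()] and summarizes: the overrepresentation
#' score `ORS = (number of modules with adjusted P below cutoff) / U`
#' over the `U` detected modules, the fraction of modules containing at
#' least one gene-set member, and how many distinct gene-set members the
#' significant ("cancer") modules cover.  Overlapping modules never
#' double-count a gene.  Two coverage denominators are reported: the
#' full gene set, and the gene-set members present in the background.
#'
#' @inheritParams module_enrichment
#' @param background Either the background size N, a character vector of
#'   background protein IDs, or a `ppi_network` (its node count is used).
#' @return One-row tibble: `n_modules`, `n_significant`, `ors`,
#'   `cancer_module_ratio`, `cancer_gene_count`, `cancer_gene_ratio`,
#'   `cancer_gene_ratio_annotated`.
#' @export
ors_report <- function(mods, gene_set, background, cutoff = 0.01) {
  gene_set <- unique(gene_set)
  if (inherits(background, "ppi_network")) {
    bg_ids <- background$nodes
    N <- length(bg_ids)
  } else if (is.character(background)) {
    bg_ids <- unique(background)
    N <- length(bg_ids)
  } else {
    bg_ids <- NULL
    N <- as.integer(background)
  }
  annotated <- if (is.null(bg_ids)) gene_set else intersect(gene_set, bg_ids)
  if (length(annotated) == 0) {
    rlang::warn("gene set is disjoint from the background; nothing can be enriched")
  }
  enr <- module_enrichment(mods, gene_set, N, cutoff = cutoff)
  U <- nrow(enr)
  sig <- enr$significant
  covered <- unique(unlist(mods$members[sig]))
  hit_genes <- intersect(covered, gene_set)
  tibble::tibble(
    n_modules = U,
    n_significant = sum(sig),
    ors = sum(sig) / U,
    cancer_module_ratio = mean(enr$t > 0),
    cancer_gene_count = length(hit_genes),
    cancer_gene_ratio = length(hit_genes) / length(gene_set),
    cancer_gene_ratio_annotated =
      if (length(annotated) == 0) NA_real_
      else length(hit_genes) / length(annotated)
  )
}
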