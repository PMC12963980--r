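#' Cauchy combination of p-values
#'
#' Combines M p-values into one via the Cauchy combination rule: each p is
#' transformed to `tan(pi * (0.5 - p))`, the transforms are summed into the
#' statistic `T`, and `T/M` is referred to the standard Cauchy survival
#' function, `p_comb = 0.5 - atan(T/M)/pi`. The rule is robust to arbitrary
#' dependence among the inputs and reduces to the identity at M = 1. Inputs
#' are clipped to `[1e-15, 1 - 1e-6]` before the tangent transform: the
#' tight lower clip preserves extreme evidence, while the wider upper clip
#' keeps p-values of exactly 1 (discrete tests, constant genes) from
#' contributing an unbounded negative term that would veto signal from the
#' other methods.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (length >= 1).
#' @return A list with `statistic` (the sum `T`) and `p_comb`.
#' @examples
#' cauchy_combine(c(0.01, 0.2, 0.8))
#' @export
cauchy_combine <- function(pvals) {
  if (!length(pvals)) abort("`pvals` must not be empty.")
  if (!all(is.finite(pvals))) abort("`pvals` must be finite.")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1].")
  out <- cauchy_combine_rows(matrix(pvals, nrow = 1L))
  list(statistic = out$statistic[1L], p_comb = out$p_comb[1L])
}

# row-wise Cauchy combination over a genes x methods matrix.
# tan(pi*(0.5 - p)) is evaluated as cot(pi*p) = 1/tanpi(p): the direct form
# loses the sign near p = 0 or 1 because pi*(0.5 - p) rounds across pi/2,
# while tanpi() is exact at the tails (and NaN only at p = 0.5, where the
# transform is 0 by symmetry).
cauchy_combine_rows <- function(pm) {
  # asymmetric clipping: 1e-15 at the significant end preserves extreme
  # evidence; the null end is capped at 1 - 1e-6 because p-values of
  # exactly 1 (discrete tests, constant genes) would otherwise contribute
  # -1/(pi*eps) ~ -3e14 and veto genuine signal from other methods
  eps <- 1e-15
  pm <- pmin(pmax(pm, eps), 1 - 1e-6)
  at_half <- pm == 0.5           # tanpi(0.5) is NaN; the transform is 0 there
  pm[at_half] <- 0.25
  tm <- 1 / tanpi(pm)
  tm[at_half] <- 0
  tstat <- rowSums(tm)
  m <- ncol(pm)
  p <- pcauchy(tstat / m, lower.tail = FALSE)
  list(statistic = tstat, p_comb = pmin(pmax(p, eps), 1 - eps))
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence: the
#' Benjamini-Hochberg adjusted values multiplied by `c(m) = sum(1/i)`,
#' with monotonicity enforced and values capped at 1. Thin wrapper around
#' `stats::p.adjust(..., method = "BY")` with input validation.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
by_adjust <- function(pvals) {
  if (!length(pvals)) abort("`pvals` must not be empty.")
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BY")
}

new_ensemble_result <- function(method, tbl, params) {
  class(tbl) <- c("ensemble_result", class(tbl))
  attr(tbl, "method") <- method
  attr(tbl, "params") <- params
  tbl
}

#' Inverse-rank aggregation of detector results
#'
#' Every gene receives the aggregation score `S_i = sum_m 1 / rank_{i,m}`
#' over the M method-specific rankings (1 = most significant; genes missing
#' from a method count with the worst possible rank, the universe size).
#' The consensus SVG set is the top `top_fraction` of genes (default 10%)
#' by score, ties broken by gene id so the selection is deterministic.
#'
#' @param results List of [detector_result] tibbles.
#' @param top_fraction Fraction of the gene universe to select, in `(0, 1]`.
#' @param universe Optional character vector fixing the gene universe.
#' @return An `ensemble_result` tibble: `gene_id`, `score`, `pvalue_comb`
#'   (`NA` here), `pvalue_adj` (`NA`), `selected`.
#' @export
rank_aggregate <- function(results, top_fraction = 0.1, universe = NULL) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must lie in (0, 1].")
  }
  aligned <- align_results(check_result_list(results), universe)
  genes <- aligned[[1L]]$gene_id
  score <- Reduce(`+`, lapply(aligned, function(r) 1 / r$rank))
  n_top <- ceiling(top_fraction * length(genes))
  ord <- order(-score, genes)
  selected <- logical(length(genes))
  selected[ord[seq_len(n_top)]] <- TRUE
  tbl <- tibble(gene_id = genes, score = score,
                pvalue_comb = NA_real_, pvalue_adj = NA_real_,
                selected = selected)
  new_ensemble_result("rank_agg", tbl,
                      list(top_fraction = top_fraction,
                           n_methods = length(aligned),
                           methods = names(aligned)))
}

#' P-value aggregation of detector results
#'
#' Per gene, the M method p-values are merged with the Cauchy combination
#' rule ([cauchy_combine()]); the combined p-values are then
#' Benjamini-Yekutieli adjusted across genes and genes with
#' `pvalue_adj < alpha` form the consensus SVG set. Raw p-values are used by
#' default; set `use_adjusted_inputs = TRUE` to combine each method's
#' adjusted p-values instead. Genes missing a p-value in a method are
#' imputed with `p = 1`; methods carrying no p-values at all are dropped
#' with a warning.
#'
#' @inheritParams rank_aggregate
#' @param alpha Significance level on the adjusted combined p-value
#'   (default 0.05).
#' @param use_adjusted_inputs Combine `pvalue_adj` instead of `pvalue`.
#' @return An `ensemble_result` tibble with `score` = combined Cauchy
#'   statistic, `pvalue_comb`, `pvalue_adj`, `selected`.
#' @export
pval_aggregate <- function(results, alpha = 0.05,
                           use_adjusted_inputs = FALSE, universe = NULL) {
  aligned <- align_results(check_result_list(results), universe)
  col <- if (use_adjusted_inputs) "pvalue_adj" else "pvalue"
  has_p <- vapply(aligned, function(r) !all(is.na(r[[col]])), logical(1))
  if (!any(has_p)) abort("No detector supplies p-values to aggregate.")
  if (!all(has_p)) {
    warn(paste0("Dropping method(s) without p-values: ",
                paste(names(aligned)[!has_p], collapse = ", ")))
    aligned <- aligned[has_p]
  }
  pm <- vapply(aligned, function(r) {
    p <- r[[col]]
    ifelse(is.na(p), 1, p)
  }, numeric(nrow(aligned[[1L]])))
  pm <- matrix(pm, ncol = length(aligned))
  cc <- cauchy_combine_rows(pm)
  padj <- by_adjust(cc$p_comb)
  tbl <- tibble(gene_id = aligned[[1L]]$gene_id, score = cc$statistic,
                pvalue_comb = cc$p_comb, pvalue_adj = padj,
                selected = padj < alpha)
  new_ensemble_result("pval_agg", tbl,
                      list(alpha = alpha,
                           use_adjusted_inputs = use_adjusted_inputs,
                           n_methods = length(aligned),
                           methods = names(aligned)))
}
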