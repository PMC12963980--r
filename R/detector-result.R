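#' Assemble a per-gene detector result table
#'
#' A detector result is a tibble with one row per gene and columns `method`,
#' `gene_id`, `statistic`, `pvalue`, `pvalue_adj`, `rank` and `selected`.
#' Ranks (1 = most significant) are computed from the best available metric:
#' raw p-values ascending, else adjusted p-values ascending, else absolute
#' statistic descending. Unless `selected` is supplied, genes with
#' `pvalue_adj < 0.05` are flagged as selected; when no adjusted p-values
#' exist nothing is selected.
#'
#' @param method Method name (single string).
#' @param gene_id Character vector of gene identifiers (unique).
#' @param statistic,pvalue,pvalue_adj Per-gene metrics; `NA` where missing.
#' @param selected Optional logical vector overriding the default rule.
#' @param ties How tied metrics are ranked: `"average"` (default) or `"min"`.
#' @return A tibble of class `detector_result`.
#' @export
detector_result <- function(method, gene_id, statistic = NA_real_,
                            pvalue = NA_real_, pvalue_adj = NA_real_,
                            selected = NULL, ties = c("average", "min")) {
  ties <- match.arg(ties)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) abort("Duplicate gene ids in detector result.")
  p_ok <- function(p) all(is.na(p) | (p >= 0 & p <= 1))
  statistic <- rep_len(as.numeric(statistic), length(gene_id))
  pvalue <- rep_len(as.numeric(pvalue), length(gene_id))
  pvalue_adj <- rep_len(as.numeric(pvalue_adj), length(gene_id))
  if (!p_ok(pvalue)) abort("`pvalue` outside [0, 1].")
  if (!p_ok(pvalue_adj)) abort("`pvalue_adj` outside [0, 1].")

  rk <- metric_ranks(statistic, pvalue, pvalue_adj, ties)
  if (is.null(selected)) {
    selected <- if (all(is.na(pvalue_adj))) rep(FALSE, length(gene_id)) else
      !is.na(pvalue_adj) & pvalue_adj < 0.05
  }
  out <- tibble(method = method, gene_id = gene_id, statistic = statistic,
                pvalue = pvalue, pvalue_adj = pvalue_adj, rank = rk,
                selected = as.logical(selected))
  class(out) <- c("detector_result", class(out))
  out
}

# rank by p ascending, else p_adj ascending, else |statistic| descending;
# rows with no metric at all go last (worst ranks)
metric_ranks <- function(statistic, pvalue, pvalue_adj, ties = "average") {
  key <- if (!all(is.na(pvalue))) pvalue
  else if (!all(is.na(pvalue_adj))) pvalue_adj
  else if (!all(is.na(statistic))) -abs(statistic)
  else abort("No metric column available to rank genes.")
  rank(key, ties.method = ties, na.last = "keep") -> rk
  if (anyNA(rk)) {
    n_ranked <- sum(!is.na(rk))
    rk[is.na(rk)] <- n_ranked + rank(seq_len(sum(is.na(rk))))  # stable tail
  }
  rk
}

#' Read a result table produced by an external SVG tool
#'
#' Adapter for per-gene result files written by third-party detectors. The
#' file must contain a gene-id column (first column, or one named
#' `gene`/`gene_id`) and at least one of `statistic`, `pvalue`,
#' `pvalue_adj` (common aliases such as `pval`, `p.value`, `padj`,
#' `qval`, `p_adj`, `adjusted_pvalue`, `stat` are recognised).
#'
#' @param path Delimited text file (`.csv` or `.tsv`).
#' @param method_name Name recorded in the `method` column.
#' @inheritParams detector_result
#' @return A `detector_result` tibble.
#' @export
read_external_result <- function(path, method_name,
                                 ties = c("average", "min")) {
  ties <- match.arg(ties)
  tab <- read_delim_auto(path)
  nm <- tolower(names(tab))
  pick <- function(aliases) {
    hit <- which(nm %in% aliases)
    if (length(hit)) as.numeric(tab[[hit[1L]]]) else NA_real_
  }
  gene_col <- which(nm %in% c("gene", "gene_id", "genes", "geneid"))
  gene_id <- if (length(gene_col)) as.character(tab[[gene_col[1L]]]) else
    as.character(tab[[1L]])
  statistic <- pick(c("statistic", "stat", "test_statistic"))
  pvalue <- pick(c("pvalue", "pval", "p.value", "p_value", "p"))
  pvalue_adj <- pick(c("pvalue_adj", "padj", "p_adj", "qval", "qvalue",
                       "adjusted_pvalue", "p.adjust", "fdr"))
  if (all(is.na(statistic)) && all(is.na(pvalue)) && all(is.na(pvalue_adj))) {
    abort(paste0("No statistic/pvalue/pvalue_adj column found in ", path))
  }
  detector_result(method_name, gene_id, statistic, pvalue, pvalue_adj,
                  ties = ties)
}

#' Align detector results onto a common gene universe
#'
#' Ensemble methods need every method's table on the same set of genes.
#' Genes missing from a method receive the worst rank (the universe size),
#' missing p-values, and `selected = FALSE`.
#'
#' @param results List of [detector_result] tibbles.
#' @param universe Character vector of gene ids; defaults to the union of
#'   genes seen across results.
#' @return Named list of aligned `detector_result` tibbles, all with
#'   `gene_id` equal to `universe` in order.
#' @export
align_results <- function(results, universe = NULL) {
  results <- check_result_list(results)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(lapply(results, `[[`, "gene_id"))))
  }
  universe <- as.character(universe)
  lapply(results, function(res) {
    idx <- match(universe, res$gene_id)
    out <- tibble(
      method = res$method[1L],
      gene_id = universe,
      statistic = res$statistic[idx],
      pvalue = res$pvalue[idx],
      pvalue_adj = res$pvalue_adj[idx],
      rank = ifelse(is.na(idx), length(universe), res$rank[idx]),
      selected = !is.na(idx) & res$selected[idx]
    )
    class(out) <- c("detector_result", class(out))
    out
  })
}

check_result_list <- function(results) {
  if (inherits(results, "detector_result")) results <- list(results)
  if (!length(results)) abort("Need at least one detector result.")
  ok <- vapply(results, inherits, logical(1), "detector_result")
  if (!all(ok)) abort("All elements must be `detector_result` tibbles.")
  names(results) <- vapply(results, function(r) r$method[1L], character(1))
  results
}
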