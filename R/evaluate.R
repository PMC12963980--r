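#' Confusion metrics against planted truth
#'
#' Computes the standard benchmark panel — accuracy, F1, recall, precision,
#' specificity, Matthews correlation and (when per-gene scores are given)
#' the rank-based Mann-Whitney AUC — plus the empirical false discovery
#' rate `FP / max(FP + TP, 1)` and the number of selections. Degenerate
#' cases use fixed conventions so pipelines never emit non-finite numbers:
#' F1 and precision are 0 when nothing is selected, MCC is 0 when any
#' confusion marginal is 0.
#'
#' @param selected Logical vector: genes called SVGs.
#' @param truth Logical vector: planted ground truth (same length).
#' @param scores Optional numeric vector for AUC (higher = more SVG-like).
#' @return A one-row tibble with columns `accuracy`, `f1`, `recall`,
#'   `precision`, `specificity`, `mcc`, `auc`, `empirical_fdr`,
#'   `n_selected`.
#' @export
confusion_metrics <- function(selected, truth, scores = NULL) {
  selected <- as.logical(selected); truth <- as.logical(truth)
  if (length(selected) != length(truth)) {
    abort("`selected` and `truth` must have the same length.")
  }
  tp <- sum(selected & truth); fp <- sum(selected & !truth)
  fn <- sum(!selected & truth); tn <- sum(!selected & !truth)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else
    (tp * tn - fp * fn) / mcc_den
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) abort("`scores` length mismatch.")
    n1 <- sum(truth); n0 <- sum(!truth)
    if (n1 >= 1 && n0 >= 1) {
      rk <- rank(scores)
      auc <- (sum(rk[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  tibble(accuracy = (tp + tn) / length(truth), f1 = f1, recall = rec,
         precision = prec, specificity = spec, mcc = mcc, auc = auc,
         empirical_fdr = fp / max(fp + tp, 1), n_selected = tp + fp)
}

#' Cross-replicate consistency of top gene lists
#'
#' For every ordered pair of replicates, the fraction of one replicate's
#' top-`top_k` genes that also appear in the other's top list; the
#' consistency score `C` is the average over ordered pairs. Identical lists
#' give 1, disjoint lists 0.
#'
#' @param lists List (length >= 2) of character vectors, each ordered by
#'   significance (best first).
#' @param top_k Number of leading genes per replicate (default 200). Lists
#'   shorter than `top_k` are used in full, with a warning.
#' @return A single number in `[0, 1]`.
#' @export
consistency_score <- function(lists, top_k = 200) {
  if (length(lists) < 2L) abort("Need at least two replicates.")
  if (any(lengths(lists) < top_k)) {
    warn("`top_k` exceeds a replicate's list length; using the full list.")
  }
  tops <- lapply(lists, function(l) head(as.character(l), top_k))
  pairs <- expand.grid(i = seq_along(tops), j = seq_along(tops))
  pairs <- pairs[pairs$i != pairs$j, ]
  rates <- mapply(function(i, j) mean(tops[[i]] %in% tops[[j]]),
                  pairs$i, pairs$j)
  mean(rates)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("Reading GMT files requires the fgsea package.")
  }
  fgsea::gmtPathways(path)
}

#' Functional specificity of a selected gene list
#'
#' Hypergeometric (one-sided) enrichment of the selected genes against each
#' gene set, Benjamini-Hochberg adjusted across sets at level `alpha`; the
#' functional specificity `FS` is the fraction of selected genes belonging
#' to at least one enriched set (0 when nothing is selected or no set is
#' enriched). Sets are intersected with the background and de-duplicated
#' first, so duplicated genes within a set and genes outside the background
#' do not matter.
#'
#' @param selected Character vector of selected gene ids.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param alpha BH-adjusted significance level for a set to count as
#'   enriched (default 0.05).
#' @return A single number in `[0, 1]`.
#' @export
functional_specificity <- function(selected, gene_sets, background,
                                   alpha = 0.05) {
  background <- unique(as.character(background))
  if (!length(background)) abort("`background` must not be empty.")
  selected <- intersect(unique(as.character(selected)), background)
  if (!length(selected)) return(0)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), background))
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) return(0)
  n_bg <- length(background); n_sel <- length(selected)
  pvals <- vapply(sets, function(s) {
    ov <- length(intersect(selected, s))
    phyper(ov - 1, length(s), n_bg - length(s), n_sel, lower.tail = FALSE)
  }, numeric(1))
  enriched <- sets[p.adjust(pvals, "BH") < alpha]
  if (!length(enriched)) return(0)
  in_enriched <- unique(unlist(enriched))
  mean(selected %in% in_enriched)
}

#' Quality score of an SVG list
#'
#' `QS = C x FS`: the product of cross-replicate consistency and functional
#' specificity, both in `[0, 1]`.
#'
#' @param consistency Consistency score `C` (see [consistency_score()]).
#' @param functional_specificity Functional specificity `FS`
#'   (see [functional_specificity()]).
#' @return A one-row tibble with `consistency`, `functional_specificity`
#'   and `qs`.
#' @export
quality_score <- function(consistency, functional_specificity) {
  for (v in c(consistency, functional_specificity)) {
    if (!is.numeric(v) || v < 0 || v > 1) abort("Inputs must lie in [0, 1].")
  }
  tibble(consistency = consistency,
         functional_specificity = functional_specificity,
         qs = consistency * functional_specificity)
}

#' Per-gene Moran's I summary
#'
#' Moran's I for a set of genes on the dataset's kNN spot graph, plus the
#' mean over the (non-constant) genes. Constant genes are skipped with a
#' warning and reported as `NA`.
#'
#' @inheritParams moran_detector
#' @param genes Character vector of gene ids (default: all genes).
#' @return A tibble `gene_id`, `morans_i`, with the mean over non-constant
#'   genes in `attr(, "mean_morans_i")`.
#' @export
moran_summary <- function(ds, genes = NULL, k = 6) {
  stopifnot(inherits(ds, "spatial_dataset"))
  genes <- genes %||% gene_ids(ds)
  missing <- setdiff(genes, gene_ids(ds))
  if (length(missing)) {
    abort(paste0("Gene(s) not in dataset: ", paste(missing, collapse = ", ")))
  }
  w <- knn_weights(ds$coords, k)
  obs <- moran_stat_rows(ds$expr[match(genes, gene_ids(ds)), , drop = FALSE], w)
  if (all(obs$constant)) abort("All requested genes are constant.")
  if (any(obs$constant)) {
    warn(sprintf("Skipping %d constant gene(s).", sum(obs$constant)))
  }
  out <- tibble(gene_id = genes, morans_i = unname(obs$i))
  attr(out, "mean_morans_i") <- mean(obs$i, na.rm = TRUE)
  out
}
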