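#' Augment a dataset with permuted artificial genes
#'
#' Creates negative-control "artificial" genes by randomly permuting each
#' gene's values across spots, which destroys any spatial structure while
#' exactly preserving the gene's marginal distribution. The artificial
#' matrix is stacked under the original one, doubling the gene count; the
#' controls later calibrate the selection-frequency threshold of
#' [fdpp_aggregate()].
#'
#' @inheritParams moran_detector
#' @param seed Integer seed for the permutations.
#' @param permute `"per_gene"` (default): every gene gets its own
#'   independent spot permutation. `"shared"`: one spot permutation is
#'   applied to all genes jointly, preserving gene-gene correlation among
#'   the controls.
#' @return An `augmented_dataset` (also a [spatial_dataset]) with `2P`
#'   genes, an `origin` field (`"original"`/`"artificial"` per gene), a
#'   `source_gene` field for the controls, and the seed used. Artificial
#'   gene ids are the source id plus the suffix `"__art"`.
#' @export
build_augmented <- function(ds, seed = 1, permute = c("per_gene", "shared")) {
  stopifnot(inherits(ds, "spatial_dataset"))
  permute <- match.arg(permute)
  p <- n_genes(ds); n <- n_spots(ds)
  art_ids <- paste0(gene_ids(ds), "__art")
  if (any(art_ids %in% gene_ids(ds))) {
    abort("Gene id collision with the `__art` suffix; rename input genes.")
  }
  x_art <- withr::with_seed(seed, {
    if (permute == "shared") {
      ds$expr[, sample.int(n), drop = FALSE]
    } else {
      t(apply(ds$expr, 1L, function(row) row[sample.int(n)]))
    }
  })
  expr <- rbind(ds$expr, x_art)
  rownames(expr) <- c(gene_ids(ds), art_ids)
  out <- spatial_dataset(expr, ds$coords, normalized = ds$normalized)
  out$origin <- stats::setNames(rep(c("original", "artificial"), each = p),
                                rownames(expr))
  out$source_gene <- stats::setNames(c(rep(NA_character_, p), gene_ids(ds)),
                                     rownames(expr))
  out$seed <- seed
  class(out) <- c("augmented_dataset", class(out))
  out
}

#' Selection frequency across methods
#'
#' The fraction of methods that call each gene significant, computed on the
#' augmented (originals + artificial controls) gene universe. All results
#' must cover the same gene set; use [align_results()] or [run_detectors()]
#' to guarantee that.
#'
#' @param results Named list of [detector_result] tibbles on a common gene
#'   universe, with populated `selected` flags (each method's own rule;
#'   the built-ins use `pvalue_adj < 0.05`, rank-only methods their top
#'   fraction).
#' @param origin Optional named character vector (`"original"` /
#'   `"artificial"` per gene id), e.g. `aug$origin`; carried into the
#'   output when given.
#' @return A tibble with `gene_id`, `frequency` (in `{0, 1/M, ..., 1}`),
#'   `n_selected_by` and, when `origin` is supplied, `origin`.
#' @export
selection_frequency <- function(results, origin = NULL) {
  results <- check_result_list(results)
  genes <- results[[1L]]$gene_id
  same <- vapply(results, function(r) identical(r$gene_id, genes), logical(1))
  if (!all(same)) {
    setwise <- vapply(results, function(r) setequal(r$gene_id, genes), logical(1))
    if (!all(setwise)) abort("Results cover different gene universes.")
    results <- lapply(results, function(r) r[match(genes, r$gene_id), ])
  }
  sel <- vapply(results, function(r) as.logical(r$selected),
                logical(length(genes)))
  sel <- matrix(sel, ncol = length(results))
  out <- tibble(gene_id = genes,
                frequency = rowMeans(sel),
                n_selected_by = rowSums(sel))
  if (!is.null(origin)) out$origin <- unname(origin[genes])
  out
}

#' False discovery proportion proxy
#'
#' `FDP_plus(t) = (1 + |A_t|) / (|O_t| v 1)`, where `A_t` and `O_t` are the
#' artificial and original genes whose selection frequency strictly exceeds
#' `t`. The pseudo-count in the numerator stabilises the estimate when few
#' originals are selected; the max operator in the denominator avoids
#' division by zero.
#'
#' @param freqs Tibble from [selection_frequency()] with an `origin` column.
#' @param t Candidate threshold in `[0, 1)`.
#' @return The proxy value (a single number).
#' @export
fdp_plus <- function(freqs, t) {
  check_freqs(freqs)
  if (!is.numeric(t) || t < 0 || t >= 1) abort("`t` must lie in [0, 1).")
  a <- sum(freqs$origin == "artificial" & freqs$frequency > t + 1e-9)
  o <- sum(freqs$origin == "original" & freqs$frequency > t + 1e-9)
  (1 + a) / max(o, 1)
}

#' Scan candidate frequency thresholds
#'
#' Evaluates `FDP_plus(t) + lambda * |A_t|` on the grid
#' `t in {0, 1/M, ..., (M-1)/M}` — with frequencies living on the `1/M`
#' lattice and strict exceedance, this grid enumerates every distinct
#' selection set. The chosen `t*` minimises the objective; ties go to the
#' largest `t` (the most conservative selection).
#'
#' @inheritParams fdp_plus
#' @param lam Penalty weight `lambda >= 0` on the number of admitted
#'   artificial genes.
#' @param m Number of methods behind the frequencies.
#' @return A `threshold_scan` tibble with columns `t`, `a_count`, `o_count`,
#'   `fdp_plus`, `objective`, and attributes `t_star`, `lam`, `m`.
#' @export
choose_threshold <- function(freqs, lam, m) {
  check_freqs(freqs)
  if (!is.numeric(lam) || lam < 0) abort("`lam` must be >= 0.")
  m <- as.integer(m)
  if (m < 1) abort("`m` must be a positive method count.")
  grid <- (seq_len(m) - 1L) / m
  f <- freqs$frequency
  is_art <- freqs$origin == "artificial"
  a_count <- vapply(grid, function(t) sum(is_art & f > t + 1e-9), numeric(1))
  o_count <- vapply(grid, function(t) sum(!is_art & f > t + 1e-9), numeric(1))
  fdp <- (1 + a_count) / pmax(o_count, 1)
  obj <- fdp + lam * a_count
  t_star <- grid[max(which(obj <= min(obj) + 1e-12))]
  out <- tibble(t = grid, a_count = a_count, o_count = o_count,
                fdp_plus = fdp, objective = obj)
  class(out) <- c("threshold_scan", class(out))
  attr(out, "t_star") <- t_star
  attr(out, "lam") <- lam
  attr(out, "m") <- m
  out
}

#' @rdname choose_threshold
#' @param scan A `threshold_scan`.
#' @export
t_star <- function(scan) attr(scan, "t_star")

#' Frequency-threshold ensemble with artificial-gene false discovery control
#'
#' The full negative-control aggregation pipeline: (1) augment the dataset
#' with per-gene permuted artificial genes ([build_augmented()]); (2) run
#' every detector on the augmented matrix; (3) compute each gene's selection
#' frequency across methods ([selection_frequency()]); (4) choose the
#' frequency threshold `t*` minimising the penalised false discovery proxy
#' ([choose_threshold()]). Original genes whose frequency exceeds `t*` are
#' the consensus SVGs; artificial genes are never reported as SVGs.
#'
#' @inheritParams run_detectors
#' @param lam Penalty weight; defaults to `1/P` so that admitting every
#'   artificial gene costs 1, commensurate with the scale of the proxy.
#' @param permute Passed to [build_augmented()].
#' @return An `ensemble_result` tibble covering both originals and controls
#'   (`origin` column; `score` = selection frequency; `selected` is `TRUE`
#'   only for originals above `t*`), with the [choose_threshold()] scan in
#'   `attr(, "scan")`.
#' @export
fdpp_aggregate <- function(ds, specs, lam = NULL, seed = 1,
                           permute = c("per_gene", "shared")) {
  stopifnot(inherits(ds, "spatial_dataset"))
  permute <- match.arg(permute)
  if (is.character(specs)) specs <- lapply(specs, function(s) list(name = s))
  if (length(specs) < 2L) {
    warn("fdpp_aggregate() with a single method: frequencies are 0/1 only.")
  }
  if (is.null(lam)) lam <- 1 / n_genes(ds)
  aug <- build_augmented(ds, seed = seed, permute = permute)
  results <- tryCatch(
    run_detectors(aug, specs, seed = seed + 1L),
    error = function(e) abort(paste0("Detector failure on augmented matrix: ",
                                     conditionMessage(e)))
  )
  freqs <- selection_frequency(results, origin = aug$origin)
  scan <- choose_threshold(freqs, lam = lam, m = length(results))
  ts <- t_star(scan)
  tbl <- tibble(gene_id = freqs$gene_id, score = freqs$frequency,
                pvalue_comb = NA_real_, pvalue_adj = NA_real_,
                selected = freqs$origin == "original" &
                  freqs$frequency > ts + 1e-9,
                origin = freqs$origin)
  res <- new_ensemble_result("fdpp_agg", tbl,
                             list(lam = lam, seed = seed, permute = permute,
                                  t_star = ts, n_methods = length(results),
                                  methods = names(results)))
  attr(res, "scan") <- scan
  res
}

check_freqs <- function(freqs) {
  if (!is.data.frame(freqs) ||
      !all(c("gene_id", "frequency", "origin") %in% names(freqs))) {
    abort("`freqs` must have columns gene_id, frequency, origin.")
  }
  invisible(freqs)
}
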