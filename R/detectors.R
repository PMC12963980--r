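#' Built-in SVG detectors
#'
#' The package ships three lightweight detectors so the ensemble layer can be
#' exercised without any external tool. They are deliberately simple screens,
#' not re-implementations of published SVG methods; the ensemble layer is
#' agnostic to where a result table came from.
#'
#' * `moran_detector()` — permutation Moran's I test per gene.
#' * `moran_rank_detector()` — Moran's I statistic only (rank-based output,
#'   no p-values), mimicking tools that emit ranked lists.
#' * `covariance_detector()` — correlation screen of each gene against a
#'   dictionary of location features, combined with the Cauchy rule.
#'
#' @name detectors
NULL

#' Permutation Moran's I detector
#'
#' For every gene, Moran's I is computed on a k-nearest-neighbour spot graph
#' and compared with its distribution under `n_perm` random permutations of
#' spot labels. The test is one-sided for positive spatial autocorrelation:
#' `p = (1 + #{I_perm >= I_obs}) / (n_perm + 1)`, so the smallest attainable
#' p-value is `1/(n_perm + 1)`. P-values are Benjamini-Hochberg adjusted
#' across genes and `pvalue_adj < 0.05` defines the selected set. Constant
#' genes get `p = 1` and a missing statistic rather than an error, so
#' whole-matrix runs never abort.
#'
#' @param ds A [spatial_dataset] (used as-is; normalize beforehand if wanted).
#' @param k Neighbours for the spot graph. The default 24 sets the graph at
#'   a regional scale: expression domains in tissue typically span tens of
#'   percent of the section, and averaging the pair covariance over a
#'   larger neighbourhood lowers the null variance of I (which shrinks
#'   roughly as `1/sqrt(N k)`) without losing domain-scale signal. Pass
#'   `k = 6` for a strictly lattice-local (hexagonal-array-like) graph.
#' @param n_perm Number of label permutations (>= 99; default 999, the
#'   common spatial-statistics convention; the p-value floor `1/(n_perm+1)`
#'   must sit well below `alpha * expected discoveries / genes` for the
#'   Benjamini-Hochberg step to admit anything in large gene families).
#' @param seed Integer seed controlling the permutations.
#' @return A [detector_result] tibble; ranks are by p-value ascending with
#'   ties broken by the observed statistic descending.
#' @export
moran_detector <- function(ds, k = 24, n_perm = 999, seed = 1) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (n_perm < 99) abort("`n_perm` must be at least 99.")
  n_perm <- as.integer(n_perm)
  w <- knn_weights(ds$coords, k)
  n <- n_spots(ds)
  obs <- moran_stat_rows(ds$expr, w)
  keep <- !obs$constant
  if (any(obs$constant)) {
    inform(sprintf("%d constant gene(s) assigned p = 1.", sum(obs$constant)))
  }
  p <- rep(1, n_genes(ds))
  if (any(keep)) {
    perms <- withr::with_seed(seed, {
      matrix(unlist(lapply(seq_len(n_perm), function(b) sample.int(n) - 1L)),
             nrow = n_perm, byrow = TRUE)
    })
    xc <- ds$expr[keep, , drop = FALSE]
    xc <- xc - rowMeans(xc)
    cnt <- moran_perm_exceed(xc, w$edges$i - 1L, w$edges$j - 1L, w$edges$w,
                             perms, obs$num[keep])
    p[keep] <- (1 + cnt) / (n_perm + 1)
  }
  res <- detector_result("moran", gene_ids(ds), statistic = obs$i,
                         pvalue = p, pvalue_adj = p.adjust(p, "BH"))
  res$rank <- rank_by_p_then_stat(res$pvalue, res$statistic)
  res
}

#' Moran's I rank-only detector
#'
#' Ranks genes by the observed Moran's I statistic alone, without any
#' significance assessment — a stand-in for methods that output ordered gene
#' lists rather than p-values. The top `top_fraction` of genes is flagged as
#' selected.
#'
#' @inheritParams moran_detector
#' @param top_fraction Fraction of genes to select (default 0.1).
#' @return A [detector_result] with `statistic` only (p-value columns `NA`).
#' @export
moran_rank_detector <- function(ds, k = 24, top_fraction = 0.1) {
  stopifnot(inherits(ds, "spatial_dataset"))
  w <- knn_weights(ds$coords, k)
  obs <- moran_stat_rows(ds$expr, w)
  stat <- ifelse(obs$constant, NA_real_, obs$i)
  ord <- order(-stat, gene_ids(ds), na.last = TRUE)
  rk <- integer(length(stat))
  rk[ord] <- seq_along(stat)
  n_top <- ceiling(top_fraction * length(stat))
  res <- detector_result("moran_rank", gene_ids(ds), statistic = stat,
                         selected = rk <= n_top)
  res$rank <- rk
  res
}

#' Spatial covariance screen
#'
#' Tests each gene's expression for (squared Pearson) correlation with a
#' fixed dictionary of location features — x, y, x^2, y^2, xy and the radial
#' distance to the centroid, computed on coordinates rescaled to the unit
#' square. The six feature columns are orthogonalised (QR) before testing so
#' the per-feature correlation tests are approximately independent; the six
#' p-values are then merged with [cauchy_combine()] into one p-value per
#' gene, Benjamini-Hochberg adjusted across genes, and `pvalue_adj < 0.05`
#' defines the selected set. Constant genes get `p = 1`.
#'
#' @inheritParams moran_detector
#' @return A [detector_result]; `statistic` holds the combined Cauchy
#'   statistic.
#' @export
covariance_detector <- function(ds) {
  stopifnot(inherits(ds, "spatial_dataset"))
  n <- n_spots(ds)
  if (n <= 10) abort("covariance_detector() needs more than 10 spots.")
  feats <- location_features(ds$coords)
  r <- suppressWarnings(cor(t(ds$expr), feats))  # P x F; NA rows = constant
  df <- n - 2
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, 1e-300))
  pm <- 2 * pt(tstat, df, lower.tail = FALSE)
  const <- !stats::complete.cases(pm)
  pm[const, ] <- 1
  cc <- cauchy_combine_rows(pm)
  res <- detector_result("covariance", gene_ids(ds),
                         statistic = ifelse(const, NA_real_, cc$statistic),
                         pvalue = ifelse(const, 1, cc$p_comb))
  res$pvalue_adj <- p.adjust(res$pvalue, "BH")
  res$selected <- res$pvalue_adj < 0.05
  res$rank <- rank_by_p_then_stat(res$pvalue, res$statistic)
  res
}

# x, y, x^2, y^2, xy, radial distance on the unit square, then centered and
# orthogonalised; rank-deficient columns (e.g. 1-D layouts) are dropped.
location_features <- function(coords) {
  xy <- coords_matrix(coords)
  u <- apply(xy, 2L, function(v) {
    rng <- diff(range(v))
    if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  })
  x <- u[, 1L]; y <- u[, 2L]
  r <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  f <- cbind(x = x, y = y, x2 = x^2, y2 = y^2, xy = x * y, r = r)
  f <- scale(f, center = TRUE, scale = FALSE)
  qr_f <- qr(f)
  q <- qr.Q(qr_f)[, seq_len(qr_f$rank), drop = FALSE]
  q
}

rank_by_p_then_stat <- function(p, stat) {
  ord <- order(p, -ifelse(is.na(stat), -Inf, stat))
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk
}

# --- detector registry -------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Register or list detectors
#'
#' Detectors are addressed by name in [run_detectors()] and pipeline
#' configurations. A detector function takes `(ds, seed, ...)` and returns a
#' [detector_result]. Built-ins `"moran"`, `"moran_rank"`, `"covariance"`
#' and the `"external"` file adapter are pre-registered.
#'
#' @param name Detector name.
#' @param fun Function `(ds, seed, ...) -> detector_result`.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = the_registry)
  invisible(name)
}

#' @rdname register_detector
#' @export
list_detectors <- function() sort(ls(the_registry))

.onLoad <- function(libname, pkgname) {
  register_detector("moran", function(ds, seed = 1, k = 24, n_perm = 999) {
    moran_detector(ds, k = k, n_perm = n_perm, seed = seed)
  })
  register_detector("moran_rank", function(ds, seed = 1, k = 24,
                                           top_fraction = 0.1) {
    moran_rank_detector(ds, k = k, top_fraction = top_fraction)
  })
  register_detector("covariance", function(ds, seed = 1) {
    covariance_detector(ds)
  })
  register_detector("external", function(ds, seed = 1, path,
                                         method_name = "external") {
    read_external_result(path, method_name)
  })
}

#' Run a set of detectors on one dataset
#'
#' Each spec is either a detector name or a list with a `name` element plus
#' parameters (for `"external"`, a `path` and optional `method_name`).
#' Results are aligned to the dataset's gene universe, so genes absent from
#' an external file get the worst rank and are not selected. Given the same
#' seed the output is fully deterministic: detector `i` runs with seed
#' `seed + i`.
#'
#' @inheritParams moran_detector
#' @param specs List of detector specs (or a character vector of names).
#' @param seed Base integer seed.
#' @return Named list of aligned [detector_result] tibbles.
#' @export
run_detectors <- function(ds, specs, seed = 1) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.character(specs)) specs <- lapply(specs, function(s) list(name = s))
  if (!length(specs)) abort("Need at least one detector spec.")
  results <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (is.character(spec)) spec <- list(name = spec)
    name <- spec$name
    if (is.null(name) || !exists(name, envir = the_registry)) {
      abort(paste0("Unknown detector `", name %||% "<missing>",
                   "`. Registered: ", paste(list_detectors(), collapse = ", ")))
    }
    fun <- get(name, envir = the_registry)
    args <- c(list(ds = ds, seed = seed + i), spec[setdiff(names(spec), "name")])
    results[[i]] <- do.call(fun, args)
  }
  align_results(results, universe = gene_ids(ds))
}
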