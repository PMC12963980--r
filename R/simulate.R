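#' Simulation configuration for synthetic spatial transcriptomics data
#'
#' Describes a synthetic dataset with planted spatially variable genes:
#' spot layout, gene counts, the fraction and spatial patterns of true SVGs,
#' the count distribution and its parameters, the multiplicative fold change
#' of the patterns, and additive Gaussian noise on the log-mean. Defaults
#' mirror a Visium-scale benchmark: 1500 spots, 10000 genes, 10% SVGs split
#' evenly over hotspot/streak/gradient/curve patterns, ZINB counts with
#' base mean 2, dispersion `theta = 5` and zero inflation `pi = 0.3`, fold
#' change 3 and no extra noise.
#'
#' @param n_spots,n_genes Dataset dimensions.
#' @param svg_fraction Fraction of genes carrying a spatial pattern,
#'   in `(0, 1)`.
#' @param patterns Named numeric vector of pattern proportions over
#'   `hotspot`, `streak`, `gradient`, `curve` (must sum to 1), or a
#'   character vector of pattern names for equal proportions.
#' @param distribution Count model: `"pois"`, `"zip"`, `"nb"` or `"zinb"`.
#' @param base_mean Baseline mean expression per spot (counts).
#' @param fold_change Peak-to-baseline mean ratio of a pattern (>= 1;
#'   1 disables the pattern).
#' @param dispersion NB/ZINB size parameter `theta` (> 0).
#' @param zero_inflation ZIP/ZINB structural-zero probability `pi` in
#'   `[0, 1)`.
#' @param noise_sd SD of additive Gaussian noise on the log-mean (>= 0).
#' @param layout `"grid"` (near-square lattice) or `"random"` (uniform on
#'   the unit square).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_spots = 1500, n_genes = 10000,
                              svg_fraction = 0.1,
                              patterns = c("hotspot", "streak",
                                           "gradient", "curve"),
                              distribution = c("zinb", "pois", "zip", "nb"),
                              base_mean = 2, fold_change = 3,
                              dispersion = 5, zero_inflation = 0.3,
                              noise_sd = 0, layout = c("grid", "random"),
                              seed = 1) {
  distribution <- match.arg(distribution)
  layout <- match.arg(layout)
  if (is.character(patterns)) {
    patterns <- stats::setNames(rep(1 / length(patterns), length(patterns)),
                                patterns)
  }
  bad <- setdiff(names(patterns), c("hotspot", "streak", "gradient", "curve"))
  if (length(bad)) abort(paste0("Unknown pattern(s): ", paste(bad, collapse = ", ")))
  if (abs(sum(patterns) - 1) > 1e-8) abort("Pattern proportions must sum to 1.")
  if (svg_fraction <= 0 || svg_fraction >= 1) abort("`svg_fraction` must be in (0, 1).")
  if (fold_change < 1) abort("`fold_change` must be >= 1.")
  if (base_mean <= 0) abort("`base_mean` must be positive.")
  if (dispersion <= 0) abort("`dispersion` must be positive.")
  if (zero_inflation < 0 || zero_inflation >= 1) {
    abort("`zero_inflation` must lie in [0, 1).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
                 svg_fraction = svg_fraction, patterns = patterns,
                 distribution = distribution, base_mean = base_mean,
                 fold_change = fold_change, dispersion = dispersion,
                 zero_inflation = zero_inflation, noise_sd = noise_sd,
                 layout = layout, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Spatial mean-multiplier field for one planted pattern
#'
#' Produces the per-spot multiplicative effect of a spatial pattern,
#' rescaled so the field spans `[1, fold_change]` (identically 1 when
#' `fold_change = 1`). Coordinates are rescaled to the unit square
#' internally. Pattern shapes:
#' * `hotspot` — isotropic Gaussian bump at `center` with width `sigma`;
#' * `streak` — Gaussian band of width `width` around a line through
#'   `center` at angle `angle`;
#' * `gradient` — affine ramp along direction `angle`;
#' * `curve` — Gaussian band of width `width` around the sine arc
#'   `y = y0 + amplitude * sin(2*pi*x + phase)`.
#'
#' Unspecified shape parameters are drawn from the current RNG state, so a
#' caller that seeds the RNG gets reproducible random placements per gene.
#'
#' @param pattern One of `"hotspot"`, `"streak"`, `"gradient"`, `"curve"`.
#' @param coords N x 2 coordinates (any units).
#' @param fold_change Peak multiplier (>= 1).
#' @param params Optional list fixing shape parameters (`center`, `sigma`,
#'   `angle`, `width`, `amplitude`, `phase`, `y0`).
#' @return Numeric vector of per-spot multipliers in `[1, fold_change]`.
#' @export
pattern_field <- function(pattern, coords, fold_change = 3, params = list()) {
  xy <- coords_matrix(coords)
  u <- apply(xy, 2L, function(v) {
    rng <- diff(range(v))
    if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  })
  x <- u[, 1L]; y <- u[, 2L]
  g <- switch(pattern,
    hotspot = {
      center <- params$center %||% runif(2, 0.2, 0.8)
      sigma <- params$sigma %||% 0.15
      exp(-((x - center[1L])^2 + (y - center[2L])^2) / (2 * sigma^2))
    },
    streak = {
      angle <- params$angle %||% runif(1, 0, pi)
      center <- params$center %||% runif(2, 0.25, 0.75)
      width <- params$width %||% 0.2
      d <- abs(-sin(angle) * (x - center[1L]) + cos(angle) * (y - center[2L]))
      exp(-d^2 / (2 * (width / 2)^2))
    },
    gradient = {
      angle <- params$angle %||% runif(1, 0, 2 * pi)
      cos(angle) * x + sin(angle) * y
    },
    curve = {
      amplitude <- params$amplitude %||% 0.2
      phase <- params$phase %||% runif(1, 0, 2 * pi)
      y0 <- params$y0 %||% runif(1, 0.35, 0.65)
      width <- params$width %||% 0.15
      d <- abs(y - (y0 + amplitude * sin(2 * pi * x + phase)))
      exp(-d^2 / (2 * (width / 2)^2))
    },
    abort(paste0("Unknown pattern label: ", pattern))
  )
  rng <- max(g) - min(g)
  if (fold_change == 1 || rng < .Machine$double.eps) {
    return(rep(1, length(g)))
  }
  1 + (fold_change - 1) * (g - min(g)) / rng
}

#' Draw counts from a (zero-inflated) count model
#'
#' Entrywise sampling from Poisson, zero-inflated Poisson, negative binomial
#' (mean/size parameterisation) or zero-inflated negative binomial.
#'
#' @param mean_matrix Matrix (or vector) of positive means.
#' @param distribution `"pois"`, `"zip"`, `"nb"` or `"zinb"`.
#' @param dispersion NB size `theta` (NB/ZINB only).
#' @param zero_inflation Structural-zero probability `pi` in `[0, 1)`
#'   (ZIP/ZINB only).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return Integer-valued matrix shaped like `mean_matrix`.
#' @export
sample_counts <- function(mean_matrix,
                          distribution = c("pois", "zip", "nb", "zinb"),
                          dispersion = 5, zero_inflation = 0.3, seed = NULL) {
  distribution <- match.arg(distribution)
  mu <- as.numeric(mean_matrix)
  if (any(!is.finite(mu) | mu <= 0)) abort("Means must be finite and positive.")
  if (distribution %in% c("zip", "zinb")) {
    if (zero_inflation >= 1 || zero_inflation < 0) {
      abort("`zero_inflation` must lie in [0, 1).")
    }
  }
  draw <- function() {
    base <- switch(distribution,
      pois = , zip = rpois(length(mu), mu),
      nb = , zinb = rnbinom(length(mu), size = dispersion, mu = mu))
    if (distribution %in% c("zip", "zinb") && zero_inflation > 0) {
      base[rbinom(length(mu), 1L, zero_inflation) == 1L] <- 0L
    }
    base
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.matrix(mean_matrix)) {
    counts <- matrix(counts, nrow = nrow(mean_matrix),
                     dimnames = dimnames(mean_matrix))
  }
  counts
}

#' Simulate a spatial transcriptomics dataset with planted SVGs
#'
#' Lays out spots, plants `round(svg_fraction * n_genes)` spatially variable
#' genes whose mean surface is `base_mean` times a random [pattern_field()]
#' (non-SVGs have a flat mean), optionally perturbs log-means with Gaussian
#' noise, and draws counts from the configured distribution. SVG positions
#' within the gene list are randomised.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `dataset` (a [spatial_dataset] of raw counts) and
#'   `truth` (tibble: `gene_id`, `is_svg`, `pattern`, `effect`).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_spots = 100, n_genes = 50,
#'                                           seed = 7))
#' table(sim$truth$pattern)
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_svg <- round(cfg$svg_fraction * cfg$n_genes)
  if (n_svg < 1) abort("svg_fraction * n_genes must be at least 1.")
  withr::with_seed(cfg$seed, {
    coords <- spot_layout(cfg$n_spots, cfg$layout)
    gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
    svg_idx <- sort(sample.int(cfg$n_genes, n_svg))
    # largest-remainder split of the SVGs over the requested patterns
    props <- cfg$patterns
    base_cnt <- floor(props * n_svg)
    rem <- n_svg - sum(base_cnt)
    if (rem > 0) {
      extra <- order(props * n_svg - base_cnt, decreasing = TRUE)[seq_len(rem)]
      base_cnt[extra] <- base_cnt[extra] + 1
    }
    pat_lab <- rep(names(props), base_cnt)

    mu <- matrix(cfg$base_mean, cfg$n_genes, cfg$n_spots)
    for (s in seq_along(svg_idx)) {
      mu[svg_idx[s], ] <- cfg$base_mean *
        pattern_field(pat_lab[s], coords, cfg$fold_change)
    }
    if (cfg$noise_sd > 0) {
      mu <- exp(log(mu) + matrix(rnorm(length(mu), 0, cfg$noise_sd),
                                 nrow(mu), ncol(mu)))
    }
    counts <- sample_counts(mu, cfg$distribution, cfg$dispersion,
                            cfg$zero_inflation)
    rownames(counts) <- gene_id
    colnames(counts) <- sprintf("spot%05d", seq_len(cfg$n_spots))
    ds <- spatial_dataset(counts,
                          tibble(spot_id = colnames(counts),
                                 x = coords[, 1L], y = coords[, 2L]))
    truth <- tibble(gene_id = gene_id, is_svg = FALSE,
                    pattern = NA_character_, effect = 1)
    truth$is_svg[svg_idx] <- TRUE
    truth$pattern[svg_idx] <- pat_lab
    truth$effect[svg_idx] <- cfg$fold_change
    list(dataset = ds, truth = truth)
  })
}

spot_layout <- function(n, layout) {
  if (layout == "random") {
    return(cbind(runif(n), runif(n)))
  }
  nr <- floor(sqrt(n))
  nc <- ceiling(n / nr)
  g <- expand.grid(x = seq(0, 1, length.out = nc),
                   y = seq(0, 1, length.out = nr))
  as.matrix(g[seq_len(n), c("x", "y")])
}
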