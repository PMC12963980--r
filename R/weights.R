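#' Symmetric k-nearest-neighbour spatial weights
#'
#' Builds a binary spatial neighbourhood graph over spots: spot pairs are
#' connected when either is among the other's `k` nearest Euclidean
#' neighbours (symmetrisation by union). Distance ties are broken by spot
#' index, so the graph is fully deterministic. The default `k = 6`
#' approximates the degree of a hexagonal capture array.
#'
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   coordinate columns (a `spatial_dataset$coords` tibble also works).
#' @param k Number of neighbours, `1 <= k < N`.
#' @return An object of class `spatial_weights`: a list with the spot count
#'   `n` and an `edges` tibble of unordered pairs (`i < j`) with weight `w`.
#' @export
knn_weights <- function(coords, k = 6) {
  xy <- coords_matrix(coords)
  n <- nrow(xy)
  if (!is.numeric(k) || k < 1 || k >= n) {
    abort(sprintf("`k` must satisfy 1 <= k < N (got k = %s, N = %d).",
                  format(k), n))
  }
  k <- as.integer(k)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  nb <- apply(d, 1L, function(r) order(r)[seq_len(k)])  # ties: lowest index
  from <- rep(seq_len(n), each = k)
  to <- as.vector(nb)
  edges <- tibble(i = pmin(from, to), j = pmax(from, to))
  edges <- dplyr::distinct(edges)
  edges <- arrange(edges, .data$i, .data$j)
  edges$w <- 1
  structure(list(n = n, edges = edges, symmetric = TRUE, k = k),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d spots, %d undirected edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' Computes Moran's I over unordered neighbour pairs,
#' \deqn{I = \frac{n}{\sum_{i<j}\omega_{ij}} \cdot
#'   \frac{\sum_{i<j}\omega_{ij}(x_i-\bar x)(x_j-\bar x)}
#'        {\sum_i (x_i-\bar x)^2},}
#' which for symmetric weights equals the classical full double-sum form.
#' Under random relabelling of spots its expectation is \eqn{-1/(n-1)};
#' positive values indicate spatially clustered expression.
#'
#' @param x Numeric vector of per-spot values (non-constant).
#' @param w A [knn_weights()] object (or any `spatial_weights`).
#' @return Moran's I as a single number.
#' @export
morans_i <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(x) != w$n) abort("`x` must have one value per spot.")
  if (!all(is.finite(x))) abort("`x` must be finite.")
  if (nrow(w$edges) < 1L) abort("Weight object has an empty edge set.")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) abort("zero variance: `x` is constant.")
  num <- sum(w$edges$w * xc[w$edges$i] * xc[w$edges$j])
  (w$n / sum(w$edges$w)) * num / den
}

# Moran's I for every row of a genes-by-spots matrix; constant rows -> NA.
# Returns list(i = Moran's I, num = pair-sum numerator, den = centered SSQ).
moran_stat_rows <- function(expr, w) {
  xc <- expr - rowMeans(expr)
  den <- rowSums(xc^2)
  num <- moran_edge_num(xc, w$edges$i - 1L, w$edges$j - 1L, w$edges$w)
  i <- ifelse(den > 0, (w$n / sum(w$edges$w)) * num / den, NA_real_)
  list(i = i, num = num, den = den, constant = den == 0)
}

coords_matrix <- function(coords) {
  if (inherits(coords, "spatial_dataset")) coords <- coords$coords
  if (is.data.frame(coords)) {
    cols <- intersect(c("x", "y"), names(coords))
    coords <- if (length(cols) == 2L) coords[, cols] else coords[, 1:2]
  }
  xy <- as.matrix(coords)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) abort("Coordinates must have two columns.")
  if (!all(is.finite(xy))) abort("Coordinates must be finite.")
  unname(xy)
}
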