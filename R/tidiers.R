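#' Tidy and summarise result objects
#'
#' broom-style accessors: `tidy()` returns the per-gene table as a plain
#' tibble, `glance()` a one-row summary.
#'
#' @param x A `detector_result`, `ensemble_result` or `threshold_scan`.
#' @param ... Unused.
#' @name svgagg-tidiers
NULL

#' @rdname svgagg-tidiers
#' @export
tidy.detector_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @rdname svgagg-tidiers
#' @export
glance.detector_result <- function(x, ...) {
  tibble(method = x$method[1L], n_genes = nrow(x),
         n_selected = sum(x$selected),
         min_pvalue = suppressWarnings(min(x$pvalue, na.rm = TRUE)))
}

#' @rdname svgagg-tidiers
#' @export
tidy.ensemble_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "method") <- NULL
  attr(out, "params") <- NULL
  attr(out, "scan") <- NULL
  out
}

#' @rdname svgagg-tidiers
#' @export
glance.ensemble_result <- function(x, ...) {
  params <- attr(x, "params")
  out <- tibble(method = attr(x, "method"), n_genes = nrow(x),
                n_selected = sum(x$selected),
                n_methods = params$n_methods %||% NA_integer_)
  if (!is.null(params$t_star)) out$t_star <- params$t_star
  out
}

#' @rdname svgagg-tidiers
#' @export
tidy.threshold_scan <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "t_star") <- NULL
  attr(out, "lam") <- NULL
  attr(out, "m") <- NULL
  out
}

#' @rdname svgagg-tidiers
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble(t_star = attr(x, "t_star"), lam = attr(x, "lam"),
         m = attr(x, "m"),
         n_selected = x$o_count[x$t == attr(x, "t_star")])
}

#' Genes selected by a result
#'
#' @param x A `detector_result` or `ensemble_result`.
#' @return Character vector of selected gene ids.
#' @export
selected_genes <- function(x) x$gene_id[x$selected]
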