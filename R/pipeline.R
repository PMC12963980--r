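#' Assemble a pipeline run configuration
#'
#' A run configuration ties together an input (paths to an expression matrix
#' and coordinates, or a [simulation_config()]), the detectors to run, the
#' ensembles to aggregate with, optional evaluation inputs, and the output
#' directory and seed. [run_pipeline()] consumes it; [read_run_config()]
#' builds one from a YAML or JSON file with the same field names.
#'
#' @param input Either `list(expr_path =, coords_path =, orientation =)` or
#'   a `simulation_config`.
#' @param detectors Detector specs as in [run_detectors()].
#' @param ensembles Character subset of `c("rank_agg", "pval_agg",
#'   "fdpp_agg")`.
#' @param normalize Library-size normalize before detection (default `TRUE`;
#'   ignored for already-normalized inputs).
#' @param evaluation Optional `list(truth_path =, gene_sets_path =)`;
#'   simulated inputs carry their own truth.
#' @param output_dir Directory for result files, or `NULL` to skip writing.
#' @param seed Integer base seed (mandatory).
#' @param params Optional named list of ensemble parameters
#'   (`top_fraction`, `alpha`, `use_adjusted_inputs`, `lam`, `permute`).
#' @return A `run_config` list.
#' @export
run_config <- function(input, detectors = c("moran", "covariance", "moran_rank"),
                       ensembles = c("rank_agg", "pval_agg", "fdpp_agg"),
                       normalize = TRUE, evaluation = NULL,
                       output_dir = NULL, seed = 1, params = list()) {
  ensembles <- as.character(unlist(ensembles))
  ensembles <- match.arg(ensembles, c("rank_agg", "pval_agg", "fdpp_agg"),
                         several.ok = TRUE)
  if (!length(detectors)) abort("Need at least one detector.")
  if (!length(ensembles)) abort("Need at least one ensemble.")
  if (is.null(seed)) abort("`seed` is mandatory.")
  structure(list(input = input, detectors = detectors, ensembles = ensembles,
                 normalize = isTRUE(normalize), evaluation = evaluation,
                 output_dir = output_dir, seed = as.integer(seed),
                 params = params),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  input <- raw$input
  if (!is.null(input$simulation)) {
    input <- do.call(simulation_config, input$simulation)
  }
  run_config(input = input,
             detectors = raw$detectors %||% c("moran", "covariance", "moran_rank"),
             ensembles = raw$ensembles %||% c("rank_agg", "pval_agg", "fdpp_agg"),
             normalize = raw$normalize %||% TRUE,
             evaluation = raw$evaluation,
             output_dir = raw$output_dir,
             seed = raw$seed %||% abort("Config must set a seed."),
             params = raw$params %||% list())
}

#' Run the full detection-aggregation-evaluation pipeline
#'
#' Stages: load or simulate the dataset; optionally normalize; run all
#' detectors; aggregate with the requested ensembles (the frequency ensemble
#' re-runs the detectors on the augmented matrix); evaluate against truth
#' when available. When `output_dir` is set, per-detector and per-ensemble
#' TSVs, the threshold-scan diagnostic, an evaluation JSON and a manifest
#' recording all parameters and seeds are written there; re-running the same
#' configuration and seed reproduces the result files byte for byte.
#'
#' @param cfg A [run_config()] (or a path understood by
#'   [read_run_config()]).
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a list with `dataset`, `truth`, `detectors`,
#'   `ensembles`, `evaluation` (tibble or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(stage, ...) {
    if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(...)))
  }
  t0 <- Sys.time()
  truth <- NULL
  if (inherits(cfg$input, "simulation_config")) {
    cfg$input$seed <- cfg$seed
    sim <- simulate_dataset(cfg$input)
    ds <- sim$dataset
    truth <- sim$truth
    say("simulate", "%d genes x %d spots (%s)", n_genes(ds), n_spots(ds),
        cfg$input$distribution)
  } else {
    ds <- load_dataset(cfg$input$expr_path, cfg$input$coords_path,
                       cfg$input$orientation %||% "genes_by_spots")
    say("load", "%d genes x %d spots", n_genes(ds), n_spots(ds))
  }
  if (!is.null(cfg$evaluation$truth_path)) {
    truth <- read_delim_auto(cfg$evaluation$truth_path)
  }
  if (cfg$normalize && !ds$normalized) {
    ds <- normalize_dataset(ds)
    say("normalize", "median-library scaling + log1p")
  }

  detectors <- run_detectors(ds, cfg$detectors, seed = cfg$seed)
  say("detect", "%d detectors: %s", length(detectors),
      paste(names(detectors), collapse = ", "))

  p <- cfg$params
  ensembles <- list()
  for (e in cfg$ensembles) {
    ensembles[[e]] <- switch(e,
      rank_agg = rank_aggregate(detectors,
                                top_fraction = p$top_fraction %||% 0.1),
      pval_agg = {
        # rank-only methods carry no p-values; exclude them up front so the
        # aggregation runs on the p-valued subset without complaint
        has_p <- vapply(detectors, function(r) !all(is.na(r$pvalue)),
                        logical(1))
        pval_aggregate(detectors[has_p], alpha = p$alpha %||% 0.05,
                       use_adjusted_inputs =
                         p$use_adjusted_inputs %||% FALSE)
      },
      fdpp_agg = fdpp_aggregate(ds, cfg$detectors, lam = p$lam,
                                seed = cfg$seed,
                                permute = p$permute %||% "per_gene"))
    say("aggregate", "%s: %d genes selected", e,
        sum(ensembles[[e]]$selected))
  }

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate_run(detectors, ensembles, truth)
    say("evaluate", "%d method rows", nrow(evaluation))
  }

  manifest <- list(package = "svgagg",
                   version = as.character(packageVersion("svgagg")),
                   seed = cfg$seed, detectors = cfg$detectors,
                   ensembles = cfg$ensembles, normalize = cfg$normalize,
                   params = p,
                   input = if (inherits(cfg$input, "simulation_config"))
                     unclass(cfg$input) else cfg$input)

  if (!is.null(cfg$output_dir)) {
    write_run_outputs(cfg$output_dir, detectors, ensembles, evaluation,
                      manifest)
    say("write", "outputs in %s", cfg$output_dir)
  }
  say("done", "elapsed %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(dataset = ds, truth = truth, detectors = detectors,
                 ensembles = ensembles, evaluation = evaluation,
                 manifest = manifest))
}

# one metrics row per detector and ensemble, against a truth table
evaluate_run <- function(detectors, ensembles, truth) {
  stopifnot(all(c("gene_id", "is_svg") %in% names(truth)))
  rows <- list()
  for (nm in names(detectors)) {
    r <- detectors[[nm]]
    idx <- match(truth$gene_id, r$gene_id)
    sc <- if (all(is.na(r$pvalue[idx]))) r$statistic[idx] else -log10(
      pmax(r$pvalue[idx], 1e-300))
    rows[[nm]] <- mutate(confusion_metrics(r$selected[idx], truth$is_svg,
                                           scores = sc),
                         method = nm, kind = "detector")
  }
  for (nm in names(ensembles)) {
    r <- ensembles[[nm]]
    idx <- match(truth$gene_id, r$gene_id)
    rows[[nm]] <- mutate(confusion_metrics(r$selected[idx], truth$is_svg,
                                           scores = r$score[idx]),
                         method = nm, kind = "ensemble")
  }
  dplyr::relocate(bind_rows(rows), "method", "kind")
}

write_run_outputs <- function(dir, detectors, ensembles, evaluation,
                              manifest) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(detectors)) {
    readr::write_tsv(detectors[[nm]],
                     file.path(dir, paste0("detector_", nm, ".tsv")))
  }
  for (nm in names(ensembles)) {
    readr::write_tsv(as_tibble(ensembles[[nm]]),
                     file.path(dir, paste0("ensemble_", nm, ".tsv")))
    scan <- attr(ensembles[[nm]], "scan")
    if (!is.null(scan)) {
      readr::write_tsv(as_tibble(scan),
                       file.path(dir, "threshold_scan.tsv"))
    }
  }
  if (!is.null(evaluation)) {
    readr::write_tsv(evaluation, file.path(dir, "evaluation.tsv"))
    jsonlite::write_json(evaluation, file.path(dir, "evaluation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Sweep one simulation parameter
#'
#' Re-runs the pipeline over a grid of values for one
#' [simulation_config()] field, with `replicates` seeds per value
#' (`seed = base seed + replicate index`, so replicate r reuses the same
#' seed at every value and comparisons across the grid are paired), and
#' collects the evaluation metrics in long format. The summary table adds the mean and a normal-theory 95%
#' confidence interval (`mean +/- 1.96 * sd / sqrt(replicates)`) per
#' value-method cell.
#'
#' @param cfg A [run_config()] whose `input` is a `simulation_config`.
#' @param parameter Name of the simulation field to vary (e.g.
#'   `"fold_change"`, `"noise_sd"`, `"n_spots"`, `"svg_fraction"`).
#' @param values Vector of values for that field.
#' @param replicates Replicate runs per value.
#' @param quiet Suppress per-run messages (default `TRUE`).
#' @return A list with `runs` (one row per run x method) and `summary`
#'   (mean and CI per value x method x metric); both tibbles. Written as
#'   TSVs to `cfg$output_dir` when set.
#' @export
sweep_simulation <- function(cfg, parameter, values, replicates = 3,
                             quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  if (!inherits(cfg$input, "simulation_config")) {
    abort("Sweeps need a simulation input (ground truth is required).")
  }
  if (!parameter %in% names(cfg$input)) {
    abort(paste0("`", parameter, "` is not a simulation_config field."))
  }
  out_dir <- cfg$output_dir
  cfg$output_dir <- NULL
  runs <- list()
  idx <- 0L
  for (vi in seq_along(values)) {
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      cfg_i <- cfg
      cfg_i$input[[parameter]] <- values[[vi]]
      cfg_i$seed <- cfg$seed + r
      res <- run_pipeline(cfg_i, quiet = quiet)
      runs[[idx]] <- mutate(res$evaluation, parameter = parameter,
                            value = values[[vi]], replicate = r,
                            seed = cfg_i$seed)
    }
  }
  runs <- bind_rows(runs)
  summary <- runs |>
    tidyr::pivot_longer(cols = c("accuracy", "f1", "recall", "precision",
                                 "specificity", "mcc", "auc",
                                 "empirical_fdr"),
                        names_to = "metric", values_to = "x") |>
    group_by(.data$parameter, .data$value, .data$method, .data$kind,
             .data$metric) |>
    summarise(mean = mean(.data$x), sd = sd(.data$x), n = dplyr::n(),
              .groups = "drop") |>
    mutate(ci_lo = .data$mean - 1.96 * .data$sd / sqrt(.data$n),
           ci_hi = .data$mean + 1.96 * .data$sd / sqrt(.data$n))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(runs, file.path(out_dir, "sweep_runs.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "sweep_summary.tsv"))
  }
  list(runs = runs, summary = summary)
}
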