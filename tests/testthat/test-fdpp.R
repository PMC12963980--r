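test_that("augmentation doubles the gene set and preserves marginals", {
  ds <- toy_dataset(n_side = 8, n_null = 9)
  aug <- build_augmented(ds, seed = 6)
  expect_equal(n_genes(aug), 2 * n_genes(ds))
  expect_identical(aug$coords, ds$coords)
  expect_setequal(unique(aug$origin), c("original", "artificial"))
  for (g in gene_ids(ds)) {
    expect_equal(sort(aug$expr[paste0(g, "__art"), ]),
                 sort(ds$expr[g, ]), ignore_attr = TRUE)
  }
  expect_equal(aug$source_gene[["hot__art"]], "hot")
  # id collision with the suffix errors
  bad <- spatial_dataset(matrix(1:4 + 0, 2, 2,
                                dimnames = list(c("a", "a__art"),
                                                c("s1", "s2"))),
                         data.frame(spot_id = c("s1", "s2"), x = 0:1, y = 0:1))
  expect_error(build_augmented(bad), "collision")
  # determinism and the shared-permutation variant
  expect_identical(build_augmented(ds, seed = 6)$expr, aug$expr)
  sh <- build_augmented(ds, seed = 6, permute = "shared")
  art <- sh$expr[grepl("__art$", rownames(sh$expr)), ]
  expect_true(any(art != ds$expr))  # permuted ...
  expect_equal(unname(colSums(art) %in% colSums(ds$expr)),
               rep(TRUE, n_spots(ds)))  # ... by one shared spot shuffle
})

test_that("artificial genes carry no spatial autocorrelation on average", {
  withr::with_seed(13, {
    n <- 200
    expr <- matrix(rnbinom(500 * n, size = 5, mu = 3 * rexp(500 * n) + 0.5),
                   500, n, dimnames = list(sprintf("g%03d", 1:500),
                                           paste0("s", 1:n)))
    coords <- data.frame(spot_id = colnames(expr), x = runif(n), y = runif(n))
  })
  ds <- spatial_dataset(expr, coords)
  aug <- build_augmented(ds, seed = 20)
  w <- knn_weights(ds$coords, k = 6)
  art <- grepl("__art$", gene_ids(aug))
  ii <- vapply(which(art), function(i) morans_i(aug$expr[i, ], w), numeric(1))
  se <- sd(ii) / sqrt(length(ii))
  expect_lt(abs(mean(ii) - (-1 / (n - 1))), 3 * se)
})

test_that("selection frequencies match a hand-counted fixture", {
  genes <- paste0("g", 1:6)
  sel <- rbind(c(1, 1, 0, 0, 1, 0),
               c(1, 0, 0, 0, 1, 0),
               c(1, 1, 0, 0, 0, 0))
  results <- lapply(1:3, function(m) {
    detector_result(paste0("m", m), genes, pvalue = runif(6),
                    selected = as.logical(sel[m, ]))
  })
  fr <- selection_frequency(results)
  expect_equal(fr$frequency, c(3, 2, 0, 0, 2, 0) / 3)
  # mismatched universes error
  bad <- detector_result("m4", c("g1", "g7"), pvalue = c(.1, .2))
  expect_error(selection_frequency(c(results, list(bad))), "universes")
})

test_that("the FDP proxy evaluates to its printed values", {
  mk <- function(o_over, a_over, o_under = 5, a_under = 5) {
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(o_over + a_over + o_under + a_under)),
      frequency = c(rep(0.9, o_over + a_over), rep(0.1, o_under + a_under)),
      origin = c(rep("original", o_over), rep("artificial", a_over),
                 rep("original", o_under), rep("artificial", a_under)))
  }
  expect_equal(fdp_plus(mk(10, 0), 0.5), 0.1)   # (1+0)/10
  expect_equal(fdp_plus(mk(0, 3), 0.5), 4)      # max operator in denominator
  expect_equal(fdp_plus(mk(30, 2), 0.5), 0.1)   # (1+2)/30
  expect_error(fdp_plus(mk(1, 1), 1), "\\[0, 1\\)")
})

test_that("threshold choice equals brute-force argmin with the stated tie rule", {
  # all originals at f = 1, all artificial at 0, lambda = 0:
  # objective constant over the grid -> tie broken to the largest t
  fr <- tibble::tibble(gene_id = paste0("g", 1:20),
                       frequency = rep(c(1, 0), each = 10),
                       origin = rep(c("original", "artificial"), each = 10))
  sc <- choose_threshold(fr, lam = 0, m = 3)
  expect_equal(t_star(sc), 2 / 3)
  expect_equal(sc$objective, rep(1 / 10, 3))

  # 20 originals at 1, 20 originals at 1/3, 40 artificial at <= 1/3:
  # both t = 1/3 and t = 2/3 admit exactly the 20 strong genes and tie on
  # the objective, so the tie rule lands on 2/3 — the selected set is the
  # 20 strong genes either way
  fr2 <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:80),
    frequency = c(rep(1, 20), rep(1 / 3, 20), rep(c(0, 1 / 3), 20)),
    origin = c(rep("original", 40), rep("artificial", 40)))
  sc2 <- choose_threshold(fr2, lam = 1e-3, m = 3)
  expect_equal(sc2$objective[2], sc2$objective[3])
  expect_equal(t_star(sc2), 2 / 3)
  expect_equal(sc2$o_count[sc2$t == t_star(sc2)], 20)
  expect_setequal(fr2$gene_id[fr2$origin == "original" &
                                fr2$frequency > t_star(sc2)],
                  sprintf("g%03d", 1:20))

  # counts are non-increasing in t and the proxy respects its lower bound
  expect_true(all(diff(sc2$a_count) <= 0) && all(diff(sc2$o_count) <= 0))
  expect_true(all(sc2$fdp_plus >= 1 / pmax(sc2$o_count, 1)))

  # random fixtures against the exhaustive oracle
  withr::with_seed(44, {
    for (rep in 1:50) {
      m <- sample(2:6, 1)
      ng <- sample(10:60, 1)
      fr3 <- tibble::tibble(
        gene_id = sprintf("g%03d", seq_len(ng)),
        frequency = sample(0:m, ng, replace = TRUE) / m,
        origin = sample(c("original", "artificial"), ng, replace = TRUE))
      lam <- sample(c(0, 1e-3, 0.05), 1)
      expect_equal(t_star(choose_threshold(fr3, lam, m)),
                   bf_choose_t(fr3$frequency, fr3$origin, lam, m))
    }
  })
})

test_that("frequency ensemble is reproducible and never reports controls", {
  ds <- toy_dataset(n_side = 10, n_null = 24)
  specs <- list(list(name = "moran", k = 8, n_perm = 99), "covariance",
                list(name = "moran_rank", k = 8))
  res <- fdpp_aggregate(ds, specs, seed = 5)
  res2 <- fdpp_aggregate(ds, specs, seed = 5)
  expect_identical(tidy(res), tidy(res2))
  expect_false(any(res$selected[res$origin == "artificial"]))
  expect_true(all(res$score >= 0 & res$score <= 1))
  expect_warning(fdpp_aggregate(ds, list("covariance"), seed = 1),
                 "single method")
})

test_that("a pattern-free dataset yields (near) zero consensus selections", {
  withr::with_seed(70, {
    n <- 150
    expr <- matrix(rpois(300 * n, 2), 300, n,
                   dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:n)))
    coords <- data.frame(spot_id = colnames(expr), x = runif(n), y = runif(n))
  })
  ds <- normalize_dataset(spatial_dataset(expr, coords))
  res <- fdpp_aggregate(ds, list(list(name = "moran", k = 8, n_perm = 199),
                                 "covariance"),
                        seed = 2)
  expect_lte(sum(res$selected), 3)
  # a rank-only member nominates its top fraction regardless of signal, so
  # on signal-free data any nonempty rung carries an honest, high FDP
  # estimate in the scan diagnostic
  res3 <- fdpp_aggregate(ds, list(list(name = "moran", k = 8, n_perm = 199),
                                  "covariance",
                                  list(name = "moran_rank", k = 8)),
                         seed = 2)
  scan <- attr(res3, "scan")
  if (sum(res3$selected) > 0) {
    expect_gte(scan$fdp_plus[scan$t == t_star(scan)], 0.5)
  }
})

test_that("strong planted signal is recovered with controlled FDR", {
  specs <- list(list(name = "moran", n_perm = 499), "covariance", "moran_rank")
  fdr <- rec <- c()
  for (seed in 1:2) {
    sim <- simulate_dataset(simulation_config(
      n_spots = 700, n_genes = 600, svg_fraction = 0.1, fold_change = 5,
      zero_inflation = 0.2, seed = seed))
    ds <- normalize_dataset(sim$dataset)
    res <- fdpp_aggregate(ds, specs, seed = seed + 50)
    idx <- match(sim$truth$gene_id, res$gene_id)
    ev <- confusion_metrics(res$selected[idx], sim$truth$is_svg)
    fdr <- c(fdr, ev$empirical_fdr); rec <- c(rec, ev$recall)
  }
  expect_lte(mean(fdr), 0.10)
  expect_gte(mean(rec), 0.9)
})
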