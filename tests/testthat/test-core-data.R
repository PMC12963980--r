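test_that("dense CSV loading honours both orientations and the shape contract", {
  dir <- withr::local_tempdir()
  expr <- matrix(c(1, 0, 3, 4, 2, 0, 1, 5, 0, 0, 2, 7), nrow = 3, byrow = TRUE,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  coords <- data.frame(spot_id = paste0("s", 1:4),
                       x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  readr::write_csv(tibble::as_tibble(expr, rownames = "gene_id"),
                   file.path(dir, "expr.csv"))
  readr::write_csv(coords, file.path(dir, "coords.csv"))
  ds <- load_dataset(file.path(dir, "expr.csv"), file.path(dir, "coords.csv"))
  expect_equal(n_genes(ds), 3)
  expect_equal(n_spots(ds), 4)
  expect_false(ds$normalized)
  expect_equal(unname(ds$expr), unname(expr))

  # the same matrix stored spots-by-genes round-trips to an identical dataset
  readr::write_csv(tibble::as_tibble(t(expr), rownames = "spot_id"),
                   file.path(dir, "exprT.csv"))
  dsT <- load_dataset(file.path(dir, "exprT.csv"), file.path(dir, "coords.csv"),
                      orientation = "spots_by_genes")
  expect_identical(ds$expr, dsT$expr)
  expect_identical(ds$coords, dsT$coords)
})

test_that("loader errors name the offending spot and reject bad inputs", {
  dir <- withr::local_tempdir()
  expr <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  readr::write_csv(tibble::as_tibble(expr, rownames = "gene_id"),
                   file.path(dir, "expr.csv"))
  readr::write_csv(data.frame(spot_id = c("s1", "s2"), x = 1:2, y = 1:2),
                   file.path(dir, "coords_short.csv"))
  expect_error(load_dataset(file.path(dir, "expr.csv"),
                            file.path(dir, "coords_short.csv")),
               "s3")
  dup <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g1"), c("s1", "s2", "s3")))
  expect_error(spatial_dataset(dup, data.frame(spot_id = paste0("s", 1:3),
                                               x = 1:3, y = 1:3)),
               "Duplicate gene")
  expect_error(spatial_dataset(expr, data.frame(spot_id = paste0("s", 1:3),
                                                x = c("a", "b", "c"), y = 1:3)),
               "finite")
})

test_that("MTX with sidecars loads as genes-by-spots", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(matrix(c(0, 2, 1, 0, 0, 3), 2, 3), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "expr.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  writeLines(c("s1", "s2", "s3"), file.path(dir, "barcodes.tsv"))
  readr::write_tsv(data.frame(spot_id = c("s1", "s2", "s3"),
                              x = c(0, 1, 2), y = c(0, 0, 0)),
                   file.path(dir, "coords.tsv"))
  ds <- load_dataset(file.path(dir, "expr.mtx"), file.path(dir, "coords.tsv"))
  expect_equal(dim(ds$expr), c(2L, 3L))
  expect_equal(ds$expr["g2", "s3"], 3)
})

test_that("write/load round-trip preserves ids exactly and values to 1e-12", {
  dir <- withr::local_tempdir()
  withr::with_seed(9, {
    expr <- matrix(rexp(30) * 10, 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    coords <- data.frame(spot_id = paste0("s", 1:6), x = runif(6), y = runif(6))
  })
  ds <- spatial_dataset(expr, coords)
  write_dataset(ds, file.path(dir, "e.tsv"), file.path(dir, "c.tsv"))
  ds2 <- load_dataset(file.path(dir, "e.tsv"), file.path(dir, "c.tsv"))
  expect_identical(gene_ids(ds2), gene_ids(ds))
  expect_identical(ds2$coords$spot_id, ds$coords$spot_id)
  expect_equal(ds2$coords$x, ds$coords$x, tolerance = 1e-12)
  expect_equal(ds2$expr, ds$expr, tolerance = 1e-12)
})

test_that("normalization rescales spots, preserves zeros and flags the dataset", {
  expr <- matrix(c(1, 1, 2,  2, 0, 0,  3, 1, 0), nrow = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  coords <- data.frame(spot_id = paste0("s", 1:3), x = 1:3, y = rep(0, 3))
  ds <- spatial_dataset(expr, coords)
  # column already summing to the target is untouched
  out <- normalize_dataset(ds, target_sum = 4, log1p = FALSE)
  expect_equal(unname(out$expr[, 1]), c(1, 1, 2))
  expect_true(out$normalized)
  # [2, 0] scaled to total 10 -> [10, 0]
  ds2 <- spatial_dataset(matrix(c(2, 0, 2, 2), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         data.frame(spot_id = c("s1", "s2"), x = 0:1, y = 0:1))
  out2 <- normalize_dataset(ds2, target_sum = 10, log1p = FALSE)
  expect_equal(unname(out2$expr[, "s1"]), c(10, 0))
  # log1p variant: [3, 1] to total 4 -> log(4), log(2)
  ds3 <- spatial_dataset(matrix(c(3, 1, 1, 1), 2, 2,
                                dimnames = list(c("a", "b"), c("s1", "s2"))),
                         data.frame(spot_id = c("s1", "s2"), x = 0:1, y = 0:1))
  out3 <- normalize_dataset(ds3, target_sum = 4, log1p = TRUE)
  expect_equal(unname(out3$expr[, "s1"]), c(log(4), log(2)))
  # zero pattern preserved under the default (median target) normalization
  expect_identical(normalize_dataset(ds)$expr == 0, ds$expr == 0)
  # zero-total spot is named in the error
  zero <- spatial_dataset(matrix(c(1, 1, 0, 0), 2, 2,
                                 dimnames = list(c("a", "b"), c("s1", "sBAD"))),
                          data.frame(spot_id = c("s1", "sBAD"), x = 0:1, y = 0:1))
  expect_error(normalize_dataset(zero), "sBAD")
})

test_that("external result tables rank by the best available metric", {
  dir <- withr::local_tempdir()
  tab <- data.frame(gene_id = paste0("g", 1:5),
                    pvalue = c(.001, .2, .03, .9, .04))
  readr::write_csv(tab, file.path(dir, "res.csv"))
  r <- read_external_result(file.path(dir, "res.csv"), "toolA")
  expect_equal(r$rank, c(1, 4, 2, 5, 3))
  expect_equal(r$method[1], "toolA")
  expect_false(any(r$selected))  # no adjusted p-values -> nothing selected

  # statistic-only table: |statistic| descending
  readr::write_csv(data.frame(gene = c("a", "b", "c"),
                              statistic = c(5, -7, 1)),
                   file.path(dir, "stat.csv"))
  r2 <- read_external_result(file.path(dir, "stat.csv"), "toolB")
  expect_equal(r2$rank, c(2, 1, 3))

  # out-of-range p-value and missing metric column both error
  readr::write_csv(data.frame(gene_id = "g1", pvalue = 1.2),
                   file.path(dir, "bad.csv"))
  expect_error(read_external_result(file.path(dir, "bad.csv"), "x"),
               "\\[0, 1\\]")
  readr::write_csv(data.frame(gene_id = "g1", note = "hi"),
                   file.path(dir, "none.csv"))
  expect_error(read_external_result(file.path(dir, "none.csv"), "x"),
               "No statistic")
})

test_that("external ranks are invariant to the row order of the file", {
  dir <- withr::local_tempdir()
  withr::with_seed(11, {
    tab <- data.frame(gene_id = paste0("g", 1:30), pvalue = runif(30))
  })
  readr::write_csv(tab, file.path(dir, "a.csv"))
  readr::write_csv(tab[sample(30), ], file.path(dir, "b.csv"))
  ra <- read_external_result(file.path(dir, "a.csv"), "m")
  rb <- read_external_result(file.path(dir, "b.csv"), "m")
  rb <- rb[match(ra$gene_id, rb$gene_id), ]
  expect_equal(ra$rank, rb$rank)
})

test_that("missing genes get worst rank after alignment", {
  r1 <- detector_result("a", c("g1", "g2", "g3"), pvalue = c(.01, .5, .2),
                        pvalue_adj = c(.03, .6, .3))
  r2 <- detector_result("b", c("g1", "g3"), pvalue = c(.2, .01),
                        pvalue_adj = c(.2, .02))
  al <- align_results(list(r1, r2), universe = c("g1", "g2", "g3"))
  expect_equal(al$b$rank[al$b$gene_id == "g2"], 3)
  expect_false(al$b$selected[al$b$gene_id == "g2"])
  expect_true(is.na(al$b$pvalue[al$b$gene_id == "g2"]))
})
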