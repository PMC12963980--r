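# Independent brute-force oracles used to verify the package's statistics.
# These deliberately re-derive everything from first principles (double
# sums, exhaustive enumeration, direct counting) and share no code with the
# implementation under test.

# classical Moran's I: full double sum over ordered pairs i != j
bf_morans_i <- function(x, wmat) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && wmat[i, j] != 0) {
        num <- num + wmat[i, j] * xc[i] * xc[j]
        s0 <- s0 + wmat[i, j]
      }
    }
  }
  (n / s0) * num / sum(xc^2)
}

# dense symmetric weight matrix from a spatial_weights object
weights_matrix <- function(w) {
  m <- matrix(0, w$n, w$n)
  for (e in seq_len(nrow(w$edges))) {
    i <- w$edges$i[e]; j <- w$edges$j[e]
    m[i, j] <- m[i, j] + w$edges$w[e]
    m[j, i] <- m[j, i] + w$edges$w[e]
  }
  m
}

# all permutations of 1..n (n <= 7), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# step-up Benjamini-Yekutieli from the printed definition
bf_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  q <- p[ord] * m * cm / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# confusion counts by direct enumeration
bf_confusion <- function(selected, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(selected)) {
    if (selected[i] && truth[i]) tp <- tp + 1
    else if (selected[i] && !truth[i]) fp <- fp + 1
    else if (!selected[i] && truth[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# exhaustive objective scan for the frequency threshold
bf_choose_t <- function(freq, origin, lam, m) {
  grid <- (seq_len(m) - 1) / m
  obj <- vapply(grid, function(t) {
    a <- sum(origin == "artificial" & freq > t + 1e-9)
    o <- sum(origin == "original" & freq > t + 1e-9)
    (1 + a) / max(o, 1) + lam * a
  }, numeric(1))
  grid[max(which(obj <= min(obj) + 1e-12))]
}

# small deterministic dataset on a grid with one strong hotspot gene
toy_dataset <- function(n_side = 12, n_null = 20, seed = 42) {
  withr::with_seed(seed, {
    g <- expand.grid(x = seq(0, 1, length.out = n_side),
                     y = seq(0, 1, length.out = n_side))
    n <- nrow(g)
    bump <- exp(-((g$x - 0.5)^2 + (g$y - 0.5)^2) / (2 * 0.15^2))
    expr <- rbind(hot = rpois(n, 2 * (1 + 4 * bump)),
                  matrix(rpois(n_null * n, 2), n_null, n))
    rownames(expr) <- c("hot", paste0("null", seq_len(n_null)))
    colnames(expr) <- paste0("s", seq_len(n))
    spatial_dataset(expr, data.frame(spot_id = colnames(expr),
                                     x = g$x, y = g$y))
  })
}
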