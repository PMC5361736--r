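# Fixture generators and independent brute-force oracles used across the
# suite.  Oracles deliberately share no code with the package's fast paths.

rand_genotypes <- function(n, m, maf = NULL, seed = NULL) {
  knnmdr:::local_seed(seed, {
    p <- if (is.null(maf)) runif(m, 0.1, 0.5) else rep_len(maf, m)
    g <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
    if (!is.matrix(g)) g <- matrix(g, nrow = n)
    rownames(g) <- sprintf("ind%03d", seq_len(n))
    colnames(g) <- sprintf("snp%03d", seq_len(m))
    storage.mode(g) <- "integer"
    g
  })
}

# squared distance by explicit double loop over individual pairs
oracle_dist2 <- function(g, cols, weights = NULL) {
  n <- nrow(g)
  v <- apply(g[, cols, drop = FALSE], 2, var)
  w <- if (is.null(weights)) rep(1, length(cols)) else weights
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_along(cols)) {
      if (v[k] > 0) {
        s <- s + w[k] * (g[i, cols[k]] - g[j, cols[k]])^2 / v[k]
      }
    }
    d2[i, j] <- s
  }
  d2
}

# full Mahalanobis quadratic form, no shortcuts
oracle_mahal2 <- function(g, cols, ridge = 0) {
  x <- g[, cols, drop = FALSE]
  storage.mode(x) <- "double"
  v <- apply(x, 2, var)
  x <- x[, v > 0, drop = FALSE]
  x <- sweep(x, 2, sqrt(apply(x, 2, var)), `/`)
  C <- cor(x) + diag(ridge, ncol(x))
  Ci <- solve(C)
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dd <- x[i, ] - x[j, ]
    d2[i, j] <- drop(t(dd) %*% Ci %*% dd)
  }
  d2
}

# exhaustive-sort KNN vote with nearest-neighbour tie break
oracle_knn <- function(d2, train, test, status, K) {
  vapply(test, function(i) {
    ord <- train[order(d2[train, i], train)]
    nn <- ord[seq_len(K)]
    votes <- sum(status[nn])
    if (2 * votes > K) 1L
    else if (2 * votes < K) 0L
    else as.integer(status[nn[1L]])
  }, 0L)
}

# explicit per-cell tally MDR
oracle_mdr <- function(g, markers, train, test, status) {
  key <- function(i) paste(g[i, markers], collapse = "/")
  tk <- vapply(train, key, "")
  all_case <- sum(status[train] == 1)
  all_ctrl <- sum(status[train] == 0)
  vapply(test, function(i) {
    in_cell <- train[tk == key(i)]
    if (length(in_cell) == 0L) return(NA_integer_)
    ca <- sum(status[in_cell] == 1)
    co <- sum(status[in_cell] == 0)
    if (ca * all_ctrl > co * all_case) 1L else 0L
  }, 0L)
}

# frequency-weighted marginal penetrance by explicit summation over the
# full multi-locus genotype grid
oracle_marginals <- function(pt) {
  G <- pt$G
  grid <- as.matrix(expand.grid(rep(list(1:3), G)))
  out <- matrix(0, G, 3)
  for (i in seq_len(G)) for (k in 1:3) {
    rows <- grid[grid[, i] == k, , drop = FALSE]
    tot <- 0
    for (r in seq_len(nrow(rows))) {
      w <- 1
      for (j in seq_len(G)[-i]) w <- w * pt$genotype_freqs[j, rows[r, j]]
      tot <- tot + w * pt$MP[matrix(rows[r, ], 1)]
    }
    out[i, k] <- tot
  }
  out
}

# two perfectly-separating windows: phenotype is the XOR of two pseudo-SNP
# haplotype patterns, each repeated across all markers of its window; the
# remaining windows are noise.  Pure epistasis: either causal window alone
# carries no information (each of its two genotype groups is half case,
# half control), but the window pair separates the classes exactly.
xor_dataset <- function(n_per_cell = 20, window_size = 5, n_windows = 4,
                        seed = 1) {
  knnmdr:::local_seed(seed, {
    n <- 4L * n_per_cell
    a <- rep(c(0L, 0L, 2L, 2L), each = n_per_cell)
    b <- rep(c(0L, 2L, 0L, 2L), each = n_per_cell)
    y <- as.integer(xor(a == 2L, b == 2L))
    m <- window_size * n_windows
    g <- rand_genotypes(n, m, seed = NULL)
    g[, seq_len(window_size)] <- a                  # window 1
    g[, window_size + seq_len(window_size)] <- b    # window 2
    perm <- sample.int(n)
    list(genotypes = g[perm, , drop = FALSE], status = y[perm])
  })
}
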