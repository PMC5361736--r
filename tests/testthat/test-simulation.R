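test_that("base panel respects the MAF floor and is reproducible", {
  p <- simulate_base_panel(n_founders = 80, n_markers = 150, maf_min = 0.3,
                           rho = 0.5, seed = 1)
  expect_equal(dim(p$genotypes), c(80L, 150L))
  expect_true(all(minor_allele_frequencies(p$genotypes) >= 0.3))
  expect_true(all(p$genotypes %in% 0:2))
  expect_equal(colSums(p$genotype_freqs), rep(1, 150))
  p2 <- simulate_base_panel(n_founders = 80, n_markers = 150, maf_min = 0.3,
                            rho = 0.5, seed = 1)
  expect_identical(p$genotypes, p2$genotypes)
  expect_error(simulate_base_panel(maf_min = 0.6), "maf_min")
})

test_that("rho controls adjacent-marker linkage disequilibrium", {
  adj_r2 <- function(rho, seed) {
    p <- simulate_base_panel(n_founders = 400, n_markers = 80, maf_min = 0.3,
                             rho = rho, seed = seed)
    g <- p$genotypes
    mean(vapply(seq_len(ncol(g) - 1),
                function(m) cor(g[, m], g[, m + 1])^2, 0))
  }
  r2_0 <- vapply(1:5, function(s) adj_r2(0, s), 0)
  r2_9 <- vapply(1:5, function(s) adj_r2(0.9, s + 10), 0)
  # independence limit: r^2 ~ 1/n_founders
  expect_lt(mean(r2_0), 0.01)
  expect_gt(mean(r2_9), 10 * mean(r2_0))
})

test_that("block resampling copies founder blocks and conserves within-block LD", {
  # a single-founder "panel" makes every resampled individual a copy
  one <- list(genotypes = rand_genotypes(1, 30, seed = 2))
  g <- resample_individuals(one, block_size = 10, n_individuals = 5, seed = 3)
  expect_true(all(apply(g, 2, function(col) length(unique(col)) == 1)))

  panel <- simulate_base_panel(n_founders = 100, n_markers = 100, maf_min = 0.3,
                               rho = 0.8, seed = 4)
  within <- numeric(0); across <- numeric(0)
  for (s in 1:5) {
    gg <- resample_individuals(panel, block_size = 10, n_individuals = 400,
                               seed = 40 + s)
    for (m in seq_len(99)) {
      r2 <- cor(gg[, m], gg[, m + 1])^2
      if (m %% 10 == 0) across <- c(across, r2) else within <- c(within, r2)
    }
  }
  expect_gt(mean(within), mean(across))
})

test_that("penetrance tables have exactly zero marginal effects", {
  # oracle check at G = 2 with Hardy-Weinberg frequencies
  pt <- build_penetrance_table(2, prevalence = 0.5, effect_size = 0.4, seed = 1)
  expect_equal(oracle_marginals(pt), matrix(0.5, 2, 3), tolerance = 1e-12)
  expect_gt(var(as.vector(pt$MP)), 0)
  expect_equal(pt$effect_size, 0.4, tolerance = 1e-12)
  expect_true(all(pt$MP >= 0 & pt$MP <= 1))

  # random frequencies, higher orders
  for (s in 1:10) {
    freqs <- knnmdr:::local_seed(s, {
      f <- matrix(runif(9, 0.05, 1), 3, 3)
      f / rowSums(f)
    })
    pt3 <- build_penetrance_table(3, prevalence = 0.4, genotype_freqs = freqs,
                                  effect_size = 0.3, seed = s)
    expect_lt(max(abs(oracle_marginals(pt3) - 0.4)), 1e-10)
    expect_gt(var(as.vector(pt3$MP)), 0)
  }
})

test_that("the product pattern is deterministic, zero-marginal and maximal", {
  freqs <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3))
  pt <- build_penetrance_table(2, prevalence = 0.5, genotype_freqs = freqs,
                               effect_size = 0.4, pattern = "product")
  pt2 <- build_penetrance_table(2, prevalence = 0.5, genotype_freqs = freqs,
                                effect_size = 0.4, pattern = "product")
  expect_identical(pt$MP, pt2$MP)  # no RNG involved
  expect_equal(oracle_marginals(pt), matrix(0.5, 2, 3), tolerance = 1e-12)
  expect_equal(max(abs(pt$MP - 0.5)), 0.4)
  # rank-1 structure: the deviation is an outer product
  E <- pt$MP - 0.5
  expect_equal(qr(E)$rank, 1)
})

test_that("G = 1 only admits the constant table", {
  pt <- build_penetrance_table(1, prevalence = 0.3, effect_size = 0)
  expect_equal(as.vector(pt$MP), rep(0.3, 3))
  expect_error(build_penetrance_table(1, effect_size = 0.2), "constant")
})

test_that("over-large effect sizes are clipped into [0, 1] with a warning", {
  expect_warning(
    pt <- build_penetrance_table(2, prevalence = 0.1, effect_size = 0.5,
                                 seed = 2),
    "clipped")
  expect_true(all(pt$MP >= 0 & pt$MP <= 1))
  expect_lt(pt$effect_size, 0.5)
  expect_lt(max(abs(penetrance_marginals(pt) - 0.1)), 1e-10)
})

test_that("phenotype assignment follows the penetrance table", {
  g <- rand_genotypes(20000, 2, maf = 0.3, seed = 5)
  pt <- build_penetrance_table(2, prevalence = 0.5, effect_size = 0.45, seed = 6)
  ph <- assign_phenotypes(g, c(1L, 2L), pt, seed = 7)
  # per-cell affected fractions converge to the table values
  cells <- interaction(g[, 1], g[, 2])
  dev <- vapply(levels(cells), function(lv) {
    ix <- cells == lv
    k <- as.integer(strsplit(lv, ".", fixed = TRUE)[[1]]) + 1L
    mp <- pt$MP[k[1], k[2]]
    (mean(ph[ix]) - mp) / sqrt(max(mp * (1 - mp), 1e-4) / sum(ix))
  }, 0)
  expect_lt(max(abs(dev)), 4)

  pt1 <- pt; pt1$MP[] <- 1
  expect_equal(sum(assign_phenotypes(g, c(1L, 2L), pt1, seed = 1)), 20000L)
  pt0 <- pt; pt0$MP[] <- 0
  expect_equal(sum(assign_phenotypes(g, c(1L, 2L), pt0, seed = 1)), 0L)
})

test_that("thinning keeps one marker of each consecutive pair", {
  g <- rand_genotypes(10, 100, seed = 8)
  th <- thin_markers(g, seed = 9)
  expect_equal(ncol(th$genotypes), 50)
  expect_true(all(ceiling(th$kept / 2) == 1:50))
  th2 <- thin_markers(g, seed = 9)
  expect_identical(th$kept, th2$kept)
  # odd marker count: last marker always kept
  th3 <- thin_markers(g[, 1:7], seed = 10)
  expect_equal(ncol(th3$genotypes), 4)
  expect_equal(th3$kept[4], 7L)
  # each marker survives about half of the time
  surv <- mean(vapply(1:200, function(s) 7L %in% thin_markers(g, seed = s)$kept,
                      TRUE))
  expect_gt(surv, 0.35)
  expect_lt(surv, 0.65)
})

test_that("simulate_dataset meets quotas, reproduces and records truth", {
  ds <- simulate_dataset(G = 2, n_cases = 120, n_controls = 120,
                         n_markers = 200, n_founders = 60, thin = TRUE,
                         effect_size = 0.5, seed = 11)
  expect_equal(sum(ds$phenotypes == 1), 120)
  expect_equal(sum(ds$phenotypes == 0), 120)
  expect_equal(ncol(ds$genotypes), 100)
  expect_equal(nrow(ds$map), 100)
  expect_equal(length(ds$truth$causal_index), 2)
  post <- ds$truth$causal_post_thin
  kept <- ds$truth$kept
  for (i in 1:2) {
    if (!is.na(post[i])) {
      expect_equal(kept[post[i]], ds$truth$causal_index[i])
    } else {
      expect_false(ds$truth$causal_index[i] %in% kept)
    }
  }
  ds2 <- simulate_dataset(G = 2, n_cases = 120, n_controls = 120,
                          n_markers = 200, n_founders = 60, thin = TRUE,
                          effect_size = 0.5, seed = 11)
  expect_identical(ds$genotypes, ds2$genotypes)
  expect_identical(ds$phenotypes, ds2$phenotypes)
})

test_that("G = 0 gives a causal-free coin-flip design", {
  ds <- simulate_dataset(G = 0, n_cases = 150, n_controls = 150,
                         n_markers = 100, n_founders = 50, thin = FALSE,
                         seed = 12)
  expect_equal(length(ds$truth$causal_index), 0)
  expect_null(ds$truth$penetrance)
  expect_equal(sum(ds$phenotypes), 150)
})

test_that("causal SNPs show no marginal association (single-SNP test is null)", {
  pvals <- vapply(1:60, function(s) {
    # causal SNPs fixed in different LD blocks: the marginal-null constraint
    # is built on per-locus frequencies, so it is exact only across blocks
    ds <- simulate_dataset(G = 2, n_cases = 100, n_controls = 100,
                           n_markers = 60, n_founders = 120, block_size = 10,
                           thin = FALSE, effect_size = 0.5,
                           causal_markers = c(5L, 35L), seed = 7000 + s)
    m <- ds$truth$causal_index[1]
    tab <- table(factor(ds$genotypes[, m], levels = 0:2), ds$phenotypes)
    suppressWarnings(chisq.test(tab)$p.value)
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals > 0.05), 0.8)
})
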