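test_that("knn_predict follows definition, majority and tie contracts", {
  # line geometry: coordinates 0,1,2,3,10; squared distances
  x <- c(0, 1, 2, 3, 10)
  d2 <- outer(x, x, function(a, b) (a - b)^2)
  status <- c(1L, 1L, 0L, 0L, 1L)
  # K = 1: nearest training individual's status
  expect_equal(knn_predict(d2, train = c(1, 3), test = c(2, 4), status, K = 1),
               c(1L, 0L))
  # K = 3 majority: neighbours of 5 among 1:4 are 4, 3, 2 -> control
  expect_equal(knn_predict(d2, train = 1:4, test = 5, status, K = 3), 0L)
  # K = 2 vote tie: nearest neighbour breaks by default
  expect_equal(knn_predict(d2, train = c(2, 3), test = 1, status, K = 2), 1L)
  expect_equal(knn_predict(d2, train = c(2, 3), test = 1, status, K = 2,
                           tie_rule = "control_wins"), 0L)
  expect_equal(knn_predict(d2, train = c(2, 3), test = 1, status, K = 2,
                           tie_rule = "case_wins"), 1L)
  expect_error(knn_predict(d2, train = 1:2, test = 3, status, K = 5), "exceeds")
  expect_error(knn_predict(d2, train = 1:3, test = 3, status, K = 1), "disjoint")
  expect_equal(knn_predict(d2, train = 1:4, test = integer(0), status, K = 2),
               integer(0))
})

test_that("knn_predict matches the exhaustive-sort oracle on random instances", {
  for (seed in 1:5) {
    g <- rand_genotypes(30, 10, seed = seed)
    d2 <- window_squared_distances(g, 1:10)
    status <- knnmdr:::local_seed(seed, sample(c(0L, 1L), 30, TRUE))
    train <- 1:20
    test <- 21:30
    expect_equal(knn_predict(d2, train, test, status, K = 5),
                 oracle_knn(d2, train, test, status, K = 5))
  }
})

test_that("knn_predict is equivariant under relabelling of individuals", {
  g <- rand_genotypes(24, 8, seed = 11)
  # jitter by row-specific noise through a continuous transform: use the
  # raw distances (generic, no exact ties across distinct pairs expected)
  d2 <- window_squared_distances(g, 1:8) +
    outer(seq_len(24) * 1e-9, seq_len(24) * 1e-9, `+`)
  diag(d2) <- 0
  status <- rep(c(1L, 0L), 12)
  perm <- knnmdr:::local_seed(2, sample.int(24))
  pred <- knn_predict(d2, 1:16, 17:24, status, K = 3)
  inv <- order(perm)
  pred_p <- knn_predict(d2[perm, perm], inv[1:16], inv[17:24], status[perm], K = 3)
  expect_equal(pred_p, pred)
})

test_that("mdr_predict labels cells against the training ratio and flags unseen cells", {
  g <- cbind(s1 = c(0L, 0L, 0L, 1L, 1L, 2L))
  rownames(g) <- sprintf("i%d", 1:6)
  status <- c(1L, 1L, 0L, 0L, 0L, 1L)
  # training 1:5 (2 cases / 3 controls): cell g=0 has 2:1 -> high risk;
  # cell g=1 has 0:2 -> low risk; cell g=2 unseen -> unclassifiable
  expect_equal(mdr_predict(g, 1, train = 1:5, test = 6, status), NA_integer_)
  g2 <- rbind(g, i7 = 0L, i8 = 1L)
  status2 <- c(status, 0L, 1L)
  expect_equal(mdr_predict(g2, 1, train = 1:5, test = 7:8, status2),
               c(1L, 0L))
})

test_that("mdr_predict matches the per-cell tally oracle on two markers", {
  for (seed in 1:5) {
    g <- rand_genotypes(40, 4, seed = seed)
    status <- knnmdr:::local_seed(seed + 50, sample(c(0L, 1L), 40, TRUE))
    train <- 1:28
    test <- 29:40
    expect_equal(mdr_predict(g, c(2, 4), train, test, status),
                 oracle_mdr(g, c(2, 4), train, test, status))
  }
})

test_that("every-individual-in-its-own-cell leaves everything unclassifiable", {
  # 8 markers give 3^8 cells; with distinct multi-locus genotypes nothing
  # observed in training matches a test individual
  g <- t(sapply(0:11, function(i) as.integer(intToBits(i))[1:8] * 2L))
  g[, 8] <- seq_len(12) %% 3L  # break accidental duplicates
  rownames(g) <- sprintf("i%d", 1:12)
  expect_false(anyDuplicated(apply(g, 1, paste, collapse = "")) > 0)
  status <- rep(c(1L, 0L), 6)
  pred <- mdr_predict(g, 1:8, train = 1:6, test = 7:12, status)
  expect_true(all(is.na(pred)))
})

test_that("balanced accuracy arithmetic and degenerate-class rule", {
  expect_equal(balanced_accuracy(tp = 5, fn = 0, tn = 7, fp = 0), 1)
  expect_equal(balanced_accuracy(tp = 3, fn = 1, tn = 2, fp = 2), 0.625)
  # always-case classifier on balanced data
  expect_equal(balanced_accuracy(tp = 10, fn = 0, tn = 0, fp = 10), 0.5)
  expect_warning(ba <- balanced_accuracy(tp = 0, fn = 0, tn = 4, fp = 1),
                 "sensitivity")
  expect_equal(ba, 0.5 * (0.5 + 0.8))
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, NA, 0, 1))
  expect_equal(cc, list(tp = 1L, fn = 0L, tn = 1L, fp = 1L, unclassified = 1L))
})

test_that("cv_plan stratifies and rejects impossible fold counts", {
  status <- rep(c(1L, 0L), c(40, 60))
  plan <- cv_plan(status, n_folds = 10, seed = 4)
  expect_equal(sort(unique(plan$fold)), 1:10)
  case_per_fold <- tapply(status, plan$fold, sum)
  expect_true(all(case_per_fold == 4))
  expect_error(cv_plan(status, n_folds = 101), "zero test individuals")
  expect_error(cv_plan(rep(1L, 10)), "control required")
})

test_that("cross-validated BA is ~0.5 on null data and ~1 on separable data", {
  # null: phenotype independent of genotype, 500 cases / 500 controls
  bas <- vapply(1:20, function(seed) {
    g <- rand_genotypes(1000, 10, seed = seed)
    status <- knnmdr:::local_seed(seed + 500, sample(rep(c(0L, 1L), 500)))
    wds <- window_distance_set(g, make_windows(10, 10))
    cross_validated_ba(wds, 1L, status, plan = cv_plan(status, seed = seed),
                       K = 10)
  }, 0)
  expect_lt(max(abs(bas - 0.5)), 0.05)
  expect_lt(abs(mean(bas) - 0.5), 0.02)

  # separable: one window's genotypes perfectly separate the classes
  xd <- xor_dataset(n_per_cell = 25, seed = 3)
  wds <- window_distance_set(xd$genotypes, make_windows(20, 5))
  plan <- cv_plan(xd$status, seed = 5)
  ba_pair <- cross_validated_ba(wds, c(1L, 2L), xd$status, plan, K = 5)
  expect_gt(ba_pair, 0.95)
  # either causal window alone is uninformative under the XOR model
  ba_one <- cross_validated_ba(wds, 1L, xd$status, plan, K = 5)
  expect_lt(ba_one, 0.65)
})

test_that("permuted phenotypes centre the CV BA on 0.5", {
  g <- rand_genotypes(120, 10, seed = 9)
  status <- rep(c(1L, 0L), 60)
  wds <- window_distance_set(g, make_windows(10, 5))
  plan <- cv_plan(status, seed = 1)
  nb <- knnmdr:::cv_knn_neighbors(combine_window_distances(wds, 1:2),
                                  plan$fold, 10L)
  perms <- knnmdr:::local_seed(77, knnmdr:::.perm_ymat(status, 200))
  bas <- knnmdr:::cv_knn_ba(nb, perms, plan$fold, plan$n_folds, 0L)
  expect_lt(abs(mean(bas) - 0.5), 2 * sd(bas) / sqrt(length(bas)))
})

test_that("cross_validated_ba agrees with a fold-by-fold recomputation", {
  g <- rand_genotypes(60, 8, seed = 21)
  status <- knnmdr:::local_seed(22, sample(rep(c(0L, 1L), 30)))
  wds <- window_distance_set(g, make_windows(8, 4))
  plan <- cv_plan(status, n_folds = 5, seed = 23)
  d2 <- combine_window_distances(wds, 1:2)
  # manual CV using the exported predictors only
  fold_bas <- vapply(1:5, function(f) {
    test <- which(plan$fold == f)
    train <- which(plan$fold != f)
    pred <- knn_predict(d2, train, test, status, K = 7)
    balanced_accuracy(confusion_counts(status[test], pred))
  }, 0)
  expect_equal(cross_validated_ba(wds, 1:2, status, plan, K = 7),
               mean(fold_bas))

  fold_bas_mdr <- vapply(1:5, function(f) {
    test <- which(plan$fold == f)
    train <- which(plan$fold != f)
    pred <- mdr_predict(g, c(1, 5), train, test, status)
    balanced_accuracy(confusion_counts(status[test], pred))
  }, 0)
  expect_equal(cross_validated_ba(g, c(1, 5), status, plan, method = "mdr"),
               mean(fold_bas_mdr))
})
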