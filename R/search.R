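#' Enumerate candidate window sets
#'
#' All subsets of `1..max_order` windows (or only the sizes in `orders`),
#' in deterministic lexicographic order within each size.  The total count
#' is `sum_k choose(W, k)` -- the `M^P/P!`-type explosion that motivates
#' pooling markers into windows in the first place.
#'
#' @param W number of windows.
#' @param max_order largest set size `P` (`1 <= P <= W`).
#' @param orders optional explicit vector of sizes (overrides `1:max_order`).
#' @return list with `sets` (list of integer vectors) and `count`.
#' @export
enumerate_window_sets <- function(W, max_order, orders = NULL) {
  if (is.null(orders)) {
    if (max_order < 1L) stop("max_order must be >= 1")
    if (max_order > W) stop("max_order exceeds window count")
    orders <- seq_len(max_order)
  }
  if (any(orders < 1L) || any(orders > W)) stop("invalid order")
  sets <- list()
  for (k in orders) {
    sets <- c(sets, asplit(t(combn(W, k)), 1L))
  }
  sets <- lapply(sets, as.integer)
  list(sets = sets, count = count_window_sets(W, orders = orders))
}

#' @rdname enumerate_window_sets
#' @export
count_window_sets <- function(W, max_order = NULL, orders = NULL) {
  if (is.null(orders)) orders <- seq_len(max_order)
  sum(choose(W, orders))
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests performed.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

.model_key <- function(model) paste(sprintf("%06d", sort(model)), collapse = "+")

.model_label <- function(model) paste(sort(model), collapse = "+")

# One phenotype-permutation matrix: each column is an independent uniform
# shuffle of the status vector, drawn sequentially from the current RNG
# stream (so chunking never changes the stream).
.perm_ymat <- function(status, k) {
  vapply(seq_len(k), function(i) sample(status), integer(length(status)))
}

#' Exhaustive window-set scan ranked by cross-validated balanced accuracy
#'
#' Scores every enumerated window set (KNN-MDR) or marker set (classic MDR)
#' with [cross_validated_ba()] and returns the ranking, best first.  Equal
#' balanced accuracies are broken lexicographically on the sorted set for
#' determinism.
#'
#' @param x a `window_distance_set` (knn_mdr) or genotype matrix (mdr).
#' @param status 0/1 case-control vector.
#' @param plan a [cv_plan()] (built with `seed` when `NULL`).
#' @param max_order largest set size (default 2).
#' @param orders explicit set sizes (overrides `max_order`).
#' @param models explicit list of candidate sets (overrides enumeration).
#' @param method `"knn_mdr"` or `"mdr"`.
#' @param K neighbour count (knn_mdr).
#' @param tie_rule vote tie rule.
#' @param seed plan seed when `plan` is `NULL`.
#' @return data.frame with `rank`, `model` (label), `cv_ba`; candidate sets
#'   in ranked order as attribute `"models"`, the plan as attribute
#'   `"plan"`.
#' @export
scan_windows <- function(x, status, plan = NULL, max_order = 2L,
                         orders = NULL, models = NULL,
                         method = c("knn_mdr", "mdr"), K = 10L,
                         tie_rule = "nearest_neighbor_breaks", seed = NULL) {
  method <- match.arg(method)
  s <- .check_status(status)
  if (is.null(plan)) plan <- cv_plan(s, seed = seed)
  if (is.null(models)) {
    W <- if (method == "knn_mdr") nrow(x$partition) else ncol(x)
    models <- enumerate_window_sets(W, max_order, orders)$sets
  }
  ymat <- matrix(s, ncol = 1L)
  ba <- vapply(models, function(m) {
    core <- .model_core(x, m, method, plan, K)
    .core_ba(core, method, ymat, plan, tie_rule, n_markers = length(m))[1L]
  }, 0)
  keys <- vapply(models, .model_key, "")
  ord <- order(-ba, keys)
  res <- data.frame(rank = seq_along(models),
                    model = vapply(models[ord], .model_label, ""),
                    cv_ba = ba[ord])
  attr(res, "models") <- models[ord]
  attr(res, "plan") <- plan
  res
}

#' Phenotype-permutation significance test
#'
#' Shuffles the phenotype labels `n_perm` times and recomputes the
#' cross-validated balanced accuracy identically for each shuffle; the
#' permutation p-value is `(#\{perm stat >= observed\} + 1) / (n_perm + 1)`
#' (add-one convention, so p is never 0 and the smallest attainable value
#' is `1/(n_perm + 1)`).
#'
#' Two modes: `"per_model"` tests each candidate against its own
#' permutation null on an independent sub-stream of the seed, which is the
#' mode the Bonferroni-corrected hierarchical scan uses; `"max_over_models"`
#' recomputes the maximum balanced accuracy over all candidates per
#' permutation (family-wise null of the best model) and reports, for every
#' candidate, the max-adjusted p-value -- `family_p` is then the adjusted p
#' of the best observed candidate.
#'
#' Distances, neighbour sets and genotype cells are phenotype-free, so they
#' are computed once and only the vote/tally step is repeated per
#' permutation; the cross-validation plan is likewise held fixed.
#'
#' @inheritParams scan_windows
#' @param models list of candidate sets (a single vector is promoted).
#' @param n_perm number of permutations.
#' @param seed master seed for the permutation streams.
#' @param mode `"max_over_models"` or `"per_model"`.
#' @param chunk permutations generated per block (memory knob; does not
#'   affect the stream).
#' @return list with `table` (data.frame: model, cv_ba, p), `family_p`,
#'   `best` (label of top-ranked model), `mode`, `n_perm`.
#' @export
permutation_test <- function(x, status, plan = NULL, models, n_perm = 99L,
                             seed = 1L, mode = c("max_over_models", "per_model"),
                             method = c("knn_mdr", "mdr"), K = 10L,
                             tie_rule = "nearest_neighbor_breaks",
                             chunk = 1000L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  s <- .check_status(status)
  if (is.null(plan)) plan <- cv_plan(s, seed = seed_for(seed, 0L))
  if (!is.list(models)) models <- list(models)
  cores <- lapply(models, .model_core, x = x, method = method, plan = plan, K = K)
  sizes <- lengths(models)
  ymat0 <- matrix(s, ncol = 1L)
  obs <- vapply(seq_along(models), function(m) {
    .core_ba(cores[[m]], method, ymat0, plan, tie_rule, sizes[m])[1L]
  }, 0)

  if (mode == "per_model") {
    exceed <- vapply(seq_along(models), function(m) {
      local_seed(seed_for(seed, m), {
        e <- 0L
        done <- 0L
        while (done < n_perm) {
          k <- min(chunk, n_perm - done)
          ymat <- .perm_ymat(s, k)
          ba <- .core_ba(cores[[m]], method, ymat, plan, tie_rule, sizes[m])
          e <- e + sum(ba >= obs[m])
          done <- done + k
        }
        e
      })
    }, 0L)
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    exceed <- integer(length(models))
    local_seed(seed_for(seed, 0L), {
      done <- 0L
      while (done < n_perm) {
        k <- min(chunk, n_perm - done)
        ymat <- .perm_ymat(s, k)
        mx <- rep(-Inf, k)
        for (m in seq_along(models)) {
          ba <- .core_ba(cores[[m]], method, ymat, plan, tie_rule, sizes[m])
          mx <- pmax(mx, ba)
        }
        for (m in seq_along(models)) exceed[m] <- exceed[m] + sum(mx >= obs[m])
        done <- done + k
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  keys <- vapply(models, .model_key, "")
  ord <- order(-obs, keys)
  tab <- data.frame(model = vapply(models[ord], .model_label, ""),
                    cv_ba = obs[ord], p = p[ord])
  attr(tab, "models") <- models[ord]
  list(table = tab, family_p = tab$p[1L], best = tab$model[1L],
       mode = mode, n_perm = as.integer(n_perm), plan = plan)
}

#' Default adaptive permutation schedule
#'
#' Cumulative permutation counts with survival thresholds
#' (100, 0.05), (1000, 5e-3), (1e4, 5e-4), (1e5, 5e-5), (1e6, 5e-6),
#' (2e6, 2.5e-6): candidates whose running p-value exceeds a round's
#' threshold are abandoned before the expensive later rounds.
#'
#' @return data.frame with columns `n_perm` (cumulative, increasing) and
#'   `threshold` (decreasing).
#' @export
default_perm_schedule <- function() {
  data.frame(n_perm = c(100, 1000, 1e4, 1e5, 1e6, 2e6),
             threshold = c(0.05, 0.005, 5e-4, 5e-5, 5e-6, 2.5e-6))
}

.check_schedule <- function(schedule) {
  if (!all(c("n_perm", "threshold") %in% names(schedule))) {
    stop("schedule needs columns n_perm and threshold")
  }
  if (nrow(schedule) < 1L) stop("empty schedule")
  if (any(diff(schedule$n_perm) <= 0)) stop("cumulative counts must be strictly increasing")
  if (nrow(schedule) > 1L && any(diff(schedule$threshold) >= 0)) {
    stop("thresholds must be strictly decreasing")
  }
  schedule
}

#' Adaptive (early-stopping) per-candidate permutation testing
#'
#' Executes the rounds of `schedule` in order on every candidate.  A
#' candidate is abandoned at a round when its running p-value exceeds the
#' round's threshold; survivors of the last round carry p-values at the
#' full cumulative resolution.  Each candidate consumes an independent
#' permutation sub-stream of `seed` (the same stream [permutation_test()]
#' uses in `per_model` mode), so a survivor's p-value is exactly the
#' single-shot p-value at the same cumulative count, and dropping one
#' candidate never perturbs another's stream.
#'
#' @inheritParams permutation_test
#' @param schedule data.frame of cumulative counts and thresholds, see
#'   [default_perm_schedule()].
#' @return data.frame: `model`, `cv_ba`, `p`, `n_perm_used`, `abandoned`
#'   (round index, `NA` for survivors), ordered like `models`.
#' @export
adaptive_permutation <- function(x, status, plan = NULL, models,
                                 schedule = default_perm_schedule(),
                                 seed = 1L, method = c("knn_mdr", "mdr"),
                                 K = 10L, tie_rule = "nearest_neighbor_breaks",
                                 chunk = 1000L) {
  method <- match.arg(method)
  s <- .check_status(status)
  if (is.null(plan)) plan <- cv_plan(s, seed = seed_for(seed, 0L))
  schedule <- .check_schedule(schedule)
  if (!is.list(models)) models <- list(models)
  if (length(models) == 0L) {
    return(data.frame(model = character(0), cv_ba = numeric(0), p = numeric(0),
                      n_perm_used = integer(0), abandoned = integer(0)))
  }
  ymat0 <- matrix(s, ncol = 1L)
  res <- lapply(seq_along(models), function(m) {
    core <- .model_core(x, models[[m]], method, plan, K)
    obs <- .core_ba(core, method, ymat0, plan, tie_rule, length(models[[m]]))[1L]
    local_seed(seed_for(seed, m), {
      exceed <- 0L
      done <- 0L
      abandoned <- NA_integer_
      p <- NA_real_
      for (r in seq_len(nrow(schedule))) {
        target <- schedule$n_perm[r]
        while (done < target) {
          k <- min(chunk, target - done)
          ymat <- .perm_ymat(s, k)
          ba <- .core_ba(core, method, ymat, plan, tie_rule, length(models[[m]]))
          exceed <- exceed + sum(ba >= obs)
          done <- done + k
        }
        p <- (exceed + 1) / (done + 1)
        if (p > schedule$threshold[r]) {
          abandoned <- r
          break
        }
      }
      data.frame(model = .model_label(models[[m]]), cv_ba = obs, p = p,
                 n_perm_used = done, abandoned = abandoned)
    })
  })
  out <- do.call(rbind, res)
  attr(out, "models") <- models
  out
}
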