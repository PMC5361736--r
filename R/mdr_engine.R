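.tie_rules <- c(nearest_neighbor_breaks = 0L, case_wins = 1L, control_wins = 2L)

.check_status <- function(status, n = NULL) {
  if (!is.null(n) && length(status) != n) stop("status length mismatch")
  s <- as.integer(status)
  if (any(!(s %in% c(0L, 1L)))) stop("status must be coded 0 (control) / 1 (case)")
  if (sum(s == 1L) == 0L) stop("at least one case required")
  if (sum(s == 0L) == 0L) stop("at least one control required")
  s
}

#' Cross-validation plan
#'
#' Assigns a fold id to every individual.  Folds are stratified by status
#' by default so each fold's case fraction is within one individual of the
#' global fraction; the seed used for the shuffle is recorded for
#' reproducibility.
#'
#' @param status 0/1 case-control vector.
#' @param n_folds fold count (default 10).
#' @param stratified stratify folds by status.
#' @param seed shuffle seed (`NULL` = use current RNG state).
#' @return a `cv_plan`: list with `fold` (integer vector), `n_folds`,
#'   `stratified`, `seed`.
#' @export
cv_plan <- function(status, n_folds = 10L, stratified = TRUE, seed = NULL) {
  s <- .check_status(status)
  n <- length(s)
  if (n_folds < 2L) stop("need at least 2 folds")
  if (n_folds > n) stop("fold with zero test individuals: n_folds > n")
  fold <- integer(n)
  local_seed(seed, {
    if (stratified) {
      for (cls in c(0L, 1L)) {
        idx <- sample(which(s == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  if (any(tabulate(fold, n_folds) == 0L)) stop("fold with zero test individuals")
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = seed),
            class = "cv_plan")
}

#' KNN status prediction from a combined squared-distance matrix
#'
#' For each test individual the `K` training individuals with smallest
#' squared distance are selected (distance ties broken by ascending
#' individual index) and the predicted status is the majority status among
#' them.  Vote ties (even `K`) are resolved by `tie_rule`; the default lets
#' the single nearest neighbour decide.
#'
#' @param d2 `n x n` combined squared-distance matrix.
#' @param train,test disjoint integer index vectors.
#' @param status 0/1 vector for all `n` individuals (only training entries
#'   are consulted).
#' @param K neighbour count, `1 <= K <= length(train)`.
#' @param tie_rule one of `"nearest_neighbor_breaks"`, `"case_wins"`,
#'   `"control_wins"`.
#' @return integer 0/1 predictions, one per test individual.
#' @export
knn_predict <- function(d2, train, test, status, K,
                        tie_rule = c("nearest_neighbor_breaks", "case_wins",
                                     "control_wins")) {
  tie_rule <- match.arg(tie_rule)
  if (length(intersect(train, test))) stop("train and test must be disjoint")
  if (K < 1L) stop("K must be >= 1")
  if (K > length(train)) stop("K exceeds training-set size")
  if (length(test) == 0L) return(integer(0))
  s <- as.integer(status)
  nb <- tt_knn_neighbors(d2, as.integer(train), as.integer(test), as.integer(K))
  votes <- matrix(s[nb], nrow(nb), ncol(nb))
  tally <- rowSums(votes)
  pred <- ifelse(2 * tally > K, 1L, ifelse(2 * tally < K, 0L, NA_integer_))
  tie <- is.na(pred)
  if (any(tie)) {
    pred[tie] <- switch(tie_rule,
                        nearest_neighbor_breaks = s[nb[tie, 1L]],
                        case_wins = 1L,
                        control_wins = 0L)
  }
  as.integer(pred)
}

#' Classic MDR cell prediction
#'
#' Each multi-locus genotype cell observed in training is labelled high
#' risk (case) when its training case:control ratio strictly exceeds the
#' overall training ratio, low risk (control) otherwise (exact equality is
#' low risk).  Test individuals whose cell was never observed in training
#' are unclassifiable and returned as `NA` -- the failure mode that the KNN
#' vote removes.
#'
#' @param g genotype matrix.
#' @param markers marker column indices defining the multi-locus genotype.
#' @param train,test disjoint individual index vectors.
#' @param status 0/1 status vector for all individuals.
#' @return integer predictions for `test` (`NA` = unclassifiable).
#' @export
mdr_predict <- function(g, markers, train, test, status) {
  if (length(markers) < 1L) stop("need at least one marker")
  if (length(intersect(train, test))) stop("train and test must be disjoint")
  s <- as.integer(status)
  cells <- .genotype_cells(g, markers)
  ncell <- 3L^length(markers)
  tr_case <- tabulate(cells[train][s[train] == 1L] + 1L, ncell)
  tr_tot <- tabulate(cells[train] + 1L, ncell)
  tr_ctrl <- tr_tot - tr_case
  all_case <- sum(s[train] == 1L)
  all_ctrl <- sum(s[train] == 0L)
  high <- tr_case * all_ctrl > tr_ctrl * all_case
  pred <- ifelse(tr_tot[cells[test] + 1L] == 0L, NA_integer_,
                 as.integer(high[cells[test] + 1L]))
  as.integer(pred)
}

# 0-based multi-locus cell index from 0/1/2 genotypes at `markers`.
.genotype_cells <- function(g, markers) {
  cells <- integer(nrow(g))
  for (m in markers) cells <- cells * 3L + as.integer(g[, m])
  cells
}

#' Confusion counts of a binary prediction
#'
#' `NA` predictions (unclassifiable individuals under classic MDR) are
#' excluded from the counts and tallied separately.
#'
#' @param truth,pred 0/1 vectors (`pred` may contain `NA`).
#' @return list with `tp`, `fn`, `tn`, `fp`, `unclassified`.
#' @export
confusion_counts <- function(truth, pred) {
  keep <- !is.na(pred)
  t <- as.integer(truth)[keep]
  p <- as.integer(pred)[keep]
  list(tp = sum(t == 1L & p == 1L), fn = sum(t == 1L & p == 0L),
       tn = sum(t == 0L & p == 0L), fp = sum(t == 0L & p == 1L),
       unclassified = sum(!keep))
}

#' Balanced accuracy
#'
#' `BA = (sensitivity + specificity) / 2 = (TP/(TP+FN) + TN/(TN+FP)) / 2`.
#' When one class is absent among the classified individuals (degenerate
#' fold) that class's rate is defined as 0.5 and a warning is raised.
#'
#' @param counts a list as returned by [confusion_counts()]; alternatively
#'   supply `tp`, `fn`, `tn`, `fp` directly.
#' @param tp,fn,tn,fp confusion counts (ignored when `counts` is given).
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts = NULL, tp = 0, fn = 0, tn = 0, fp = 0) {
  if (!is.null(counts)) {
    tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  }
  if (tp + fn == 0) {
    warning("no classified cases; sensitivity set to 0.5")
    sens <- 0.5
  } else sens <- tp / (tp + fn)
  if (tn + fp == 0) {
    warning("no classified controls; specificity set to 0.5")
    spec <- 0.5
  } else spec <- tn / (tn + fp)
  (sens + spec) / 2
}

# Internal fast path shared by the scan and the permutation machinery.
# For knn_mdr: returns the CV neighbour matrix; for mdr: the cell vector.
.model_core <- function(x, model, method, plan, K) {
  if (method == "knn_mdr") {
    d2 <- combine_window_distances(x, model)
    min_train <- length(plan$fold) - max(tabulate(plan$fold, plan$n_folds))
    if (K > min_train) stop("K exceeds the smallest training-fold size")
    cv_knn_neighbors(d2, plan$fold, as.integer(K))
  } else {
    .genotype_cells(x, model)
  }
}

.core_ba <- function(core, method, ymat, plan, tie_rule, n_markers = NULL) {
  if (method == "knn_mdr") {
    cv_knn_ba(core, ymat, plan$fold, plan$n_folds, .tie_rules[[tie_rule]])
  } else {
    cv_mdr_ba(core, 3L^n_markers, ymat, plan$fold, plan$n_folds)
  }
}

#' Cross-validated balanced accuracy of a candidate model
#'
#' Scores one window set (KNN-MDR) or marker set (classic MDR): for each
#' fold of the plan, the classifier is trained on the remaining folds, the
#' fold is predicted, and its balanced accuracy computed; the unweighted
#' mean over folds is returned.  Deterministic given the plan and
#' configuration.
#'
#' @param x a `window_distance_set` (method `"knn_mdr"`) or a genotype
#'   matrix (method `"mdr"`).
#' @param model integer vector of window ids (knn_mdr) or marker column
#'   indices (mdr).
#' @param status 0/1 case-control vector.
#' @param plan a [cv_plan()]; built with defaults when `NULL`.
#' @param method `"knn_mdr"` or `"mdr"`.
#' @param K neighbour count (knn_mdr only).
#' @param tie_rule vote tie rule, see [knn_predict()].
#' @param seed plan seed when `plan` is `NULL`.
#' @return mean test balanced accuracy over folds.
#' @export
cross_validated_ba <- function(x, model, status, plan = NULL,
                               method = c("knn_mdr", "mdr"), K = 10L,
                               tie_rule = "nearest_neighbor_breaks",
                               seed = NULL) {
  method <- match.arg(method)
  s <- .check_status(status)
  if (is.null(plan)) plan <- cv_plan(s, seed = seed)
  for (f in seq_len(plan$n_folds)) {
    test <- plan$fold == f
    if (sum(s[test] == 1L) == 0L || sum(s[test] == 0L) == 0L) {
      warning("degenerate fold ", f, ": one class absent; rate set to 0.5")
    }
  }
  core <- .model_core(x, model, method, plan, K)
  ymat <- matrix(s, ncol = 1L)
  .core_ba(core, method, ymat, plan, tie_rule,
           n_markers = length(model))[1L]
}
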