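#' Hierarchical stride-subsampling interaction scan for large panels
#'
#' Three-stage protocol for marker panels too large for a direct windowed
#' scan:
#'
#' 1. *Coarse round*: every `stride`-th marker is kept and split into
#'    windows of `round1_window` retained markers; all window pairs are
#'    tested by KNN-MDR with adaptive permutations, and pairs passing the
#'    Bonferroni threshold (`alpha` over the number of pairs) survive.
#' 2. *Refinement*: the markers hidden by the striding are recovered inside
#'    each surviving pair's regions; each recovered marker set is re-split
#'    into windows of `round2_window` markers and all window pairs are
#'    rescanned the same way.
#' 3. *Final stage*: classic MDR is run on every SNP pair inside each
#'    surviving refined window pair, and SNP pairs passing the Bonferroni
#'    threshold over the pairs tested within their set are reported.
#'
#' Every round logs candidate counts and thresholds.  No survivors at some
#' round yields an empty result with the log, not an error.
#'
#' @param g genotype matrix (all markers).
#' @param map marker map data.frame (`id`, `chrom`, `pos`).
#' @param status 0/1 case-control vector.
#' @param stride keep one marker every `stride` markers in round 1.
#' @param round1_window window size (in retained markers) for round 1.
#' @param round2_window window size for the refinement round.
#' @param K neighbour count for the KNN vote.
#' @param alpha family-wise error level for every Bonferroni correction.
#' @param schedule1,schedule2,schedule_final adaptive permutation schedules
#'   for the three stages (see [default_perm_schedule()]); their deepest
#'   threshold must reach the corresponding Bonferroni level for survivors
#'   to be declarable significant.
#' @param n_folds cross-validation folds.
#' @param tie_rule vote tie rule.
#' @param seed master seed (plan + permutation streams).
#' @param verbose emit progress messages.
#' @return list with `results` (data.frame of significant SNP pairs:
#'   ids, positions, `cv_ba`, `p`, `significant`) and `log` (character).
#' @export
hierarchical_scan <- function(g, map, status, stride = 15L,
                              round1_window = 10L, round2_window = 10L,
                              K = 10L, alpha = 0.05,
                              schedule1 = default_perm_schedule(),
                              schedule2 = default_perm_schedule(),
                              schedule_final = default_perm_schedule(),
                              n_folds = 10L,
                              tie_rule = "nearest_neighbor_breaks",
                              seed = 1L, verbose = TRUE) {
  if (stride < 1L) stop("stride must be >= 1")
  s <- .check_status(status, nrow(g))
  M <- ncol(g)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
    invisible(NULL)
  }
  empty <- data.frame(snp1 = character(0), snp2 = character(0),
                      pos1 = character(0), pos2 = character(0),
                      cv_ba = numeric(0), p = numeric(0),
                      significant = logical(0))
  plan <- cv_plan(s, n_folds = n_folds, seed = seed_for(seed, 1L))

  ## Round 1: strided coarse scan
  idx1 <- seq(1L, M, by = stride)
  say("round 1: %d of %d markers retained (stride %d)", length(idx1), M, stride)
  part1 <- make_windows(length(idx1), round1_window)
  wds1 <- window_distance_set(g[, idx1, drop = FALSE], part1)
  pairs1 <- enumerate_window_sets(nrow(part1), max_order = 2L, orders = 2L)$sets
  thr1 <- bonferroni_threshold(alpha, length(pairs1))
  say("round 1: %d windows, %d pairs, Bonferroni threshold %.3g",
      nrow(part1), length(pairs1), thr1)
  res1 <- adaptive_permutation(wds1, s, plan, pairs1, schedule1,
                               seed = seed_for(seed, 2L), K = K,
                               tie_rule = tie_rule)
  keep1 <- which(is.na(res1$abandoned) & res1$p <= thr1)
  say("round 1: %d surviving window pair(s)", length(keep1))
  if (length(keep1) == 0L) return(list(results = empty, log = log))

  ## Recover hidden markers inside each surviving pair's regions
  window_region <- function(w) {
    sidx <- part1$start[w]:part1$end[w]
    lo <- idx1[min(sidx)]
    hi <- min(idx1[max(sidx)] + stride - 1L, M)
    lo:hi
  }
  sets2 <- lapply(keep1, function(i) {
    pr <- attr(res1, "models")[[i]]
    sort(unique(c(window_region(pr[1L]), window_region(pr[2L]))))
  })
  sets2 <- unique(sets2)
  say("round 2: %d recovered marker set(s), sizes %s", length(sets2),
      paste(unique(lengths(sets2)), collapse = "/"))

  ## Round 2: refined windowed rescans per recovered set
  final_sets <- list()
  for (i in seq_along(sets2)) {
    set <- sets2[[i]]
    part2 <- make_windows(length(set), round2_window)
    wds2 <- window_distance_set(g[, set, drop = FALSE], part2)
    pairs2 <- enumerate_window_sets(nrow(part2), max_order = 2L, orders = 2L)$sets
    thr2 <- bonferroni_threshold(alpha, length(pairs2))
    res2 <- adaptive_permutation(wds2, s, plan, pairs2, schedule2,
                                 seed = seed_for(seed, 100L + i), K = K,
                                 tie_rule = tie_rule)
    keep2 <- which(is.na(res2$abandoned) & res2$p <= thr2)
    say("round 2, set %d: %d windows, %d pairs, threshold %.3g, %d survivor(s)",
        i, nrow(part2), length(pairs2), thr2, length(keep2))
    for (j in keep2) {
      pr <- attr(res2, "models")[[j]]
      mk <- sort(unique(c(set[part2$start[pr[1L]]:part2$end[pr[1L]]],
                          set[part2$start[pr[2L]]:part2$end[pr[2L]]])))
      final_sets <- c(final_sets, list(mk))
    }
  }
  final_sets <- unique(final_sets)
  if (length(final_sets) == 0L) return(list(results = empty, log = log))
  say("final stage: %d marker set(s) for SNP-level MDR", length(final_sets))

  ## Final stage: classic MDR over all SNP pairs within each set
  rows <- list()
  for (i in seq_along(final_sets)) {
    mk <- final_sets[[i]]
    pairs <- lapply(asplit(combn(mk, 2L), 2L), as.integer)
    thrf <- bonferroni_threshold(alpha, length(pairs))
    resf <- adaptive_permutation(g, s, plan, pairs, schedule_final,
                                 seed = seed_for(seed, 1000L + i),
                                 method = "mdr", tie_rule = tie_rule)
    sig <- which(is.na(resf$abandoned) & resf$p <= thrf)
    say("final stage, set %d: %d SNP pairs, threshold %.3g, %d significant",
        i, length(pairs), thrf, length(sig))
    for (j in sig) {
      pr <- attr(resf, "models")[[j]]
      rows <- c(rows, list(data.frame(
        snp1 = map$id[pr[1L]], snp2 = map$id[pr[2L]],
        pos1 = paste0(map$chrom[pr[1L]], ":", map$pos[pr[1L]]),
        pos2 = paste0(map$chrom[pr[2L]], ":", map$pos[pr[2L]]),
        marker1 = pr[1L], marker2 = pr[2L],
        cv_ba = resf$cv_ba[j], p = resf$p[j], significant = TRUE)))
    }
  }
  if (length(rows) == 0L) return(list(results = empty, log = log))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("snp1", "snp2")]), , drop = FALSE]
  out <- out[order(out$p, -out$cv_ba), , drop = FALSE]
  rownames(out) <- NULL
  list(results = out, log = log)
}

#' Write a ranked results table as TSV
#'
#' Columns mirror a standard interaction-scan report: model id, marker or
#' window ids with map positions when available, testing balanced accuracy,
#' p-value and significance flag.
#'
#' @param results data.frame (e.g. `hierarchical_scan()$results` or a
#'   [permutation_test()] table).
#' @param path output path.
#' @export
write_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
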