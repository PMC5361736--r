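#' Run the interaction scan on one simulated replicate and score it
#'
#' Builds the window partition and distance set, runs the exhaustive scan
#' with the family-wise (max-statistic) permutation null, and evaluates
#' detection and coverage against the replicate's truth record.
#'
#' *Detected*: the best model's family-wise permutation p-value is below
#' `alpha`.  *Covered*: under the default `"all"` rule, every causal SNP
#' that survived thinning lies inside some window of the best model
#' (`"any"` requires at least one).  When causal SNPs exist but none
#' survived thinning the coverage test is vacuous and flagged; a `G = 0`
#' replicate is never covered.
#'
#' @param dataset a list as returned by [simulate_dataset()] (`genotypes`,
#'   `phenotypes`, `truth`; `map` optional).
#' @param window_size markers per window.
#' @param K neighbour count.
#' @param max_order largest window-set size scanned.
#' @param alpha detection level.
#' @param n_perm permutations for the max-statistic null.
#' @param coverage_rule `"all"` (stricter, default) or `"any"`.
#' @param n_folds cross-validation folds.
#' @param seed seed for plan + permutation stream.
#' @return one-row data.frame: best model, its balanced accuracy,
#'   family-wise p, `detected`, `covered`, `vacuous`.
#' @export
evaluate_replicate <- function(dataset, window_size = 10L, K = 10L,
                               max_order = 2L, alpha = 0.05, n_perm = 99L,
                               coverage_rule = c("all", "any"),
                               n_folds = 10L, seed = 1L) {
  coverage_rule <- match.arg(coverage_rule)
  g <- dataset$genotypes
  s <- .check_status(dataset$phenotypes, nrow(g))
  part <- make_windows(ncol(g), window_size)
  wds <- window_distance_set(g, part)
  plan <- cv_plan(s, n_folds = n_folds, seed = seed_for(seed, 1L))
  models <- enumerate_window_sets(nrow(part), max_order)$sets
  pt <- permutation_test(wds, s, plan, models, n_perm = n_perm,
                         seed = seed_for(seed, 2L), K = K,
                         mode = "max_over_models")
  best_model <- attr(pt$table, "models")[[1L]]
  detected <- pt$family_p < alpha

  causal <- dataset$truth$causal_post_thin
  vacuous <- FALSE
  if (length(causal) == 0L) {
    covered <- FALSE
  } else {
    surviving <- causal[!is.na(causal)]
    if (length(surviving) == 0L) {
      vacuous <- TRUE
      covered <- detected
    } else {
      in_best <- surviving %in% unlist(lapply(best_model, function(w) {
        part$start[w]:part$end[w]
      }))
      hit <- if (coverage_rule == "all") all(in_best) else any(in_best)
      covered <- detected && hit
    }
  }
  data.frame(best_model = pt$best, cv_ba = pt$table$cv_ba[1L],
             p = pt$family_p, detected = detected, covered = covered,
             vacuous = vacuous, n_markers = ncol(g),
             null_design = length(causal) == 0L)
}

#' Summarize replicate results into power, corrected power and FPR
#'
#' Power is the fraction of replicates with a significant detection
#' (`p < alpha`); corrected power additionally requires the detection to
#' cover the causal SNPs, so `corrected_power <= power` structurally.  For
#' null designs (`G = 0`) the "power" is the false-positive rate.
#'
#' @param results data.frame of rows from [evaluate_replicate()].
#' @param alpha detection level used.
#' @return an `experiment_summary` list: `n_replicates`, `power`,
#'   `corrected_power`, `fpr` (`NA` unless all replicates are null),
#'   `alpha`, plus the per-replicate table.
#' @export
summarize_experiment <- function(results, alpha = 0.05) {
  if (nrow(results) < 1L) stop("need at least one replicate")
  power <- mean(results$detected)
  corrected <- mean(results$detected & results$covered)
  fpr <- if (all(results$null_design)) power else NA_real_
  structure(list(n_replicates = nrow(results), power = power,
                 corrected_power = corrected, fpr = fpr, alpha = alpha,
                 replicates = results),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("Experiment summary over %d replicate(s) (alpha = %g)\n",
              x$n_replicates, x$alpha))
  cat(sprintf("  power:           %.3f\n", x$power))
  cat(sprintf("  corrected power: %.3f\n", x$corrected_power))
  if (!is.na(x$fpr)) cat(sprintf("  false-positive rate: %.3f\n", x$fpr))
  invisible(x)
}

.default_experiment_config <- function() {
  list(n_replicates = 10L, alpha = 0.05, seed_base = 1L,
       sim = list(G = 2L, n_cases = 500L, n_controls = 500L,
                  n_markers = 2000L, n_founders = 197L, maf_min = 0.3,
                  rho = 0.5, block_size = 10L, effect_size = 0.5,
                  prevalence = 0.5, thin = TRUE),
       scan = list(window_size = 10L, K = 10L, max_order = 2L,
                   n_perm = 99L, coverage_rule = "all", n_folds = 10L))
}

#' Run a replicate-level power / false-positive-rate experiment
#'
#' Simulates `n_replicates` datasets (per-replicate seeds derived as
#' `seed_base + replicate` for audit), scores each with
#' [evaluate_replicate()], and writes per-replicate TSVs, truth JSONs, a
#' summary TSV and a log under `out_dir`.  Completed replicates found on
#' disk are skipped, so an interrupted run can be resumed and reruns are
#' deterministic; partially written files are ignored and redone (results
#' are written to a temporary file, then renamed).
#'
#' @param config a list (see `knnmdr:::.default_experiment_config()` for
#'   the schema: `n_replicates`, `alpha`, `seed_base`, `sim`, `scan`) or
#'   the path of a JSON file with those fields; missing fields take the
#'   defaults.
#' @param out_dir output directory (created if needed).
#' @param verbose emit progress messages.
#' @return the [summarize_experiment()] result.
#' @export
run_experiment <- function(config = list(), out_dir, verbose = TRUE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .default_experiment_config()
  for (k in setdiff(names(config), c("sim", "scan"))) cfg[[k]] <- config[[k]]
  for (k in names(config$sim)) cfg$sim[[k]] <- config$sim[[k]]
  for (k in names(config$scan)) cfg$scan[[k]] <- config$scan[[k]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "experiment_log.txt")
  say <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    res_path <- file.path(out_dir, sprintf("replicate_%03d.tsv", r))
    if (file.exists(res_path)) {
      rows[[r]] <- read.table(res_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      say("replicate %d: found on disk, skipped", r)
      next
    }
    seed_r <- cfg$seed_base + r
    ds <- do.call(simulate_dataset, c(cfg$sim, list(seed = seed_r)))
    row <- do.call(evaluate_replicate,
                   c(list(dataset = ds, seed = seed_r, alpha = cfg$alpha),
                     cfg$scan))
    row <- cbind(replicate = r, seed = seed_r, row)
    truth <- ds$truth
    truth$penetrance <- if (is.null(truth$penetrance)) NULL else {
      list(MP = as.vector(truth$penetrance$MP), G = truth$penetrance$G,
           prevalence = truth$penetrance$prevalence,
           genotype_freqs = truth$penetrance$genotype_freqs,
           effect_size = truth$penetrance$effect_size)
    }
    jsonlite::write_json(truth, file.path(out_dir, sprintf("truth_%03d.json", r)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    tmp <- paste0(res_path, ".tmp")
    write.table(row, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, res_path)
    rows[[r]] <- row
    say("replicate %d: p = %.4g detected = %s covered = %s", r, row$p,
        row$detected, row$covered)
  }
  results <- do.call(rbind, rows)
  summary <- summarize_experiment(results, cfg$alpha)
  write.table(data.frame(n_replicates = summary$n_replicates,
                         power = summary$power,
                         corrected_power = summary$corrected_power,
                         fpr = summary$fpr, alpha = summary$alpha),
              file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  say("done: power = %.3f corrected = %.3f", summary$power,
      summary$corrected_power)
  summary
}
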