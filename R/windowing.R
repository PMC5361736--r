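#' Partition markers into windows of contiguous markers
#'
#' Splits `n_markers` markers into `floor(n_markers / window_size)` full
#' windows; a trailing remainder window is appended when
#' `n_markers %% window_size > 0`.  Windows are the unit of the interaction
#' scan: the distance between two individuals is defined per window and
#' combined additively over the windows of a candidate model.
#'
#' @param n_markers total marker count.
#' @param window_size markers per window (>= 1).
#' @return a `window_partition`: data.frame with columns `window`, `start`,
#'   `end` (1-based, inclusive).
#' @export
make_windows <- function(n_markers, window_size) {
  if (window_size < 1L) stop("window_size must be >= 1")
  if (window_size > n_markers) stop("window_size exceeds marker count")
  starts <- seq(1L, n_markers, by = window_size)
  ends <- pmin(starts + window_size - 1L, n_markers)
  structure(data.frame(window = seq_along(starts), start = starts, end = ends),
            n_markers = n_markers, class = c("window_partition", "data.frame"))
}

#' Build a window partition from explicit boundaries
#'
#' `boundaries` are strictly increasing 0-based cut points; consecutive
#' pairs `(b[i], b[i+1]]` become windows, so `c(0, 5, 10)` gives two
#' windows of five markers.  This supports window sizes that vary along the
#' genome (e.g. to track the local linkage-disequilibrium extent).
#'
#' @param boundaries integer vector of 0-based cut points.
#' @return a `window_partition`.
#' @export
make_windows_from_boundaries <- function(boundaries) {
  b <- as.integer(boundaries)
  if (length(b) < 2L) stop("need at least two boundaries")
  if (any(diff(b) <= 0L)) stop("boundaries must be strictly increasing (no empty windows)")
  if (b[1L] < 0L) stop("boundaries must be >= 0")
  starts <- b[-length(b)] + 1L
  ends <- b[-1L]
  structure(data.frame(window = seq_along(starts), start = starts, end = ends),
            n_markers = max(ends), class = c("window_partition", "data.frame"))
}

# Scale genotype columns for the normalized-Euclidean family: each marker is
# divided by its sample standard deviation so one allele substitution
# contributes 1/s_m^2 to the squared distance.  Monomorphic markers carry no
# discriminative information and contribute 0 by convention.
.scaled_columns <- function(g, cols, weights = NULL) {
  x <- g[, cols, drop = FALSE]
  storage.mode(x) <- "double"
  v <- apply(x, 2L, var)
  w <- if (is.null(weights)) rep(1, length(cols)) else {
    if (length(weights) != length(cols)) stop("weights length must match window size")
    weights
  }
  sc <- ifelse(v > 0, sqrt(w / ifelse(v > 0, v, 1)), 0)
  sweep(x, 2L, sc, `*`)
}

.dist2_from_rows <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Squared distance matrix between individuals for one marker window
#'
#' For the default `normalized_euclidean` metric,
#' `d2(i, j) = sum_m w_m (g_im - g_jm)^2 / s2_m`, where `s2_m` is the
#' sample variance of marker `m`; a single heterozygous difference thus
#' contributes a quarter of a homozygote-homozygote difference, i.e.
#' `D(AA, AB) = D(AB, BB) = 0.5 * D(AA, BB)` for a single SNP.  The
#' `binary` metric squares the number of differing alleles (0, 1 or 2)
#' between the two genotypes with the same per-marker normalization; for
#' biallelic 0/1/2 counts it coincides numerically with the normalized
#' Euclidean metric.  `mahalanobis` applies the full quadratic form with
#' the inverse in-window marker correlation matrix (estimated once on the
#' whole sample), optionally stabilised by a ridge term.
#'
#' @param g genotype matrix.
#' @param window integer vector of marker column indices (contiguous or not).
#' @param metric one of `"normalized_euclidean"`, `"mahalanobis"`, `"binary"`.
#' @param weights optional per-marker weights (default uniform); hook for
#'   up-weighting informative (e.g. rare) alleles.
#' @param ridge ridge term added to the correlation diagonal for
#'   `mahalanobis` (0 disables).
#' @return symmetric `n x n` matrix of squared distances, zero diagonal.
#' @export
window_squared_distances <- function(g, window,
                                     metric = c("normalized_euclidean",
                                                "mahalanobis", "binary"),
                                     weights = NULL, ridge = 0) {
  metric <- match.arg(metric)
  window <- as.integer(window)
  if (length(window) == 0L) stop("empty window")
  if (any(window < 1L) || any(window > ncol(g))) stop("window out of matrix bounds")
  if (metric %in% c("normalized_euclidean", "binary")) {
    x <- .scaled_columns(g, window, weights)
    return(.dist2_from_rows(x))
  }
  # mahalanobis: drop monomorphic markers (zero contribution), then
  # d2 = diff' C^-1 diff on standardized columns.
  x <- .scaled_columns(g, window, weights)
  keep <- apply(x, 2L, function(col) var(col) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) return(matrix(0, nrow(g), nrow(g)))
  C <- cor(x)
  if (ridge > 0) C <- C + diag(ridge, ncol(C))
  U <- tryCatch(chol(C), error = function(e) {
    stop("singular in-window correlation matrix; retry with ridge > 0 ",
         "(e.g. ridge = 1e-6)")
  })
  y <- x %*% backsolve(U, diag(ncol(C)))
  .dist2_from_rows(y)
}

#' Pre-compute squared distance matrices for every window of a partition
#'
#' Distances are phenotype-free, so they are computed once on the full
#' sample and reused across cross-validation folds and phenotype
#' permutations.
#'
#' @inheritParams window_squared_distances
#' @param partition a `window_partition`.
#' @return a `window_distance_set`: list with `d2` (list of matrices),
#'   `metric`, `partition`, `n_ind`, `individual_ids`.
#' @export
window_distance_set <- function(g, partition,
                                metric = c("normalized_euclidean",
                                           "mahalanobis", "binary"),
                                weights = NULL, ridge = 0) {
  metric <- match.arg(metric)
  d2 <- lapply(seq_len(nrow(partition)), function(w) {
    cols <- partition$start[w]:partition$end[w]
    wts <- if (is.null(weights)) NULL else weights[cols]
    window_squared_distances(g, cols, metric, wts, ridge)
  })
  structure(list(d2 = d2, metric = metric, partition = partition,
                 n_ind = nrow(g),
                 individual_ids = rownames(g) %||% sprintf("ind%d", seq_len(nrow(g)))),
            class = "window_distance_set")
}

#' Combine per-window squared distances over a window set
#'
#' Squared distances are additive over disjoint marker sets for the
#' normalized-Euclidean and binary metrics (no cross-window terms), so the
#' combined matrix equals a one-pass computation over the pooled markers.
#'
#' @param wds a `window_distance_set`.
#' @param window_ids window indices to combine (no duplicates).
#' @return combined squared-distance matrix.
#' @export
combine_window_distances <- function(wds, window_ids) {
  if (!inherits(wds, "window_distance_set")) stop("wds must be a window_distance_set")
  if (length(window_ids) == 0L) stop("empty window set")
  if (anyDuplicated(window_ids)) stop("duplicated window id in set")
  if (any(!(window_ids %in% seq_along(wds$d2)))) stop("unknown window id")
  Reduce(`+`, wds$d2[window_ids])
}

#' Read/write window partitions as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `window` with 0-based half-open marker
#' index intervals, mirroring BED conventions.
#'
#' @param partition a `window_partition`.
#' @param path file path.
#' @param chrom chromosome label to write (single value recycled).
#' @export
write_window_partition <- function(partition, path, chrom = "1") {
  d <- data.frame(chrom = chrom, start = partition$start - 1L,
                  end = partition$end, window = partition$window)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_partition
#' @export
read_window_partition <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  if (nrow(d) > 1L && any(d$start[-1L] != d$end[-nrow(d)])) {
    stop("windows in file are not contiguous")
  }
  make_windows_from_boundaries(c(d$start[1L], d$end))
}
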