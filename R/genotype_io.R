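#' Validate a genotype matrix of minor-allele counts
#'
#' A genotype matrix is an `n_individuals x n_markers` integer matrix with
#' entries in \{0, 1, 2\} (counts of the minor allele), unique individual
#' ids as row names and marker ids as column names.  Missing genotypes
#' (`NA`) are rejected unless `allows_missing = TRUE`.
#'
#' @param g matrix of genotype counts.
#' @param allows_missing logical; accept `NA` entries.
#' @return `g`, invisibly, after validation.
#' @export
validate_genotypes <- function(g, allows_missing = FALSE) {
  if (!is.matrix(g)) stop("genotypes must be a matrix")
  if (nrow(g) < 2L) stop("at least 2 individuals are required")
  if (ncol(g) < 1L) stop("at least 1 marker is required")
  if (anyNA(g) && !allows_missing) {
    stop("missing genotypes present; set allows_missing = TRUE or impute")
  }
  v <- g[!is.na(g)]
  if (length(v) && (any(v != as.integer(v)) || any(v < 0) || any(v > 2))) {
    stop("genotype entries must be integers in {0, 1, 2}")
  }
  ids <- rownames(g)
  if (!is.null(ids) && anyDuplicated(ids)) stop("individual ids must be unique")
  invisible(g)
}

#' Per-marker minor allele frequencies
#'
#' `MAF_m = min(p, 1 - p)` with `p = mean(count_m) / 2`, so every value lies
#' in `[0, 0.5]` whichever allele the counts refer to.
#'
#' @inheritParams validate_genotypes
#' @return numeric vector, one MAF per marker.
#' @export
minor_allele_frequencies <- function(g, allows_missing = FALSE) {
  validate_genotypes(g, allows_missing = allows_missing)
  p <- colMeans(g, na.rm = allows_missing) / 2
  pmin(p, 1 - p)
}

#' Mean-impute missing genotypes
#'
#' Replaces `NA` entries by the rounded per-marker mean count.  Off by
#' default everywhere: inputs are expected complete, and imputation is a
#' convenience for exploratory use only.
#'
#' @param g genotype matrix possibly containing `NA`.
#' @return completed integer genotype matrix.
#' @export
impute_mean <- function(g) {
  validate_genotypes(g, allows_missing = TRUE)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) {
      m <- mean(g[!miss, j])
      if (is.nan(m)) m <- 0
      g[miss, j] <- as.integer(round(m))
    }
  }
  storage.mode(g) <- "integer"
  g
}

.split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read genotypes from PLINK-text .ped/.map files
#'
#' Markers must be biallelic.  Counts are coded per marker as the number of
#' copies of the sample minor allele; when both alleles have frequency 0.5
#' the lexicographically smaller allele label is taken as the minor allele.
#' Missing genotypes (allele code "0") are rejected unless
#' `allows_missing = TRUE` (optionally followed by [impute_mean()] when
#' `impute = TRUE`).
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param allows_missing accept "0 0" genotypes as `NA`.
#' @param impute mean-impute missing genotypes after reading.
#' @return list with `genotypes` (matrix), `map` (data.frame with columns
#'   `id`, `chrom`, `pos`, `minor_allele`, `major_allele`), and
#'   `phenotypes_raw` (character, column 6 of the .ped).
#' @export
read_ped_map <- function(ped_path, map_path, allows_missing = FALSE,
                         impute = FALSE) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  mf <- .split_ws(map_lines)
  nfield <- lengths(mf)
  if (any(nfield < 3L)) {
    stop("malformed map line ", which(nfield < 3L)[1L], ": expected >= 3 fields")
  }
  chrom <- vapply(mf, `[`, "", 1L)
  mid <- vapply(mf, `[`, "", 2L)
  pos <- as.numeric(vapply(mf, function(x) x[length(x)], ""))
  if (anyNA(pos)) stop("malformed map line ", which(is.na(pos))[1L],
                       ": non-numeric position")
  if (anyDuplicated(mid)) stop("duplicated marker ids in map")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  n_mark <- length(mid)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  pf <- .split_ws(ped_lines)
  need <- 6L + 2L * n_mark
  bad <- which(lengths(pf) != need)
  if (length(bad)) {
    stop("malformed ped line ", bad[1L], ": expected ", need, " fields, got ",
         lengths(pf)[bad[1L]], " (map lists ", n_mark, " markers)")
  }
  n_ind <- length(pf)
  iid <- vapply(pf, `[`, "", 2L)
  if (anyDuplicated(iid)) stop("duplicated individual ids in ped")
  pheno_raw <- vapply(pf, `[`, "", 6L)

  a1 <- matrix("", n_ind, n_mark)
  a2 <- matrix("", n_ind, n_mark)
  for (i in seq_len(n_ind)) {
    al <- pf[[i]][-(1:6)]
    a1[i, ] <- al[c(TRUE, FALSE)]
    a2[i, ] <- al[c(FALSE, TRUE)]
  }

  g <- matrix(NA_integer_, n_ind, n_mark, dimnames = list(iid, mid))
  minor <- character(n_mark)
  major <- character(n_mark)
  for (j in seq_len(n_mark)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    if (any(xor(x1 == "0", x2 == "0"))) {
      stop("half-missing genotype at marker ", mid[j])
    }
    if (any(miss) && !allows_missing) {
      stop("missing genotypes at marker ", mid[j],
           "; set allows_missing = TRUE")
    }
    alleles <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(alleles) > 2L) {
      stop("marker ", mid[j], " is not biallelic: alleles ",
           paste(alleles, collapse = "/"))
    }
    if (length(alleles) == 0L) stop("marker ", mid[j], " has no called genotypes")
    if (length(alleles) == 1L) alleles <- c(alleles, alleles)
    n1 <- sum(x1[!miss] == alleles[1L]) + sum(x2[!miss] == alleles[1L])
    n2 <- sum(x1[!miss] == alleles[2L]) + sum(x2[!miss] == alleles[2L])
    # minor = rarer allele; tie (including the monomorphic degenerate case)
    # resolved towards the lexicographically smaller label, which is
    # alleles[1] because `alleles` is sorted.
    mi <- if (n1 <= n2) alleles[1L] else alleles[2L]
    ma <- if (n1 <= n2) alleles[2L] else alleles[1L]
    minor[j] <- mi
    major[j] <- ma
    cnt <- (x1 == mi) + (x2 == mi)
    cnt[miss] <- NA_integer_
    g[, j] <- as.integer(cnt)
  }
  if (impute) g <- impute_mean(g)
  validate_genotypes(g, allows_missing = allows_missing && !impute)
  map <- data.frame(id = mid, chrom = chrom, pos = pos,
                    minor_allele = minor, major_allele = major,
                    stringsAsFactors = FALSE)
  list(genotypes = g, map = map, phenotypes_raw = setNames(pheno_raw, iid))
}

#' Write genotypes as PLINK-text .ped/.map files
#'
#' Counts are expanded into allele pairs using the map's allele labels
#' (defaults `A` = minor, `B` = major).  A column whose coded allele has
#' sample frequency above 0.5 would be re-oriented by [read_ped_map()]'s
#' minor-allele rule, so the round trip is only the identity for matrices in
#' canonical minor-allele coding; a warning is emitted otherwise.
#'
#' @param g genotype matrix (complete).
#' @param map data.frame with at least `id`, `chrom`, `pos`; optional
#'   `minor_allele` / `major_allele` label columns.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param phenotypes optional named 0/1 vector (1 = case), written as
#'   PLINK labels 2 (case) / 1 (control) in column 6.
#' @return invisibly, the two file paths.
#' @export
write_ped_map <- function(g, map, prefix, phenotypes = NULL) {
  validate_genotypes(g)
  if (nrow(map) != ncol(g)) stop("map rows must match marker count")
  minor <- map$minor_allele %||% rep("A", ncol(g))
  major <- map$major_allele %||% rep("B", ncol(g))
  p <- colMeans(g) / 2
  if (any(p > 0.5)) {
    warning("some columns are not minor-allele coded (frequency > 0.5); ",
            "they will be re-oriented when read back")
  }
  tie_bad <- p == 0.5 & minor > major
  if (any(tie_bad)) {
    warning("tied allele frequencies with lexicographically larger minor ",
            "label; these columns will be re-oriented when read back")
  }
  ids <- rownames(g) %||% sprintf("ind%d", seq_len(nrow(g)))
  ph <- rep("0", nrow(g))
  if (!is.null(phenotypes)) {
    ph <- ifelse(phenotypes[ids] == 1, "2", "1")
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  lines <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    al <- character(2L * ncol(g))
    cnt <- g[i, ]
    al[c(TRUE, FALSE)] <- ifelse(cnt >= 1, minor, major)
    al[c(FALSE, TRUE)] <- ifelse(cnt == 2, minor, major)
    lines[i] <- paste(c(ids[i], ids[i], "0", "0", "0", ph[i], al),
                      collapse = "\t")
  }
  writeLines(lines, ped_path)
  writeLines(paste(map$chrom, map$id, 0, map$pos, sep = "\t"), map_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read/write the TSV genotype dialect
#'
#' Plain tab-separated matrix: header row of marker ids, first column the
#' individual id, entries the 0/1/2 minor-allele counts.  This dialect
#' round-trips any valid genotype matrix exactly.
#'
#' @param path file path.
#' @param allows_missing accept empty/NA cells.
#' @return genotype matrix with ids as dimnames.
#' @export
read_genotype_tsv <- function(path, allows_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  colClasses = "character")
  ids <- d[[1L]]
  g <- as.matrix(d[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(g) <- "integer")
  rownames(g) <- ids
  validate_genotypes(g, allows_missing = allows_missing)
  g
}

#' @rdname read_genotype_tsv
#' @param g genotype matrix to write.
#' @export
write_genotype_tsv <- function(g, path) {
  validate_genotypes(g, allows_missing = TRUE)
  ids <- rownames(g) %||% sprintf("ind%d", seq_len(nrow(g)))
  d <- data.frame(id = ids, g, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary phenotype file
#'
#' Two tab-separated columns without header: individual id and status
#' label.  Default labels follow PLINK text convention (2 = case,
#' 1 = control).  When `ids` is supplied the statuses are re-aligned to
#' that order and every id must be present.
#'
#' @param path phenotype file.
#' @param ids optional character vector of individual ids to align to.
#' @param case_label,control_label status labels in the file.
#' @return named integer vector, 1 = case, 0 = control.
#' @export
read_phenotypes <- function(path, ids = NULL, case_label = "2",
                            control_label = "1") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.table(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(d) < 2L) stop("phenotype file needs two columns: id, status")
  pid <- d[[1L]]
  lab <- d[[2L]]
  if (anyDuplicated(pid)) stop("duplicated individual ids in phenotype file")
  bad <- !(lab %in% c(case_label, control_label))
  if (any(bad)) {
    stop("unknown status label '", lab[bad][1L], "' for individual ",
         pid[bad][1L])
  }
  status <- setNames(as.integer(lab == case_label), pid)
  if (!is.null(ids)) {
    miss <- setdiff(ids, pid)
    if (length(miss)) stop("missing individual(s) in phenotype file: ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    status <- status[ids]
  }
  if (sum(status == 1L) == 0L) stop("at least one case required")
  if (sum(status == 0L) == 0L) stop("at least one control required")
  status
}

#' @rdname read_phenotypes
#' @param status named 0/1 vector to write.
#' @export
write_phenotypes <- function(status, path, case_label = "2",
                             control_label = "1") {
  ids <- names(status) %||% sprintf("ind%d", seq_along(status))
  writeLines(paste(ids, ifelse(status == 1, case_label, control_label),
                   sep = "\t"), path)
  invisible(path)
}
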