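#' Simulate a base haplotype panel with block-wise linkage disequilibrium
#'
#' Stands in for a real reference panel: haplotypes follow a first-order
#' Markov chain along markers (a latent AR(1) Gaussian with
#' autocorrelation `rho`, thresholded at each marker's allele frequency),
#' per-marker allele frequencies are drawn uniformly in
#' `[maf_min, 0.5]`, and two haplotypes are summed per founder.  Markers
#' whose realized sample MAF falls below `maf_min` are re-thresholded with
#' a freshly drawn frequency (same latent column, preserving LD) for a
#' bounded number of retries.
#'
#' @param n_founders founder individuals (default 197).
#' @param n_markers markers (default 2000).
#' @param maf_min minimum minor allele frequency (default 0.3).
#' @param rho latent adjacent-marker autocorrelation in `[0, 1)`
#'   (default 0.5).
#' @param seed RNG seed.
#' @param max_retries per-marker re-threshold budget.
#' @return a `base_panel`: list with `genotypes` (founders x markers),
#'   `map`, `genotype_freqs` (3 x n_markers empirical genotype class
#'   frequencies), and the generating parameters.
#' @export
simulate_base_panel <- function(n_founders = 197L, n_markers = 2000L,
                                maf_min = 0.3, rho = 0.5, seed = NULL,
                                max_retries = 100L) {
  if (n_founders < 1L || n_markers < 1L) stop("counts must be positive")
  if (maf_min >= 0.5) stop("maf_min must be < 0.5")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  H <- 2L * n_founders
  local_seed(seed, {
    z <- matrix(0, H, n_markers)
    z[, 1L] <- rnorm(H)
    if (n_markers > 1L) {
      for (m in 2:n_markers) {
        z[, m] <- rho * z[, m - 1L] + sqrt(1 - rho^2) * rnorm(H)
      }
    }
    p <- runif(n_markers, maf_min, 0.5)
    hap <- sweep(z, 2L, qnorm(p), `<`)
    freq <- colMeans(hap)
    bad <- which(pmin(freq, 1 - freq) < maf_min)
    tries <- 0L
    while (length(bad) && tries < max_retries) {
      p[bad] <- runif(length(bad), maf_min, 0.5)
      hap[, bad] <- sweep(z[, bad, drop = FALSE], 2L, qnorm(p[bad]), `<`)
      freq <- colMeans(hap)
      bad <- which(pmin(freq, 1 - freq) < maf_min)
      tries <- tries + 1L
    }
    if (length(bad)) {
      stop("could not reach realized MAF >= maf_min after ", max_retries,
           " retries; try a smaller maf_min or more founders")
    }
    g <- hap[seq(1L, H, by = 2L), , drop = FALSE] +
      hap[seq(2L, H, by = 2L), , drop = FALSE]
    storage.mode(g) <- "integer"
    rownames(g) <- sprintf("founder%03d", seq_len(n_founders))
    colnames(g) <- sprintf("snp%05d", seq_len(n_markers))
    gf <- vapply(seq_len(n_markers),
                 function(m) tabulate(g[, m] + 1L, 3L) / n_founders,
                 numeric(3L))
    map <- data.frame(id = colnames(g), chrom = "1",
                      pos = 5000 * seq_len(n_markers))
    structure(list(genotypes = g, map = map, genotype_freqs = gf,
                   maf_min = maf_min, rho = rho, seed = seed),
              class = "base_panel")
  })
}

#' Resample new individuals from a base panel by haplotype-block shuffling
#'
#' Each simulated genotype is assembled by chopping the markers into
#' blocks of `block_size` and, for every block independently, copying one
#' founder's block genotype chosen uniformly at random.  Within-block LD of
#' the panel is conserved while the number of distinct composable
#' individuals grows as `n_founders ^ n_blocks`.
#'
#' @param panel a `base_panel` (or any list with a `genotypes` matrix).
#' @param block_size markers per block (trailing remainder block allowed).
#' @param n_individuals individuals to draw.
#' @param seed RNG seed.
#' @return genotype matrix `n_individuals x n_markers`.
#' @export
resample_individuals <- function(panel, block_size = 10L, n_individuals,
                                 seed = NULL) {
  gp <- panel$genotypes
  blocks <- make_windows(ncol(gp), block_size)
  local_seed(seed, {
    pick <- matrix(sample.int(nrow(gp), n_individuals * nrow(blocks),
                              replace = TRUE),
                   n_individuals, nrow(blocks))
    g <- matrix(0L, n_individuals, ncol(gp),
                dimnames = list(sprintf("ind%05d", seq_len(n_individuals)),
                                colnames(gp)))
    for (b in seq_len(nrow(blocks))) {
      cols <- blocks$start[b]:blocks$end[b]
      g[, cols] <- gp[pick[, b], cols, drop = FALSE]
    }
    g
  })
}

#' Hardy-Weinberg genotype class frequencies
#'
#' @param maf minor allele frequency.
#' @return numeric(3): probabilities of carrying 0, 1, 2 minor alleles.
#' @export
hwe_genotype_freqs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# Contract mode j of array A (dim rep(3, G)) against weights f (length 3),
# then broadcast the result back along mode j -- the "constant along locus
# j" component under the frequency-weighted decomposition.
.mode_const <- function(A, j, f) {
  G <- length(dim(A))
  perm <- c(j, setdiff(seq_len(G), j))
  B <- aperm(A, perm)
  m <- matrix(B, nrow = 3L)
  cm <- colSums(f * m)
  Bc <- array(matrix(rep(cm, each = 3L), nrow = 3L), dim = dim(B))
  aperm(Bc, order(perm))
}

#' Build a multi-locus penetrance table with exactly zero marginal effects
#'
#' Constructs penetrances `MP(g1, ..., gG)` such that for every causal
#' locus `i` and every genotype value `k`, the frequency-weighted marginal
#' penetrance equals the prevalence:
#' `sum over other loci of MP * freq = P(A | G_i = k) = P`.
#' The construction draws a random table, removes its grand mean and all
#' single-locus components under the frequency-weighted tensor
#' decomposition (leaving only pure interaction terms, which span the null
#' space of all `3 G` marginalization constraints), and scales the residual
#' so its largest absolute deviation from the prevalence equals
#' `effect_size`, clipping (with a warning) if that would push a
#' penetrance outside `[0, 1]`.
#'
#' For `G = 1` the null space is trivial: only the constant table exists,
#' so any positive `effect_size` is an error.
#'
#' @param G number of interacting causal loci (1-5 supported).
#' @param prevalence disease prevalence `P` in `(0, 1)` (0.5 for a
#'   balanced case-control design).
#' @param genotype_freqs per-locus genotype class frequencies: `G x 3`
#'   matrix (rows sum to 1), a list of length-`G`, or `NULL` for
#'   Hardy-Weinberg frequencies at MAF 0.3 for every locus.
#' @param effect_size largest absolute penetrance deviation from the
#'   prevalence (0 gives the constant table).
#' @param pattern `"random"` draws the interaction direction at random in
#'   the constraint null space (each draw has its own, possibly weak,
#'   detectable interaction energy); `"product"` uses the deterministic
#'   canonical rank-1 pattern `E = u_1 (x) ... (x) u_G` with each
#'   `u_i` the frequency-centred heterozygote-vs-homozygote contrast --
#'   the strongest "planted signal" available at a given `effect_size`
#'   (an XOR-like checkerboard for `G = 2`).
#' @param seed RNG seed for the random interaction draw
#'   (`pattern = "random"` only).
#' @return a `penetrance_table`: list with `MP` (array, dim `rep(3, G)`),
#'   `G`, `prevalence`, `genotype_freqs` (G x 3), `effect_size` (realized).
#' @export
build_penetrance_table <- function(G, prevalence = 0.5, genotype_freqs = NULL,
                                   effect_size = 0.5,
                                   pattern = c("random", "product"),
                                   seed = NULL) {
  pattern <- match.arg(pattern)
  if (G < 1L) stop("G must be >= 1")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (is.null(genotype_freqs)) {
    genotype_freqs <- matrix(rep(hwe_genotype_freqs(0.3), each = G), G, 3L)
  }
  if (is.list(genotype_freqs)) {
    genotype_freqs <- do.call(rbind, genotype_freqs)
  }
  if (!is.matrix(genotype_freqs) || nrow(genotype_freqs) != G ||
      ncol(genotype_freqs) != 3L) {
    stop("genotype_freqs must be a G x 3 matrix")
  }
  if (any(genotype_freqs < 0) ||
      any(abs(rowSums(genotype_freqs) - 1) > 1e-8)) {
    stop("each row of genotype_freqs must be a probability distribution")
  }
  dims <- rep(3L, G)
  if (G == 1L && effect_size > 0) {
    stop("G = 1: the zero-marginal-effect constraint forces the constant ",
         "table; effect_size must be 0")
  }
  if (effect_size == 0) {
    E <- array(0, dims)
  } else if (pattern == "product") {
    # deterministic pure-interaction direction: tensor product of per-locus
    # contrasts u_i with sum_k f_ik u_ik = 0, so every one-locus
    # marginalization vanishes; based on the heterozygote-vs-homozygote
    # contrast, giving the XOR-like checkerboard for G = 2
    E <- 1
    for (i in seq_len(G)) {
      f <- genotype_freqs[i, ]
      v <- c(1, -1, 1)
      u <- v - sum(f * v)
      if (max(abs(u)) < 1e-9) {
        v <- c(1, 0, -1)
        u <- v - sum(f * v)
      }
      E <- outer(E, u)
    }
    E <- array(E, dims)
  } else {
    E <- local_seed(seed, {
      for (attempt in 1:50) {
        R <- array(runif(3^G), dims)
        # remove grand mean and every single-locus component
        terms <- .mode_const(R, 1L, genotype_freqs[1L, ])
        for (j in seq_len(G)[-1L]) {
          terms <- .mode_const(terms, j, genotype_freqs[j, ])
        }
        mu_term <- terms              # fully contracted (constant) part
        res <- R - mu_term
        single <- array(0, dims)
        for (i in seq_len(G)) {
          Ti <- R
          for (j in setdiff(seq_len(G), i)) {
            Ti <- .mode_const(Ti, j, genotype_freqs[j, ])
          }
          single <- single + (Ti - mu_term)
        }
        E0 <- res - single
        if (max(abs(E0)) > 1e-9) break
      }
      if (max(abs(E0)) <= 1e-9) stop("degenerate interaction draw")
      E0
    })
  }
  if (effect_size > 0) {
    cmax_up <- (1 - prevalence) / max(E[E > 0], 1e-300)
    cmax_dn <- prevalence / max(-E[E < 0], 1e-300)
    c0 <- effect_size / max(abs(E))
    cm <- min(cmax_up, cmax_dn)
    if (c0 > cm) {
      warning("effect_size ", effect_size, " would push penetrances outside ",
              "[0, 1]; clipped to ", signif(cm * max(abs(E)), 4))
      c0 <- cm
    }
    E <- c0 * E
  }
  MP <- prevalence + E
  MP <- pmin(pmax(MP, 0), 1)
  pt <- structure(list(MP = array(MP, dims), G = as.integer(G),
                       prevalence = prevalence,
                       genotype_freqs = genotype_freqs,
                       effect_size = max(abs(E))),
                  class = "penetrance_table")
  resid <- max(abs(penetrance_marginals(pt) - prevalence))
  if (resid > 1e-10) stop("marginal constraint violated (residual ", resid, ")")
  pt
}

#' Frequency-weighted marginal penetrances of a penetrance table
#'
#' For each locus `i` and genotype value `k`, contracts the table against
#' the other loci's genotype frequencies; a valid zero-marginal-effect
#' table returns the prevalence in every entry.
#'
#' @param pt a `penetrance_table`.
#' @return `G x 3` matrix of marginal penetrances.
#' @export
penetrance_marginals <- function(pt) {
  G <- pt$G
  out <- matrix(NA_real_, G, 3L)
  for (i in seq_len(G)) {
    Ti <- pt$MP
    for (j in setdiff(seq_len(G), i)) {
      Ti <- .mode_const(Ti, j, pt$genotype_freqs[j, ])
    }
    # Ti is now constant along all modes but i; read off mode i
    for (k in 1:3) {
      idx <- rep(1L, G)
      idx[i] <- k
      out[i, k] <- Ti[matrix(idx, 1L)]
    }
  }
  out
}

#' Assign binary phenotypes from a penetrance table
#'
#' Each individual draws one uniform deviate `d`; the individual is
#' affected iff `d < MP(g)` where `g` is its multi-locus genotype at the
#' causal markers.
#'
#' @param g genotype matrix.
#' @param causal_markers column indices of the `G` causal markers.
#' @param pt a `penetrance_table` with matching `G`.
#' @param seed RNG seed.
#' @return named integer vector, 1 = affected (case), 0 = unaffected.
#' @export
assign_phenotypes <- function(g, causal_markers, pt, seed = NULL) {
  if (anyDuplicated(causal_markers)) stop("causal markers must be distinct")
  if (length(causal_markers) != pt$G) stop("need exactly G causal markers")
  idx <- g[, causal_markers, drop = FALSE] + 1L
  mp <- pt$MP[idx]
  local_seed(seed, {
    d <- runif(nrow(g))
    setNames(as.integer(d < mp), rownames(g))
  })
}

#' Randomly thin one marker out of every consecutive pair
#'
#' Emulates panels where the causative mutation may or may not have been
#' genotyped: from each pair of consecutive markers exactly one is kept,
#' chosen by a fair coin, halving the marker count (the last marker of an
#' odd panel is always kept).
#'
#' @param g genotype matrix.
#' @param map marker map (or `NULL`).
#' @param seed RNG seed.
#' @return list with `genotypes`, `map`, `kept` (original column indices).
#' @export
thin_markers <- function(g, map = NULL, seed = NULL) {
  M <- ncol(g)
  n_pairs <- M %/% 2L
  local_seed(seed, {
    coin <- sample(c(0L, 1L), n_pairs, replace = TRUE)
    kept <- 2L * seq_len(n_pairs) - 1L + coin
    if (M %% 2L == 1L) kept <- c(kept, M)
    list(genotypes = g[, kept, drop = FALSE],
         map = if (is.null(map)) NULL else map[kept, , drop = FALSE],
         kept = kept)
  })
}

#' Simulate a complete case-control epistasis dataset
#'
#' End-to-end generator: synthetic LD panel, block-resampled individuals,
#' random choice of `G` causal SNPs, zero-marginal-effect penetrance table
#' built on the panel's empirical genotype frequencies at the causal loci,
#' phenotype assignment with exact case/control quotas (individuals are
#' drawn in batches and kept until both quotas are met), and optional
#' thinning of one marker out of every two.  `G = 0` produces a null
#' dataset (phenotypes are fair coin flips at the given prevalence, no
#' causal record) for false-positive-rate experiments.
#'
#' @param G number of interacting causal SNPs (0 for a null dataset).
#' @param n_cases,n_controls quotas (defaults 500/500).
#' @param n_markers,n_founders,maf_min,rho,block_size panel and resampling
#'   parameters, see [simulate_base_panel()] and [resample_individuals()].
#' @param effect_size largest penetrance deviation, see
#'   [build_penetrance_table()].
#' @param pattern interaction pattern of the penetrance table:
#'   `"random"` (default; emulates drawing an arbitrary zero-marginal
#'   epistasis model) or `"product"` (deterministic canonical planted
#'   signal), see [build_penetrance_table()].
#' @param prevalence disease prevalence (0.5 for the balanced design).
#' @param thin discard one marker of every consecutive pair after
#'   phenotype assignment.
#' @param causal_markers optional explicit causal column indices
#'   (default: drawn uniformly without replacement -- causal SNPs may or
#'   may not be in LD with each other).
#' @param freq_mode `"panel"` uses the founders' empirical genotype
#'   frequencies for the marginal constraint (matches the distribution the
#'   resampled cohort is drawn from); `"hwe"` uses Hardy-Weinberg
#'   frequencies at each causal marker's panel MAF.
#' @param panel optionally, a pre-built `base_panel` (e.g. from real data)
#'   to reproduce the resampling protocol on a genuine LD structure.
#' @param seed master seed; all internal streams are derived from it.
#' @param max_batches resampling batch budget before giving up on quotas.
#' @return list with `genotypes`, `map`, `phenotypes` (named 0/1), and
#'   `truth` (causal ids and pre/post-thinning indices, penetrance table,
#'   seeds, config echo).
#' @export
simulate_dataset <- function(G = 2L, n_cases = 500L, n_controls = 500L,
                             n_markers = 2000L, n_founders = 197L,
                             maf_min = 0.3, rho = 0.5, block_size = 10L,
                             effect_size = 0.5, prevalence = 0.5,
                             pattern = c("random", "product"),
                             thin = TRUE, causal_markers = NULL,
                             freq_mode = c("panel", "hwe"), panel = NULL,
                             seed = 1L, max_batches = 50L) {
  freq_mode <- match.arg(freq_mode)
  pattern <- match.arg(pattern)
  if (n_cases < 1L || n_controls < 1L) stop("quotas must be positive")
  if (is.null(panel)) {
    panel <- simulate_base_panel(n_founders, n_markers, maf_min, rho,
                                 seed = seed_for(seed, 11L))
  }
  M <- ncol(panel$genotypes)
  if (G > 0L) {
    causal <- if (!is.null(causal_markers)) {
      as.integer(causal_markers)
    } else {
      local_seed(seed_for(seed, 12L), sort(sample.int(M, G)))
    }
    if (length(causal) != G || anyDuplicated(causal)) {
      stop("need G distinct causal markers")
    }
    freqs <- if (freq_mode == "panel") {
      t(panel$genotype_freqs[, causal, drop = FALSE])
    } else {
      maf <- minor_allele_frequencies(panel$genotypes)[causal]
      do.call(rbind, lapply(pmin(maf, 1 - maf), hwe_genotype_freqs))
    }
    pt <- build_penetrance_table(G, prevalence, freqs, effect_size,
                                 pattern = pattern,
                                 seed = seed_for(seed, 13L))
  } else {
    causal <- integer(0)
    pt <- NULL
  }

  n_total <- n_cases + n_controls
  got_case <- 0L; got_ctrl <- 0L
  rows <- vector("list", max_batches)
  phs <- vector("list", max_batches)
  batch <- 0L
  while ((got_case < n_cases || got_ctrl < n_controls) && batch < max_batches) {
    batch <- batch + 1L
    nb <- max(2L * n_total, 200L)
    gb <- resample_individuals(panel, block_size, nb,
                               seed = seed_for(seed, 20L + batch))
    ph <- if (G > 0L) {
      assign_phenotypes(gb, causal, pt, seed = seed_for(seed, 60L + batch))
    } else {
      local_seed(seed_for(seed, 60L + batch),
                 setNames(as.integer(runif(nb) < prevalence), rownames(gb)))
    }
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    take <- c(utils::head(which(ph == 1L), need_case),
              utils::head(which(ph == 0L), need_ctrl))
    rows[[batch]] <- gb[take, , drop = FALSE]
    phs[[batch]] <- ph[take]
    got_case <- got_case + min(need_case, sum(ph == 1L))
    got_ctrl <- got_ctrl + min(need_ctrl, sum(ph == 0L))
  }
  if (got_case < n_cases || got_ctrl < n_controls) {
    stop("could not meet case/control quotas in ", max_batches,
         " batches (penetrances too extreme?)")
  }
  g <- do.call(rbind, rows[seq_len(batch)])
  status <- unlist(phs[seq_len(batch)], use.names = FALSE)
  ids <- sprintf("ind%05d", seq_len(nrow(g)))
  rownames(g) <- ids
  status <- setNames(as.integer(status), ids)

  map <- panel$map
  kept <- seq_len(M)
  causal_post <- causal
  if (thin) {
    th <- thin_markers(g, map, seed = seed_for(seed, 14L))
    g <- th$genotypes
    map <- th$map
    kept <- th$kept
    causal_post <- match(causal, kept)  # NA when the causal SNP was discarded
  }
  truth <- list(G = G,
                causal_index = causal,
                causal_id = if (G > 0L) panel$map$id[causal] else character(0),
                causal_post_thin = causal_post,
                penetrance = pt,
                kept = kept,
                seed = seed,
                config = list(n_cases = n_cases, n_controls = n_controls,
                              n_markers = M, n_founders = nrow(panel$genotypes),
                              maf_min = maf_min, rho = rho,
                              block_size = block_size,
                              effect_size = effect_size,
                              prevalence = prevalence, pattern = pattern,
                              thin = thin,
                              freq_mode = freq_mode))
  list(genotypes = g, map = map, phenotypes = status, truth = truth)
}
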