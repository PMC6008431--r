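## Ground-truthed simulators. Every generator is a pure function of
## (parameters, seed): the caller's RNG state is saved and restored, and the
## returned truth record carries the parameters and seed so any dataset can
## be regenerated bit-identically.

#' Random barcode panels and plate maps for simulation
#'
#' Draws random A/C/G/T barcodes with a guaranteed minimum pairwise Hamming
#' distance (rejection sampling), so the panel passes [validate_panel()] at
#' the matching tolerance.
#'
#' @param n number of entries.
#' @param bc_len barcode length (nt).
#' @param min_dist minimum pairwise Hamming distance (default 3, safe for
#'   single-error correction).
#' @param prefix id prefix.
#' @param seed RNG seed.
#' @return character vector of barcodes named by id.
#' @export
simulate_barcodes <- function(n, bc_len = 10L, min_dist = 3L,
                              prefix = "BC", seed = 1L) {
  with_seed(seed, {
    bcs <- character(0)
    mats <- list()
    tries <- 0L
    while (length(bcs) < n) {
      cand <- random_dna(1L, bc_len)
      tries <- tries + 1L
      if (tries > 1000L * n)
        stop("cannot place ", n, " barcodes of length ", bc_len,
             " at distance ", min_dist)
      cc <- strsplit(cand, "")[[1L]]
      ok <- TRUE
      for (m in mats) if (sum(m != cc) < min_dist) { ok <- FALSE; break }
      if (ok) {
        bcs <- c(bcs, cand)
        mats[[length(mats) + 1L]] <- cc
      }
    }
    stats::setNames(bcs, paste0(prefix, seq_len(n)))
  })
}

#' Simulate a plate map with treatment / replicate / batch structure
#'
#' @param n_wells number of wells.
#' @param treatments character vector of treatment labels recycled over
#'   wells (default control vs treated).
#' @param n_replicates replicates cycled within treatment (default 2).
#' @param n_batches batches assigned in contiguous blocks (default 2).
#' @param bc_len well-barcode length (default 10).
#' @param seed RNG seed.
#' @return a [plate_map()].
#' @export
simulate_plate <- function(n_wells = 96L,
                           treatments = c("control", "treated"),
                           n_replicates = 2L, n_batches = 2L,
                           bc_len = 10L, seed = 1L) {
  bcs <- simulate_barcodes(n_wells, bc_len, prefix = "W", seed = seed)
  ids <- sprintf("well%03d", seq_len(n_wells))
  cov <- data.frame(
    treatment = rep_len(treatments, n_wells),
    replicate = paste0("rep", rep_len(rep(seq_len(n_replicates),
                                          each = length(treatments)),
                                      n_wells)),
    batch = paste0("batch", rep(seq_len(n_batches),
                                each = ceiling(n_wells / n_batches),
                                length.out = n_wells)),
    stringsAsFactors = FALSE)
  plate_map(ids, unname(bcs), covariates = cov)
}

#' Simulate an antibody panel
#' @param n_antibodies panel size (default 70).
#' @param bc_len barcode length (default 10).
#' @param seed RNG seed.
#' @return an [antibody_panel()].
#' @export
simulate_panel <- function(n_antibodies = 70L, bc_len = 10L, seed = 1L) {
  bcs <- simulate_barcodes(n_antibodies, bc_len, prefix = "A", seed = seed)
  antibody_panel(sprintf("ab%02d", seq_len(n_antibodies)), unname(bcs))
}

#' Simulate triple-barcoded FASTQ reads with PCR duplicates and errors
#'
#' For every (antibody, well) cell of `truth_counts`, draws that many
#' distinct random UMIs, emits each molecule `1 + Geometric(duplication_rate)`
#' times (memoryless PCR resampling; expected duplicate fraction equals
#' `duplication_rate`), applies independent per-base substitution errors at
#' `barcode_error_rate` to the two barcode segments, assembles reads
#' following `layout`, and writes them in shuffled order.
#'
#' @param panel an [antibody_panel()].
#' @param plate a [plate_map()].
#' @param layout a [read_layout()].
#' @param truth_counts antibodies x wells integer matrix of true distinct
#'   molecules; alternatively a single number used for every cell.
#' @param duplication_rate probability in `[0, 1)` governing PCR duplication.
#' @param barcode_error_rate per-base substitution probability in `[0, 1)`
#'   applied to barcode bases.
#' @param seed RNG seed.
#' @param path optional FASTQ output path (`.gz` supported); if `NULL`, the
#'   reads are returned in memory.
#' @return list with `reads` (character vector, `NULL` when written to
#'   `path`), `path`, and `truth` (truth record: parameters, seed and the
#'   truth count matrix).
#' @export
simulate_fastq <- function(panel, plate, layout, truth_counts,
                           duplication_rate = 0.05,
                           barcode_error_rate = 0.001,
                           seed = 1L, path = NULL) {
  stopifnot(inherits(panel, "antibody_panel"), inherits(plate, "plate_map"),
            inherits(layout, "read_layout"))
  if (duplication_rate < 0 || duplication_rate >= 1)
    stop("duplication_rate must be in [0, 1)")
  if (barcode_error_rate < 0 || barcode_error_rate >= 1)
    stop("barcode_error_rate must be in [0, 1)")
  n_ab <- length(panel$ids); n_well <- length(plate$ids)
  if (length(truth_counts) == 1L)
    truth_counts <- matrix(as.integer(truth_counts), n_ab, n_well)
  truth_counts <- as.matrix(truth_counts)
  dimnames(truth_counts) <- list(panel$ids, plate$ids)
  if (any(truth_counts > 4^layout$umi_len))
    stop("truth count exceeds the UMI space (4^umi_len)")

  reads <- with_seed(seed, {
    umi_list <- vector("list", n_ab * n_well)
    a_idx <- integer(0); w_idx <- integer(0); n_mol <- integer(n_ab * n_well)
    cell <- 0L
    for (w in seq_len(n_well)) {
      for (a in seq_len(n_ab)) {
        cell <- cell + 1L
        k <- truth_counts[a, w]
        if (k == 0L) next
        umis <- unique(random_dna(k + ceiling(0.1 * k) + 5L, layout$umi_len))
        while (length(umis) < k)
          umis <- unique(c(umis, random_dna(k, layout$umi_len)))
        umis <- umis[seq_len(k)]
        copies <- 1L + stats::rgeom(k, prob = 1 - duplication_rate)
        umi_list[[cell]] <- rep(umis, copies)
        n_mol[cell] <- sum(copies)
        a_idx <- c(a_idx, a); w_idx <- c(w_idx, w)
      }
    }
    filled <- n_mol > 0L
    if (!any(filled)) character(0) else {
      mol_umi <- unlist(umi_list[filled], use.names = FALSE)
      mol_a <- rep(a_idx, n_mol[filled])
      mol_w <- rep(w_idx, n_mol[filled])
      bc1 <- unname(panel$barcodes)[mol_a]
      bc2 <- unname(plate$barcodes)[mol_w]
      if (barcode_error_rate > 0) {
        bc1 <- mutate_bases(bc1, barcode_error_rate)
        bc2 <- mutate_bases(bc2, barcode_error_rate)
      }
      parts <- list(UMI = mol_umi, ANCHOR = layout$anchor,
                    BC1 = bc1, BC2 = bc2)
      rd <- do.call(paste0, parts[layout$segment_order])
      sample(rd)
    }
  })

  truth <- list(kind = "fastq", seed = seed,
                parameters = list(duplication_rate = duplication_rate,
                                  barcode_error_rate = barcode_error_rate,
                                  umi_len = layout$umi_len),
                counts = truth_counts)
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(reads)) {
      qual <- strrep("I", nchar(reads[1L]))
      writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual),
                 con)
    }
    return(list(reads = NULL, path = path, truth = truth))
  }
  list(reads = reads, path = NULL, truth = truth)
}

## Independent per-base substitutions at rate `rate` on equal-length strings.
mutate_bases <- function(seqs, rate) {
  L <- nchar(seqs[1L])
  n <- length(seqs)
  hit <- matrix(stats::runif(n * L) < rate, n, L)
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      cur <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  seqs
}

#' Simulate a negative-binomial UMI count matrix with planted effects
#'
#' Counts follow `NB(mean = s_w * mu_a * exp(x_w * beta_a), dispersion)`
#' where `s_w` is a well size factor drawn log-uniformly over `depth_range`,
#' `mu_a` a per-antibody baseline drawn log-normally, and `x_w` the 0/1
#' treatment indicator from the plate covariates. Optional log-scale normal
#' replicate and batch effects emulate nuisance structure.
#'
#' @param plate a [plate_map()] with covariates (`treatment` column; first
#'   level alphabetically is baseline).
#' @param n_antibodies number of antibody rows (default 70).
#' @param effects per-antibody natural-log fold change of the non-baseline
#'   treatment level; recycled (default 0).
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha mu^2.
#' @param depth_range range of well size factors, drawn log-uniform
#'   (default c(0.5, 2)).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-antibody baseline mean (defaults log(500), 1).
#' @param replicate_sd,batch_sd standard deviation of log-scale replicate /
#'   batch effects (default 0).
#' @param seed RNG seed.
#' @return list with `counts` (a `umi_counts`-compatible integer matrix),
#'   and `truth` (seed, parameters, per-antibody effects, well size factors,
#'   baselines).
#' @export
simulate_counts <- function(plate, n_antibodies = 70L, effects = 0,
                            dispersion = 0.2, depth_range = c(0.5, 2),
                            baseline_meanlog = log(500), baseline_sdlog = 1,
                            replicate_sd = 0, batch_sd = 0, seed = 1L) {
  stopifnot(inherits(plate, "plate_map"))
  if (dispersion <= 0) stop("dispersion must be > 0")
  cov <- plate$covariates
  if (is.null(cov) || !"treatment" %in% names(cov))
    stop("plate must carry a treatment covariate")
  tr <- factor(cov$treatment)
  x <- as.integer(tr != levels(tr)[1L])
  n_well <- length(plate$ids)
  beta <- rep_len(effects, n_antibodies)
  with_seed(seed, {
    s_w <- exp(stats::runif(n_well, log(depth_range[1L]), log(depth_range[2L])))
    mu_a <- exp(stats::rnorm(n_antibodies, baseline_meanlog, baseline_sdlog))
    log_mu <- outer(log(mu_a), log(s_w), "+") + outer(beta, x)
    if (replicate_sd > 0 && "replicate" %in% names(cov)) {
      re <- stats::rnorm(nlevels(factor(cov$replicate)), 0, replicate_sd)
      log_mu <- log_mu + matrix(re[as.integer(factor(cov$replicate))],
                                n_antibodies, n_well, byrow = TRUE)
    }
    if (batch_sd > 0 && "batch" %in% names(cov)) {
      be <- stats::rnorm(nlevels(factor(cov$batch)), 0, batch_sd)
      log_mu <- log_mu + matrix(be[as.integer(factor(cov$batch))],
                                n_antibodies, n_well, byrow = TRUE)
    }
    counts <- matrix(stats::rnbinom(n_antibodies * n_well,
                                    size = 1 / dispersion,
                                    mu = exp(log_mu)),
                     n_antibodies, n_well,
                     dimnames = list(sprintf("ab%02d", seq_len(n_antibodies)),
                                     plate$ids))
    list(counts = counts,
         truth = list(kind = "counts", seed = seed,
                      parameters = list(dispersion = dispersion,
                                        depth_range = depth_range,
                                        baseline_meanlog = baseline_meanlog,
                                        baseline_sdlog = baseline_sdlog,
                                        replicate_sd = replicate_sd,
                                        batch_sd = batch_sd),
                      effects = beta, size_factors = s_w, baseline = mu_a))
  })
}

#' Simulate a screen matrix with planted low-rank structure and probe sets
#'
#' Emulates the geometry of a kinase-inhibitor screen read out over many
#' molecular phenotypes: a probes x phenotypes signed-p-style matrix built
#' from planted orthogonal axes (e.g. a signalling axis and a
#' differentiation axis) plus Gaussian noise, and a probes x kinases
#' %-inhibition matrix in which each kinase's true member probes receive
#' high inhibition values. Kinase-inhibitor probes are polypharmacological:
#' a coherent pool of "differentiation-inducing" probes (default 24)
#' carries the planted shift on the last axis, and each active kinase's
#' member probes are drawn from that pool — so active kinases share
#' overlapping probe groups, the way a family of kinases upstream of one
#' phenotype is inhibited by overlapping chemotypes. Inactive kinases draw
#' members from the remaining probes.
#'
#' @param n_probes,n_phenotypes,n_kinases matrix geometry (defaults 294 x 70
#'   probes x phenotypes, 225 kinases).
#' @param n_axes number of planted orthonormal axes (default 2).
#' @param axis_sd per-axis score standard deviations, decreasing (default
#'   `c(6, 2.5)`: a dominant signalling axis and a weaker differentiation
#'   axis, recycled to `n_axes`).
#' @param noise_sd entry-level Gaussian noise (default 1).
#' @param n_active_kinases number of kinases whose member probes come from
#'   the planted pool (the "differentiation" kinases; default 10).
#' @param n_diff_probes size of the shared differentiation-inducing probe
#'   pool (default 24).
#' @param probes_per_kinase true members per kinase (default 10, the size
#'   of a typical kinase-inhibitor probe set).
#' @param planted_shift score shift of the differentiation-probe pool on
#'   the last axis (default 10, separating responder probes from the bulk
#'   as seen for strong differentiation-inducing inhibitors).
#' @param inhibition_high mean % inhibition of true members (default 85).
#' @param seed RNG seed.
#' @return list with `values` (probes x phenotypes), `inhibition` (probes x
#'   kinases, in `[0, 100]`), and `truth` (axes, per-probe axis scores,
#'   member lists, active kinases, parameters, seed).
#' @export
simulate_screen <- function(n_probes = 294L, n_phenotypes = 70L,
                            n_kinases = 225L, n_axes = 2L,
                            axis_sd = c(6, 2.5), noise_sd = 1,
                            n_active_kinases = 10L, n_diff_probes = 24L,
                            probes_per_kinase = 10L,
                            planted_shift = 10, inhibition_high = 85,
                            seed = 1L) {
  if (n_axes > min(n_probes, n_phenotypes)) stop("n_axes too large")
  if (n_active_kinases > n_kinases)
    stop("n_active_kinases cannot exceed n_kinases")
  if (n_diff_probes >= n_probes)
    stop("n_diff_probes must be smaller than n_probes")
  if (probes_per_kinase > min(n_diff_probes, n_probes - n_diff_probes))
    stop("probes_per_kinase exceeds the available probe pools")
  axis_sd <- rep_len(axis_sd, n_axes)
  probes <- sprintf("probe%03d", seq_len(n_probes))
  phenos <- sprintf("ph%02d", seq_len(n_phenotypes))
  kinases <- sprintf("KIN%03d", seq_len(n_kinases))
  with_seed(seed, {
    ## orthonormal loadings via QR of a Gaussian matrix
    Q <- qr.Q(qr(matrix(stats::rnorm(n_phenotypes * n_axes), n_phenotypes)))
    scores <- matrix(stats::rnorm(n_probes * n_axes), n_probes) %*%
      diag(axis_sd, n_axes)
    active <- sample(kinases, n_active_kinases)
    diff_pool <- sample(probes, n_diff_probes)
    other_pool <- setdiff(probes, diff_pool)
    members <- stats::setNames(vector("list", n_kinases), kinases)
    for (k in kinases) {
      members[[k]] <- if (k %in% active) {
        sort(sample(diff_pool, probes_per_kinase))
      } else {
        sort(sample(other_pool, probes_per_kinase))
      }
    }
    scores[match(diff_pool, probes), n_axes] <-
      scores[match(diff_pool, probes), n_axes] + planted_shift
    values <- scores %*% t(Q) +
      matrix(stats::rnorm(n_probes * n_phenotypes, 0, noise_sd), n_probes)
    dimnames(values) <- list(probes, phenos)
    inhibition <- matrix(pmin(pmax(stats::rnorm(n_probes * n_kinases, 15, 8),
                                   0), 100),
                         n_probes, n_kinases,
                         dimnames = list(probes, kinases))
    for (k in kinases) {
      idx <- match(members[[k]], probes)
      inhibition[idx, k] <- pmin(pmax(stats::rnorm(length(idx),
                                                   inhibition_high, 5),
                                      0), 100)
    }
    list(values = values, inhibition = inhibition,
         truth = list(kind = "screen", seed = seed,
                      parameters = list(n_axes = n_axes, axis_sd = axis_sd,
                                        noise_sd = noise_sd,
                                        planted_shift = planted_shift,
                                        probes_per_kinase = probes_per_kinase,
                                        inhibition_high = inhibition_high),
                      axes = Q, axis_scores = scores,
                      members = members, active_kinases = active,
                      diff_probes = diff_pool))
  })
}

#' Serialize a truth record next to a generated dataset
#' @param truth truth record from a `simulate_*` function.
#' @param path JSON output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
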