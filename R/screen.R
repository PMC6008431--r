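#' Principal-component aggregation of a screen matrix
#'
#' Combines per-probe effects over many molecular phenotypes (signed
#' -log10 p-values or model estimates) into principal components. Columns
#' are mean-centered by default and not variance-scaled: signed-p values
#' already share a scale across phenotypes. The sign of each component is
#' fixed by convention: the loading with the largest magnitude is positive.
#'
#' @param values probes x phenotypes numeric matrix with dimnames; entries
#'   must be finite (impute explicitly before calling).
#' @param k number of components to return (default 5).
#' @param scale. also scale columns to unit variance (default `FALSE`).
#' @param center mean-center columns (default `TRUE`).
#' @return object of class `screen_pca`: `scores` (probes x k), `loadings`
#'   (phenotypes x k), `variance_explained` (length-k proportions of total
#'   variance), `center`, `scale`.
#' @export
screen_pca <- function(values, k = 5L, scale. = FALSE, center = TRUE) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("screen matrix has missing/non-finite values; impute explicitly ",
         "(e.g. impute_screen_matrix()) before PCA")
  k <- as.integer(k)
  if (k < 1L || k > min(dim(values)))
    stop("k must be between 1 and min(dim(values))")
  pc <- stats::prcomp(values, center = center, scale. = scale.)
  k_avail <- min(k, ncol(pc$rotation))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k_avail), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k_avail), drop = FALSE]
  for (j in seq_len(k_avail)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve[seq_len(k_avail)],
                 center = pc$center, scale = pc$scale),
            class = "screen_pca")
}

#' @export
print.screen_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("Screen PCA:", nrow(x$scores), "probes,", nrow(x$loadings),
      "phenotypes,", k, "components\n")
  cat("  variance explained:",
      paste0(round(100 * x$variance_explained, 1), "%", collapse = ", "),
      "(cumulative ", round(100 * sum(x$variance_explained), 1), "%)\n",
      sep = "")
  invisible(x)
}

#' Replace missing screen-matrix entries by the phenotype mean
#' @param values probes x phenotypes matrix possibly containing `NA`.
#' @return matrix with `NA`s replaced by their column means (0 if a whole
#'   column is missing).
#' @export
impute_screen_matrix <- function(values) {
  values <- as.matrix(values)
  for (j in seq_len(ncol(values))) {
    miss <- !is.finite(values[, j])
    if (any(miss)) {
      fill <- mean(values[!miss, j])
      values[miss, j] <- if (is.finite(fill)) fill else 0
    }
  }
  values
}

#' Correlate phenotypes with principal components
#'
#' Pearson-correlates each phenotype column of the screen matrix with each of
#' the top PC score vectors, and orders phenotypes by average-linkage
#' hierarchical clustering on correlation distance (1 - r between the
#' phenotypes' correlation profiles), mirroring the clustered
#' phenotype-by-PC heat maps used to attach biological meaning to PCs.
#'
#' @param values probes x phenotypes matrix used for the PCA.
#' @param pca a [screen_pca()] result.
#' @param top_k number of PCs to correlate (default: all in `pca`).
#' @return list with `correlations` (phenotypes x top_k), `order` (row order
#'   from clustering) and `hclust`.
#' @export
annotate_pcs <- function(values, pca, top_k = ncol(pca$scores)) {
  stopifnot(inherits(pca, "screen_pca"))
  top_k <- as.integer(top_k)
  if (top_k < 1L || top_k > ncol(pca$scores))
    stop("top_k must be between 1 and the number of computed PCs")
  values <- as.matrix(values)
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant phenotype column(s): correlation set to 0 for ",
            paste(colnames(values)[sds == 0], collapse = ", "))
  cors <- suppressWarnings(
    stats::cor(values, pca$scores[, seq_len(top_k), drop = FALSE]))
  cors[!is.finite(cors)] <- 0
  if (nrow(cors) > 2L) {
    dmat <- 1 - suppressWarnings(stats::cor(t(cors)))
    dmat[!is.finite(dmat)] <- 2  # constant profiles: maximal distance
    hc <- stats::hclust(stats::as.dist(dmat), method = "average")
    ord <- hc$order
  } else {
    hc <- NULL
    ord <- seq_len(nrow(cors))
  }
  list(correlations = cors, order = ord, hclust = hc)
}

#' Contrast phenotypes between top and bottom probes of a PC
#'
#' Ranks probes by a principal-component score and compares, for each
#' phenotype, the top `fraction` against the bottom `fraction` of probes
#' with a Welch t-test; Benjamini-Hochberg q-values across phenotypes. A
#' phenotype is called significant when `p < alpha` and `q < fdr`.
#'
#' @param values probes x phenotypes matrix (signed-p or estimates).
#' @param pc_scores numeric vector of scores named by probe (e.g. one column
#'   of `screen_pca()$scores`).
#' @param fraction tail fraction on each side (default 0.10).
#' @param alpha p-value threshold (default 0.01).
#' @param fdr q-value threshold (default 0.01).
#' @return data frame: phenotype, mean_top, mean_bottom, t_stat, direction
#'   (+1/-1), p_value, q_value, significant.
#' @export
decile_contrast <- function(values, pc_scores, fraction = 0.10,
                            alpha = 0.01, fdr = 0.01) {
  values <- as.matrix(values)
  if (!(fraction > 0 && fraction <= 0.5))
    stop("fraction must be in (0, 0.5]")
  if (is.null(names(pc_scores)))
    names(pc_scores) <- rownames(values)
  common <- intersect(rownames(values), names(pc_scores))
  if (length(common) < 6L) stop("need at least 6 probes shared with pc_scores")
  sc <- pc_scores[common]
  ## deterministic ranking: score descending, probe id breaks ties
  ord <- common[order(-sc, common)]
  n_sel <- max(1L, floor(fraction * length(ord)))
  top <- ord[seq_len(n_sel)]
  bottom <- rev(ord)[seq_len(n_sel)]
  res <- lapply(colnames(values) %||% seq_len(ncol(values)), function(ph) {
    x <- values[top, ph]; y <- values[bottom, ph]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 3L || length(y) < 3L) {
      warning("phenotype ", ph, " skipped: fewer than 3 values per group")
      return(data.frame(phenotype = ph, mean_top = NA_real_,
                        mean_bottom = NA_real_, t_stat = NA_real_,
                        direction = NA_real_, p_value = NA_real_))
    }
    wt <- welch_t(x, y)
    data.frame(phenotype = ph, mean_top = mean(x), mean_bottom = mean(y),
               t_stat = wt$t, direction = sign(mean(x) - mean(y)),
               p_value = wt$p)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha &
    out$q_value < fdr
  out
}

## Welch t-test robust to zero-variance groups: equal means give p = 1.
welch_t <- function(x, y) {
  v <- stats::var(x) / length(x) + stats::var(y) / length(y)
  d <- mean(x) - mean(y)
  if (v == 0) return(list(t = 0, p = if (d == 0) 1 else 0))
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Assign inhibitory probe sets to kinases by outlier statistics
#'
#' For each kinase (column of the %-inhibition matrix) the probes that
#' inhibit it unusually strongly are identified as upper-tail outliers of a
#' robust z-score: `z = (x - median) / (1.4826 * MAD)` with normal tail
#' probability `p = P(Z > z)`; probes with `p < alpha` form the kinase's
#' probe set. Columns with zero MAD (most probes at one value) fall back to
#' a rank rule: probes strictly above the column median whose upper-tail
#' empirical fraction (rank from top / n) is at most `alpha`.
#'
#' @param inhibition probes x kinases matrix of % inhibition in `[0, 100]`.
#' @param alpha upper-tail threshold (default 0.01).
#' @return named list (one element per kinase) of class-`probe_set` lists:
#'   `kinase`, `members`, `inhibition` (members' %), `p_value` (members'
#'   assignment p, `NA` under the rank fallback).
#' @export
assign_probe_sets <- function(inhibition, alpha = 0.01) {
  m <- as.matrix(inhibition)
  if (any(m < 0 | m > 100, na.rm = TRUE))
    stop("inhibition values must lie in [0, 100]")
  kinases <- colnames(m) %||% paste0("K", seq_len(ncol(m)))
  probes <- rownames(m) %||% paste0("probe", seq_len(nrow(m)))
  out <- stats::setNames(vector("list", ncol(m)), kinases)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- is.finite(x)
    med <- stats::median(x[ok])
    madj <- stats::mad(x[ok])  # constant = 1.4826
    if (madj > 0) {
      z <- (x - med) / madj
      p <- stats::pnorm(z, lower.tail = FALSE)
      sel <- ok & p < alpha
      pv <- p[sel]
    } else if (all(x[ok] == med)) {
      warning("kinase ", kinases[j], ": constant inhibition column, ",
              "empty probe set")
      sel <- rep(FALSE, length(x))
      pv <- numeric(0)
    } else {
      above <- ok & x > med
      r <- rank(-x[above], ties.method = "max")
      keep <- r / sum(ok) <= alpha
      sel <- above
      sel[above] <- keep
      pv <- rep(NA_real_, sum(sel))
    }
    out[[j]] <- structure(list(kinase = kinases[j], members = probes[sel],
                               inhibition = unname(x[sel]), p_value = unname(pv)),
                          class = "probe_set")
  }
  out
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe set for ", x$kinase, ": ", length(x$members), " probes\n",
      sep = "")
  invisible(x)
}

## Normalise the many accepted set formats to a named list of member vectors.
as_member_list <- function(sets) {
  if (inherits(sets, "probe_set")) sets <- list(sets)
  nm <- names(sets)
  members <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s) && !is.null(s$members)) as.character(s$members)
    else as.character(s)
  })
  names(members) <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s) && !is.null(s$kinase)) as.character(s$kinase)
    else nm[i] %||% paste0("set", i)
  }, character(1))
  members
}

## Weighted Kolmogorov-Smirnov running-sum enrichment score evaluated only
## at member positions (the running sum is piecewise linear between hits).
## pos: sorted ranks of the members; w: |score|^weight at every rank.
es_from_positions <- function(pos, w, n) {
  m <- length(pos)
  wp <- w[pos]
  nr <- sum(wp)
  if (nr == 0) wp[] <- 1 / m else wp <- wp / nr
  cw <- cumsum(wp)
  miss_step <- 1 / (n - m)
  after <- cw - (pos - seq_len(m)) * miss_step
  before <- c(0, cw[-m]) - (pos - seq_len(m)) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Probe-set enrichment along a principal-component ranking
#'
#' GSEA-style weighted Kolmogorov-Smirnov statistic: probes are ranked by
#' `pc_scores` (descending, ties broken by probe id) and, for each probe
#' set, the running-sum enrichment score (weight exponent `weight`, classic
#' value 1) is compared with a permutation null obtained by resampling
#' member labels. Enrichment at the top of the ranking gives a positive ES.
#'
#' Significance is reported two ways. `p_value` is the per-set permutation
#' p (two-sided on |ES|), with Benjamini-Hochberg adjustment in `q_bh`.
#' The primary FDR, `q_value`, follows the canonical GSEA recipe: each ES
#' is normalised by the mean same-sign permutation |ES| of its own set
#' (`nes`), the normalised permutation scores of all sets are pooled, and
#' the sign-stratified FDR is the pooled-null tail fraction beyond `nes`
#' divided by the observed tail fraction. Per-set p-values floor at
#' `1/(n_perm+1)`, which BH cannot push below any practical set-level FDR
#' when hundreds of sets are tested; the pooled null has resolution
#' `~1/(n_sets * n_perm)` and is the statistic this screen's set-level
#' discovery cutoff is meant for.
#'
#' @param pc_scores numeric vector named by probe (the ranking variable).
#' @param sets probe sets: output of [assign_probe_sets()] or a named list
#'   of member-id vectors.
#' @param weight weight exponent on |score| (default 1).
#' @param n_perm number of label permutations (default 1000; use 10000 for
#'   final set-level discovery).
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param min_size sets smaller than this (after intersecting with the
#'   ranking) are skipped with a warning (default 3).
#' @return data frame of class `enrichment_table`: kinase, size, es, nes,
#'   p_value, q_value (pooled GSEA FDR), q_bh (BH on per-set p),
#'   leading_edge (comma-separated probe ids).
#' @export
gsea <- function(pc_scores, sets, weight = 1, n_perm = 1000L, seed = 1L,
                 min_size = 3L) {
  if (is.null(names(pc_scores))) stop("pc_scores must be named by probe")
  members <- as_member_list(sets)
  ord <- order(-pc_scores, names(pc_scores))
  ranked <- names(pc_scores)[ord]
  w <- abs(pc_scores[ord])^weight
  n <- length(ranked)
  rows <- list()
  null_nes <- list()
  with_seed(seed, {
    for (kin in names(members)) {
      mem <- intersect(members[[kin]], ranked)
      m <- length(mem)
      if (m < min_size) {
        warning("set ", kin, " skipped: fewer than ", min_size,
                " members in the ranking")
        next
      }
      if (m >= n) {
        warning("set ", kin, " skipped: set covers the whole ranking")
        next
      }
      pos <- sort(match(mem, ranked))
      es_obs <- es_from_positions(pos, w, n)
      es_null <- vapply(seq_len(n_perm), function(b) {
        es_from_positions(sort(sample.int(n, m)), w, n)
      }, numeric(1))
      p <- (1 + sum(abs(es_null) >= abs(es_obs))) / (n_perm + 1)
      ## sign-stratified normalisation by the set's own null
      pos_mean <- mean(es_null[es_null > 0])
      neg_mean <- mean(-es_null[es_null < 0])
      if (!is.finite(pos_mean)) pos_mean <- 1
      if (!is.finite(neg_mean)) neg_mean <- 1
      nes_obs <- if (es_obs >= 0) es_obs / pos_mean else es_obs / neg_mean
      null_nes[[kin]] <- ifelse(es_null >= 0, es_null / pos_mean,
                                es_null / neg_mean)
      ## leading edge: members at or before (after, for negative ES) the
      ## running-sum extremum
      cw <- cumsum((w[pos] / max(sum(w[pos]), .Machine$double.eps)))
      after <- cw - (pos - seq_along(pos)) / (n - m)
      if (es_obs >= 0) {
        lead <- ranked[pos[seq_len(which.max(after))]]
      } else {
        before <- c(0, cw[-m]) - (pos - seq_along(pos)) / (n - m)
        lead <- ranked[pos[seq(which.min(before), m)]]
      }
      rows[[kin]] <- data.frame(kinase = kin, size = m, es = es_obs,
                                nes = nes_obs, p_value = p,
                                leading_edge = paste(lead, collapse = ","),
                                stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) stop("no probe set passed the size filter")
  out <- do.call(rbind, rows)
  pool <- unlist(null_nes, use.names = FALSE)
  out$q_value <- gsea_pooled_fdr(out$nes, pool)
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, -abs(out$es)), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

## Pooled sign-stratified FDR over normalised enrichment scores: for each
## observed NES, (null tail fraction beyond it) / (observed tail fraction),
## computed within its sign stratum, clipped to [0, 1] and made monotone
## in |NES| within each stratum.
gsea_pooled_fdr <- function(nes, pool) {
  q <- rep(NA_real_, length(nes))
  for (s in c(1, -1)) {
    obs_idx <- which(sign(nes) == s | (s == 1 & nes == 0))
    if (!length(obs_idx)) next
    null_s <- if (s == 1) pool[pool >= 0] else -pool[pool < 0]
    obs_s <- abs(nes[obs_idx])
    q_s <- vapply(obs_s, function(v) {
      null_tail <- if (length(null_s)) mean(null_s >= v) else 0
      obs_tail <- mean(obs_s >= v)
      min(1, null_tail / obs_tail)
    }, numeric(1))
    ## enforce monotonicity: a more extreme NES never has a larger q
    ord_s <- order(obs_s, decreasing = TRUE)
    q_s[ord_s] <- cummax(q_s[ord_s])
    q[obs_idx] <- q_s
  }
  q
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat("Probe-set enrichment:", nrow(x), "sets tested\n")
  show <- utils::head(as.data.frame(x)[, c("kinase", "size", "es",
                                           "p_value", "q_value")], n)
  print(show, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Mean molecular-phenotype profile of each probe set
#'
#' @param estimates probes x phenotypes matrix of model estimates.
#' @param sets probe sets ([assign_probe_sets()] output or named list of
#'   member vectors).
#' @return list with `mean` (kinases x phenotypes), `se` (standard error,
#'   `NA` for singleton sets) and `size` (member count per kinase). Sets
#'   with no screened member are dropped with a warning.
#' @export
kinase_profiles <- function(estimates, sets) {
  est <- as.matrix(estimates)
  members <- as_member_list(sets)
  keep <- vapply(members, function(m) sum(m %in% rownames(est)) > 0, logical(1))
  if (!all(keep))
    warning("dropping sets with no screened member: ",
            paste(names(members)[!keep], collapse = ", "))
  members <- members[keep]
  prof <- matrix(NA_real_, length(members), ncol(est),
                 dimnames = list(names(members), colnames(est)))
  se <- prof
  sizes <- integer(length(members))
  for (i in seq_along(members)) {
    mm <- intersect(members[[i]], rownames(est))
    sizes[i] <- length(mm)
    sub <- est[mm, , drop = FALSE]
    prof[i, ] <- colMeans(sub)
    se[i, ] <- if (length(mm) > 1L) {
      apply(sub, 2L, stats::sd) / sqrt(length(mm))
    } else NA_real_
  }
  list(mean = prof, se = se, size = stats::setNames(sizes, names(members)))
}

#' Cluster probe-set profiles and contrast each set with a reference
#'
#' K-means clusters the kinase x phenotype mean-effect profiles (best of
#' `restarts` random starts by within-cluster sum of squares), and compares
#' each kinase's member-probe estimates with the reference kinase's, one
#' Welch t-test per phenotype.
#'
#' @param profiles output of [kinase_profiles()].
#' @param estimates probes x phenotypes estimate matrix.
#' @param sets the probe sets used for `profiles`.
#' @param reference_kinase kinase id to compare against.
#' @param k_clusters number of k-means clusters (must be < number of
#'   kinases).
#' @param seed RNG seed for the k-means restarts.
#' @param restarts number of k-means restarts (default 50).
#' @return list with `clusters` (named integer vector), `tests` (kinases x
#'   phenotypes matrix of Welch p-values vs the reference) and `kmeans`.
#' @export
profile_cluster_compare <- function(profiles, estimates, sets,
                                    reference_kinase, k_clusters,
                                    seed = 1L, restarts = 50L) {
  prof <- profiles$mean
  if (k_clusters >= nrow(prof))
    stop("k_clusters must be smaller than the number of kinases")
  if (nrow(unique(prof)) < k_clusters)
    warning("fewer distinct profiles than clusters requested")
  km <- with_seed(seed,
                  stats::kmeans(prof, centers = min(k_clusters,
                                                    nrow(unique(prof))),
                                nstart = restarts))
  est <- as.matrix(estimates)
  members <- as_member_list(sets)
  if (!reference_kinase %in% names(members))
    stop("reference kinase not among the probe sets")
  ref_mem <- intersect(members[[reference_kinase]], rownames(est))
  tests <- matrix(NA_real_, nrow(prof), ncol(est),
                  dimnames = list(rownames(prof), colnames(est)))
  for (kin in rownames(prof)) {
    mem <- intersect(members[[kin]], rownames(est))
    if (setequal(mem, ref_mem)) {
      tests[kin, ] <- 1
      next
    }
    if (length(mem) < 2L || length(ref_mem) < 2L) next
    for (ph in seq_len(ncol(est))) {
      tests[kin, ph] <- welch_t(est[mem, ph], est[ref_mem, ph])$p
    }
  }
  list(clusters = stats::setNames(km$cluster, rownames(prof)),
       tests = tests, kmeans = km)
}
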