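test_that("screen PCA satisfies its algebraic contract", {
  set.seed(71)
  # rank-1 matrix: PC1 explains everything
  u <- rnorm(40); v <- rnorm(12)
  m1 <- outer(u, v)
  dimnames(m1) <- list(paste0("p", 1:40), paste0("ph", 1:12))
  pca1 <- screen_pca(m1, k = 3)
  expect_equal(pca1$variance_explained[1], 1, tolerance = 1e-10)
  # orthonormal loadings, sign convention, reconstruction at full rank
  m <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(paste0("p", 1:40), paste0("ph", 1:12)))
  pca <- screen_pca(m, k = 12)
  expect_equal(crossprod(pca$loadings), diag(12), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in 1:12) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(recon + rep(pca$center, each = 40), m, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$variance_explained) < 1e-12))
  expect_lte(sum(pca$variance_explained), 1 + 1e-12)
  expect_error(screen_pca(m, k = 40), "k must be")
  m[3, 4] <- NA
  expect_error(screen_pca(m), "impute")
  expect_false(anyNA(impute_screen_matrix(m)))
})

test_that("planted axes are recovered by the top components", {
  sim <- simulate_screen(n_probes = 200, n_phenotypes = 40, n_kinases = 20,
                         noise_sd = 0.5, seed = 81)
  pca <- screen_pca(sim$values, k = 2)
  cors <- abs(cor(pca$scores, sim$truth$axis_scores))
  # each planted axis is captured by one of the two top PCs
  expect_gt(max(cors[, 1]), 0.9)
  expect_gt(max(cors[, 2]), 0.9)
})

test_that("annotate_pcs correlates phenotypes with components", {
  set.seed(91)
  m <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(paste0("p", 1:60), paste0("ph", 1:8)))
  pca <- screen_pca(m, k = 3)
  # a phenotype equal to the PC1 score vector correlates exactly
  m2 <- cbind(m, pc1copy = pca$scores[, 1])
  pca2 <- screen_pca(m2, k = 3)
  ann <- annotate_pcs(m2, pca2, top_k = 3)
  expect_gt(ann$correlations["pc1copy", 1], 0.99)
  expect_true(all(abs(ann$correlations) <= 1 + 1e-12))
  expect_setequal(ann$order, seq_len(nrow(ann$correlations)))
  # constant phenotype: warning and zero correlation
  m3 <- cbind(m, flat = 5)
  expect_warning(ann3 <- annotate_pcs(m3, screen_pca(m3, k = 2)), "constant")
  expect_equal(unname(ann3$correlations["flat", ]), c(0, 0))
})

test_that("decile contrasts detect planted shifts and are antisymmetric", {
  set.seed(101)
  n <- 200
  pc <- setNames(sort(rnorm(n), decreasing = TRUE), paste0("p", 1:n))
  vals <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(names(pc), paste0("ph", 1:6)))
  # phenotype 3 shifted by 2 s.d. in the top decile
  top_idx <- seq_len(20)
  vals[top_idx, 3] <- vals[top_idx, 3] + 2
  res <- decile_contrast(vals, pc, fraction = 0.10)
  expect_true(res$significant[3])
  expect_equal(res$direction[3], 1)
  # flipping the ranking flips every direction
  res_flip <- decile_contrast(vals, -pc, fraction = 0.10)
  expect_equal(res$direction, -res_flip$direction)
  expect_equal(res$p_value, res_flip$p_value, tolerance = 1e-12)
  # identical groups: p = 1 everywhere
  same <- matrix(1, n, 2, dimnames = list(names(pc), c("a", "b")))
  res_same <- decile_contrast(same, pc)
  expect_true(all(res_same$p_value == 1))
  expect_error(decile_contrast(vals, pc, fraction = 0.7), "fraction")
})

test_that("probe-set outlier assignment matches hand-computed robust z", {
  # deterministic column: median 16.83, MAD 12.36, one clear outlier
  x <- c((1:100) / 3, 95)
  names(x) <- c(paste0("p", 1:100), "hit")
  m <- matrix(x, ncol = 1, dimnames = list(names(x), "KIN1"))
  med <- median(x); madv <- mad(x)
  p_hit <- pnorm((95 - med) / madv, lower.tail = FALSE)
  sets <- assign_probe_sets(m, alpha = 0.01)
  expect_equal(sets$KIN1$members, "hit")
  expect_equal(sets$KIN1$p_value, p_hit)
  expect_equal(sets$KIN1$inhibition, 95)
  # alpha = 1: every probe is a member
  all_in <- assign_probe_sets(m, alpha = 1)
  expect_equal(length(all_in$KIN1$members), 101L)
  # zero-MAD column with one high probe: rank fallback still assigns it
  z <- c(rep(0, 300), 90)
  mz <- matrix(z, ncol = 1,
               dimnames = list(paste0("p", 0:300), "KIN2"))
  sz <- assign_probe_sets(mz, alpha = 0.01)
  expect_equal(sz$KIN2$members, "p300")
  # constant column: warning, empty set
  mc <- matrix(5, 10, 1, dimnames = list(paste0("p", 1:10), "KIN3"))
  expect_warning(sc <- assign_probe_sets(mc), "constant")
  expect_length(sc$KIN3$members, 0)
  expect_error(assign_probe_sets(matrix(150, 2, 1)), "0, 100")
})

test_that("enrichment scores equal a brute-force running sum and fgsea", {
  set.seed(111)
  scores <- setNames(rnorm(120), sprintf("p%03d", 1:120))
  brute_es <- function(scores, members, w = 1) {
    ord <- order(-scores, names(scores))
    r <- names(scores)[ord]
    hit <- r %in% members
    wts <- abs(scores[ord])^w
    ph <- cumsum(ifelse(hit, wts, 0)) / sum(wts[hit])
    pm <- cumsum(!hit) / (length(r) - sum(hit))
    dev <- ph - pm
    dev[which.max(abs(dev))]
  }
  top_m <- names(sort(scores, decreasing = TRUE))[1:10]
  rand_m <- sample(names(scores), 15)
  bot_m <- names(sort(scores))[1:12]
  for (mem in list(top_m, rand_m, bot_m)) {
    got <- gsea(scores, list(S = mem), n_perm = 50, seed = 2)
    expect_equal(got$es, unname(brute_es(scores, mem)), tolerance = 1e-12)
    s <- sort(scores, decreasing = TRUE)
    expect_equal(got$es,
                 fgsea::calcGseaStat(s, which(names(s) %in% mem)),
                 tolerance = 1e-12)
  }
  # a top-m set nearly attains the maximal ES
  expect_gt(gsea(scores, list(S = top_m), n_perm = 50, seed = 2)$es, 0.9)
  # reversing the ranking negates the ES
  a <- gsea(scores, list(S = rand_m), n_perm = 50, seed = 2)
  b <- gsea(-scores, list(S = rand_m), n_perm = 50, seed = 2)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
  # undersized sets are skipped
  expect_warning(
    expect_error(gsea(scores, list(S = top_m[1:2]), n_perm = 10, seed = 1),
                 "no probe set"),
    "skipped")
})

test_that("kinase profiles are member means with standard errors", {
  est <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                dimnames = list(c("pa", "pb", "pc"), c("ph1", "ph2")))
  prof <- kinase_profiles(est, list(K1 = c("pa", "pb"), K2 = "pc"))
  expect_equal(prof$mean["K1", ], c(ph1 = 1.5, ph2 = 4.5))
  expect_equal(prof$se["K1", "ph1"], sd(c(1, 2)) / sqrt(2))
  expect_true(all(is.na(prof$se["K2", ])))  # singleton set
  # identical member probes give the common profile with zero s.e.
  est2 <- rbind(pa = c(2, 7), pb = c(2, 7))
  colnames(est2) <- c("ph1", "ph2")
  prof2 <- kinase_profiles(est2, list(K = c("pa", "pb")))
  expect_equal(unname(prof2$mean["K", ]), c(2, 7))
  expect_equal(unname(prof2$se["K", ]), c(0, 0))
  expect_warning(kinase_profiles(est, list(K1 = "pa", KX = "zz")), "dropping")
})

test_that("profile clustering separates planted mechanisms", {
  set.seed(121)
  n_ph <- 10
  centre_a <- rnorm(n_ph, 3); centre_b <- rnorm(n_ph, -3)
  est <- rbind(
    matrix(rep(centre_a, each = 12), 12) + rnorm(12 * n_ph, 0, 0.2),
    matrix(rep(centre_b, each = 12), 12) + rnorm(12 * n_ph, 0, 0.2))
  rownames(est) <- paste0("p", 1:24)
  colnames(est) <- paste0("ph", 1:n_ph)
  sets <- c(lapply(1:4, function(i) paste0("p", (i - 1) * 3 + 1:3)),
            lapply(1:4, function(i) paste0("p", 12 + (i - 1) * 3 + 1:3)))
  names(sets) <- paste0("K", 1:8)
  prof <- kinase_profiles(est, sets)
  cmp <- profile_cluster_compare(prof, est, sets, reference_kinase = "K1",
                                 k_clusters = 2, seed = 3)
  cl <- cmp$clusters
  expect_equal(length(unique(cl[1:4])), 1L)
  expect_equal(length(unique(cl[5:8])), 1L)
  expect_true(cl[1] != cl[5])  # perfect two-group recovery
  # the reference kinase against itself: p = 1 for every phenotype
  expect_true(all(cmp$tests["K1", ] == 1))
  # kinases from the other mechanism differ significantly somewhere
  expect_lt(min(cmp$tests["K5", ]), 0.01)
})
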