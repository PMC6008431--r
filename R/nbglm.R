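## Negative-binomial GLM with log link and depth offset.
## Parametrisation: Var(y) = mu + alpha * mu^2 (alpha = dispersion,
## size = 1/alpha); alpha -> 0 is the Poisson limit.

NB_ALPHA_MIN <- 1e-8
NB_ALPHA_MAX <- 1e3

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

## One IRLS pass to convergence for fixed dispersion; beta0 optional start.
nb_irls <- function(y, X, offset, alpha, beta0 = NULL,
                    max_iter = 100L, tol = 1e-10) {
  if (is.null(beta0)) {
    ## Poisson start via one linearisation around the data
    z0 <- log(pmax(y, 0.5)) - offset
    beta <- stats::lm.fit(X, z0)$coefficients
  } else beta <- beta0
  beta[!is.finite(beta)] <- 0
  eta <- drop(X %*% beta) + offset
  mu <- pmax(exp(eta), 1e-10)
  ll <- nb_loglik(y, mu, alpha)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    beta_new[!is.finite(beta_new)] <- 0
    eta_new <- drop(X %*% beta_new) + offset
    ## step-halving on likelihood decrease (guards separation paths)
    step <- 1
    repeat {
      eta_try <- eta + step * (eta_new - eta)
      mu_try <- pmin(pmax(exp(eta_try), 1e-10), 1e12)
      ll_try <- nb_loglik(y, mu_try, alpha)
      if (is.finite(ll_try) && (ll_try >= ll - 1e-12)) break
      step <- step / 2
      if (step < 1e-4) break
    }
    beta <- beta + step * (beta_new - beta)
    eta <- eta + step * (eta_new - eta)
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    ll_new <- nb_loglik(y, mu, alpha)
    if (is.finite(ll_new) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(beta = beta, mu = mu, eta = eta, loglik = ll, converged = converged)
}

## ML (optionally Cox-Reid adjusted) dispersion given fitted means.
nb_alpha_ml <- function(y, mu, X, cox_reid = TRUE) {
  obj <- function(la) {
    alpha <- exp(la)
    ll <- nb_loglik(y, mu, alpha)
    if (cox_reid) {
      w <- mu / (1 + alpha * mu)
      XtWX <- crossprod(X * sqrt(w))
      ll <- ll - 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
    }
    as.numeric(ll)
  }
  opt <- stats::optimize(obj, c(log(NB_ALPHA_MIN), log(NB_ALPHA_MAX)),
                         maximum = TRUE, tol = 1e-6)
  ## optimize never evaluates the boundary; snap when the interior optimum
  ## hugs an endpoint (Poisson-like data)
  alpha <- exp(opt$maximum)
  if (opt$maximum < log(NB_ALPHA_MIN) + 1e-3) alpha <- NB_ALPHA_MIN
  alpha
}

#' Fit a negative-binomial regression to one antibody's counts
#'
#' Maximises the negative-binomial log-likelihood with log link and mean
#' `mu_w = s_w * exp(x_w' beta)`, where `s_w` is the well size factor
#' (entering as offset `log s_w`). Estimation alternates iteratively
#' reweighted least squares for the coefficients with one-dimensional
#' maximisation for the dispersion; by default the dispersion objective
#' carries a Cox-Reid adjustment (`-0.5 log det X'WX`) to offset the
#' downward small-sample bias of plain maximum likelihood.
#'
#' @param counts_row non-negative integer counts, one per well.
#' @param design model matrix (wells x coefficients), e.g. one of the designs
#'   built by [model_spec()].
#' @param factors size factors from [size_factors()] (default all 1).
#' @param dispersion fix the dispersion at this value instead of estimating
#'   it (used for likelihood-ratio testing against a reduced design).
#' @param cox_reid use the Cox-Reid adjusted dispersion objective
#'   (default `TRUE`).
#' @param max_iter,tol outer-loop iteration cap and relative log-likelihood
#'   tolerance.
#' @return object of class `nb_fit`: coefficients, `dispersion` (alpha),
#'   `theta` (1/alpha), `loglik`, `converged`, `grad_norm`, `fitted`,
#'   `degenerate` flag (all-zero response), plus the inputs needed for
#'   testing.
#' @examples
#' y <- c(5L, 7L, 6L, 30L, 28L, 25L)
#' X <- cbind(1, rep(0:1, each = 3))
#' coef(fit_nb(y, X))
#' @export
fit_nb <- function(counts_row, design, factors = NULL, dispersion = NULL,
                   cox_reid = TRUE, max_iter = 100L, tol = 1e-8) {
  y <- as.numeric(counts_row)
  X <- as.matrix(design)
  if (length(y) != nrow(X)) stop("counts_row length must match design rows")
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  offset <- if (is.null(factors)) rep(0, length(y)) else {
    f <- unclass(factors)
    if (!is.null(names(f)) && !is.null(names(counts_row)))
      f <- f[names(counts_row)]
    if (length(f) != length(y)) stop("factors must cover all wells")
    log(f)
  }
  if (all(y == 0)) {
    beta <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
    return(structure(list(coefficients = beta, dispersion = NA_real_,
                          theta = NA_real_, loglik = 0, converged = TRUE,
                          degenerate = TRUE, grad_norm = 0,
                          fitted = rep(0, length(y)), y = y, X = X,
                          offset = offset, df = 0L),
                     class = "nb_fit"))
  }

  fixed_alpha <- !is.null(dispersion)
  alpha <- if (fixed_alpha) max(dispersion, NB_ALPHA_MIN) else 0.1
  fit <- nb_irls(y, X, offset, alpha)
  if (!fixed_alpha) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      alpha_new <- nb_alpha_ml(y, fit$mu, X, cox_reid = cox_reid)
      fit <- nb_irls(y, X, offset, alpha_new, beta0 = fit$beta)
      alpha <- alpha_new
      if (abs(fit$loglik - ll_prev) < tol * (abs(fit$loglik) + 1)) break
      ll_prev <- fit$loglik
    }
  }
  grad <- drop(crossprod(X, (y - fit$mu) / (1 + alpha * fit$mu)))
  structure(list(coefficients = stats::setNames(fit$beta, colnames(X)),
                 dispersion = alpha, theta = 1 / alpha, loglik = fit$loglik,
                 converged = fit$converged, degenerate = FALSE,
                 grad_norm = sqrt(sum(grad^2)), fitted = fit$mu,
                 y = y, X = X, offset = offset, df = ncol(X)),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, digits = 4, ...) {
  cat("Negative-binomial GLM fit",
      if (x$degenerate) "(degenerate: all-zero counts)" else "", "\n")
  if (!x$degenerate) {
    print(round(x$coefficients, digits))
    cat(sprintf("dispersion %.4g (theta %.4g), logLik %.4f, %s\n",
                x$dispersion, x$theta, x$loglik,
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$loglik, df = object$df + 1L, class = "logLik")
}

#' @export
fitted.nb_fit <- function(object, ...) object$fitted

#' @export
residuals.nb_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 + object$dispersion * object$fitted))
  r
}

#' Likelihood-ratio test between nested negative-binomial fits
#'
#' The statistic is twice the log-likelihood difference, clipped at zero.
#' By default its upper tail is read off the asymptotic chi-square with
#' `df` = coefficient difference. With few wells the chi-square reference
#' is anticonservative for NB fits with estimated dispersion; setting
#' `small_sample = TRUE` uses the F reference `F(df, n - p_full)` on
#' `statistic / df` instead, which holds the nominal size in small designs
#' and converges to the chi-square as wells accumulate.
#'
#' @param full,reduced `nb_fit` objects on the same response, the reduced
#'   design nested in the full design.
#' @param small_sample use the small-sample F reference (default `FALSE`).
#' @return list with `statistic`, `df` (coefficient difference),
#'   `df_residual` and `p_value`.
#' @export
lrt <- function(full, reduced, small_sample = FALSE) {
  stopifnot(inherits(full, "nb_fit"), inherits(reduced, "nb_fit"))
  if (length(full$y) != length(reduced$y) || any(full$y != reduced$y))
    stop("full and reduced fits must be on the same data")
  df <- full$df - reduced$df
  if (df <= 0L) stop("reduced model must have fewer coefficients than full")
  resid_proj <- qr.resid(qr(full$X), reduced$X)
  if (max(abs(resid_proj)) > 1e-8)
    stop("designs are not nested: reduced columns outside full column space")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df_resid <- length(full$y) - full$df
  p <- if (small_sample) {
    if (df_resid < 1L) stop("no residual degrees of freedom for the F test")
    stats::pf(stat / df, df, df_resid, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, df_residual = df_resid, p_value = p)
}

#' Declare the per-antibody differential model
#'
#' Builds the full (blocks + treatment) and reduced (blocks only) design
#' matrices from the plate covariates. Treatment and blocking covariates are
#' coded as fixed-effect factors; sequencing depth enters the model as the
#' size-factor offset, not as a covariate.
#'
#' @param data plate covariates: a data frame with one row per well, or a
#'   [plate_map()] with covariates.
#' @param treatment name of the treatment column (default `"treatment"`).
#' @param blocks character vector of blocking columns present in `data`
#'   (default: whichever of `"replicate"`, `"batch"` exist).
#' @param reference optional reference level for the treatment factor.
#' @return object of class `model_spec` with elements `full`, `reduced`
#'   (design matrices), `treatment_cols` (columns of `full` testing the
#'   treatment) and `wells`.
#' @export
model_spec <- function(data, treatment = "treatment", blocks = NULL,
                       reference = NULL) {
  if (inherits(data, "plate_map")) {
    if (is.null(data$covariates)) stop("plate map carries no covariates")
    data <- data$covariates
  }
  data <- as.data.frame(data)
  if (!treatment %in% names(data))
    stop("treatment column '", treatment, "' not found")
  if (is.null(blocks)) blocks <- intersect(c("replicate", "batch"), names(data))
  missing_blocks <- setdiff(blocks, names(data))
  if (length(missing_blocks))
    stop("blocking columns not found: ", paste(missing_blocks, collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (b in blocks) df[[b]] <- factor(data[[b]])
  tr <- factor(data[[treatment]])
  if (!is.null(reference)) tr <- stats::relevel(tr, ref = reference)
  if (nlevels(tr) < 2L) stop("treatment must have at least two levels")
  if (min(table(tr)) < 2L)
    stop("each treatment level needs at least two wells")
  df[[treatment]] <- tr
  drop_const <- vapply(df[blocks], function(f) nlevels(f) < 2L, logical(1))
  blocks <- blocks[!drop_const]
  fml_full <- stats::reformulate(c(blocks, treatment), intercept = TRUE)
  fml_red <- if (length(blocks)) stats::reformulate(blocks, intercept = TRUE)
             else ~ 1
  X_full <- stats::model.matrix(fml_full, df)
  X_red <- stats::model.matrix(fml_red, df)
  if (qr(X_full)$rank < ncol(X_full))
    stop("full design matrix is rank deficient (confounded covariates?)")
  tr_cols <- which(attr(X_full, "assign") == length(blocks) + 1L)
  structure(list(full = X_full, reduced = X_red, treatment = treatment,
                 treatment_levels = levels(tr), blocks = blocks,
                 treatment_cols = tr_cols,
                 wells = rownames(data) %||% as.character(seq_len(nrow(data)))),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Differential model: ~", paste(c(x$blocks, x$treatment), collapse = " + "),
      "vs ~", if (length(x$blocks)) paste(x$blocks, collapse = " + ") else "1", "\n")
  cat("  treatment levels:", paste(x$treatment_levels, collapse = ", "), "\n")
  cat("  wells:", nrow(x$full), " full rank:", ncol(x$full), "\n")
  invisible(x)
}

#' Per-antibody differential test table
#'
#' Fits the full and reduced negative-binomial models to every antibody row
#' and tests the treatment term by likelihood ratio. The dispersion is
#' estimated per antibody under the full model and held fixed when refitting
#' the reduced model, so the test statistic compares like with like. By
#' default the statistic is referred to the small-sample F distribution
#' (see [lrt()]), which keeps the nominal size on plates with few wells.
#'
#' @param counts `umi_counts` object or antibodies x wells count matrix.
#' @param spec a [model_spec()].
#' @param factors size factors from [size_factors()]; `NULL` for none.
#' @param small_sample use the F reference of [lrt()] (default `TRUE`).
#' @param cox_reid passed to [fit_nb()].
#' @return data frame of class `diff_table`: one row per antibody with
#'   `estimate` (treatment coefficient, natural-log scale; `NA` for
#'   multi-level treatments), `dispersion`, `lrt_stat`, `df`, `p_value`,
#'   `q_value` (Benjamini-Hochberg), `signed_logp`
#'   (`sign(estimate) * -log10(p)`, p clipped at 1e-300), `converged`,
#'   `degenerate`.
#' @export
differential_table <- function(counts, spec, factors = NULL,
                               small_sample = TRUE, cox_reid = TRUE) {
  m <- if (inherits(counts, "umi_counts")) counts$counts else as.matrix(counts)
  stopifnot(inherits(spec, "model_spec"))
  if (ncol(m) != nrow(spec$full))
    stop("count matrix wells do not match model spec")
  single_df <- length(spec$treatment_cols) == 1L
  res <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    y <- m[i, ]
    full <- fit_nb(y, spec$full, factors, cox_reid = cox_reid)
    if (full$degenerate) {
      res[[i]] <- data.frame(estimate = NA_real_, dispersion = NA_real_,
                             lrt_stat = NA_real_, df = NA_integer_,
                             p_value = NA_real_, converged = TRUE,
                             degenerate = TRUE)
      next
    }
    reduced <- fit_nb(y, spec$reduced, factors, dispersion = full$dispersion,
                      cox_reid = cox_reid)
    test <- lrt(full, reduced, small_sample = small_sample)
    est <- if (single_df) unname(full$coefficients[spec$treatment_cols])
           else NA_real_
    res[[i]] <- data.frame(estimate = est, dispersion = full$dispersion,
                           lrt_stat = test$statistic, df = test$df,
                           p_value = test$p_value,
                           converged = full$converged && reduced$converged,
                           degenerate = FALSE)
  }
  out <- do.call(rbind, res)
  out <- cbind(data.frame(antibody_id = rownames(m) %||%
                            as.character(seq_len(nrow(m))),
                          stringsAsFactors = FALSE), out)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  p_clip <- pmax(out$p_value, 1e-300)
  out$signed_logp <- ifelse(is.na(out$estimate), NA_real_,
                            sign(out$estimate) * -log10(p_clip))
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, n = 10, ...) {
  cat("Differential NB-LRT results:", nrow(x), "antibodies\n")
  ord <- order(x$p_value)
  print.data.frame(utils::head(x[ord, ], n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' Write a differential table as TSV
#' @param x `diff_table` from [differential_table()].
#' @param path output file.
#' @export
write_diff_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
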