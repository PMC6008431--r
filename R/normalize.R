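#' Median-of-ratios size factors for sequencing depth
#'
#' Estimates one positive factor per well from the antibody x well UMI count
#' matrix, by the median-of-ratios method: each well's counts are divided by
#' the per-antibody geometric mean across wells (computed over antibodies
#' with no zero counts), and the per-well median of those ratios is the size
#' factor. Factors are then rescaled to geometric mean 1 so that the model
#' intercept stays identifiable.
#'
#' @param counts `umi_counts` object or antibodies x wells count matrix.
#' @param poscounts if `TRUE`, zero-containing antibody rows are retained and
#'   the reference geometric mean is taken over positive entries only (for
#'   sparse plates where no antibody is positive everywhere).
#' @return named numeric vector of per-well size factors (class
#'   `size_factors`).
#' @examples
#' m <- rbind(c(10, 20), c(100, 200))
#' size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(counts, poscounts = FALSE) {
  m <- if (inherits(counts, "umi_counts")) counts$counts else as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (ncol(m) == 1L) {
    sf <- stats::setNames(1, colnames(m))
    class(sf) <- "size_factors"
    return(sf)
  }
  logm <- log(m)
  if (poscounts) {
    ref <- apply(logm, 1L, function(r) mean(r[is.finite(r)]))
    use <- is.finite(ref)
  } else {
    ref <- rowMeans(logm)
    use <- is.finite(ref)  # rows with any zero drop out (log 0 = -Inf)
    if (!any(use))
      stop("no antibody has positive counts in all wells; ",
           "rerun with poscounts = TRUE")
  }
  log_sf <- apply(logm[use, , drop = FALSE] - ref[use], 2L,
                  function(v) stats::median(v[is.finite(v)]))
  if (any(!is.finite(log_sf)))
    stop("size factor undefined for wells: ",
         paste(colnames(m)[!is.finite(log_sf)], collapse = ", "))
  log_sf <- log_sf - mean(log_sf)  # centre to geometric mean 1
  sf <- stats::setNames(exp(log_sf), colnames(m))
  class(sf) <- "size_factors"
  sf
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size factors for", length(x), "wells (geometric mean 1):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Depth-normalized counts
#'
#' Divides each well's counts by its size factor. The differential model uses
#' size factors as offsets; normalized counts are for QC and plotting.
#'
#' @param counts `umi_counts` object or count matrix.
#' @param factors size factors from [size_factors()], named by well.
#' @return numeric matrix of the same shape as `counts`.
#' @export
normalized_counts <- function(counts, factors) {
  m <- if (inherits(counts, "umi_counts")) counts$counts else as.matrix(counts)
  f <- unclass(factors)
  if (!is.null(colnames(m))) {
    if (!all(colnames(m) %in% names(f)))
      stop("size factors missing for wells: ",
           paste(setdiff(colnames(m), names(f)), collapse = ", "))
    f <- f[colnames(m)]
  } else if (length(f) != ncol(m)) {
    stop("size factors must cover all wells")
  }
  sweep(m, 2L, f, "/")
}
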