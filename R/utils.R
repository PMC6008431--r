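#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## Run code under a fixed RNG state, restoring the caller's state afterwards.
## All simulators funnel through this so that (parameters, seed) -> output is
## a pure function regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

## Split sequences of equal length into an n x L character matrix.
seq_char_matrix <- function(x) {
  L <- unique(nchar(x))
  stopifnot(length(L) == 1L)
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

#' Pairwise Hamming distances between equal-length sequences
#'
#' @param x character vector of equal-length sequences.
#' @return integer matrix of pairwise Hamming distances.
#' @keywords internal
hamming_matrix <- function(x) {
  m <- seq_char_matrix(x)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(names(x), names(x)))
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  storage.mode(d) <- "integer"
  d
}

## Hamming distance from each of many observed sequences to one barcode.
## Any character differing from the barcode base (including N) is a mismatch.
hamming_to <- function(observed_mat, barcode_chars) {
  n_mm <- integer(nrow(observed_mat))
  for (j in seq_along(barcode_chars)) {
    n_mm <- n_mm + (observed_mat[, j] != barcode_chars[j])
  }
  n_mm
}

random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
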