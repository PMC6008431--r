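#' Describe the triple-barcode read architecture
#'
#' An ID-seq read carries, at fixed positions, a unique molecular identifier
#' (UMI), a constant anchor sequence, an antibody-dedicated barcode (BC1) and
#' a well-specific barcode (BC2). `read_layout()` records where each segment
#' sits so that reads can be parsed by direct substring extraction.
#'
#' The shipped default order is `UMI - ANCHOR - BC1 - BC2` with a 15-nt UMI
#' and a 10-nt antibody barcode. The exact geometry of any given assay is
#' configurable: pass the anchor sequence and segment order used by your
#' library design.
#'
#' @param anchor constant anchor sequence (A/C/G/T string) used to verify the
#'   read architecture.
#' @param umi_len UMI length in nucleotides (default 15).
#' @param bc1_len antibody-barcode length in nucleotides (default 10).
#' @param bc2_len well-barcode length in nucleotides (default 10).
#' @param segment_order character vector over tokens `"UMI"`, `"ANCHOR"`,
#'   `"BC1"`, `"BC2"`; `UMI`, `BC1` and `BC2` must each appear exactly once
#'   and `ANCHOR` at least once.
#' @param anchor_max_mismatch maximum number of substitutions tolerated,
#'   summed over all anchor occurrences (default 2).
#'
#' @return An object of class `read_layout` with the segment offsets
#'   precomputed (`$segments`: data frame of token, start, end) and the total
#'   layout length (`$width`).
#' @examples
#' lay <- read_layout(anchor = "GTACGGATCC")
#' lay$width
#' @export
read_layout <- function(anchor = "GTACGGATCC",
                        umi_len = 15L, bc1_len = 10L, bc2_len = 10L,
                        segment_order = c("UMI", "ANCHOR", "BC1", "BC2"),
                        anchor_max_mismatch = 2L) {
  anchor <- toupper(anchor)
  umi_len <- as.integer(umi_len); bc1_len <- as.integer(bc1_len)
  bc2_len <- as.integer(bc2_len)
  anchor_max_mismatch <- as.integer(anchor_max_mismatch)
  if (umi_len < 1L || bc1_len < 1L || bc2_len < 1L)
    stop("umi_len, bc1_len and bc2_len must all be >= 1")
  if (nchar(anchor) < 1L || grepl("[^ACGT]", anchor))
    stop("anchor must be a non-empty A/C/G/T string")
  if (anchor_max_mismatch < 0L)
    stop("anchor_max_mismatch must be >= 0")
  tok <- toupper(as.character(segment_order))
  if (!all(tok %in% c("UMI", "ANCHOR", "BC1", "BC2")))
    stop("segment_order contains unknown tokens")
  counts <- table(factor(tok, levels = c("UMI", "ANCHOR", "BC1", "BC2")))
  if (counts[["UMI"]] != 1L || counts[["BC1"]] != 1L || counts[["BC2"]] != 1L)
    stop("segment_order must contain UMI, BC1 and BC2 exactly once")
  if (counts[["ANCHOR"]] < 1L)
    stop("segment_order must contain ANCHOR at least once")

  seg_len <- c(UMI = umi_len, ANCHOR = nchar(anchor),
               BC1 = bc1_len, BC2 = bc2_len)
  lens <- unname(seg_len[tok])
  end <- cumsum(lens)
  segments <- data.frame(token = tok, start = end - lens + 1L, end = end,
                         stringsAsFactors = FALSE)
  structure(
    list(anchor = anchor, umi_len = umi_len, bc1_len = bc1_len,
         bc2_len = bc2_len, segment_order = tok,
         anchor_max_mismatch = anchor_max_mismatch,
         segments = segments, width = sum(lens)),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat("ID-seq read layout (", x$width, " nt):\n", sep = "")
  lab <- ifelse(x$segments$token == "ANCHOR",
                paste0("ANCHOR[", x$anchor, "]"),
                paste0(x$segments$token, "(",
                       x$segments$end - x$segments$start + 1L, ")"))
  cat(" ", paste(lab, collapse = " - "), "\n")
  cat("  anchor mismatches tolerated:", x$anchor_max_mismatch, "\n")
  invisible(x)
}

## Extract one segment type from a vector of reads; multiple ANCHOR
## occurrences are returned concatenated (in order) for mismatch counting.
layout_extract <- function(layout, reads, token) {
  seg <- layout$segments[layout$segments$token == token, , drop = FALSE]
  out <- substr(reads, seg$start[1L], seg$end[1L])
  if (nrow(seg) > 1L) {
    for (i in seq_len(nrow(seg))[-1L]) {
      out <- paste0(out, substr(reads, seg$start[i], seg$end[i]))
    }
  }
  out
}
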