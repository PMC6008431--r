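#' Parse triple-barcoded reads into UMI / antibody / well assignments
#'
#' Each read is split at the fixed positions declared by the layout: the
#' anchor is checked at its declared offset(s) (within
#' `layout$anchor_max_mismatch` substitutions), then the antibody barcode
#' (BC1) and well barcode (BC2) are matched against the panel and plate map
#' with `tolerance` substitution errors. Failures are recorded as statuses,
#' never exceptions, with the first failing stage reported:
#' `too_short`, `no_anchor`, `bad_bc1`, `bad_bc2`, `ok`.
#'
#' @param sequences character vector of read sequences.
#' @param layout a [read_layout()].
#' @param panel an [antibody_panel()].
#' @param plate a [plate_map()].
#' @param tolerance barcode-matching tolerance in substitutions (default 1).
#' @return data frame with columns `status`, `umi`, `antibody_id`, `well_id`
#'   (fields `NA` beyond the failing stage).
#' @export
parse_reads <- function(sequences, layout, panel, plate, tolerance = 1L) {
  stopifnot(inherits(layout, "read_layout"),
            inherits(panel, "antibody_panel"),
            inherits(plate, "plate_map"))
  if (panel$bc_len != layout$bc1_len)
    stop("antibody panel barcode length does not match layout bc1_len")
  if (plate$bc_len != layout$bc2_len)
    stop("plate map barcode length does not match layout bc2_len")
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  status <- rep.int("too_short", n)
  umi <- rep(NA_character_, n)
  ab <- rep(NA_character_, n)
  well <- rep(NA_character_, n)
  long_enough <- !is.na(sequences) & nchar(sequences) >= layout$width
  if (any(long_enough)) {
    s <- sequences[long_enough]
    anchor_obs <- layout_extract(layout, s, "ANCHOR")
    n_anchor <- nrow(layout$segments[layout$segments$token == "ANCHOR", ])
    anchor_ref <- strsplit(strrep(layout$anchor, n_anchor), "")[[1L]]
    mm <- hamming_to(seq_char_matrix(anchor_obs), anchor_ref)
    has_anchor <- mm <= layout$anchor_max_mismatch
    st <- rep.int("no_anchor", length(s))
    u <- rep(NA_character_, length(s))
    a <- rep(NA_character_, length(s))
    w <- rep(NA_character_, length(s))
    if (any(has_anchor)) {
      sa <- s[has_anchor]
      a_id <- match_barcode(layout_extract(layout, sa, "BC1"), panel,
                            tolerance)
      w_id <- rep(NA_character_, length(sa))
      got_a <- !is.na(a_id)
      if (any(got_a)) {
        w_id[got_a] <- match_barcode(
          layout_extract(layout, sa[got_a], "BC2"), plate, tolerance)
      }
      st_a <- ifelse(!got_a, "bad_bc1", ifelse(is.na(w_id), "bad_bc2", "ok"))
      st[has_anchor] <- st_a
      ok <- st_a == "ok"
      ua <- rep(NA_character_, length(sa))
      ua[ok] <- layout_extract(layout, sa[ok], "UMI")
      u[has_anchor] <- ua
      aa <- rep(NA_character_, length(sa)); aa[ok] <- a_id[ok]
      wa <- rep(NA_character_, length(sa)); wa[ok] <- w_id[ok]
      a[has_anchor] <- aa
      w[has_anchor] <- wa
    }
    status[long_enough] <- st
    umi[long_enough] <- u
    ab[long_enough] <- a
    well[long_enough] <- w
  }
  data.frame(status = status, umi = umi, antibody_id = ab, well_id = well,
             stringsAsFactors = FALSE)
}

#' Count distinct UMIs per (antibody, well) from FASTQ
#'
#' Streams a FASTQ (optionally gzipped) file in chunks, parses each read with
#' [parse_reads()], removes duplicate reads -- defined as exact identity of
#' the corrected (well, antibody, UMI) triple -- and counts the distinct UMIs
#' per antibody and well.
#'
#' @param fastq path to a FASTQ or FASTQ.gz file, or a character vector of
#'   raw read sequences.
#' @param layout,panel,plate,tolerance as in [parse_reads()].
#' @param chunk_size number of records read per chunk (memory/speed knob;
#'   results are independent of it).
#' @return An object of class `umi_counts`: a list with `counts` (integer
#'   matrix, antibodies x wells), `reads_total`, `reads_assigned`,
#'   `duplicates_removed`, `duplicate_rate`, and `status_tally`.
#' @examples
#' lay <- read_layout(anchor = "GTACGGATCC", bc2_len = 8)
#' pan <- antibody_panel("ACTB", "ACGTACGTAC")
#' plm <- plate_map("A01", "TTGGCCAA")
#' rd <- paste0(strrep("A", 15), "GTACGGATCC", "ACGTACGTAC", "TTGGCCAA")
#' count_umis(c(rd, rd), lay, pan, plm)$counts
#' @export
count_umis <- function(fastq, layout, panel, plate, tolerance = 1L,
                       chunk_size = 5e5) {
  n_ab <- length(panel$ids); n_well <- length(plate$ids)
  status_levels <- c("ok", "no_anchor", "bad_bc1", "bad_bc2", "too_short")
  tally <- stats::setNames(integer(length(status_levels)), status_levels)
  triples <- character(0)
  reads_total <- 0L

  consume <- function(seqs) {
    parsed <- parse_reads(seqs, layout, panel, plate, tolerance)
    tally <<- tally + table(factor(parsed$status, levels = status_levels))
    ok <- parsed$status == "ok"
    new_triples <- paste(parsed$antibody_id[ok], parsed$well_id[ok],
                         parsed$umi[ok], sep = "\r")
    triples <<- unique(c(triples, new_triples))
    reads_total <<- reads_total + length(seqs)
  }

  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    skip <- 0L
    repeat {
      chunk <- tryCatch(
        Biostrings::readDNAStringSet(fastq, format = "fastq",
                                     nrec = chunk_size, skip = skip),
        error = function(e) {
          stop("unreadable FASTQ record near record ", skip + 1L, ": ",
               conditionMessage(e), call. = FALSE)
        })
      if (length(chunk) == 0L) break
      consume(as.character(chunk))
      skip <- skip + length(chunk)
      if (length(chunk) < chunk_size) break
    }
  } else if (is.character(fastq)) {
    if (length(fastq) == 1L && grepl("\\.(fastq|fq)(\\.gz)?$", fastq))
      stop("FASTQ file not found: ", fastq)
    consume(fastq)
  } else {
    stop("fastq must be a file path or a character vector of sequences")
  }

  counts <- matrix(0L, n_ab, n_well, dimnames = list(panel$ids, plate$ids))
  if (length(triples)) {
    parts <- strsplit(triples, "\r", fixed = TRUE)
    ai <- match(vapply(parts, `[[`, "", 1L), panel$ids)
    wi <- match(vapply(parts, `[[`, "", 2L), plate$ids)
    tab <- table(factor(ai, levels = seq_len(n_ab)),
                 factor(wi, levels = seq_len(n_well)))
    counts[] <- as.integer(tab)
  }
  reads_assigned <- unname(tally[["ok"]])
  dup <- reads_assigned - sum(counts)
  structure(
    list(counts = counts,
         reads_total = reads_total,
         reads_assigned = reads_assigned,
         duplicates_removed = dup,
         duplicate_rate = if (reads_assigned > 0) dup / reads_assigned else 0,
         status_tally = tally),
    class = "umi_counts")
}

#' @export
print.umi_counts <- function(x, ...) {
  cat("UMI count matrix: ", nrow(x$counts), " antibodies x ",
      ncol(x$counts), " wells\n", sep = "")
  cat(sprintf("  reads: %d total, %d assigned (%.1f%%), %d duplicates removed (%.2f%% duplicate rate)\n",
              x$reads_total, x$reads_assigned,
              if (x$reads_total > 0) 100 * x$reads_assigned / x$reads_total else 0,
              x$duplicates_removed, 100 * x$duplicate_rate))
  cat("  total distinct UMIs:", sum(x$counts), "\n")
  invisible(x)
}

#' QC summary of a demultiplexing run
#'
#' @param x a `umi_counts` object from [count_umis()].
#' @return list (JSON-ready) with assignment rate, duplicate rate, status
#'   tally, and per-well / per-antibody UMI totals.
#' @export
demux_report <- function(x) {
  stopifnot(inherits(x, "umi_counts"))
  list(
    reads_total = x$reads_total,
    reads_assigned = x$reads_assigned,
    assignment_rate = if (x$reads_total > 0)
      x$reads_assigned / x$reads_total else 0,
    duplicates_removed = x$duplicates_removed,
    duplicate_rate = x$duplicate_rate,
    status_tally = as.list(x$status_tally),
    umis_total = sum(x$counts),
    per_well_umis = as.list(colSums(x$counts)),
    per_antibody_umis = as.list(rowSums(x$counts))
  )
}

#' Write / read a UMI count matrix as TSV (antibodies x wells)
#'
#' @param counts matrix or `umi_counts` object.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  m <- if (inherits(counts, "umi_counts")) counts$counts else counts
  df <- data.frame(antibody_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
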