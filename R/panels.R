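#' Antibody panel: antibody identifiers and their dedicated barcodes
#'
#' @param ids character vector of antibody identifiers (unique).
#' @param barcodes character vector of equal-length A/C/G/T barcodes, one per
#'   antibody.
#' @param spike_in optional logical vector flagging spike-in control barcodes;
#'   spike-ins are counted and reported like any antibody but carry the flag
#'   so downstream analyses can exclude them.
#' @return object of class `antibody_panel` (and `barcode_panel`).
#' @seealso [plate_map()], [validate_panel()], [match_barcode()]
#' @export
antibody_panel <- function(ids, barcodes, spike_in = NULL) {
  new_barcode_panel(ids, barcodes, class = "antibody_panel",
                    extra = list(spike_in = spike_in %||%
                                   rep(FALSE, length(ids))))
}

#' Plate map: well identifiers, well barcodes and sample covariates
#'
#' @param ids character vector of well identifiers (unique).
#' @param barcodes equal-length A/C/G/T well barcodes, one per well.
#' @param covariates data frame of per-well sample annotation (e.g. columns
#'   `treatment`, `replicate`, `batch`), one row per well. May be `NULL`.
#' @return object of class `plate_map` (and `barcode_panel`).
#' @export
plate_map <- function(ids, barcodes, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(ids))
      stop("covariates must have one row per well")
    rownames(covariates) <- ids
  }
  new_barcode_panel(ids, barcodes, class = "plate_map",
                    extra = list(covariates = covariates))
}

new_barcode_panel <- function(ids, barcodes, class, extra = list()) {
  ids <- as.character(ids)
  barcodes <- toupper(as.character(barcodes))
  if (length(ids) != length(barcodes))
    stop("ids and barcodes must have the same length")
  if (length(ids) == 0L) stop("panel must contain at least one entry")
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(unique(nchar(barcodes))) != 1L)
    stop("all barcodes must have the same length")
  if (any(grepl("[^ACGT]", barcodes)))
    stop("barcodes must use the A/C/G/T alphabet only")
  dup <- duplicated(barcodes) | duplicated(barcodes, fromLast = TRUE)
  if (any(dup))
    stop("duplicate barcodes shared by ids: ",
         paste(ids[dup], collapse = ", "))
  structure(c(list(ids = ids, barcodes = stats::setNames(barcodes, ids),
                   bc_len = nchar(barcodes[1L])), extra),
            class = c(class, "barcode_panel"))
}

#' @export
print.barcode_panel <- function(x, ...) {
  kind <- if (inherits(x, "plate_map")) "plate map" else "antibody panel"
  cat(kind, ": ", length(x$ids), " entries, ", x$bc_len, "-nt barcodes\n",
      sep = "")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read an antibody panel from TSV/CSV
#'
#' Expects columns `antibody_id` and `barcode`, plus an optional logical
#' `spike_in` column. The delimiter is inferred from the file extension
#' (`.csv` vs anything else = tab).
#'
#' @param path file path.
#' @return an [antibody_panel()].
#' @export
read_antibody_panel <- function(path) {
  df <- read_delim_auto(path)
  need <- c("antibody_id", "barcode")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  spike <- if ("spike_in" %in% names(df)) as.logical(df$spike_in) else NULL
  antibody_panel(df$antibody_id, df$barcode, spike_in = spike)
}

#' Read a plate map from TSV/CSV
#'
#' Expects columns `well_id` and `barcode`; all remaining columns (typically
#' `treatment`, `replicate`, `batch`) become sample covariates.
#'
#' @param path file path.
#' @return a [plate_map()].
#' @export
read_plate_map <- function(path) {
  df <- read_delim_auto(path)
  need <- c("well_id", "barcode")
  if (!all(need %in% names(df)))
    stop("plate map file must have columns: ", paste(need, collapse = ", "))
  cov <- df[setdiff(names(df), need)]
  plate_map(df$well_id, df$barcode,
            covariates = if (ncol(cov)) cov else NULL)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Validate a barcode panel for unambiguous error correction
#'
#' Computes the minimum pairwise Hamming distance of the panel's barcodes and
#' checks it against the requirement for unambiguous correction of up to
#' `tolerance` substitution errors: minimum distance >= 2 * tolerance + 1.
#'
#' @param panel an [antibody_panel()] or [plate_map()].
#' @param tolerance number of substitution errors to correct (>= 0).
#' @return list with `min_distance`, `tolerance`, `pass`, and the closest
#'   pair of ids (`closest_pair`).
#' @examples
#' p <- antibody_panel(c("A", "B"), c("AAAA", "TTTT"))
#' validate_panel(p, tolerance = 1)$pass
#' @export
validate_panel <- function(panel, tolerance = 1L) {
  stopifnot(inherits(panel, "barcode_panel"))
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) stop("tolerance must be >= 0")
  n <- length(panel$ids)
  if (n == 1L) {
    return(list(min_distance = panel$bc_len, tolerance = tolerance,
                pass = TRUE, closest_pair = character(0)))
  }
  d <- hamming_matrix(panel$barcodes)
  diag(d) <- NA_integer_
  min_d <- min(d, na.rm = TRUE)
  idx <- which(d == min_d, arr.ind = TRUE)[1L, ]
  list(min_distance = as.integer(min_d), tolerance = tolerance,
       pass = tolerance == 0L || min_d >= 2L * tolerance + 1L,
       closest_pair = panel$ids[sort(unname(idx))])
}

#' Match observed barcode sequences against a panel
#'
#' Returns, for each observed sequence, the unique panel id whose barcode
#' lies at minimal Hamming distance, provided that distance is at most
#' `tolerance`; ambiguous sequences (two or more ids tied at the minimal
#' distance) and sequences farther than `tolerance` from every barcode give
#' `NA` (no match). Non-A/C/G/T characters (e.g. `N`) mismatch every base.
#'
#' @param observed character vector of sequences, each of the panel's barcode
#'   length.
#' @param panel an [antibody_panel()] or [plate_map()].
#' @param tolerance maximum Hamming distance for a match (default 1).
#' @return character vector of ids, `NA` where unmatched.
#' @examples
#' p <- antibody_panel(c("A", "B"), c("AAAA", "TTTT"))
#' match_barcode(c("AAAA", "AAAT", "ATTT"), p, tolerance = 1)
#' @export
match_barcode <- function(observed, panel, tolerance = 1L) {
  stopifnot(inherits(panel, "barcode_panel"))
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) stop("tolerance must be >= 0")
  observed <- toupper(as.character(observed))
  if (length(observed) == 0L) return(character(0))
  if (any(nchar(observed) != panel$bc_len))
    stop("observed sequences must have the panel barcode length (",
         panel$bc_len, ")")
  if (tolerance <= 1L) {
    ## panel barcodes are ACGT-only, so every non-ACGT observed character
    ## mismatches all barcodes -- identical to N; normalise for the lookup
    observed <- gsub("[^ACGT]", "N", observed)
    dict <- barcode_dictionary(panel, tolerance)
    unname(dict[observed])
  } else {
    match_barcode_scan(observed, panel, tolerance)
  }
}

## Exhaustive Hamming scan; used for tolerance > 1 and as the reference
## semantics for the precomputed dictionary.
match_barcode_scan <- function(observed, panel, tolerance) {
  obs_mat <- seq_char_matrix(observed)
  bc_chars <- strsplit(unname(panel$barcodes), "", fixed = TRUE)
  best_d <- rep.int(panel$bc_len + 1L, length(observed))
  best_i <- rep.int(NA_integer_, length(observed))
  tied <- logical(length(observed))
  for (i in seq_along(bc_chars)) {
    d <- hamming_to(obs_mat, bc_chars[[i]])
    tied <- ifelse(d < best_d, FALSE, tied | (d == best_d))
    upd <- d < best_d
    best_i[upd] <- i
    best_d[upd] <- d[upd]
  }
  ok <- best_d <= tolerance & !tied
  out <- rep(NA_character_, length(observed))
  out[ok] <- panel$ids[best_i[ok]]
  out
}

## For tolerance <= 1, matching reduces to a hash lookup in a dictionary of
## every barcode and (at tolerance 1) every single-substitution neighbour
## over {A,C,G,T,N}. Neighbours claimed by two barcodes resolve to the
## smaller distance, or to no-match on a tie -- exactly the scan semantics.
barcode_dictionary <- function(panel, tolerance) {
  ids <- panel$ids
  bcs <- unname(panel$barcodes)
  seqs <- bcs
  seq_id <- ids
  seq_d <- rep.int(0L, length(bcs))
  if (tolerance >= 1L) {
    L <- panel$bc_len
    alphabet <- c(DNA_BASES, "N")
    for (pos in seq_len(L)) {
      for (base in alphabet) {
        variant <- bcs
        substr(variant, pos, pos) <- base
        changed <- variant != bcs
        seqs <- c(seqs, variant[changed])
        seq_id <- c(seq_id, ids[changed])
        seq_d <- c(seq_d, rep.int(1L, sum(changed)))
      }
    }
  }
  o <- order(seqs, seq_d)
  seqs <- seqs[o]; seq_id <- seq_id[o]; seq_d <- seq_d[o]
  first <- !duplicated(seqs)
  ## a variant is ambiguous if its minimal distance is claimed by >= 2 ids;
  ## distance-0 entries are unique by panel validation
  grp <- cumsum(first)
  min_d <- seq_d[first][grp]
  at_min <- seq_d == min_d
  n_min <- tabulate(grp[at_min], nbins = sum(first))
  id_at_min <- seq_id[first]  # first entry per group is at minimal distance
  id_at_min[n_min > 1L] <- NA_character_
  stats::setNames(id_at_min, seqs[first])
}
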