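## Small fixtures shared across test files; everything is built in code.

tiny_layout <- function(...) read_layout(anchor = "GTACGGATCC", ...)

## A 4-antibody panel at mutual Hamming distance >= 3 (hand-checked).
tiny_panel <- function() {
  antibody_panel(c("abA", "abB", "abC", "abD"),
                 c("AAAAACCCCC", "GGGGGTTTTT", "ACACACACAC", "TGTGTGTGTG"))
}

tiny_plate <- function() {
  plate_map(c("w1", "w2", "w3", "w4"),
            c("CCCCCAAAAA", "TTTTTGGGGG", "CACACACACA", "GTGTGTGTGT"),
            covariates = data.frame(
              treatment = c("control", "treated", "control", "treated"),
              replicate = c("r1", "r1", "r2", "r2"),
              batch = "b1"))
}

## Assemble a read for the default UMI-ANCHOR-BC1-BC2 layout.
make_read <- function(umi, bc1, bc2, anchor = "GTACGGATCC") {
  paste0(umi, anchor, bc1, bc2)
}

## Reference Hamming matcher, written independently of the package internals:
## plain character-by-character comparison over the whole panel.
oracle_match <- function(observed, barcodes, ids, tolerance) {
  vapply(observed, function(o) {
    oc <- strsplit(o, "")[[1]]
    d <- vapply(barcodes, function(b) {
      sum(strsplit(b, "")[[1]] != oc)
    }, numeric(1))
    dmin <- min(d)
    if (dmin > tolerance || sum(d == dmin) > 1) NA_character_ else ids[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
}

random_dna_test <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }, character(1))
}

## Mutate one or more positions of a barcode to different bases.
mutate_barcode <- function(bc, n_mut) {
  chars <- strsplit(bc, "")[[1]]
  pos <- sample(length(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

with_seed_test <- function(seed, code) withr::with_seed(seed, code)
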