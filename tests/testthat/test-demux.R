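test_that("parse_reads recovers fields and reports failure stages", {
  lay <- tiny_layout()
  pan <- tiny_panel()
  plm <- tiny_plate()
  umi <- strrep("ACGTA", 3)
  good <- make_read(umi, pan$barcodes[["abB"]], plm$barcodes[["w3"]])
  res <- parse_reads(good, lay, pan, plm)
  expect_equal(res$status, "ok")
  expect_equal(res$umi, umi)
  expect_equal(res$antibody_id, "abB")
  expect_equal(res$well_id, "w3")
  # each failure mode, first failing stage wins
  bad_anchor <- make_read(umi, pan$barcodes[["abB"]], plm$barcodes[["w3"]],
                          anchor = "CATGCATGCA")
  bad_bc1 <- make_read(umi, "GGGGGAAAAA", plm$barcodes[["w3"]])
  bad_bc2 <- make_read(umi, pan$barcodes[["abB"]], "GGGGGCCCCC")
  res <- parse_reads(c(bad_anchor, bad_bc1, bad_bc2, "ACGT"), lay, pan, plm)
  expect_equal(res$status, c("no_anchor", "bad_bc1", "bad_bc2", "too_short"))
  expect_true(all(is.na(res$umi)))
  # anchor tolerated within anchor_max_mismatch
  wobble <- make_read(umi, pan$barcodes[["abA"]], plm$barcodes[["w1"]],
                      anchor = "GAACGGATCC")  # 2 substitutions
  expect_equal(parse_reads(wobble, lay, pan, plm)$status, "ok")
})

test_that("single-substitution barcode noise is fully corrected at tolerance 1", {
  set.seed(9)
  lay <- tiny_layout()
  pan <- antibody_panel(sprintf("a%d", 1:12),
                        unname(simulate_barcodes(12, 10, 3, seed = 31)))
  plm <- plate_map(sprintf("w%d", 1:8),
                   unname(simulate_barcodes(8, 10, 3, seed = 32)))
  n <- 2000
  ai <- sample(12, n, TRUE); wi <- sample(8, n, TRUE)
  bc1 <- vapply(unname(pan$barcodes)[ai], mutate_barcode, character(1), 1)
  bc2 <- vapply(unname(plm$barcodes)[wi], mutate_barcode, character(1), 1)
  reads <- make_read(random_dna_test(n, 15), bc1, bc2)
  res <- parse_reads(reads, lay, pan, plm)
  expect_true(all(res$status == "ok"))
  expect_identical(res$antibody_id, pan$ids[ai])
  expect_identical(res$well_id, plm$ids[wi])
})

test_that("count_umis dedups on the (antibody, well, UMI) triple", {
  lay <- tiny_layout(); pan <- tiny_panel(); plm <- tiny_plate()
  rd <- make_read(strrep("A", 15), pan$barcodes[["abA"]],
                  plm$barcodes[["w1"]])
  m <- count_umis(c(rd, rd, rd), lay, pan, plm)
  expect_equal(sum(m$counts), 1L)
  expect_equal(m$counts["abA", "w1"], 1L)
  expect_equal(m$duplicates_removed, 2L)
  expect_equal(m$duplicate_rate, 2 / 3)
  rep <- demux_report(m)
  expect_equal(rep$duplicate_rate, 2 / 3, tolerance = 1e-12)
  expect_equal(rep$assignment_rate, 1)
  # empty input
  m0 <- count_umis(character(0), lay, pan, plm)
  expect_equal(sum(m0$counts), 0L)
  expect_equal(m0$reads_total, 0L)
  expect_equal(demux_report(m0)$assignment_rate, 0)
})

test_that("counting is order-independent and duplication-invariant", {
  set.seed(12)
  lay <- tiny_layout(); pan <- tiny_panel(); plm <- tiny_plate()
  sim <- simulate_fastq(pan, plm, lay, 8, duplication_rate = 0.3,
                        barcode_error_rate = 0.01, seed = 44)
  reads <- sim$reads
  a <- count_umis(reads, lay, pan, plm)
  b <- count_umis(sample(reads), lay, pan, plm)
  expect_identical(a$counts, b$counts)
  expect_identical(a$status_tally, b$status_tally)
  # k-fold duplicated stream counts like the original
  k3 <- count_umis(rep(reads, each = 3), lay, pan, plm)
  expect_identical(k3$counts, a$counts)
  expect_equal(k3$reads_total, 3L * a$reads_total)
  # disjoint UMI sets concatenate additively
  reads_x <- make_read(c("AAACCCGGGTTTAAA", "CCCGGGTTTAAACCC"),
                       pan$barcodes[["abC"]], plm$barcodes[["w2"]])
  reads_y <- make_read("GGGTTTAAACCCGGG",
                       pan$barcodes[["abC"]], plm$barcodes[["w2"]])
  xy <- count_umis(c(reads_x, reads_y), lay, pan, plm)
  expect_equal(xy$counts["abC", "w2"], 3L)
})

test_that("FASTQ files stream correctly, including gzip and chunking", {
  lay <- tiny_layout(); pan <- tiny_panel(); plm <- tiny_plate()
  sim <- simulate_fastq(pan, plm, lay, 6, 0.2, 0, seed = 7)
  fq <- tempfile(fileext = ".fastq")
  fqgz <- tempfile(fileext = ".fastq.gz")
  writeLines(paste0("@r", seq_along(sim$reads), "\n", sim$reads, "\n+\n",
                    strrep("I", nchar(sim$reads[1]))), fq)
  con <- gzfile(fqgz, "w")
  writeLines(readLines(fq), con); close(con)
  direct <- count_umis(sim$reads, lay, pan, plm)
  from_file <- count_umis(fq, lay, pan, plm)
  from_gz <- count_umis(fqgz, lay, pan, plm)
  chunked <- count_umis(fq, lay, pan, plm, chunk_size = 17)
  expect_identical(from_file$counts, direct$counts)
  expect_identical(from_gz$counts, direct$counts)
  expect_identical(chunked$counts, direct$counts)
  expect_identical(chunked$status_tally, direct$status_tally)
  # malformed record reported with an index
  writeLines(c("@r1", "ACGT", "no-plus-line", "IIII"), fq)
  expect_error(count_umis(fq, lay, pan, plm), "record")
  expect_error(count_umis("no/such/file.fastq", lay, pan, plm), "not found")
})

test_that("demux report totals equal matrix marginals", {
  lay <- tiny_layout(); pan <- tiny_panel(); plm <- tiny_plate()
  sim <- simulate_fastq(pan, plm, lay, 10, 0.1, 0.005, seed = 3)
  m <- count_umis(sim$reads, lay, pan, plm)
  rep <- demux_report(m)
  expect_equal(unlist(rep$per_well_umis), colSums(m$counts))
  expect_equal(unlist(rep$per_antibody_umis), rowSums(m$counts))
  expect_equal(rep$umis_total, sum(m$counts))
  expect_equal(rep$reads_assigned + sum(unlist(rep$status_tally[-1])),
               rep$reads_total)
})
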