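# Coordinate conventions, GTF/FASTA/BED I/O and P-site assignment.

test_that("read_gtf converts 1-based inclusive coordinates and groups exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 301, 350, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), gtf)
  ann <- read_gtf(gtf)
  expect_length(ann$transcripts, 1L)
  tx <- ann$transcripts[["t1"]]
  expect_equal(tx$exons$start, c(100, 300))
  expect_equal(tx$exons$end, c(200, 350))
  expect_equal(tx$exons$end[1] - tx$exons$start[1], 100)
  expect_equal(tx$tx_length, 150)
  expect_equal(tx$biotype, "other")  # no biotype attribute
})

test_that("read_gtf rejects malformed lines with the line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", "src", "exon", 500, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), gtf)
  expect_error(read_gtf(gtf), "line 2")
  writeLines("chr1\tonly\tthree", gtf)
  expect_error(read_gtf(gtf), "columns")
  expect_error(read_gtf(tempfile()), "no such file")
})

test_that("transcript models reject overlapping exons", {
  expect_error(
    transcript_model("t", "g", "chr1", "+",
                     data.frame(start = c(0, 50), end = c(60, 100))),
    "overlapping")
})

test_that("GTF write -> read round-trips exon structure, strand, biotype", {
  set.seed(42)
  txs <- lapply(1:20, function(i) random_transcript(paste0("t", i)))
  txs[[1]]$biotype <- "lncRNA"
  ann <- annotation_set(txs)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  ann2 <- read_gtf(path)
  for (id in names(ann$transcripts)) {
    a <- ann$transcripts[[id]]; b <- ann2$transcripts[[id]]
    expect_equal(b$exons, a$exons)
    expect_equal(b$strand, a$strand)
    expect_equal(b$biotype, a$biotype)
  }
})

test_that("extract_transcript_seq honors strand and splicing", {
  genome <- c(chr1 = "ATGCCC")
  plus <- transcript_model("t", "g", "chr1", "+",
                           data.frame(start = 0, end = 6))
  minus <- transcript_model("t", "g", "chr1", "-",
                            data.frame(start = 0, end = 6))
  expect_equal(extract_transcript_seq(genome, plus), "ATGCCC")
  expect_equal(extract_transcript_seq(genome, minus), "GGGCAT")

  # spliced: per-base concatenation oracle on ATG xxx TAA
  genome2 <- c(chr1 = "ATGXXXTAA")
  genome2 <- c(chr1 = "ATGCCCTAA")
  spliced <- transcript_model("t", "g", "chr1", "+",
                              data.frame(start = c(0, 6), end = c(3, 9)))
  expect_equal(extract_transcript_seq(genome2, spliced), "ATGTAA")

  out_of_bounds <- transcript_model("t", "g", "chr1", "+",
                                    data.frame(start = 0, end = 50))
  expect_error(extract_transcript_seq(genome, out_of_bounds), "bounds")
  bad_chrom <- transcript_model("t", "g", "chrX", "+",
                                data.frame(start = 0, end = 6))
  expect_error(extract_transcript_seq(genome, bad_chrom),
               "unknown chromosome")
})

test_that("tx_to_genome maps the worked examples", {
  expect_equal(tx_to_genome(tx_plus(), 5, 15),
               data.frame(start = c(105, 120), end = c(110, 125)))
  expect_equal(tx_to_genome(tx_minus(), 0, 5),
               data.frame(start = 125, end = 130))
  # full-length interval returns the exact exon chain
  expect_equal(tx_to_genome(tx_plus(), 0, 20),
               data.frame(start = c(100, 120), end = c(110, 130)))
  expect_error(tx_to_genome(tx_plus(), 5, 25), "outside transcript")
})

test_that("genome_to_tx is the per-base inverse of tx_to_genome", {
  set.seed(7)
  for (rep in 1:60) {
    tx <- random_transcript(paste0("t", rep))
    # every transcript position round-trips
    gpos <- vapply(seq_len(tx$tx_length) - 1L, function(p)
      tx_to_genome(tx, p, p + 1L)$start, 0)
    expect_equal(genome_to_tx(tx, gpos), seq_len(tx$tx_length) - 1L)
    # block lengths always add up
    a <- sample(tx$tx_length - 1L, 1L) - 1L
    b <- sample((a + 1L):tx$tx_length, 1L)
    blocks <- tx_to_genome(tx, a, b)
    expect_equal(sum(blocks$end - blocks$start), b - a)
  }
  # intronic positions are a defined NA, not an error
  expect_true(is.na(genome_to_tx(tx_plus(), 115)))
})

test_that("assign_psites applies 5'-end offsets by strand", {
  genome_tx <- transcript_model("t1", "g1", "chr1", "+",
                                data.frame(start = 900, end = 1100))
  ann <- annotation_set(list(
    genome_tx,
    transcript_model("t2", "g2", "chr1", "-",
                     data.frame(start = 900, end = 1100))))
  reads <- data.frame(
    chrom = "chr1",
    start = c(1000, 1000, 1000), end = c(1029, 1029, 1017),
    strand = c("+", "-", "+"),
    sample = "S1", stringsAsFactors = FALSE)
  tracks <- assign_psites(reads, ann, psite_offset_table())
  # + read start 1000, len 29, offset 12 -> genomic P-site 1012 -> t1 pos 112
  expect_equal(tracks$S1$counts[["t1"]][112 + 1L], 1L)
  # - read [1000,1029): 5' end 1028, P-site 1016 -> t2 pos 1099-1016 = 83
  expect_equal(tracks$S1$counts[["t2"]][83 + 1L], 1L)
  # read of length 17 skipped under the default fallback, and logged
  expect_equal(tracks$S1$n_unassigned, 1L)
  expect_equal(tracks$S1$n_assigned, 2L)
})

test_that("reads are conserved: assigned + unassigned = input", {
  set.seed(11)
  # disjoint transcripts so no double counting
  txs <- list(
    transcript_model("a", "ga", "chr1", "+",
                     data.frame(start = 1000, end = 2000)),
    transcript_model("b", "gb", "chr1", "+",
                     data.frame(start = 5000, end = 6000)))
  ann <- annotation_set(txs)
  n <- 500
  reads <- data.frame(
    chrom = "chr1", start = sample(0:7000, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    sample = sample(c("S1", "S2"), n, replace = TRUE))
  reads$end <- reads$start + sample(26:32, n, replace = TRUE)
  tracks <- assign_psites(reads, ann)
  total <- sum(vapply(tracks, track_total, 0)) +
    sum(vapply(tracks, `[[`, 0L, "n_unassigned"))
  expect_equal(total, n)
})

test_that("BED12 fields are consistent and round-trip", {
  sm <- list(orf_id = "orf1", chrom = "chr1", strand = "+", score = 0.83,
             blocks = data.frame(start = c(105, 120), end = c(110, 125)))
  single <- list(orf_id = "orf2", chrom = "chr1", strand = "-",
                 score = 2,  # clamped to 1000
                 blocks = data.frame(start = 500, end = 560))
  path <- tempfile(fileext = ".bed")
  write_bed12(list(sm, single), path)
  f <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_equal(as.integer(f[c(2, 3, 10)]), c(105, 125, 2))
  expect_equal(f[11], "5,5,")
  expect_equal(f[12], "0,15,")
  expect_equal(as.integer(f[5]), 830)
  f2 <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(as.integer(f2[c(5, 10)]), c(1000, 1))
  expect_equal(f2[12], "0,")
  back <- read_bed12(path)
  expect_equal(back[[1]]$blocks, sm$blocks)
  expect_equal(back[[2]]$blocks, single$blocks)
})

test_that("footprint BED and P-site tables round-trip", {
  reads <- data.frame(chrom = "chr1", start = c(10, 50), end = c(39, 78),
                      strand = c("+", "-"), length = c(29, 28),
                      sample = c("S1", "S2"), stringsAsFactors = FALSE)
  p <- tempfile(); write_footprints(reads, p)
  expect_equal(read_footprints(p), reads)

  ann <- annotation_set(list(
    transcript_model("t1", "g", "chr1", "+",
                     data.frame(start = 0, end = 100))))
  tr <- fake_track(list(t1 = c(3L, rep(0L, 98), 2L)))
  p2 <- tempfile(); write_psite_table(list(S1 = tr), p2)
  back <- read_psite_table(p2, ann)
  expect_equal(back$S1$counts$t1, tr$counts$t1)
})
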