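test_that("transcript models extract strand-correct sequences", {
  # + strand: exon 1..12, CDS 4..9 over a 13nt genome
  txset <- make_txset(c(chr1 = "ATGAAAGGGTTTC"),
                      rbind(gtf_row("chr1", 1, 12, "+", "exon", "g1", "t1"),
                            gtf_row("chr1", 4, 9, "+", "CDS", "g1", "t1")))
  m <- txset$transcripts$t1
  expect_equal(nchar(m$cds_sequence), 6L)
  expect_equal(m$cds_sequence, "AAAGGG")
  expect_equal(m$spliced_sequence, "ATGAAAGGGTTT")
  expect_true(m$complete)

  # - strand transcript over plus-strand exon sequence TTTCAT
  txset2 <- make_txset(c(chr1 = "TTTCAT"),
                       rbind(gtf_row("chr1", 1, 6, "-", "exon", "g1", "t1"),
                             gtf_row("chr1", 1, 6, "-", "CDS", "g1", "t1")))
  expect_equal(txset2$transcripts$t1$spliced_sequence, "ATGAAA")

  # CDS length 7 -> flagged incomplete
  txset3 <- make_txset(c(chr1 = "ATGAAAGGGTTTC"),
                       rbind(gtf_row("chr1", 1, 12, "+", "exon", "g1", "t1"),
                             gtf_row("chr1", 4, 10, "+", "CDS", "g1", "t1")))
  expect_false(txset3$transcripts$t1$complete)

  # ambiguous status tag excludes an otherwise well-formed transcript
  txset4 <- make_txset(c(chr1 = "ATGAAAGGGTTTC"),
                       rbind(gtf_row("chr1", 1, 12, "+", "exon", "g1", "t1",
                                     tag = "nonstop"),
                             gtf_row("chr1", 4, 9, "+", "CDS", "g1", "t1",
                                     tag = "nonstop")))
  expect_false(txset4$transcripts$t1$complete)
})

test_that("annotation errors are fatal and informative", {
  fa <- write_fasta(c(chr1 = "ATGAAAGGGTTTC"))
  gtf <- write_gtf_file(gtf_row("chr2", 1, 6, "+", "exon", "g1", "t1"))
  expect_error(read_annotation(gtf, fa), "chr2")
  gtf2 <- write_gtf_file(gtf_row("chr1", 1, 60, "+", "exon", "g1", "t1"))
  expect_error(read_annotation(gtf2, fa), "beyond chromosome")
})

test_that("multi-exon splicing round-trips through annotation files", {
  # exon1 1..6, intron, exon2 10..15; CDS spans the junction
  seqs <- c(chr1 = "ATGAAACCCGTTTAAGG")
  rows <- rbind(gtf_row("chr1", 1, 6, "+", "exon", "g1", "t1"),
                gtf_row("chr1", 10, 15, "+", "exon", "g1", "t1"),
                gtf_row("chr1", 1, 6, "+", "CDS", "g1", "t1"),
                gtf_row("chr1", 10, 15, "+", "CDS", "g1", "t1"))
  txset <- make_txset(seqs, rows)
  m <- txset$transcripts$t1
  expect_equal(m$cds_sequence, "ATGAAAGTTTAA")
  # re-write the model back to GTF and re-read: identical sequences
  rows2 <- data.frame(chrom = m$chrom,
                      start = c(m$exons[, 1], m$cds[, 1]) + 1L,
                      end = c(m$exons[, 2], m$cds[, 2]),
                      strand = m$strand,
                      type = rep(c("exon", "CDS"),
                                 c(nrow(m$exons), nrow(m$cds))),
                      gene_id = m$gene_id, transcript_id = m$transcript_id,
                      stringsAsFactors = FALSE)
  txset2 <- make_txset(seqs, rows2)
  expect_identical(txset2$transcripts$t1$spliced_sequence,
                   m$spliced_sequence)
  expect_identical(txset2$transcripts$t1$cds_sequence, m$cds_sequence)
})

test_that("identical-CDS transcripts merge into one group", {
  # two isoforms of g1 share a CDS but differ in 3'UTR; g2 differs by 1 base
  seqs <- c(chr1 = "AATATGAAATTTTAAGGCC", chr2 = "AATATGAAATTCTAAGGCC")
  rows <- rbind(
    gtf_row("chr1", 1, 19, "+", "exon", "g1", "t1a"),
    gtf_row("chr1", 4, 15, "+", "CDS", "g1", "t1a"),
    gtf_row("chr1", 1, 17, "+", "exon", "g1", "t1b"),
    gtf_row("chr1", 4, 15, "+", "CDS", "g1", "t1b"),
    gtf_row("chr2", 1, 19, "+", "exon", "g2", "t2"),
    gtf_row("chr2", 4, 15, "+", "CDS", "g2", "t2"))
  cds_set <- merge_identical_cds(make_txset(seqs, rows))
  expect_length(cds_set$groups, 2L)
  expect_setequal(cds_set$groups[[cds_set$tx2group[["t1a"]]]],
                  c("t1a", "t1b"))
  expect_equal(cds_set$tx2group[["t1a"]], cds_set$tx2group[["t1b"]])
  expect_false(cds_set$tx2group[["t2"]] == cds_set$tx2group[["t1a"]])
  expect_equal(length(cds_set$gene2groups$g1), 1L)
  # empty input
  empty <- merge_identical_cds(list())
  expect_length(empty$groups, 0L)
})

test_that("adenine census splits coding and noncoding in transcript sense", {
  # 5'UTR AAT + CDS ATGTAA: noncoding_A = 2, coding_A = 3
  txset <- make_txset(c(chr1 = "AATATGTAA"),
                      rbind(gtf_row("chr1", 1, 9, "+", "exon", "g1", "t1"),
                            gtf_row("chr1", 4, 9, "+", "CDS", "g1", "t1")))
  census <- count_transcribed_adenines(txset)
  expect_equal(census$noncoding_A, 2L)
  expect_equal(census$coding_A, 3L)

  # - strand exon with plus-strand TTT contributes 3 transcript-sense As
  txset2 <- make_txset(c(chr1 = "TTT"),
                       gtf_row("chr1", 1, 3, "-", "exon", "g1", "t1",
                               biotype = "noncoding"))
  census2 <- count_transcribed_adenines(txset2)
  expect_equal(census2$noncoding_A, 3L)
  expect_equal(census2$coding_A, 0L)

  # positions shared by two same-gene isoforms count once per gene
  seqs <- c(chr1 = "AATATGTAAGG")
  rows <- rbind(gtf_row("chr1", 1, 11, "+", "exon", "g1", "t1"),
                gtf_row("chr1", 4, 9, "+", "CDS", "g1", "t1"),
                gtf_row("chr1", 1, 9, "+", "exon", "g1", "t2"),
                gtf_row("chr1", 4, 9, "+", "CDS", "g1", "t2"))
  census3 <- count_transcribed_adenines(make_txset(seqs, rows))
  expect_equal(census3$coding_A, 3L)
  expect_equal(census3$noncoding_A, 2L)
})
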