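# shared toy: 5'UTR AAT, CDS ATG AAA TTT TAA (4..15), 3'UTR GGC
toy <- toy_single_gene()

test_that("sites map to transcript regions in transcript sense", {
  hit_utr5 <- map_site_to_transcripts(sites_df("chr1", 2L, "+"), toy)
  expect_equal(hit_utr5$region, "UTR5")
  hit_cds <- map_site_to_transcripts(sites_df("chr1", 7L, "+"), toy)
  expect_equal(hit_cds$region, "CDS")
  expect_equal(hit_cds$cds_offset, 3L)
  hit_utr3 <- map_site_to_transcripts(sites_df("chr1", 17L, "+"), toy)
  expect_equal(hit_utr3$region, "UTR3")
  # outside all exons and wrong strand give no hits
  expect_equal(nrow(map_site_to_transcripts(sites_df("chr1", 19L, "+"), toy)), 0L)
  expect_equal(nrow(map_site_to_transcripts(sites_df("chr1", 7L, "-"), toy)), 0L)
})

test_that("recoding classification matches the genetic code and categories", {
  site <- sites_df("chr1", 7L, "+")
  hit <- map_site_to_transcripts(site, toy)
  ev <- classify_event(hit, toy$transcripts$t1, site)
  # codon AAA edited at position 1 -> GAA: K to E, Somewhat different
  expect_equal(ev$codon, "AAA")
  expect_equal(ev$pos_in_codon, 1L)
  expect_equal(ev$aa_from, "K")
  expect_equal(ev$aa_to, "E")
  expect_equal(ev$transition, "KtoE")
  expect_false(ev$synonymous)
  expect_equal(ev$category, "Somewhat different")

  # codon AAA at position 3 -> AAG: synonymous K to K
  site3 <- sites_df("chr1", 9L, "+")
  ev3 <- classify_event(map_site_to_transcripts(site3, toy),
                        toy$transcripts$t1, site3)
  expect_equal(ev3$transition, "KtoK")
  expect_true(ev3$synonymous)
  expect_equal(ev3$category, "Synonymous")

  # GAT edited at position 2 -> GGT: D to G, Very different
  txset <- make_txset(c(chr1 = "ATGGATTAA"),
                      rbind(gtf_row("chr1", 1, 9, "+", "exon", "g1", "t1"),
                            gtf_row("chr1", 1, 9, "+", "CDS", "g1", "t1")))
  s <- sites_df("chr1", 5L, "+")
  evd <- classify_event(map_site_to_transcripts(s, txset),
                        txset$transcripts$t1, s)
  expect_equal(evd$transition, "DtoG")
  expect_equal(evd$category, "Very different")

  # a stop-codon edit is classified with '*', never dropped
  s2 <- sites_df("chr1", 14L, "+")   # TAA pos 2 -> TGA
  ev2 <- classify_event(map_site_to_transcripts(s2, toy),
                        toy$transcripts$t1, s2)
  expect_equal(ev2$aa_from, "*")
  expect_equal(ev2$aa_to, "*")
  expect_equal(ev2$category, "Synonymous")
})

test_that("recoded amino acid is invariant under strand flip", {
  # the toy gene moved to the minus strand of the reverse-complemented genome
  fwd <- c(chr1 = "AATATGAAATTTTAAGGC")
  rev <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd[["chr1"]]))))
  L <- nchar(fwd[["chr1"]])
  toy_rev <- make_txset(rev,
                        rbind(gtf_row("chr1", 1, 18, "-", "exon", "g1", "t1"),
                              gtf_row("chr1", L - 15 + 1, L - 4 + 1, "-",
                                      "CDS", "g1", "t1")))
  for (pos1 in c(4L, 7L, 9L, 14L)) {   # CDS adenines on the + toy
    site_f <- sites_df("chr1", pos1, "+")
    ev_f <- classify_event(map_site_to_transcripts(site_f, toy),
                           toy$transcripts$t1, site_f)
    site_r <- sites_df("chr1", L - pos1 + 1L, "-")
    ev_r <- classify_event(map_site_to_transcripts(site_r, toy_rev),
                           toy_rev$transcripts$t1, site_r)
    expect_identical(ev_r$transition, ev_f$transition)
    expect_identical(ev_r$cds_offset, ev_f$cds_offset)
  }
})

test_that("unique-CDS rule keeps single-CDS genes and logs the rest", {
  # g1: two same-CDS isoforms; g2: CDS-distinct in-frame isoforms;
  # g3: single isoform; g4: CDS-distinct isoforms with discordant frames
  seg <- "AATATGAAATTTTAAGGC"
  seqs <- c(chr1 = strrep(seg, 4))   # g1 1..18, g2 19..36, g3 37..54, g4 55..72
  rows <- rbind(
    gtf_row("chr1", 1, 18, "+", "exon", "g1", "g1a"),
    gtf_row("chr1", 4, 15, "+", "CDS", "g1", "g1a"),
    gtf_row("chr1", 1, 16, "+", "exon", "g1", "g1b"),
    gtf_row("chr1", 4, 15, "+", "CDS", "g1", "g1b"),
    gtf_row("chr1", 19, 36, "+", "exon", "g2", "g2a"),
    gtf_row("chr1", 22, 33, "+", "CDS", "g2", "g2a"),
    gtf_row("chr1", 19, 36, "+", "exon", "g2", "g2b"),
    gtf_row("chr1", 28, 33, "+", "CDS", "g2", "g2b"),
    gtf_row("chr1", 37, 54, "+", "exon", "g3", "g3a"),
    gtf_row("chr1", 40, 51, "+", "CDS", "g3", "g3a"),
    gtf_row("chr1", 55, 72, "+", "exon", "g4", "g4a"),
    gtf_row("chr1", 58, 69, "+", "CDS", "g4", "g4a"),
    gtf_row("chr1", 55, 60, "+", "exon", "g4", "g4b"),
    gtf_row("chr1", 62, 72, "+", "exon", "g4", "g4b"),
    gtf_row("chr1", 58, 60, "+", "CDS", "g4", "g4b"),
    gtf_row("chr1", 62, 70, "+", "CDS", "g4", "g4b"))
  txset <- make_txset(seqs, rows)
  cds_set <- merge_identical_cds(txset)
  sites <- sites_df("chr1", c(7L, 32L, 43L, 63L), "+")
  events <- map_and_classify(sites, txset)
  sel <- select_unambiguous_events(events, cds_set)
  # g1 event kept once (not once per isoform), g3 kept, g2/g4 excluded
  expect_equal(sort(sel$kept$gene_id), c("g1", "g3"))
  expect_equal(sum(sel$kept$gene_id == "g1"), 1L)
  expect_setequal(unique(sel$excluded$gene_id), c("g2", "g4"))
  # an in-frame alternative start keeps the frame; the exon-skipping
  # isoform of g4 shifts it
  expect_true(all(sel$excluded$same_frame[sel$excluded$gene_id == "g2"]))
  expect_false(any(sel$excluded$same_frame[sel$excluded$gene_id == "g4"]))
})
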