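test_that("reference generation is deterministic and round-trips", {
  cfg <- sim_config(seed = 3L, n_genes = 12L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- generate_reference(cfg, d1)
  r2 <- generate_reference(cfg, d2)
  expect_identical(readLines(r1$genome_path), readLines(r2$genome_path))
  expect_identical(readLines(r1$annotation_path),
                   readLines(r2$annotation_path))
  # configured CDS lengths survive the GTF/FASTA round trip
  for (m in r1$txset$transcripts) {
    if (!m$coding) next
    g <- r1$genes[r1$genes$gene_id == m$gene_id, ]
    if (m$transcript_id == paste0(m$gene_id, ".t1")) {
      expect_equal(nchar(m$cds_sequence), g$cds_len)
    }
    if (m$complete) {
      expect_equal(nchar(m$cds_sequence) %% 3L, 0L)
      expect_equal(substr(m$cds_sequence, 1, 3), "ATG")
      expect_true(translate_codons(substring(
        m$cds_sequence, nchar(m$cds_sequence) - 2,
        nchar(m$cds_sequence))) == "*")
    }
  }
  # different seed changes the output
  r3 <- generate_reference(sim_config(seed = 4L, n_genes = 12L),
                           withr::local_tempdir())
  expect_false(identical(readLines(r1$genome_path),
                         readLines(r3$genome_path)))
})

test_that("strand mix approaches the configured proportion", {
  cfg <- sim_config(seed = 8L, n_genes = 120L, p_minus = 0.5)
  ref <- generate_reference(cfg, withr::local_tempdir())
  frac_minus <- mean(ref$genes$strand == "-")
  expect_lt(abs(frac_minus - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("planted decoys are removed by filtering, true sites survive", {
  cfg <- sim_config(seed = 21L, n_genes = 25L, n_coding_events = 40L,
                    noncoding_coding_ratio = 2, n_nonA_decoys = 3L,
                    n_snp_site_decoys = 3L, n_cancer_decoys = 2L)
  dir <- withr::local_tempdir()
  ref <- generate_reference(cfg, dir)
  cat_out <- generate_editing_sites(cfg, ref)
  sites <- read_sites(cat_out$sites_path)
  snps <- read_snps(cat_out$snp_path)
  res <- filter_sites(sites, snps, ref$txset$genome)
  truth <- cat_out$truth
  expect_equal(unname(res$report[["not_adenine"]]),
               sum(truth$class == "decoy_nonA"))
  expect_equal(unname(res$report[["snp_overlap"]]),
               sum(truth$class == "decoy_snp"))
  expect_equal(unname(res$report[["tag_excluded"]]),
               sum(truth$class == "decoy_cancer"))
  expect_equal(unname(res$report[["retained"]]),
               sum(truth$class %in% c("coding", "noncoding")))
})

test_that("unbiased event placement follows the pool expectation", {
  cfg <- sim_config(seed = 13L, n_genes = 60L, n_coding_events = 300L,
                    noncoding_coding_ratio = 0.5)
  dir <- withr::local_tempdir()
  ref <- generate_reference(cfg, dir)
  cat_out <- generate_editing_sites(cfg, ref)
  truth <- cat_out$truth[cat_out$truth$class == "coding", ]
  cds_set <- merge_identical_cds(ref$txset)
  pool <- build_codon_pool(cds_set$cds_sequences)
  p <- analytic_expectation(pool)
  obs <- table(truth$transition)
  # chi-square goodness of fit over bins with decent expected counts
  keep <- names(p)[p * nrow(truth) >= 5]
  o <- c(as.vector(obs[keep]), nrow(truth) - sum(obs[keep]))
  o[is.na(o)] <- 0
  pp <- c(p[keep], 1 - sum(p[keep]))
  gof <- suppressWarnings(chisq.test(o, p = pp))
  expect_gt(gof$p.value, 0.001)
})

test_that("family generation responds to configured rates", {
  cfg <- sim_config(seed = 6L, n_genes = 15L, n_coding_events = 30L,
                    noncoding_coding_ratio = 1, background_sub_rate = 0,
                    gap_rate = 0)
  dir <- withr::local_tempdir()
  ref <- generate_reference(cfg, dir)
  cat_out <- generate_editing_sites(cfg, ref)
  fam <- generate_families(cfg, ref, truth = cat_out$truth)
  alns <- lapply(list.files(fam$family_dir, full.names = TRUE),
                 read_family_alignment)
  # substitution rate 0: columns perfectly conserved up to homolog gaps
  H <- unlist(lapply(alns, function(a) {
    keep <- !apply(a$mat == "-", 2, any)
    entropy_profile(a)$H[keep]
  }))
  expect_true(all(H == 0))
  # gap insertion shifts residue-to-column mapping beyond the residue index
  cfg2 <- sim_config(seed = 6L, n_genes = 15L, n_coding_events = 30L,
                     noncoding_coding_ratio = 1, gap_rate = 0.2)
  fam2 <- generate_families(cfg2, ref, truth = cat_out$truth)
  a2 <- read_family_alignment(list.files(fam2$family_dir,
                                         full.names = TRUE)[1])
  ref_row <- a2$mat[1, ]
  expect_gt(sum(ref_row == "-"), 0)
  k <- sum(ref_row != "-")          # last residue index
  col_k <- which(cumsum(ref_row != "-") == k & ref_row != "-")[1]
  expect_gt(col_k, k)
})
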