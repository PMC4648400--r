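#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: a toy genome with
#' UTR-CDS-UTR gene structure on both strands, editing-site catalogs with
#' a configurable noncoding:coding rate ratio and per-transition
#' enrichment, SNP/decoy lists, and homolog families with configurable
#' per-column conservation. A single integer seed drives one derived
#' pseudo-random stream per generator stage, so regenerating one stage
#' does not perturb the others.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes genes are distributed over.
#' @param p_minus probability a gene sits on the minus strand.
#' @param utr5_len,utr3_len integer ranges (min, max) of UTR lengths (nt).
#' @param cds_codons integer range of CDS lengths in codons (incl. stop).
#' @param n_exons_range integer range of exons per transcript.
#' @param intron_len,intergenic_len integer ranges (nt).
#' @param base_probs named probabilities for A, C, G, T in UTR/intron/
#'   intergenic sequence.
#' @param p_same_cds_isoform probability a gene gains a second isoform
#'   with identical CDS but shorter 3' UTR.
#' @param p_diff_cds_isoform probability a gene gains a CDS-distinct
#'   isoform (alternative in-frame start), exercising the unique-CDS rule.
#' @param p_noncoding_gene probability a gene is noncoding (no CDS).
#' @param p_ambiguous probability a coding transcript carries an
#'   ambiguous-annotation status tag and is excluded downstream.
#' @param n_coding_events number of true coding editing events planted.
#' @param noncoding_coding_ratio per-adenine editing-rate ratio,
#'   noncoding over coding.
#' @param transition_enrichment named multiplicative factors applied to
#'   the null probability of selected transitions when placing coding
#'   events (renormalized).
#' @param direction_bias weight multiplier for synonymous coding
#'   candidates whose edit replaces a less frequent codon with a more
#'   frequent one (1 = unbiased).
#' @param n_snps SNP positions emitted to the exclusion list.
#' @param n_snp_site_decoys planted sites coinciding with SNPs.
#' @param n_nonA_decoys planted sites whose reference base is not A.
#' @param n_cancer_decoys planted sites tagged `cancer`.
#' @param family_members homolog rows per family alignment.
#' @param background_sub_rate per-column substitution probability of a
#'   homolog residue.
#' @param edited_rate_multiplier factor scaling the substitution rate of
#'   columns holding nonsynonymously edited residues (< 1 = more
#'   conserved).
#' @param gap_rate per-residue probability of inserting a reference-gap
#'   column, making the residue-to-column mapping nontrivial.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 80L, n_chroms = 2L,
                       p_minus = 0.5,
                       utr5_len = c(40L, 120L), cds_codons = c(60L, 160L),
                       utr3_len = c(60L, 180L), n_exons_range = c(1L, 3L),
                       intron_len = c(50L, 150L),
                       intergenic_len = c(80L, 200L),
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       p_same_cds_isoform = 0.15, p_diff_cds_isoform = 0.1,
                       p_noncoding_gene = 0.1, p_ambiguous = 0.05,
                       n_coding_events = 200L, noncoding_coding_ratio = 10,
                       transition_enrichment = numeric(0),
                       direction_bias = 1,
                       n_snps = 15L, n_snp_site_decoys = 3L,
                       n_nonA_decoys = 3L, n_cancer_decoys = 3L,
                       family_members = 8L, background_sub_rate = 0.5,
                       edited_rate_multiplier = 1, gap_rate = 0.05) {
  cfg <- as.list(environment())
  probs <- c(p_minus, p_same_cds_isoform, p_diff_cds_isoform,
             p_noncoding_gene, p_ambiguous, background_sub_rate, gap_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(base_probs) - 1) < 1e-8,
            all(transition_enrichment > 0), direction_bias > 0,
            edited_rate_multiplier >= 0, noncoding_coding_ratio > 0,
            n_genes >= 1, family_members >= 2)
  structure(cfg, class = "sim_config")
}

# one derived RNG seed per generator stage (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

.rand_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# sample n sense (non-stop) codons with per-base composition
.rand_codons <- function(n, probs) {
  all64 <- names(.code())
  sense <- all64[.code() != "*"]
  b <- do.call(rbind, strsplit(sense, ""))
  w <- probs[b[, 1L]] * probs[b[, 2L]] * probs[b[, 3L]]
  sample(sense, n, replace = TRUE, prob = w)
}

#' Generate a synthetic genome and annotation
#'
#' Writes a toy genome FASTA and GTF annotation: multi-exon genes with
#' 5'UTR-CDS-3'UTR structure on both strands, CDSs starting at ATG and
#' ending at a stop with length a multiple of 3, optional second isoforms
#' (same CDS / different 3'UTR, or a CDS-distinct in-frame alternative
#' start), noncoding genes and occasional ambiguously tagged transcripts.
#' The files are re-read through [read_annotation()] so the returned
#' transcript set is exactly what the pipeline will see.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if missing).
#' @return list with `genome_path`, `annotation_path`, `txset` (the
#'   re-read `transcript_set`) and `genes` (truth table of gene
#'   structures).
#' @export
generate_reference <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  local_seed(.stage_seed(config$seed, 1L), {
    probs <- config$base_probs
    runif_len <- function(rg) sample(seq(rg[1L], rg[2L]), 1L)
    chrom_seq <- stats::setNames(rep("", config$n_chroms),
                                 paste0("chr", seq_len(config$n_chroms)))
    gtf <- list()
    genes <- list()
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("g%03d", i)
      chrom <- paste0("chr", (i - 1L) %% config$n_chroms + 1L)
      strand <- if (stats::runif(1) < config$p_minus) "-" else "+"
      noncoding <- stats::runif(1) < config$p_noncoding_gene
      u5 <- runif_len(config$utr5_len)
      u3 <- runif_len(config$utr3_len)
      diff_iso <- !noncoding && stats::runif(1) < config$p_diff_cds_isoform
      same_iso <- !noncoding && !diff_iso &&
        stats::runif(1) < config$p_same_cds_isoform
      if (noncoding) {
        cds_seq <- ""
        mature <- .rand_bases(u5 + u3 + 3L * runif_len(config$cds_codons), probs)
      } else {
        nc <- runif_len(config$cds_codons)
        internal <- .rand_codons(nc - 2L, probs)
        # a CDS-distinct isoform reuses an in-frame internal ATG as start
        if (diff_iso) internal[2L] <- "ATG"
        stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
        cds_seq <- paste(c("ATG", internal, stop_codon), collapse = "")
        mature <- paste0(.rand_bases(u5, probs), cds_seq,
                         .rand_bases(u3, probs))
      }
      L <- nchar(mature)
      n_ex <- runif_len(config$n_exons_range)
      cuts <- if (n_ex > 1L) sort(sample(seq(15L, L - 15L), n_ex - 1L)) else integer(0)
      ex_start <- c(0L, cuts)             # sense, 0-based half-open
      ex_end <- c(cuts, L)
      introns <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L), function(k)
          .rand_bases(runif_len(config$intron_len), probs), character(1))
      } else character(0)
      # assemble gene-local genomic sequence (sense orientation)
      pieces <- character(0)
      gpos <- integer(0)                  # sense-genomic start of each exon
      off <- 0L
      for (k in seq_len(n_ex)) {
        gpos[k] <- off
        pieces <- c(pieces, substring(mature, ex_start[k] + 1L, ex_end[k]))
        off <- off + (ex_end[k] - ex_start[k])
        if (k < n_ex) {
          pieces <- c(pieces, introns[k])
          off <- off + nchar(introns[k])
        }
      }
      gene_seq <- paste(pieces, collapse = "")
      Lg <- nchar(gene_seq)
      # map a sense mature interval [s,e) to gene-local genomic intervals
      sense_to_local <- function(s, e) {
        out <- NULL
        for (k in seq_len(n_ex)) {
          a <- max(s, ex_start[k]); b <- min(e, ex_end[k])
          if (a < b) {
            out <- rbind(out, c(gpos[k] + (a - ex_start[k]),
                                gpos[k] + (b - ex_start[k])))
          }
        }
        out
      }
      flip <- function(iv) cbind(Lg - iv[, 2L], Lg - iv[, 1L])
      orient <- function(iv) if (strand == "-") flip(iv) else iv
      if (strand == "-") gene_seq <- .revcomp(gene_seq)
      offset <- nchar(chrom_seq[chrom]) +
        runif_len(config$intergenic_len)
      chrom_seq[chrom] <- paste0(
        chrom_seq[chrom],
        .rand_bases(offset - nchar(chrom_seq[chrom]), probs), gene_seq)
      add_tx <- function(tid, mat_start, mat_end, cds_s, cds_e, tag = NA) {
        ex <- orient(sense_to_local(mat_start, mat_end)) + offset
        rows <- data.frame(chrom = chrom, start = ex[, 1L] + 1L,
                           end = ex[, 2L], strand = strand, type = "exon",
                           gene_id = gid, transcript_id = tid,
                           biotype = if (is.na(cds_s)) "noncoding" else "protein_coding",
                           tag = tag, stringsAsFactors = FALSE)
        if (!is.na(cds_s)) {
          cd <- orient(sense_to_local(cds_s, cds_e)) + offset
          rows <- rbind(rows, data.frame(
            chrom = chrom, start = cd[, 1L] + 1L, end = cd[, 2L],
            strand = strand, type = "CDS", gene_id = gid,
            transcript_id = tid, biotype = "protein_coding", tag = tag,
            stringsAsFactors = FALSE))
        }
        gtf[[length(gtf) + 1L]] <<- rows
      }
      tag1 <- if (!noncoding && stats::runif(1) < config$p_ambiguous)
        "conflict" else NA_character_
      if (noncoding) {
        add_tx(paste0(gid, ".t1"), 0L, L, NA, NA)
      } else {
        cds_s <- u5; cds_e <- u5 + nchar(cds_seq)
        add_tx(paste0(gid, ".t1"), 0L, L, cds_s, cds_e, tag1)
        if (same_iso) {
          trunc <- min(20L, u3 - 10L)
          if (trunc > 0L) add_tx(paste0(gid, ".t2"), 0L, L - trunc,
                                 cds_s, cds_e, tag1)
        }
        if (diff_iso) {
          # alternative start at the in-frame ATG planted at codon 3
          add_tx(paste0(gid, ".t2"), 0L, L, cds_s + 6L, cds_e, tag1)
        }
      }
      genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                               noncoding = noncoding, same_iso = same_iso,
                               diff_iso = diff_iso,
                               cds_len = nchar(cds_seq),
                               ambiguous = !is.na(tag1),
                               stringsAsFactors = FALSE)
    }
    # pad chromosome tails
    for (ch in names(chrom_seq)) {
      chrom_seq[ch] <- paste0(chrom_seq[ch], .rand_bases(100L, probs))
    }
    genome_path <- file.path(dir, "genome.fa")
    annotation_path <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(chrom_seq),
                                genome_path)
    ann <- do.call(rbind, gtf)
    write_gtf(ann, annotation_path)
    txset <- read_annotation(annotation_path, genome_path)
    list(genome_path = genome_path, annotation_path = annotation_path,
         txset = txset, genes = do.call(rbind, genes))
  })
}

# minimal GTF emitter for the generator's own annotation rows
write_gtf <- function(ann, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";%s',
                   ann$gene_id, ann$transcript_id, ann$biotype,
                   ifelse(is.na(ann$tag), "",
                          sprintf(' tag "%s";', ann$tag)))
  lines <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, ann$type, ann$start, ann$end, ann$strand, attrs)
  writeLines(lines, path)
}

# adenine positions (0-based, transcript-sense A) per gene region;
# returns data.frames chrom/pos/strand for coding and noncoding exonic
.adenine_positions_by_region <- function(txset) {
  models <- txset$transcripts
  coding <- list(); noncoding <- list()
  key <- paste(vapply(models, `[[`, character(1), "gene_id"),
               vapply(models, `[[`, character(1), "chrom"),
               vapply(models, `[[`, character(1), "strand"), sep = "\r")
  for (grp in split(models, key)) {
    chrom <- grp[[1L]]$chrom; strand <- grp[[1L]]$strand
    exon_iv <- do.call(rbind, lapply(grp, `[[`, "exons"))
    cds_iv <- do.call(rbind, lapply(Filter(function(m) isTRUE(m$complete), grp),
                                    `[[`, "cds"))
    exonic <- IRanges::reduce(IRanges::IRanges(exon_iv[, 1L] + 1L, exon_iv[, 2L]))
    cod <- if (!is.null(cds_iv) && nrow(cds_iv)) {
      IRanges::reduce(IRanges::IRanges(cds_iv[, 1L] + 1L, cds_iv[, 2L]))
    } else IRanges::IRanges()
    nc <- IRanges::setdiff(exonic, cod)
    base <- if (strand == "+") "A" else "T"
    chrom_str <- as.character(txset$genome[[chrom]])
    scan <- function(rng) {
      if (length(rng) == 0L) return(integer(0))
      unlist(lapply(seq_along(rng), function(k) {
        s <- IRanges::start(rng)[k]; e <- IRanges::end(rng)[k]
        piece <- substring(chrom_str, s, e)
        s - 1L + which(strsplit(piece, "")[[1L]] == base) - 1L
      }), use.names = FALSE)
    }
    pc <- scan(cod); pn <- scan(nc)
    if (length(pc)) coding[[length(coding) + 1L]] <-
      data.frame(chrom = chrom, pos = pc, strand = strand,
                 stringsAsFactors = FALSE)
    if (length(pn)) noncoding[[length(noncoding) + 1L]] <-
      data.frame(chrom = chrom, pos = pn, strand = strand,
                 stringsAsFactors = FALSE)
  }
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  list(coding = if (length(coding)) do.call(rbind, coding) else empty,
       noncoding = if (length(noncoding)) do.call(rbind, noncoding) else empty)
}

# enumerate coding edit candidates over unique-CDS group representatives
.coding_candidates <- function(txset, cds_set) {
  n_groups_of_gene <- vapply(cds_set$gene2groups, length, integer(1))
  reps <- cds_set$representative
  out <- list()
  for (g in seq_along(cds_set$groups)) {
    m <- txset$transcripts[[reps[g]]]
    gene_ok <- n_groups_of_gene[[m$gene_id]] == 1L
    codons <- split_codons(m$cds_sequence)
    ed <- enumerate_edits(unique(codons))
    if (nrow(ed) == 0L) next
    inst <- data.frame(ci = seq_along(codons), codon = codons,
                       stringsAsFactors = FALSE)
    cand <- merge(inst, ed, by = "codon")
    cand$cds_offset <- (cand$ci - 1L) * 3L + cand$pos_in_codon - 1L
    cand$pos <- vapply(cand$cds_offset, function(o)
      cds_offset_to_genome(m, o), integer(1))
    cand$chrom <- m$chrom; cand$strand <- m$strand
    cand$transcript_id <- m$transcript_id
    cand$gene_id <- m$gene_id
    cand$unique_cds <- gene_ok
    out[[length(out) + 1L]] <- cand
  }
  cand <- do.call(rbind, out)
  key <- paste(cand$chrom, cand$pos, cand$strand, sep = "\r")
  cand <- cand[!duplicated(key), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Generate a synthetic editing-site catalog
#'
#' Plants editing events on transcribed adenines of the reference:
#' coding events are drawn so realized transition frequencies follow the
#' codon pool's analytic expectation multiplied by the configured
#' per-transition enrichment (renormalized), with an optional usage-
#' direction bias on synonymous candidates; noncoding events are placed
#' uniformly at the rate implied by `noncoding_coding_ratio`. SNP lists
#' and decoy sites (SNP-coincident, non-adenine, cancer-tagged) exercise
#' the catalog filter. A truth table records the intended class and
#' transition of every planted site.
#'
#' @param config a `sim_config`.
#' @param reference the list returned by [generate_reference()].
#' @param dir output directory (defaults to the reference directory).
#' @return list with `sites_path`, `snp_path`, `truth` (data.frame, also
#'   written as `truth_sites.tsv`).
#' @export
generate_editing_sites <- function(config, reference,
                                   dir = dirname(reference$genome_path)) {
  stopifnot(inherits(config, "sim_config"))
  txset <- reference$txset
  local_seed(.stage_seed(config$seed, 2L), {
    cds_set <- merge_identical_cds(txset)
    cand <- .coding_candidates(txset, cds_set)
    if (is.null(cand) || nrow(cand) < config$n_coding_events) {
      stop("requested coding events exceed available adenine candidates")
    }
    w <- rep(1, nrow(cand)) / cand$n_adenines
    enr <- config$transition_enrichment
    if (length(enr)) {
      hit <- cand$transition %in% names(enr)
      w[hit] <- w[hit] * enr[cand$transition[hit]]
    }
    if (config$direction_bias != 1) {
      usage <- build_usage_table(cds_set)
      syn <- which(cand$synonymous)
      d <- classify_direction(cand$codon[syn], cand$codon_to[syn], usage)
      w[syn[d == "less_to_more"]] <- w[syn[d == "less_to_more"]] *
        config$direction_bias
    }
    pick <- sample.int(nrow(cand), config$n_coding_events, prob = w)
    coding <- cand[pick, , drop = FALSE]
    # noncoding events at rate ratio r per adenine
    regions <- .adenine_positions_by_region(txset)
    census <- count_transcribed_adenines(txset)
    n_nc <- round(config$noncoding_coding_ratio * config$n_coding_events /
                    census$coding_A * census$noncoding_A)
    if (n_nc > nrow(regions$noncoding)) {
      stop("requested noncoding events exceed available adenines")
    }
    nc_pick <- regions$noncoding[sample.int(nrow(regions$noncoding), n_nc), ,
                                 drop = FALSE]
    used <- paste(c(coding$chrom, nc_pick$chrom),
                  c(coding$pos, nc_pick$pos), sep = "\r")
    # SNP positions on unused adenines; some coincide with decoy sites
    free_nc <- regions$noncoding[
      !(paste(regions$noncoding$chrom, regions$noncoding$pos, sep = "\r")
        %in% used), , drop = FALSE]
    snp_rows <- free_nc[sample.int(nrow(free_nc),
                                   min(config$n_snps, nrow(free_nc))), ,
                        drop = FALSE]
    snp_decoys <- utils::head(snp_rows, config$n_snp_site_decoys)
    # non-adenine decoys: exonic positions whose sense base is not A
    nonA <- list()
    tries <- 0L
    while (length(nonA) < config$n_nonA_decoys && tries < 500L) {
      tries <- tries + 1L
      row <- regions$noncoding[sample.int(nrow(regions$noncoding), 1L), ]
      cand_pos <- row$pos + 1L   # neighbour of an adenine
      chrom_str <- as.character(txset$genome[[row$chrom]])
      if (cand_pos >= nchar(chrom_str)) next
      b <- substring(chrom_str, cand_pos + 1L, cand_pos + 1L)
      want <- if (row$strand == "+") "A" else "T"
      if (b != want) {
        nonA[[length(nonA) + 1L]] <- data.frame(
          chrom = row$chrom, pos = cand_pos, strand = row$strand,
          stringsAsFactors = FALSE)
      }
    }
    nonA <- if (length(nonA)) unique(do.call(rbind, nonA)) else
      data.frame(chrom = character(0), pos = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    cancer <- free_nc[sample.int(nrow(free_nc),
                                 min(config$n_cancer_decoys, nrow(free_nc))), ,
                      drop = FALSE]
    site_df <- function(df, tag, class, transition = NA_character_,
                        transcript_id = NA_character_,
                        cds_offset = NA_integer_) {
      if (nrow(df) == 0L) {
        return(data.frame(chrom = character(0), pos = integer(0),
                          strand = character(0), tag = character(0),
                          class = character(0), transition = character(0),
                          transcript_id = character(0),
                          cds_offset = integer(0), stringsAsFactors = FALSE))
      }
      data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
                 tag = tag, class = class, transition = transition,
                 transcript_id = transcript_id, cds_offset = cds_offset,
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(
      site_df(coding, "sim", "coding", coding$transition,
              coding$transcript_id, coding$cds_offset),
      site_df(nc_pick, "sim", "noncoding"),
      site_df(snp_decoys, "sim", "decoy_snp"),
      site_df(nonA, "sim", "decoy_nonA"),
      site_df(cancer, "cancer", "decoy_cancer"))
    truth <- truth[order(truth$chrom, truth$pos, truth$strand), , drop = FALSE]
    rownames(truth) <- NULL
    truth$pos <- truth$pos + 1L      # files are 1-based
    sites_path <- file.path(dir, "sites.tsv")
    snp_path <- file.path(dir, "snps.tsv")
    truth_path <- file.path(dir, "truth_sites.tsv")
    utils::write.table(truth[, c("chrom", "pos", "strand", "tag")],
                       sites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(chrom = snp_rows$chrom,
                                  pos = snp_rows$pos + 1L),
                       snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(sites_path = sites_path, snp_path = snp_path, truth = truth)
  })
}

#' Generate synthetic homolog-family alignments
#'
#' Emulates pre-computed family alignments for the edited proteins: each
#' family holds the reference protein plus homolog rows produced by
#' independent per-column substitution at the background rate, with
#' columns holding nonsynonymously edited residues scaled by
#' `edited_rate_multiplier`. Reference-gap columns are inserted at the
#' configured rate so the residue-to-column mapping is exercised, and a
#' small fraction of homolog cells become gaps.
#'
#' @param config a `sim_config`.
#' @param reference the list returned by [generate_reference()].
#' @param truth optional truth table from [generate_editing_sites()];
#'   proteins with at least one planted coding event get a family, and
#'   their nonsynonymously edited residue columns get the rate multiplier.
#' @param dir output directory.
#' @return list with `family_dir`, `mapping_path`, `mapping` and
#'   `edited_residues` (data.frame protein_id/residue_pos of planted
#'   nonsynonymous residues).
#' @export
generate_families <- function(config, reference, truth = NULL,
                              dir = dirname(reference$genome_path)) {
  stopifnot(inherits(config, "sim_config"))
  txset <- reference$txset
  fam_dir <- file.path(dir, "families")
  dir.create(fam_dir, showWarnings = FALSE, recursive = TRUE)
  local_seed(.stage_seed(config$seed, 3L), {
    aas <- setdiff(.aa22, c("-", "X"))
    coding_truth <- if (is.null(truth)) NULL else
      truth[truth$class == "coding", , drop = FALSE]
    prot_ids <- unique(coding_truth$transcript_id)
    prot_ids <- prot_ids[!is.na(prot_ids)]
    mapping <- list(); edited <- list()
    for (pid in prot_ids) {
      m <- txset$transcripts[[pid]]
      codons <- split_codons(m$cds_sequence)
      aa <- translate_codons(codons)
      if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
      L <- length(aa)
      if (L == 0L) next
      rows <- coding_truth[coding_truth$transcript_id == pid, , drop = FALSE]
      res <- rows$cds_offset %/% 3L + 1L
      lab <- rows$transition
      nonsyn <- res[substr(lab, 1L, 1L) !=
                      substring(lab, nchar(lab)) & res <= L]
      nonsyn <- sort(unique(nonsyn))
      rate <- rep(config$background_sub_rate, L)
      rate[nonsyn] <- config$background_sub_rate * config$edited_rate_multiplier
      M <- config$family_members
      mat <- matrix("", nrow = M, ncol = L)
      mat[1L, ] <- aa
      for (r in 2L:M) {
        mut <- stats::runif(L) < rate
        row <- aa
        if (any(mut)) {
          row[mut] <- vapply(row[mut], function(a)
            sample(setdiff(aas, a), 1L), character(1))
        }
        # sparse homolog gaps exercise the 22-letter alphabet
        gap <- stats::runif(L) < 0.02
        row[gap] <- "-"
        mat[r, ] <- row
      }
      # insert reference-gap columns
      n_ins <- stats::rbinom(1L, L, config$gap_rate)
      if (n_ins > 0L) {
        at <- sort(sample.int(L, n_ins))
        newmat <- matrix("", nrow = M, ncol = L + n_ins)
        src <- seq_len(L)
        dest <- src + findInterval(src - 0.5, at)
        ins_dest <- setdiff(seq_len(L + n_ins), dest)
        newmat[, dest] <- mat
        newmat[1L, ins_dest] <- "-"
        for (r in 2L:M) newmat[r, ins_dest] <- sample(aas, n_ins, replace = TRUE)
        mat <- newmat
      }
      fam_id <- paste0("fam_", m$gene_id)
      members <- c(pid, paste0(fam_id, ".h", seq_len(M - 1L)))
      path <- file.path(fam_dir, paste0(fam_id, ".fa"))
      writeLines(paste0(">", members, "\n",
                        apply(mat, 1L, paste, collapse = "")), path)
      mapping[[length(mapping) + 1L]] <-
        data.frame(protein_id = pid, family_id = fam_id, member_id = pid,
                   stringsAsFactors = FALSE)
      if (length(nonsyn)) {
        edited[[length(edited) + 1L]] <-
          data.frame(protein_id = pid, residue_pos = nonsyn,
                     stringsAsFactors = FALSE)
      }
    }
    empty_map <- data.frame(protein_id = character(0),
                            family_id = character(0),
                            member_id = character(0), stringsAsFactors = FALSE)
    mapping <- if (length(mapping)) do.call(rbind, mapping) else empty_map
    mapping_path <- file.path(dir, "family_mapping.tsv")
    utils::write.table(mapping, mapping_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    edited <- if (length(edited)) do.call(rbind, edited) else
      data.frame(protein_id = character(0), residue_pos = integer(0),
                 stringsAsFactors = FALSE)
    list(family_dir = fam_dir, mapping_path = mapping_path,
         mapping = mapping, edited_residues = edited)
  })
}
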