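# in-code fixture builders shared across test files

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# rows: data.frame(chrom, start, end (1-based incl.), strand, type,
#       gene_id, transcript_id, biotype, tag)
write_gtf_file <- function(rows, path = tempfile(fileext = ".gtf")) {
  if (is.null(rows$biotype)) rows$biotype <- "protein_coding"
  if (is.null(rows$tag)) rows$tag <- NA_character_
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";%s',
                   rows$gene_id, rows$transcript_id, rows$biotype,
                   ifelse(is.na(rows$tag), "", sprintf(' tag "%s";', rows$tag)))
  writeLines(sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     rows$chrom, rows$type, as.integer(rows$start),
                     as.integer(rows$end), rows$strand, attrs), path)
  path
}

make_txset <- function(seqs, rows) {
  read_annotation(write_gtf_file(rows), write_fasta(seqs))
}

gtf_row <- function(chrom, start, end, strand, type, gene, tx,
                    biotype = "protein_coding", tag = NA_character_) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             type = type, gene_id = gene, transcript_id = tx,
             biotype = biotype, tag = tag, stringsAsFactors = FALSE)
}

# an editing_sites data.frame from 1-based coordinates
sites_df <- function(chrom, pos1, strand, tag = "") {
  out <- data.frame(chrom = chrom, pos = pos1 - 1L, strand = strand,
                    tag = tag, stringsAsFactors = FALSE)
  class(out) <- c("editing_sites", "data.frame")
  out
}

write_sites_file <- function(df1based, path = tempfile(fileext = ".tsv")) {
  write.table(df1based, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a single-gene plus-strand toy: 5'UTR AAT, CDS ATGAAATTTTAA, 3'UTR GGC
toy_single_gene <- function() {
  seqs <- c(chr1 = "AATATGAAATTTTAAGGC")
  rows <- rbind(gtf_row("chr1", 1, 18, "+", "exon", "g1", "t1"),
                gtf_row("chr1", 4, 15, "+", "CDS", "g1", "t1"))
  make_txset(seqs, rows)
}

# independent brute-force translation oracle (seqinr)
oracle_translate <- function(codon) {
  seqinr::translate(seqinr::s2c(tolower(codon)))
}

# independent two-sided Fisher p by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  ks <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(ks, m1, m2, k)
  sum(pr[pr <= stats::dhyper(a, m1, m2, k) * (1 + 1e-7)])
}
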