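#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet
#'   reverseComplement letterFrequency Views
#' @importFrom IRanges IRanges reduce setdiff start end
NULL

# annotation status tags that mark a transcript as ambiguously annotated
.ambiguous_tags <- c("conflict", "nonstop", "non_start", "stop_read_through")

.load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

.revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# extract and concatenate plus-strand sequence over 0-based half-open
# intervals (matrix cols start,end), then orient to transcript sense
.spliced_seq <- function(chrom_seq, ivs, strand) {
  if (nrow(ivs) == 0L) return("")
  pieces <- substring(chrom_seq, ivs[, 1L] + 1L, ivs[, 2L])
  s <- paste(pieces, collapse = "")
  if (strand == "-") .revcomp(s) else s
}

.sort_ivs <- function(ivs) {
  ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
  if (nrow(ivs) > 1L && any(ivs[-1L, 1L] < ivs[-nrow(ivs), 2L])) {
    stop("overlapping intervals in one transcript")
  }
  ivs
}

#' Read transcript models from GTF annotation and genome FASTA
#'
#' Builds one transcript model per annotated transcript: sorted 0-based
#' half-open exon and CDS intervals, plus spliced and CDS sequences in
#' transcript sense (minus-strand transcripts are reverse-complemented).
#' Input coordinates follow the GTF convention (1-based inclusive).
#' Transcripts whose CDS length is not a multiple of 3, or that carry an
#' ambiguous-annotation status tag (conflict, nonstop, non-start,
#' stop-read-through), are flagged incomplete and excluded from the
#' recoding analysis downstream; transcripts without any CDS are treated
#' as noncoding.
#'
#' @param annotation_file path to a GTF file (ensembl dialect: features
#'   `exon` and `CDS` carrying `gene_id` and `transcript_id` attributes; an
#'   optional `tag` attribute holds the ambiguous-status flag).
#' @param genome path to a genome FASTA, or a `DNAStringSet`.
#' @return an object of class `transcript_set`: a list with elements
#'   `transcripts` (named list of `transcript_model`s) and `genome`.
#' @export
read_annotation <- function(annotation_file, genome) {
  genome <- .load_genome(genome)
  gtf <- rtracklayer::import(annotation_file)
  df <- as.data.frame(gtf, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (is.null(df$tag)) df$tag <- NA_character_
  feat <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  missing_chrom <- !(feat$seqnames %in% names(genome))
  if (any(missing_chrom)) {
    i <- which(missing_chrom)[1L]
    stop("chromosome '", feat$seqnames[i], "' of transcript '",
         feat$transcript_id[i], "' is not in the genome FASTA")
  }
  if (any(feat$end < feat$start)) stop("malformed interval: end < start")
  chrom_cache <- new.env(parent = emptyenv())
  get_chrom <- function(ch) {
    if (is.null(chrom_cache[[ch]])) chrom_cache[[ch]] <- as.character(genome[[ch]])
    chrom_cache[[ch]]
  }
  models <- list()
  for (tid in unique(feat$transcript_id)) {
    rows <- feat[feat$transcript_id == tid, , drop = FALSE]
    chrom <- unique(rows$seqnames)
    strand <- unique(rows$strand)
    gene <- unique(rows$gene_id)
    if (length(chrom) != 1L || length(strand) != 1L || length(gene) != 1L ||
        !(strand %in% c("+", "-"))) {
      stop("ambiguous chrom/strand/gene for transcript '", tid, "'")
    }
    ex <- rows[rows$type == "exon", , drop = FALSE]
    cd <- rows[rows$type == "CDS", , drop = FALSE]
    exons <- .sort_ivs(cbind(start = ex$start - 1L, end = ex$end))
    cds <- if (nrow(cd)) .sort_ivs(cbind(start = cd$start - 1L, end = cd$end))
           else matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    if (max(exons[, 2L]) > nchar(get_chrom(chrom))) {
      stop("transcript '", tid, "' extends beyond chromosome '", chrom, "'")
    }
    # every CDS interval must lie inside some exon
    if (nrow(cds)) {
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
      }, logical(1))
      if (!all(inside)) stop("CDS outside exons for transcript '", tid, "'")
    }
    status <- rows$tag[!is.na(rows$tag)]
    status <- if (length(status)) status[1L] else ""
    chrom_seq <- get_chrom(chrom)
    spliced <- .spliced_seq(chrom_seq, exons, strand)
    cds_seq <- .spliced_seq(chrom_seq, cds, strand)
    complete <- nrow(cds) > 0L && nchar(cds_seq) %% 3L == 0L &&
      !(status %in% .ambiguous_tags)
    models[[tid]] <- structure(list(
      transcript_id = tid, gene_id = gene, chrom = chrom, strand = strand,
      exons = exons, cds = cds,
      spliced_sequence = spliced, cds_sequence = cds_seq,
      coding = nrow(cds) > 0L, complete = complete, status = status),
      class = "transcript_model")
  }
  structure(list(transcripts = models, genome = genome),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  n <- length(x$transcripts)
  comp <- sum(vapply(x$transcripts, `[[`, logical(1), "complete"))
  cat("transcript_set:", n, "transcripts (", comp, "complete ) on",
      length(x$genome), "sequences\n")
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%s exons=%d cds=%dnt %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nchar(x$cds_sequence),
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}

# ---- transcript coordinate arithmetic (0-based throughout) ----

.tx_length <- function(model) sum(model$exons[, 2L] - model$exons[, 1L])

# genomic position -> transcript-sense offset, NA if not exonic
genome_to_tx <- function(model, gpos) {
  ex <- model$exons
  hit <- which(ex[, 1L] <= gpos & gpos < ex[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  before <- if (hit > 1L) sum(ex[seq_len(hit - 1L), 2L] - ex[seq_len(hit - 1L), 1L]) else 0L
  plus_off <- before + (gpos - ex[hit, 1L])
  if (model$strand == "-") .tx_length(model) - 1L - plus_off else plus_off
}

# transcript-sense offset -> genomic position
tx_to_genome <- function(model, tpos) {
  total <- .tx_length(model)
  if (tpos < 0L || tpos >= total) stop("transcript offset out of range")
  plus_off <- if (model$strand == "-") total - 1L - tpos else tpos
  ex <- model$exons
  w <- ex[, 2L] - ex[, 1L]
  cum <- cumsum(w)
  i <- which(plus_off < cum)[1L]
  prev <- if (i > 1L) cum[i - 1L] else 0L
  ex[i, 1L] + (plus_off - prev)
}

# transcript-sense span of the CDS: c(first, last) offsets, or NULL
.cds_span_tx <- function(model) {
  if (nrow(model$cds) == 0L) return(NULL)
  # 5'-most CDS base in transcript sense
  g5 <- if (model$strand == "+") min(model$cds[, 1L]) else max(model$cds[, 2L]) - 1L
  g3 <- if (model$strand == "+") max(model$cds[, 2L]) - 1L else min(model$cds[, 1L])
  c(genome_to_tx(model, g5), genome_to_tx(model, g3))
}

# CDS offset (0-based within cds_sequence) -> genomic position
cds_offset_to_genome <- function(model, offset) {
  span <- .cds_span_tx(model)
  if (is.null(span)) stop("transcript has no CDS")
  tx_to_genome(model, span[1L] + offset)
}

#' Merge transcripts sharing an identical CDS
#'
#' Groups complete transcripts by exact CDS-sequence identity; each group
#' is the merged "CDS transcript" the enrichment analysis operates on. A
#' gene whose complete transcripts all fall into a single group has a
#' unique CDS; events on genes with several CDS-distinct isoforms are
#' excluded from the statistical analysis.
#'
#' @param transcripts a `transcript_set` or list of `transcript_model`s
#'   (incomplete transcripts are ignored).
#' @return an object of class `cds_transcript_set`: list with `groups`
#'   (list of transcript-id vectors), `representative` (one id per group),
#'   `cds_sequences` (one per group), `tx2group` (named integer) and
#'   `gene2groups` (named list: gene id -> group indices).
#' @export
merge_identical_cds <- function(transcripts) {
  if (inherits(transcripts, "transcript_set")) transcripts <- transcripts$transcripts
  transcripts <- Filter(function(m) isTRUE(m$complete), transcripts)
  if (length(transcripts) == 0L) {
    return(structure(list(groups = list(), representative = character(0),
                          cds_sequences = character(0),
                          tx2group = integer(0), gene2groups = list()),
                     class = "cds_transcript_set"))
  }
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  seqs <- vapply(transcripts, `[[`, character(1), "cds_sequence")
  genes <- vapply(transcripts, `[[`, character(1), "gene_id")
  f <- factor(seqs, levels = unique(seqs))
  groups <- split(ids, f)
  names(groups) <- NULL
  representative <- vapply(groups, `[[`, character(1), 1L)
  tx2group <- as.integer(f)
  names(tx2group) <- ids
  gene2groups <- lapply(split(as.integer(f), genes), function(g) sort(unique(g)))
  structure(list(groups = groups, representative = representative,
                 cds_sequences = unique(seqs), tx2group = tx2group,
                 gene2groups = gene2groups),
            class = "cds_transcript_set")
}

#' @export
print.cds_transcript_set <- function(x, ...) {
  cat("cds_transcript_set:", length(x$tx2group), "transcripts in",
      length(x$groups), "CDS groups\n")
  invisible(x)
}

#' Count transcribed adenines by coding/noncoding region
#'
#' Counts adenines, in transcript sense, over the exonic footprint of each
#' gene. Genomic positions covered by several transcripts of the same gene
#' are counted once per gene, classified coding if they lie in the CDS of
#' any complete transcript; noncoding positions are exonic non-CDS
#' (UTRs and noncoding transcripts). Positions shared by overlapping genes
#' are counted in both genes' censuses.
#'
#' @param txset a `transcript_set`.
#' @return object of class `adenine_census`: list with `coding_A` and
#'   `noncoding_A`.
#' @export
count_transcribed_adenines <- function(txset) {
  stopifnot(inherits(txset, "transcript_set"))
  models <- txset$transcripts
  coding_A <- 0L; noncoding_A <- 0L
  if (length(models)) {
    key <- paste(vapply(models, `[[`, character(1), "gene_id"),
                 vapply(models, `[[`, character(1), "chrom"),
                 vapply(models, `[[`, character(1), "strand"), sep = "\r")
    for (grp in split(models, key)) {
      chrom <- grp[[1L]]$chrom; strand <- grp[[1L]]$strand
      exon_iv <- do.call(rbind, lapply(grp, `[[`, "exons"))
      cds_iv <- do.call(rbind, lapply(Filter(function(m) isTRUE(m$complete), grp),
                                      `[[`, "cds"))
      exonic <- IRanges::reduce(IRanges::IRanges(exon_iv[, 1L] + 1L, exon_iv[, 2L]))
      coding <- if (!is.null(cds_iv) && nrow(cds_iv)) {
        IRanges::reduce(IRanges::IRanges(cds_iv[, 1L] + 1L, cds_iv[, 2L]))
      } else IRanges::IRanges()
      noncoding <- IRanges::setdiff(exonic, coding)
      base <- if (strand == "+") "A" else "T"   # transcript-sense adenine
      cnt <- function(rng) {
        if (length(rng) == 0L) return(0L)
        v <- Biostrings::Views(txset$genome[[chrom]], start = IRanges::start(rng),
                               end = IRanges::end(rng))
        sum(Biostrings::letterFrequency(v, base))
      }
      coding_A <- coding_A + cnt(coding)
      noncoding_A <- noncoding_A + cnt(noncoding)
    }
  }
  structure(list(coding_A = as.integer(coding_A),
                 noncoding_A = as.integer(noncoding_A)),
            class = "adenine_census")
}

#' @export
print.adenine_census <- function(x, ...) {
  cat("adenine_census: coding_A =", x$coding_A,
      " noncoding_A =", x$noncoding_A, "\n")
  invisible(x)
}
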