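#' Map one editing site onto overlapping transcripts
#'
#' Returns one hit per transcript whose exons cover the site's genomic
#' position on the same strand; the region is classified in transcript
#' sense (CDS, 5'/3' UTR of coding transcripts, or `noncoding_exon` for
#' transcripts without a CDS). For CDS hits the 0-based offset within
#' `cds_sequence` is reported. An empty result means the site is intronic
#' or intergenic with respect to the supplied transcripts.
#'
#' @param site a single-row `editing_sites` data.frame (0-based `pos`).
#' @param txset a `transcript_set` (or list of `transcript_model`s).
#' @return data.frame with columns `transcript_id`, `gene_id`, `region`,
#'   `cds_offset` (NA outside CDS).
#' @export
map_site_to_transcripts <- function(site, txset) {
  models <- if (inherits(txset, "transcript_set")) txset$transcripts else txset
  hits <- lapply(models, function(m) {
    if (m$chrom != site$chrom || m$strand != site$strand) return(NULL)
    tpos <- genome_to_tx(m, site$pos)
    if (is.na(tpos)) return(NULL)
    span <- .cds_span_tx(m)
    if (is.null(span)) {
      region <- "noncoding_exon"; off <- NA_integer_
    } else if (tpos < span[1L]) {
      region <- "UTR5"; off <- NA_integer_
    } else if (tpos > span[2L]) {
      region <- "UTR3"; off <- NA_integer_
    } else {
      region <- "CDS"; off <- tpos - span[1L]
    }
    data.frame(transcript_id = m$transcript_id, gene_id = m$gene_id,
               region = region, cds_offset = off, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(transcript_id = character(0), gene_id = character(0),
                       region = character(0), cds_offset = integer(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  hits
}

#' Classify a CDS editing event
#'
#' Resolves the codon context of a CDS hit and derives the recoding
#' consequence of reading the edited adenosine as guanosine: original and
#' edited amino acid, the `"XtoY"` transition label, synonymous status and
#' the Laurent residue-change category. The reading frame is recomputed
#' from the CDS offset (`offset %% 3`), never trusted from annotation
#' phase fields.
#'
#' @param hit one row of [map_site_to_transcripts()] output with
#'   `region == "CDS"`.
#' @param transcript the matching complete `transcript_model`.
#' @param site the single-row `editing_sites` data.frame of the event.
#' @param categories category map from [laurent_categories()].
#' @return one-row data.frame of class `recoding_event` with the site
#'   columns plus `transcript_id`, `gene_id`, `region`, `cds_offset`,
#'   `codon`, `pos_in_codon`, `aa_from`, `aa_to`, `transition`,
#'   `synonymous`, `category`.
#' @export
classify_event <- function(hit, transcript, site,
                           categories = laurent_categories()) {
  stopifnot(hit$region == "CDS", isTRUE(transcript$complete))
  off <- hit$cds_offset
  codon_i <- off %/% 3L
  pos_in_codon <- off %% 3L + 1L
  codon <- substring(transcript$cds_sequence, codon_i * 3L + 1L,
                     codon_i * 3L + 3L)
  if (substring(codon, pos_in_codon, pos_in_codon) != "A") {
    stop("internal inconsistency: CDS base at edited position of ",
         transcript$transcript_id, " offset ", off, " is not A")
  }
  edited <- edit_codon(codon, pos_in_codon)
  aa_from <- translate_codons(codon)
  aa_to <- translate_codons(edited)
  lab <- transition_label(aa_from, aa_to)
  out <- data.frame(chrom = site$chrom, pos = site$pos, strand = site$strand,
                    tag = site$tag,
                    transcript_id = hit$transcript_id, gene_id = hit$gene_id,
                    region = "CDS", cds_offset = off,
                    codon = codon, pos_in_codon = pos_in_codon,
                    codon_to = edited, aa_from = aa_from, aa_to = aa_to,
                    transition = lab, synonymous = aa_from == aa_to,
                    category = categorise_transitions(lab, categories),
                    stringsAsFactors = FALSE)
  class(out) <- c("recoding_event", "data.frame")
  out
}

#' Map and classify a whole catalog of editing sites
#'
#' Convenience wrapper running [map_site_to_transcripts()] and
#' [classify_event()] over all retained sites. CDS hits on incomplete
#' transcripts are dropped (counted in the attribute
#' `n_incomplete_dropped`); non-CDS hits are reported with NA codon
#' columns.
#'
#' @inheritParams map_site_to_transcripts
#' @inheritParams classify_event
#' @param sites an `editing_sites` data.frame.
#' @return data.frame of per-(site, transcript) records; CDS rows carry
#'   the full recoding annotation.
#' @export
map_and_classify <- function(sites, txset, categories = laurent_categories()) {
  models <- txset$transcripts
  out <- vector("list", nrow(sites))
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    hits <- map_site_to_transcripts(site, txset)
    if (nrow(hits) == 0L) next
    rows <- vector("list", nrow(hits))
    for (j in seq_len(nrow(hits))) {
      hit <- hits[j, , drop = FALSE]
      m <- models[[hit$transcript_id]]
      if (hit$region == "CDS") {
        if (!isTRUE(m$complete)) { dropped <- dropped + 1L; next }
        rows[[j]] <- classify_event(hit, m, site, categories)
      } else {
        rows[[j]] <- data.frame(chrom = site$chrom, pos = site$pos,
                                strand = site$strand, tag = site$tag,
                                transcript_id = hit$transcript_id,
                                gene_id = hit$gene_id, region = hit$region,
                                cds_offset = NA_integer_, codon = NA_character_,
                                pos_in_codon = NA_integer_,
                                codon_to = NA_character_,
                                aa_from = NA_character_, aa_to = NA_character_,
                                transition = NA_character_, synonymous = NA,
                                category = NA_character_,
                                stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), tag = character(0),
                      transcript_id = character(0), gene_id = character(0),
                      region = character(0), cds_offset = integer(0),
                      codon = character(0), pos_in_codon = integer(0),
                      codon_to = character(0), aa_from = character(0),
                      aa_to = character(0), transition = character(0),
                      synonymous = logical(0), category = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "n_incomplete_dropped") <- dropped
  res
}

#' Apply the unique-CDS inclusion rule
#'
#' A CDS event is retained for the statistical analysis only when every
#' complete transcript of its gene belongs to a single CDS-identity group
#' (the gene has a unique CDS); retained events are reported once per CDS
#' group. Events on genes with several CDS-distinct isoforms are excluded
#' and written to a side table that also records, per excluded site,
#' whether all its overlapping transcripts share the same reading frame at
#' the site (identical `pos_in_codon`).
#'
#' @param events classified event data.frame from [map_and_classify()]
#'   (CDS rows are considered; others are ignored).
#' @param cds_set a `cds_transcript_set` from [merge_identical_cds()].
#' @return list with `kept` (one record per site x CDS group, with a
#'   `cds_group` column) and `excluded` (side table with a `same_frame`
#'   logical column).
#' @export
select_unambiguous_events <- function(events, cds_set) {
  ev <- events[events$region == "CDS", , drop = FALSE]
  if (nrow(ev) == 0L) {
    ev$cds_group <- integer(0)
    return(list(kept = ev, excluded = cbind(ev, same_frame = logical(0))))
  }
  n_groups_of_gene <- vapply(cds_set$gene2groups, length, integer(1))
  gene_unique <- names(n_groups_of_gene)[n_groups_of_gene == 1L]
  keep <- ev$gene_id %in% gene_unique
  kept <- ev[keep, , drop = FALSE]
  kept$cds_group <- unname(cds_set$tx2group[kept$transcript_id])
  # one record per (site, CDS group)
  key <- paste(kept$chrom, kept$pos, kept$strand, kept$cds_group, sep = "\r")
  kept <- kept[!duplicated(key), , drop = FALSE]
  rownames(kept) <- NULL
  excl <- ev[!keep, , drop = FALSE]
  if (nrow(excl)) {
    skey <- paste(excl$chrom, excl$pos, excl$strand, sep = "\r")
    same_frame <- stats::ave(excl$pos_in_codon, skey,
                             FUN = function(p) length(unique(p)) == 1L)
    excl$same_frame <- as.logical(same_frame)
  } else {
    excl$same_frame <- logical(0)
  }
  rownames(excl) <- NULL
  list(kept = kept, excluded = excl)
}
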