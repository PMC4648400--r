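#' @importFrom Biostrings GENETIC_CODE
NULL

# Standard genetic code as a fast named lookup (codon -> single-letter aa,
# stop = "*").
.code <- function() Biostrings::GENETIC_CODE

#' Translate codons under the standard genetic code
#'
#' @param codons character vector of 3-mers (ACGT alphabet, uppercase).
#' @return character vector of single-letter amino acids; stop codons
#'   translate to `"*"`.
#' @export
translate_codons <- function(codons) {
  aa <- unname(.code()[codons])
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    stop("not a standard codon: ", paste(bad, collapse = ", "))
  }
  aa
}

#' Split an in-frame CDS into codons
#'
#' @param cds a nucleotide string whose length is a multiple of 3.
#' @return character vector of codons.
#' @export
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Apply an A-to-G edit at one codon position
#'
#' Inosine is read as guanosine by the ribosome, so an edited adenosine
#' behaves as G; the edited codon is the original with the adenine at
#' `pos_in_codon` replaced by G.
#'
#' @param codon a 3-mer containing `A` at `pos_in_codon`.
#' @param pos_in_codon integer in 1..3.
#' @return the edited codon.
#' @export
edit_codon <- function(codon, pos_in_codon) {
  base <- substring(codon, pos_in_codon, pos_in_codon)
  if (any(base != "A")) stop("codon base at edited position is not A")
  substr(codon, pos_in_codon, pos_in_codon) <- "G"
  codon
}

# positions (1..3) of adenines within each codon; list parallel to `codons`
.adenine_positions <- function(codons) {
  lapply(strsplit(codons, ""), function(b) which(b == "A"))
}

#' Amino-acid transition label
#'
#' @param aa_from,aa_to single-letter amino acids (stop = `*`).
#' @return labels of the form `"KtoE"`.
#' @export
transition_label <- function(aa_from, aa_to) paste0(aa_from, "to", aa_to)

#' Enumerate every possible A-to-G edit of a set of codons
#'
#' The exhaustive event space used both by the analytic null expectation
#' and by the synthetic-data generator: one row per (codon, adenine
#' position) pair.
#'
#' @param codons character vector of codons (need not be unique).
#' @return data.frame with columns `codon`, `pos_in_codon`, `codon_to`,
#'   `aa_from`, `aa_to`, `transition`, `synonymous`, `n_adenines`.
#' @export
enumerate_edits <- function(codons) {
  codons <- unique(codons)
  apos <- .adenine_positions(codons)
  n <- lengths(apos)
  keep <- n > 0L
  codon <- rep(codons[keep], n[keep])
  pos <- unlist(apos[keep], use.names = FALSE)
  if (length(codon) == 0L) {
    return(data.frame(codon = character(0), pos_in_codon = integer(0),
                      codon_to = character(0), aa_from = character(0),
                      aa_to = character(0), transition = character(0),
                      synonymous = logical(0), n_adenines = integer(0),
                      stringsAsFactors = FALSE))
  }
  codon_to <- mapply(edit_codon, codon, pos, USE.NAMES = FALSE)
  aa_from <- translate_codons(codon)
  aa_to <- translate_codons(codon_to)
  data.frame(codon = codon, pos_in_codon = pos, codon_to = codon_to,
             aa_from = aa_from, aa_to = aa_to,
             transition = transition_label(aa_from, aa_to),
             synonymous = aa_from == aa_to,
             n_adenines = rep(n[keep], n[keep]),
             stringsAsFactors = FALSE)
}

#' Editable residues of a CDS
#'
#' A residue is *editable* when its codon contains at least one adenine
#' whose A-to-G edit is nonsynonymous. This is the reference set against
#' which the conservation of edited residues is compared.
#'
#' @param cds_sequence in-frame CDS nucleotide string.
#' @return 1-based residue indices (the terminal stop codon is excluded).
#' @export
editable_residues <- function(cds_sequence) {
  codons <- split_codons(cds_sequence)
  if (length(codons) == 0L) return(integer(0))
  ed <- enumerate_edits(unique(codons))
  nonsyn <- unique(ed$codon[!ed$synonymous])
  idx <- which(codons %in% nonsyn)
  # the terminal stop codon encodes no residue
  last <- length(codons)
  if (last > 0L && translate_codons(codons[last]) == "*") {
    idx <- idx[idx != last]
  }
  idx
}
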