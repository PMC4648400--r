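#' @importFrom Biostrings readAAStringSet
NULL

# the 22-symbol alphabet: 20 standard amino acids, gap, mask
.aa22 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y","-","X")

#' Read one family alignment from aligned FASTA
#'
#' @param path aligned FASTA (all rows equal length).
#' @param family_id identifier for the family (defaults to the file name).
#' @return object of class `family_alignment`: list with `family_id`,
#'   `members` (row names) and `mat` (character matrix, rows = members).
#' @export
read_family_alignment <- function(path, family_id = basename(path)) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0L) stop("empty alignment: ", path)
  if (length(unique(Biostrings::width(aln))) != 1L) {
    stop("alignment rows differ in length: ", path)
  }
  mat <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(mat) <- sub("\\s.*$", "", names(aln))
  structure(list(family_id = family_id, members = rownames(mat), mat = mat),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat("family_alignment", x$family_id, ":", nrow(x$mat), "members x",
      ncol(x$mat), "columns\n")
  invisible(x)
}

#' Shannon entropy of one alignment column
#'
#' Column entropy in bits over the 22-symbol alphabet (20 standard amino
#' acids, the gap character `-` and the mask character `X`); symbols
#' outside the alphabet, including `.` and ambiguity codes, are mapped to
#' the mask. A fully conserved column has H = 0; the maximum is
#' log2(22) ~ 4.46 bits.
#'
#' @param alignment a `family_alignment`.
#' @param column 1-based column index.
#' @return entropy in bits.
#' @export
column_entropy <- function(alignment, column) {
  if (column < 1L || column > ncol(alignment$mat)) {
    stop("column ", column, " outside alignment width ", ncol(alignment$mat))
  }
  col <- toupper(alignment$mat[, column])
  if (length(col) == 0L) stop("empty column: alignment has no rows")
  col[col == "."] <- "-"
  col[!(col %in% .aa22)] <- "X"
  p <- table(col) / length(col)
  -sum(p * log2(p))
}

#' Per-column entropy profile of a family alignment
#'
#' @param alignment a `family_alignment`.
#' @return object of class `column_entropy_profile`: data.frame with
#'   `column` and `H` (bits).
#' @export
entropy_profile <- function(alignment) {
  H <- vapply(seq_len(ncol(alignment$mat)), function(j)
    column_entropy(alignment, j), numeric(1))
  structure(data.frame(column = seq_along(H), H = H),
            class = c("column_entropy_profile", "data.frame"))
}

#' Entropy of one residue of a reference protein
#'
#' Maps a 1-based residue position of the ungapped reference member onto
#' its alignment column (skipping gap columns of that member) and returns
#' the column entropy.
#'
#' @param member_id row name of the reference member in the alignment.
#' @param residue_pos 1-based position in the ungapped member sequence.
#' @param alignment a `family_alignment`.
#' @return entropy in bits.
#' @export
residue_entropy <- function(member_id, residue_pos, alignment) {
  if (!(member_id %in% rownames(alignment$mat))) {
    stop("member '", member_id, "' not in family ", alignment$family_id)
  }
  row <- alignment$mat[member_id, ]
  nongap <- row != "-" & row != "."
  col <- which(cumsum(nongap) == residue_pos & nongap)[1L]
  if (is.na(col)) {
    stop("residue ", residue_pos, " of '", member_id,
         "' maps to no alignment column (sequence length ",
         sum(nongap), ")")
  }
  column_entropy(alignment, col)
}

#' Compare conservation of edited vs editable residues
#'
#' Collects the column entropies of residues hit by nonsynonymous editing
#' and of all editable residues (those whose codon contains at least one
#' adenine whose edit would be nonsynonymous) over the same protein set,
#' and compares the two entropy samples with a two-sided
#' Wilcoxon-Mann-Whitney test (midrank ties). Residues are pooled across
#' proteins; families with fewer than `min_members` rows are excluded as
#' uninformative.
#'
#' @param edited_positions data.frame with columns `protein_id`,
#'   `residue_pos` (1-based) for nonsynonymously edited residues.
#' @param editable_positions same layout, for the editable reference set.
#' @param alignments named list of `family_alignment`s keyed by family id.
#' @param mapping data.frame with columns `protein_id`, `family_id`,
#'   `member_id` locating each protein in its family alignment.
#' @param min_members minimum family size (default 3).
#' @return object of class `conservation_comparison`: list with
#'   `edited_H`, `editable_H`, `W`, `p_value`, `n_edited`, `n_editable`.
#'   Empty sets yield NA with a warning.
#' @export
conservation_comparison <- function(edited_positions, editable_positions,
                                    alignments, mapping, min_members = 3L) {
  get_H <- function(df) {
    out <- numeric(0)
    for (i in seq_len(nrow(df))) {
      pid <- df$protein_id[i]
      m <- mapping[mapping$protein_id == pid, , drop = FALSE]
      if (nrow(m) == 0L) next
      aln <- alignments[[m$family_id[1L]]]
      if (is.null(aln) || nrow(aln$mat) < min_members) next
      out <- c(out, residue_entropy(m$member_id[1L], df$residue_pos[i], aln))
    }
    out
  }
  edited_H <- get_H(edited_positions)
  editable_H <- get_H(editable_positions)
  if (length(edited_H) == 0L || length(editable_H) == 0L) {
    warning("empty entropy set; conservation comparison undefined")
    W <- NA_real_; p <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(edited_H, editable_H))
    W <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(edited_H = edited_H, editable_H = editable_H,
                 W = W, p_value = p,
                 n_edited = length(edited_H), n_editable = length(editable_H)),
            class = "conservation_comparison")
}

#' @export
print.conservation_comparison <- function(x, ...) {
  cat(sprintf(paste0("conservation_comparison: %d edited (median H %.3f)",
                     " vs %d editable (median H %.3f), W = %.1f, p = %.3g\n"),
              x$n_edited, stats::median(x$edited_H),
              x$n_editable, stats::median(x$editable_H), x$W, x$p_value))
  invisible(x)
}

#' @method plot conservation_comparison
#' @export
plot.conservation_comparison <- function(x, ...) {
  graphics::boxplot(list(edited = x$edited_H, editable = x$editable_H),
                    ylab = "Shannon entropy (bits)", ...)
  invisible(x)
}
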