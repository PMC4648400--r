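#' Read an editing-site catalog
#'
#' Reads a DARNED-style tab-separated catalog with header columns `chrom`,
#' `pos` (1-based), `strand` and optional `tag`. Coordinates are converted
#' to the package-internal 0-based convention; file order is preserved and
#' exact duplicates (same chrom, position, strand) are collapsed with a
#' warning giving the duplicate count.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `editing_sites` with columns `chrom`, `pos`
#'   (0-based), `strand`, `tag`.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(df))) {
    stop("site catalog must have columns chrom, pos, strand")
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    stop("non-integer position at line ", which(is.na(pos))[1L] + 1L,
         " of ", path)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- which(!(df$strand %in% c("+", "-")))[1L]
    stop("invalid strand '", df$strand[bad], "' at line ", bad + 1L,
         " of ", path)
  }
  out <- data.frame(chrom = df$chrom, pos = pos - 1L, strand = df$strand,
                    tag = if (is.null(df$tag)) "" else df$tag,
                    stringsAsFactors = FALSE)
  key <- paste(out$chrom, out$pos, out$strand, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate site(s) collapsed")
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("editing_sites", "data.frame")
  out
}

#' Read a SNP exclusion list
#'
#' @param path TSV with header columns `chrom`, `pos` (1-based).
#' @return data.frame with `chrom` and 0-based `pos`.
#' @export
read_snps <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (!all(c("chrom", "pos") %in% names(df))) {
    stop("SNP list must have columns chrom, pos")
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) stop("non-integer SNP position in ", path)
  data.frame(chrom = df$chrom, pos = pos - 1L, stringsAsFactors = FALSE)
}

#' Filter an editing-site catalog
#'
#' Applies the standard catalog cleaning: removes sites carrying an
#' excluded source tag (e.g. sites annotated in cancer tissues), sites at
#' known SNP positions (matched by chromosome and position only, ignoring
#' alleles), sites beyond the end of their chromosome, and sites whose
#' strand-adjusted reference base is not adenine (for minus-strand sites
#' the plus-strand base must be T). Each removed site is counted under the
#' first matching reason, in the order listed above. Filtering is
#' idempotent.
#'
#' @param sites an `editing_sites` data.frame (see [read_sites()]).
#' @param snps SNP data.frame from [read_snps()] (or NULL for none).
#' @param genome genome FASTA path or `DNAStringSet`.
#' @param exclude_tags character vector of source tags to drop
#'   (default `"cancer"`).
#' @return list with `retained` (an `editing_sites` data.frame) and
#'   `report` (named integer: input, retained and per-reason removal
#'   counts).
#' @export
filter_sites <- function(sites, snps = NULL, genome,
                         exclude_tags = "cancer") {
  genome <- .load_genome(genome)
  n_in <- nrow(sites)
  reason <- rep(NA_character_, n_in)
  if (length(exclude_tags) && !is.null(sites$tag)) {
    reason[is.na(reason) & sites$tag %in% exclude_tags] <- "tag_excluded"
  }
  if (!is.null(snps) && nrow(snps)) {
    snp_key <- paste(snps$chrom, snps$pos, sep = "\r")
    site_key <- paste(sites$chrom, sites$pos, sep = "\r")
    reason[is.na(reason) & site_key %in% snp_key] <- "snp_overlap"
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  oob <- !(sites$chrom %in% names(genome)) |
    sites$pos < 0L | sites$pos >= chrom_len[sites$chrom]
  oob[is.na(oob)] <- TRUE
  reason[is.na(reason) & oob] <- "out_of_bounds"
  # strand-adjusted reference base must be adenine
  chk <- which(is.na(reason))
  if (length(chk)) {
    chrom_str <- lapply(stats::setNames(nm = unique(sites$chrom[chk])),
                        function(ch) as.character(genome[[ch]]))
    base <- vapply(chk, function(i) {
      substring(chrom_str[[sites$chrom[i]]], sites$pos[i] + 1L,
                sites$pos[i] + 1L)
    }, character(1))
    want <- ifelse(sites$strand[chk] == "+", "A", "T")
    reason[chk[base != want]] <- "not_adenine"
  }
  retained <- sites[is.na(reason), , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("editing_sites", "data.frame")
  reasons <- c("tag_excluded", "snp_overlap", "out_of_bounds", "not_adenine")
  report <- c(input = n_in, retained = nrow(retained),
              stats::setNames(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                                     integer(1)), reasons))
  list(retained = retained, report = report)
}
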