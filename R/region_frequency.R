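#' Coding vs noncoding editing-frequency test
#'
#' Compares the per-adenine editing frequency between coding (CDS) and
#' noncoding (exonic non-CDS) regions with a two-sided Fisher exact test
#' on `[[edited_coding, coding_A - edited_coding],
#' [edited_noncoding, noncoding_A - edited_noncoding]]`.
#'
#' @param edited_coding,edited_noncoding numbers of edited adenines per
#'   region.
#' @param census an `adenine_census` from [count_transcribed_adenines()].
#' @return object of class `region_frequency`: list with the counts, the
#'   census, `freq_coding`, `freq_noncoding`, `ratio`
#'   (noncoding/coding frequency) and `p_value`. A zero census in either
#'   region yields `p_value = NA` with a warning.
#' @export
region_editing_test <- function(edited_coding, edited_noncoding, census) {
  stopifnot(inherits(census, "adenine_census"))
  if (edited_coding > census$coding_A || edited_noncoding > census$noncoding_A) {
    stop("edited counts exceed the adenine census")
  }
  if (edited_coding < 0 || edited_noncoding < 0) stop("negative counts")
  if (census$coding_A == 0L || census$noncoding_A == 0L) {
    warning("zero adenine census in a region; p-value undefined")
    p <- NA_real_
    fc <- if (census$coding_A) edited_coding / census$coding_A else NA_real_
    fn <- if (census$noncoding_A) edited_noncoding / census$noncoding_A else NA_real_
  } else {
    m <- matrix(c(edited_coding, census$coding_A - edited_coding,
                  edited_noncoding, census$noncoding_A - edited_noncoding),
                nrow = 2L, byrow = TRUE)
    p <- stats::fisher.test(m)$p.value
    fc <- edited_coding / census$coding_A
    fn <- edited_noncoding / census$noncoding_A
  }
  structure(list(edited_coding = edited_coding,
                 edited_noncoding = edited_noncoding,
                 census = census, freq_coding = fc, freq_noncoding = fn,
                 ratio = fn / fc, p_value = p),
            class = "region_frequency")
}

#' @export
print.region_frequency <- function(x, ...) {
  cat(sprintf(paste0("region_frequency: coding %d/%d (%.3g), noncoding",
                     " %d/%d (%.3g), ratio %.2f, p = %.3g\n"),
              x$edited_coding, x$census$coding_A, x$freq_coding,
              x$edited_noncoding, x$census$noncoding_A, x$freq_noncoding,
              x$ratio, x$p_value))
  invisible(x)
}
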