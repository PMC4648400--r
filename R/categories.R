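#' Laurent residue-change categories
#'
#' The four-way classification of amino-acid changes (Synonymous / Similar /
#' Somewhat different / Very different) used throughout the recoding
#' analysis, covering the 26 transitions observed in the fly and human
#' datasets. Transitions absent from the map (including any involving a
#' stop codon) fall back to `"Unclassified"` unless the caller extends the
#' map.
#'
#' @param extra optional named character vector of additional
#'   `transition -> category` assignments; may also override defaults.
#' @return named character vector mapping transition labels (e.g. `"KtoE"`)
#'   to category names.
#' @export
laurent_categories <- function(extra = NULL) {
  map <- c(
    KtoK = "Synonymous", EtoE = "Synonymous", VtoV = "Synonymous",
    QtoQ = "Synonymous", LtoL = "Synonymous", TtoT = "Synonymous",
    PtoP = "Synonymous", StoS = "Synonymous", RtoR = "Synonymous",
    AtoA = "Synonymous", GtoG = "Synonymous",
    ItoM = "Similar", KtoR = "Similar", NtoD = "Similar",
    MtoV = "Similar", ItoV = "Similar",
    KtoE = "Somewhat different", StoG = "Somewhat different",
    TtoA = "Somewhat different", NtoS = "Somewhat different",
    QtoR = "Somewhat different",
    RtoG = "Very different", YtoC = "Very different",
    HtoR = "Very different", EtoG = "Very different",
    DtoG = "Very different")
  if (!is.null(extra)) {
    stopifnot(!is.null(names(extra)))
    map[names(extra)] <- extra
  }
  map
}

#' Categorise transition labels
#'
#' Synonymous transitions (XtoX) are always `"Synonymous"`; other labels
#' are looked up in the category map, defaulting to `"Unclassified"`.
#'
#' @param transitions character vector of `"XtoY"` labels.
#' @param categories a map from [laurent_categories()].
#' @return character vector of categories.
#' @export
categorise_transitions <- function(transitions, categories = laurent_categories()) {
  out <- unname(categories[transitions])
  aa <- substr(transitions, 1L, 1L)
  to <- substring(transitions, nchar(transitions))
  syn <- aa == to
  out[syn] <- "Synonymous"
  out[is.na(out)] <- "Unclassified"
  out
}

#' @rdname categorise_transitions
#' @export
nonsynonymous_categories <- function() {
  c("Similar", "Somewhat different", "Very different")
}
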