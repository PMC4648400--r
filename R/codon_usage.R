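#' Relative synonymous codon usage of a CDS set
#'
#' Counts every in-frame codon over the supplied complete CDS sequences
#' and computes each codon's frequency within its synonymous family (the
#' codons encoding the same amino acid, stop codons forming their own
#' family). Frequencies within a family sum to one; families absent from
#' the CDS set get NA frequencies.
#'
#' @param cds_set character vector of complete CDS sequences, or a
#'   `cds_transcript_set` (group-representative CDSs are used).
#' @return data.frame of class `codon_usage` with columns `codon`, `aa`,
#'   `count`, `family_frequency`, covering all 64 codons.
#' @export
build_usage_table <- function(cds_set) {
  if (inherits(cds_set, "cds_transcript_set")) cds_set <- cds_set$cds_sequences
  codons <- unlist(lapply(cds_set, split_codons), use.names = FALSE)
  all64 <- names(.code())
  count <- stats::setNames(rep(0L, 64L), all64)
  if (length(codons)) {
    tab <- table(codons)
    count[names(tab)] <- as.integer(tab)
  }
  aa <- translate_codons(all64)
  fam_tot <- stats::ave(count, aa, FUN = sum)
  out <- data.frame(codon = all64, aa = aa, count = unname(count),
                    family_frequency = ifelse(fam_tot > 0, count / fam_tot,
                                              NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Codon-usage direction of synonymous edits
#'
#' Classifies a synonymous codon change by whether it replaces a less
#' frequently used codon with a more frequently used one of the same
#' family (`less_to_more`), the opposite (`more_to_less`), or an equally
#' used one (`equal`).
#'
#' @param codon_from,codon_to synonymous codon pair(s).
#' @param usage a `codon_usage` table.
#' @return character vector of directions.
#' @export
classify_direction <- function(codon_from, codon_to, usage) {
  if (any(translate_codons(codon_from) != translate_codons(codon_to))) {
    stop("direction classification requires synonymous codon pairs")
  }
  f <- stats::setNames(usage$family_frequency, usage$codon)
  from <- unname(f[codon_from]); to <- unname(f[codon_to])
  ifelse(from < to, "less_to_more",
         ifelse(from > to, "more_to_less", "equal"))
}

#' Direction enrichment of synonymous events
#'
#' Applies the ER/Fisher machinery of the transition analysis to the three
#' codon-usage direction classes of the synonymous events. The null
#' tallies come from the same codon-pool randomizations, recorded at
#' codon-transition resolution and re-classified by direction, so observed
#' and expected counts live under one model. The 2x2 Fisher tables are
#' formed within synonymous events only.
#'
#' @param events classified event data.frame (e.g. the kept events from
#'   [select_unambiguous_events()]); only synonymous rows are used.
#' @param null a `null_distribution` (carries codon-resolution tallies).
#' @param usage a `codon_usage` table.
#' @return data.frame of class `direction_table` with columns `direction`,
#'   `n_obs`, `n_rand`, `ER`, `fisher_p`, `fdr_p`.
#' @export
direction_enrichment <- function(events, null, usage) {
  stopifnot(inherits(null, "null_distribution"))
  syn <- events[which(events$synonymous), , drop = FALSE]
  dirs <- c("less_to_more", "more_to_less", "equal")
  obs <- stats::setNames(rep(0L, 3L), dirs)
  if (nrow(syn)) {
    d <- classify_direction(syn$codon, syn$codon_to, usage)
    tab <- table(d)
    obs[names(tab)] <- as.integer(tab)
  }
  # null synonymous tallies by direction
  nc <- null$n_rand_codon
  parts <- strsplit(names(nc), ">", fixed = TRUE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  is_syn <- translate_codons(from) == translate_codons(to)
  rnd <- stats::setNames(rep(0, 3L), dirs)
  if (any(is_syn)) {
    d0 <- classify_direction(from[is_syn], to[is_syn], usage)
    agg <- vapply(split(nc[is_syn], d0), sum, numeric(1))
    rnd[names(agg)] <- agg
  }
  n_obs_syn <- sum(obs)
  n_rand_syn <- sum(rnd)
  fisher_p <- vapply(dirs, function(d) {
    if (n_obs_syn == 0 || n_rand_syn == 0) return(NA_real_)
    m <- matrix(c(obs[[d]], n_obs_syn - obs[[d]],
                  rnd[[d]], n_rand_syn - rnd[[d]]), nrow = 2L, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  er <- er_ratio(unname(obs), unname(rnd), null$N_rand)
  er[obs == 0 & rnd == 0] <- NA_real_   # direction never realisable here
  out <- data.frame(direction = dirs, n_obs = unname(obs),
                    n_rand = unname(rnd), ER = er,
                    fisher_p = unname(fisher_p),
                    fdr_p = unname(stats::p.adjust(fisher_p, method = "BH")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("direction_table", "data.frame")
  out
}
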