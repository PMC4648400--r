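#' Build the adenine-containing codon pool
#'
#' The null model draws from the multiset of in-frame codons containing at
#' least one adenine, collected over the CDS sequences of the edited
#' transcript set (with multiplicity).
#'
#' @param edited_cds character vector of complete CDS sequences (lengths
#'   divisible by 3).
#' @return object of class `codon_pool`: list with `counts` (named integer
#'   codon multiplicities) and `total`.
#' @export
build_codon_pool <- function(edited_cds) {
  codons <- unlist(lapply(edited_cds, split_codons), use.names = FALSE)
  codons <- codons[grepl("A", codons, fixed = TRUE)]
  counts <- table(codons)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 total = length(codons)),
            class = "codon_pool")
}

#' @export
print.codon_pool <- function(x, ...) {
  cat("codon_pool:", x$total, "adenine-containing codons,",
      length(x$counts), "distinct\n")
  invisible(x)
}

# event space of a pool: one row per (codon, adenine position), with the
# probability that a single null draw produces that event
.pool_event_space <- function(pool) {
  if (is.null(pool$total) || pool$total == 0L) stop("empty codon pool")
  ed <- enumerate_edits(names(pool$counts))
  mult <- pool$counts[ed$codon]
  ed$prob <- unname(mult) / pool$total / ed$n_adenines
  ed
}

#' Exact per-transition null probabilities
#'
#' Analytic expectation for a single draw of the random model: a codon is
#' drawn from the pool proportionally to its multiplicity, then one of its
#' adenines is picked uniformly at random. The returned probabilities sum
#' to one and serve as the exact oracle for the Monte-Carlo sampler.
#'
#' @param pool a `codon_pool`.
#' @param level `"aa"` for amino-acid transition labels (e.g. `"KtoE"`),
#'   `"codon"` for codon-resolution labels (e.g. `"AAA>GAA"`).
#' @return named numeric vector of probabilities.
#' @export
analytic_expectation <- function(pool, level = c("aa", "codon")) {
  level <- match.arg(level)
  ed <- .pool_event_space(pool)
  key <- if (level == "aa") ed$transition else paste0(ed$codon, ">", ed$codon_to)
  p <- vapply(split(ed$prob, key), sum, numeric(1))
  p / sum(p)
}

#' Draw one randomization of the null model
#'
#' Draws `n_events` codons from the pool uniformly with replacement and,
#' for each, picks one adenine uniformly at random, recording the
#' resulting amino-acid transition. Uses the current RNG state.
#'
#' @param pool a `codon_pool`.
#' @param n_events number of events to draw.
#' @return named integer tally per transition summing to `n_events`, with
#'   attribute `"codon"` holding the codon-resolution tally.
#' @export
sample_randomization <- function(pool, n_events) {
  ed <- .pool_event_space(pool)
  if (n_events == 0L) {
    out <- integer(0)
    attr(out, "codon") <- integer(0)
    return(out)
  }
  idx <- sample.int(nrow(ed), n_events, replace = TRUE, prob = ed$prob)
  aa <- table(ed$transition[idx])
  co <- table(paste0(ed$codon[idx], ">", ed$codon_to[idx]))
  out <- stats::setNames(as.integer(aa), names(aa))
  attr(out, "codon") <- stats::setNames(as.integer(co), names(co))
  out
}

#' Run the codon-resampling null model
#'
#' Accumulates per-transition event tallies over `N_rand` randomizations
#' of `n_events` draws each. Because every draw is independent (codons are
#' sampled with replacement and one adenine per codon uniformly), the
#' pooled tallies are multinomial with `N_rand * n_events` trials and the
#' analytic event probabilities, and are sampled directly as such; this is
#' distributionally identical to looping over randomizations and makes one
#' million randomizations immediate.
#'
#' @param pool a `codon_pool`.
#' @param n_events events per randomization (the observed dataset size).
#' @param N_rand number of randomizations (one million reproduces the
#'   published analysis; 1e4 to 1e5 is ample for testing).
#' @param seed integer seed making the run reproducible.
#' @return object of class `null_distribution`: list with `n_rand` (named
#'   numeric, pooled per-transition tallies), `n_rand_codon`
#'   (codon-resolution tallies), `n_events`, `N_rand`, `seed`.
#' @export
run_null_model <- function(pool, n_events, N_rand, seed = 1L) {
  stopifnot(N_rand >= 1, n_events >= 1)
  ed <- .pool_event_space(pool)
  total <- as.numeric(N_rand) * n_events
  if (total > .Machine$integer.max) {
    stop("N_rand * n_events exceeds integer range; reduce N_rand")
  }
  draw <- local_seed(seed, {
    as.vector(stats::rmultinom(1L, size = as.integer(total), prob = ed$prob))
  })
  key_codon <- paste0(ed$codon, ">", ed$codon_to)
  n_rand_codon <- vapply(split(draw, key_codon), sum, numeric(1))
  n_rand <- vapply(split(draw, ed$transition), sum, numeric(1))
  structure(list(n_rand = n_rand, n_rand_codon = n_rand_codon,
                 n_events = n_events, N_rand = N_rand, seed = seed),
            class = "null_distribution")
}

# evaluate `expr` under a private RNG seed, restoring the caller's state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution:", x$N_rand, "randomizations x", x$n_events,
      "events;", length(x$n_rand), "transitions\n")
  invisible(x)
}

#' Enrichment ratio (ER) score
#'
#' Base-2 logarithm of the observed event count over the mean randomized
#' count, with a pseudocount of 1 added to both counts:
#' `ER = log2((n_obs + 1) * N_rand / (n_rand + 1))`, where `n_rand` is the
#' total count over all `N_rand` randomizations. Monotone increasing in
#' `n_obs` and decreasing in `n_rand`.
#'
#' @param n_obs observed event count(s).
#' @param n_rand total randomized count(s) over all randomizations.
#' @param N_rand number of randomizations.
#' @return numeric ER score(s).
#' @export
er_ratio <- function(n_obs, n_rand, N_rand) {
  log2((n_obs + 1) * N_rand / (n_rand + 1))
}

#' Per-transition enrichment tests
#'
#' For each transition, compares the observed count against the pooled
#' null tally with a two-sided Fisher exact test on the 2x2 table
#' `[[n_obs, n_events - n_obs], [n_rand, N_rand*n_events - n_rand]]`,
#' corrects across transitions with Benjamini-Hochberg, and attaches the
#' ER score and Laurent category. Transitions with zero counts in both the
#' observed and the null tallies are not tested.
#'
#' @param n_obs named integer vector of observed per-transition counts
#'   (or a character vector of transition labels, one per event).
#' @param null a `null_distribution` whose `n_events` equals `sum(n_obs)`.
#' @param categories category map from [laurent_categories()].
#' @return data.frame of class `transition_table` with columns
#'   `transition`, `n_obs`, `n_rand`, `ER`, `fisher_p`, `fdr_p`,
#'   `category`, sorted by decreasing ER.
#' @export
transition_tests <- function(n_obs, null, categories = laurent_categories()) {
  stopifnot(inherits(null, "null_distribution"))
  if (is.character(n_obs) && is.null(names(n_obs))) {
    tab <- table(n_obs)
    n_obs <- stats::setNames(as.integer(tab), names(tab))
  }
  if (sum(n_obs) != null$n_events) {
    stop("sum(n_obs) = ", sum(n_obs), " differs from null n_events = ",
         null$n_events)
  }
  labels <- sort(union(names(n_obs)[n_obs > 0], names(null$n_rand)[null$n_rand > 0]))
  obs <- stats::setNames(rep(0L, length(labels)), labels)
  obs[names(n_obs)[names(n_obs) %in% labels]] <-
    n_obs[names(n_obs) %in% labels]
  rnd <- stats::setNames(rep(0, length(labels)), labels)
  rnd[names(null$n_rand)[names(null$n_rand) %in% labels]] <-
    null$n_rand[names(null$n_rand) %in% labels]
  n_ev <- null$n_events
  grand <- as.numeric(null$N_rand) * n_ev
  fisher_p <- vapply(labels, function(t) {
    m <- matrix(c(obs[[t]], n_ev - obs[[t]], rnd[[t]], grand - rnd[[t]]),
                nrow = 2L, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  out <- data.frame(transition = labels,
                    n_obs = unname(obs), n_rand = unname(rnd),
                    ER = er_ratio(unname(obs), unname(rnd), null$N_rand),
                    fisher_p = unname(fisher_p),
                    fdr_p = unname(stats::p.adjust(fisher_p, method = "BH")),
                    category = categorise_transitions(labels, categories),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ER), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transition_table", "data.frame")
  attr(out, "n_events") <- n_ev
  attr(out, "N_rand") <- null$N_rand
  out
}

#' @export
print.transition_table <- function(x, digits = 3, ...) {
  cat("transition_table:", nrow(x), "transitions,",
      attr(x, "n_events"), "observed events, N_rand =",
      format(attr(x, "N_rand"), big.mark = ","), "\n")
  y <- as.data.frame(x)
  y$ER <- round(y$ER, digits)
  y$fisher_p <- signif(y$fisher_p, digits)
  y$fdr_p <- signif(y$fdr_p, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @method summary transition_table
#' @export
summary.transition_table <- function(object, alpha = 0.05, ...) {
  sig <- object$fdr_p < alpha
  cat(nrow(object), "transitions;", sum(sig), "significant at BH",
      alpha, "\n")
  if (any(sig)) {
    dir <- ifelse(object$ER[sig] > 0, "enriched", "depleted")
    cat(paste0("  ", object$transition[sig], " (", dir, ", ER = ",
               round(object$ER[sig], 2), ", fdr = ",
               signif(object$fdr_p[sig], 2), ")", collapse = "\n"), "\n")
  }
  invisible(object)
}

#' @method plot transition_table
#' @export
plot.transition_table <- function(x, ...) {
  cols <- c(Synonymous = "white", Similar = "grey70",
            `Somewhat different` = "lightblue", `Very different` = "steelblue",
            Unclassified = "grey40")
  bp <- graphics::barplot(x$ER, names.arg = x$transition, las = 2,
                          col = cols[x$category], ylab = "ER (log2)",
                          border = "grey30", ...)
  graphics::abline(h = 0)
  invisible(bp)
}
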