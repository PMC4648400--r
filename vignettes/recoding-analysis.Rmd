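---
title: "Methods: recoding analysis of A-to-I editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recoding analysis of A-to-I editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editrec)
```

## The problem and the model

A-to-I editing by ADAR enzymes makes an adenosine read as guanosine.
Inside a CDS this can recode the protein, and the scientific question is
whether the observed spectrum of amino-acid transitions departs from what
indiscriminate editing of the same coding sequences would produce. The
package's core is a *codon-resampling null model*: the reference
distribution is built from the codons actually present in the edited
CDSs, so it automatically conditions on codon composition, amino-acid
composition and adenine availability of the analysed genes.

One null *event* is generated by (i) drawing a codon, proportionally to
its multiplicity, from the pool of in-frame codons containing at least
one adenine, and (ii) editing one of its adenines chosen uniformly at
random. A *randomization* is `n_events` such draws, where `n_events` is
the size of the observed dataset, and `N_rand` randomizations are
accumulated. Drawing one adenine per drawn codon means a codon with two
editable adenines contributes one event, not two — this deliberately
avoids over-weighting nonsynonymous outcomes of multi-adenine codons,
which is the main difference from adenine-level (rather than
codon-level) nulls.

Per transition `t` the enrichment score is

$$\mathrm{ER}(t) = \log_2 \frac{(n_\mathrm{obs}(t) + 1)\, N_\mathrm{rand}}
                              {n_\mathrm{rand}(t) + 1},$$

with `n_rand(t)` the total count over all randomizations; the
pseudocounts keep the score finite for empty cells. Significance per
transition comes from a two-sided Fisher exact test on
`[[n_obs, n_events - n_obs], [n_rand, N_rand * n_events - n_rand]]`, with
Benjamini–Hochberg correction across the tested transitions (those with
nonzero observed or randomized counts).

### Assumptions

* Editing is A-to-I only, read as A→G, under the standard genetic code.
* The catalog, after filtering, contains genuine adenosine sites on the
  annotated strand; sites on SNPs or non-adenine positions are artefacts
  and are removed, not modelled.
* Events on genes with several CDS-distinct isoforms cannot be assigned
  to a transcript and are excluded from the enrichment analysis (they are
  logged with a same-reading-frame flag instead).
* The null conditions on the edited CDS set: the codon pool is built from
  the CDS sequences of the transcripts that carry kept events.

## Sampler implementation and its oracle

Because codons are drawn with replacement and adenines independently,
every null event is i.i.d., and the pooled tallies over
`N_rand * n_events` draws are exactly multinomial with the event
probabilities

$$P(t) = \sum_{c} \frac{m_c}{|{\rm pool}|}\cdot
         \frac{\#\{\text{adenines of } c \text{ yielding } t\}}{\#\{\text{adenines of } c\}}.$$

`run_null_model()` therefore samples the pooled tallies directly with
`rmultinom()`, which is distributionally identical to looping over
randomizations and makes `N_rand = 10^6` immediate;
`sample_randomization()` keeps the literal per-draw loop for single
randomizations. `analytic_expectation()` computes `P(t)` exactly and is
the oracle against which both samplers are tested (chi-square goodness of
fit at `alpha = 0.001` over randomized pools). Whether the original
procedure sampled codons with or without replacement within one
randomization is not specified anywhere; with replacement was chosen
because the pool is three to four orders of magnitude larger than
`n_events`, making the distinction negligible, and because it admits the
exact oracle above. Likewise the Fisher tables pool counts over all
randomizations rather than conditioning per randomization.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `N_rand` | 10^4 (pipeline), 10^6 for publication-scale runs | randomizations; ER precision grows with `N_rand`, runtime is insensitive thanks to the multinomial sampler |
| `seed` | 1 | drives every random stage; identical config + seed gives byte-identical reports |
| `exclude_tags` | `"cancer"` | catalog source tags removed before analysis |
| `min_family_members` | 3 | family alignments smaller than this are uninformative for entropy and are skipped |

The ER pseudocount placement deserves a note: the score is defined
verbally as "observed over randomized times the number of
randomizations, with a pseudocount of 1". We place the pseudocounts as
`(n_obs + 1)` and `(n_rand + 1)`, which matches the verbal definition,
keeps the score finite in both directions, and reproduces the range of
the published fly/human table (−4.07 to 3.33). The alternative parse
`log2((n_obs + 1)/((n_rand/N_rand) + 1))` compresses all depletion scores
into (−1, 0] and cannot produce a value like −4.07, so it was rejected.

## Conservation comparison

Column conservation is Shannon entropy in bits over a 22-symbol alphabet
(20 standard amino acids, gap `-`, mask `X`; anything else maps to the
mask), computed per alignment column; a residue of a reference protein is
mapped to its column by skipping that member's gaps. Nonsynonymously
edited residues are compared with all *editable* residues — those whose
codon contains at least one adenine whose edit would be nonsynonymous —
from the same protein set, pooled across proteins (each residue counts
once; proteins with many editable residues contribute more residues, by
design). The two entropy samples are compared with a two-sided
Wilcoxon–Mann–Whitney test with midrank ties. Base-2 logarithms are used
throughout so entropies read as bits with maximum `log2(22) ≈ 4.46`.

## Codon-usage direction of synonymous events

Relative synonymous codon usage is computed from the analysis's own CDS
set (the merged CDS transcripts carrying events), keeping the pipeline
self-contained; an organism-wide table can be supplied instead via
`build_usage_table()` on any CDS collection. A synonymous event is
`less_to_more` if the edited codon is the more frequently used member of
the family, `more_to_less` if less, `equal` on ties. The same null
randomizations, recorded at codon-transition resolution, provide the
expected direction counts, so observed and expected live under one
model. A direction with zero observed and zero randomized counts is
reported with `ER = NA` rather than a pseudocount artefact.

## Cross-dataset comparisons

Per-transition ER profiles of two datasets are compared by Pearson
correlation over the transitions present in both (separately for
synonymous and nonsynonymous categories; fewer than three pairs give
`NA`), and by a two-sided rank-sum test on ER values or their absolute
magnitudes. "Absolute values" is interpreted as |ER|: on the shipped
reference table this interpretation reproduces the published statistic
(W = 170, recomputing from the rounded printed values gives 170.5) while
the signed values do not. The exact rank-sum null is used for untied
samples with both sizes ≤ 20, the normal approximation with tie
correction otherwise.

## What the synthetic generator emulates — and what it does not

`sim_config()` + the three `generate_*()` stages produce everything the
pipeline reads: multi-exon genes on both strands with ATG…stop CDSs,
same-CDS and CDS-distinct second isoforms (exercising the unique-CDS
rule), noncoding genes, ambiguously tagged transcripts, editing catalogs
whose coding events follow the pool's analytic expectation times a
configurable per-transition enrichment, noncoding events at a
configurable per-adenine rate ratio, SNP/non-adenine/tagged decoys, and
family alignments with per-column substitution at a background rate
scaled on edited columns. One master seed derives an independent stream
per stage, so regenerating sites does not perturb the reference.

The generator deliberately does **not** model ADAR sequence-context
preferences (5' and 3' neighbour biases), double-stranded RNA structure,
editing levels (percent edited per site), overlapping genes, or
phylogenetically structured family divergence (homolog columns evolve
i.i.d. given the rate). Passing recovery tests therefore demonstrates
that the statistical machinery recovers planted effects under the model's
own assumptions — not that those assumptions hold in any real
transcriptome.

## Numerical and degenerate-input choices

* Input annotation and site files are 1-based inclusive (GTF/DARNED
  convention); everything internal is 0-based half-open.
* Reading frame is recomputed from the CDS offset (`offset %% 3`), never
  trusted from GTF phase fields.
* Census de-duplication: a genomic position covered by several
  transcripts of one gene counts once per gene, coding if coding in any
  complete transcript; positions shared by overlapping genes count in
  each gene's census.
* Stop-codon edits (`*to*`, `*toW`) are classified and retained in
  counts; transitions absent from the 26-entry Laurent map are
  `"Unclassified"` and excluded from category-level summaries only.
* A zero adenine census, an empty codon pool, or an empty entropy set
  yield `NA`/fatal errors with explicit messages rather than silent
  zeros; duplicate catalog rows collapse with a warning count.
* Filtering removal reasons are assigned in a fixed order (tag, SNP,
  out-of-bounds, non-adenine), making the per-reason report
  deterministic and filtering idempotent.

## Problem sizes used by the tests

The test and acceptance suites run the generator at 40–80 genes with
120–200 coding events, `N_rand` between 500 and 10^4, 10 seeds for
enrichment recovery (one transition enriched 4-fold) and 20 seeds for
the conservation calibration (edited-column rate multiplier 1 must stay
non-significant; 0.3 must be detected). These sizes keep the full suite
in the minutes range while leaving the recovery margins wide; the same
code runs unchanged at publication scale (`N_rand = 10^6`, thousands of
events).

## Known limitations

* GTF ingestion targets the ensembl dialect (exon/CDS features with
  `gene_id`/`transcript_id` attributes); full GFF3, trans-splicing,
  selenocysteine recoding and fuzzy coordinates are out of scope.
* Only A-to-I (read A→G) editing under the standard genetic code is
  modelled.
* The conservation module consumes pre-computed alignments; it does not
  run an aligner, and entropy is unweighted by sequence redundancy
  within a family.
* Editing-level modelling (fraction of transcripts edited) and ADAR
  structural context are outside the model; conclusions about them
  cannot be drawn from this package's statistics.
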