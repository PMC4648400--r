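#' Demo pipeline configuration
#'
#' A self-contained configuration that simulates its own inputs (toy
#' genome, annotation, editing catalog with a 10-fold noncoding:coding
#' rate ratio, SNP/decoy lists, homolog families) and runs every stage at
#' sizes that complete in seconds.
#'
#' @param seed integer seed driving both the simulation and the null
#'   model.
#' @param ... overrides for the `simulate` block (passed to
#'   [sim_config()]).
#' @return a configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, ...) {
  sim <- utils::modifyList(
    list(seed = seed, n_genes = 40L, n_coding_events = 120L,
         noncoding_coding_ratio = 10), list(...))
  list(simulate = sim, n_rand = 5000L, seed = seed,
       exclude_tags = "cancer", min_family_members = 3L)
}

# region of a retained site under the census rule: coding if inside the
# CDS of any complete transcript, noncoding if exonic otherwise
.site_regions <- function(sites, txset) {
  vapply(seq_len(nrow(sites)), function(i) {
    hits <- map_site_to_transcripts(sites[i, , drop = FALSE], txset)
    if (nrow(hits) == 0L) return("outside")
    complete <- vapply(hits$transcript_id, function(tid)
      isTRUE(txset$transcripts[[tid]]$complete), logical(1))
    if (any(hits$region == "CDS" & complete)) "coding" else "noncoding"
  }, character(1))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the editing-recoding analysis pipeline
#'
#' Orchestrates the full analysis: catalog filtering, site-to-transcript
#' mapping and recoding classification, the unique-CDS selection rule,
#' the coding/noncoding frequency comparison, the codon-resampling null
#' model with per-transition ER and Fisher/BH tests, the conservation
#' comparison of edited vs editable residues, the codon-usage direction
#' analysis of synonymous events, and the within-dataset synonymous vs
#' nonsynonymous ER comparison. All reports are written as TSV files plus
#' a YAML manifest of input checksums and parameters; given an identical
#' configuration and seed the outputs are byte-identical across runs.
#'
#' @param config a configuration list (see [demo_config()]) or path to a
#'   YAML file with the same structure: either a `simulate` block
#'   ([sim_config()] arguments) or an `inputs` block with paths `genome`,
#'   `annotation`, `sites`, optional `snps`, `families_dir`,
#'   `family_mapping`; plus `n_rand`, `seed`, `exclude_tags`,
#'   `min_family_members`.
#' @param out_dir output directory for reports (created if missing).
#' @return object of class `editing_analysis`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_rand = 10000L, seed = 1L, exclude_tags = "cancer",
                   min_family_members = 3L)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- config$inputs
  truth <- NULL
  if (!is.null(config$simulate)) {
    message("stage simulate: generating reference and catalogs")
    sim <- do.call(sim_config, config$simulate)
    ref <- generate_reference(sim, file.path(out_dir, "inputs"))
    cat_out <- generate_editing_sites(sim, ref)
    fam_out <- generate_families(sim, ref, truth = cat_out$truth)
    truth <- cat_out$truth
    inputs <- list(genome = ref$genome_path,
                   annotation = ref$annotation_path,
                   sites = cat_out$sites_path, snps = cat_out$snp_path,
                   families_dir = fam_out$family_dir,
                   family_mapping = fam_out$mapping_path)
    txset <- ref$txset
  } else {
    if (is.null(inputs)) stop("config needs either 'simulate' or 'inputs'")
    message("stage annotation: reading transcript models")
    txset <- read_annotation(inputs$annotation, inputs$genome)
  }

  message("stage filter: reading and filtering the site catalog")
  sites <- read_sites(inputs$sites)
  snps <- if (!is.null(inputs$snps)) read_snps(inputs$snps) else NULL
  filt <- filter_sites(sites, snps, txset$genome,
                       exclude_tags = config$exclude_tags)
  message("  sites in: ", filt$report[["input"]],
          ", retained: ", filt$report[["retained"]])

  message("stage map: classifying recoding events")
  events_all <- map_and_classify(filt$retained, txset)
  cds_set <- merge_identical_cds(txset)
  sel <- select_unambiguous_events(events_all, cds_set)
  message("  CDS events kept (unique CDS): ", nrow(sel$kept),
          ", excluded: ", nrow(sel$excluded))

  message("stage census: coding/noncoding frequency comparison")
  census <- count_transcribed_adenines(txset)
  regions <- .site_regions(filt$retained, txset)
  region <- region_editing_test(sum(regions == "coding"),
                                sum(regions == "noncoding"), census)

  message("stage null: codon-resampling null model (N_rand = ",
          config$n_rand, ")")
  kept <- sel$kept
  if (nrow(kept) == 0L) stop("stage null: no events survive selection")
  kept$protein_id <- cds_set$representative[kept$cds_group]
  pool <- build_codon_pool(cds_set$cds_sequences[sort(unique(kept$cds_group))])
  null <- run_null_model(pool, n_events = nrow(kept),
                         N_rand = config$n_rand,
                         seed = .stage_seed(config$seed, 4L))
  tt <- transition_tests(kept$transition, null)

  message("stage conserve: edited vs editable residue entropy")
  cons <- NULL
  cons_tab <- NULL
  if (!is.null(inputs$families_dir) && !is.null(inputs$family_mapping)) {
    mapping <- utils::read.table(inputs$family_mapping, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
    fam_files <- list.files(inputs$families_dir, pattern = "\\.fa$",
                            full.names = TRUE)
    alignments <- lapply(fam_files, function(f)
      read_family_alignment(f, sub("\\.fa$", "", basename(f))))
    names(alignments) <- vapply(alignments, `[[`, character(1), "family_id")
    nonsyn <- kept[!kept$synonymous & kept$aa_from != "*", , drop = FALSE]
    prot_len <- vapply(nonsyn$cds_group, function(g)
      nchar(cds_set$cds_sequences[g]) %/% 3L - 1L, integer(1))
    edited_pos <- data.frame(protein_id = nonsyn$protein_id,
                             residue_pos = nonsyn$cds_offset %/% 3L + 1L,
                             stringsAsFactors = FALSE)
    edited_pos <- edited_pos[edited_pos$residue_pos <= prot_len, , drop = FALSE]
    prots <- unique(kept$protein_id)
    editable_pos <- do.call(rbind, lapply(prots, function(p) {
      g <- cds_set$tx2group[[p]]
      data.frame(protein_id = p,
                 residue_pos = editable_residues(cds_set$cds_sequences[g]),
                 stringsAsFactors = FALSE)
    }))
    cons <- conservation_comparison(edited_pos, editable_pos, alignments,
                                    mapping,
                                    min_members = config$min_family_members)
    cons_tab <- rbind(
      data.frame(set = "edited", H = cons$edited_H),
      data.frame(set = "editable", H = cons$editable_H))
  }

  message("stage usage: codon-usage direction of synonymous events")
  usage <- build_usage_table(cds_set$cds_sequences[sort(unique(kept$cds_group))])
  directions <- direction_enrichment(kept, null, usage)

  message("stage compare: synonymous vs nonsynonymous ER")
  syn_er <- tt$ER[tt$category == "Synonymous"]
  nonsyn_er <- tt$ER[tt$category %in% nonsynonymous_categories()]
  comparison <- if (length(syn_er) && length(nonsyn_er)) {
    er_group_comparison(syn_er, nonsyn_er)
  } else list(W = NA_real_, p_value = NA_real_, n_a = length(syn_er),
              n_b = length(nonsyn_er))

  message("stage report: writing TSV reports")
  .write_tsv(data.frame(reason = names(filt$report),
                        count = unname(filt$report)),
             file.path(out_dir, "filter_report.tsv"))
  .write_tsv(local({ k <- kept; k$pos <- k$pos + 1L; k }),
             file.path(out_dir, "events.tsv"))
  .write_tsv(local({ e <- sel$excluded; e$pos <- e$pos + 1L; e }),
             file.path(out_dir, "excluded_events.tsv"))
  .write_tsv(data.frame(edited_coding = region$edited_coding,
                        coding_A = census$coding_A,
                        edited_noncoding = region$edited_noncoding,
                        noncoding_A = census$noncoding_A,
                        freq_coding = region$freq_coding,
                        freq_noncoding = region$freq_noncoding,
                        ratio = region$ratio, p_value = region$p_value),
             file.path(out_dir, "region_frequency.tsv"))
  .write_tsv(as.data.frame(tt), file.path(out_dir, "transition_table.tsv"))
  if (!is.null(cons_tab)) {
    .write_tsv(cons_tab, file.path(out_dir, "conservation.tsv"))
    .write_tsv(data.frame(W = cons$W, p_value = cons$p_value,
                          n_edited = cons$n_edited,
                          n_editable = cons$n_editable),
               file.path(out_dir, "conservation_test.tsv"))
  }
  .write_tsv(as.data.frame(usage), file.path(out_dir, "codon_usage.tsv"))
  .write_tsv(as.data.frame(directions),
             file.path(out_dir, "direction_enrichment.tsv"))
  .write_tsv(data.frame(comparison = "syn_vs_nonsyn_ER",
                        W = comparison$W, p_value = comparison$p_value,
                        n_syn = comparison$n_a, n_nonsyn = comparison$n_b),
             file.path(out_dir, "comparison.tsv"))
  manifest <- list(
    inputs = lapply(inputs, function(p)
      if (is.character(p) && file.exists(p) && !dir.exists(p))
        unname(tools::md5sum(p)) else NULL),
    parameters = list(n_rand = config$n_rand, seed = config$seed,
                      exclude_tags = config$exclude_tags,
                      min_family_members = config$min_family_members,
                      simulate = config$simulate),
    counts = list(sites_in = unname(filt$report[["input"]]),
                  sites_retained = unname(filt$report[["retained"]]),
                  events_kept = nrow(kept),
                  events_excluded = nrow(sel$excluded)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  structure(list(config = config, inputs = inputs, out_dir = out_dir,
                 filter_report = filt$report, events = kept,
                 excluded = sel$excluded, census = census, region = region,
                 pool = pool, null = null, transition_table = tt,
                 conservation = cons, usage = usage,
                 directions = directions, comparison = comparison,
                 truth = truth),
            class = "editing_analysis")
}

#' @export
print.editing_analysis <- function(x, ...) {
  cat("editing_analysis\n")
  cat("  sites: ", x$filter_report[["input"]], " in, ",
      x$filter_report[["retained"]], " retained\n", sep = "")
  cat("  events kept (unique CDS): ", nrow(x$events), " (",
      sum(x$events$synonymous), " synonymous / ",
      sum(!x$events$synonymous), " nonsynonymous)\n", sep = "")
  cat(sprintf("  region frequency: coding %.3g vs noncoding %.3g (p = %.3g)\n",
              x$region$freq_coding, x$region$freq_noncoding,
              x$region$p_value))
  sig <- x$transition_table$fdr_p < 0.05
  cat("  transitions: ", nrow(x$transition_table), " tested, ",
      sum(sig), " significant at BH 0.05\n", sep = "")
  if (!is.null(x$conservation)) {
    cat(sprintf("  conservation: W = %.0f, p = %.3g\n",
                x$conservation$W, x$conservation$p_value))
  }
  cat("  reports in ", x$out_dir, "\n", sep = "")
  invisible(x)
}

#' @method summary editing_analysis
#' @export
summary.editing_analysis <- function(object, ...) {
  print(object)
  cat("\n")
  summary(object$transition_table)
  invisible(object)
}
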