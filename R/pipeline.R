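# End-to-end orchestration: score -> infer -> quantify -> partition ->
# enrich, under one configuration, with a run manifest capturing the
# bookkeeping statistics of the run.

#' Run the full pipeline
#'
#' Executes every stage in order on in-memory inputs (or file paths):
#' mixture fitting and PSM filtering, peptide-to-protein mapping and
#' parsimony grouping, spectral-count quantitation, the all-or-nothing
#' partition with novelty screening, and (when annotation sets are given)
#' over-representation testing of the cancer-only set against the
#' universe of all proteins present in at least one arm.
#'
#' @param psms PSM data.frame or path to a PSM TSV.
#' @param db protein database data.frame or FASTA path.
#' @param samples sample sheet data.frame or TSV path.
#' @param config a [specuniq_config()].
#' @param kb a [knowledge_base()] (optional).
#' @param gmt annotation sets from [read_gmt()] or a GMT path (optional;
#'   enrichment is skipped with a warning when absent).
#' @param normalization passed to [normalize_counts()]; the default
#'   `"none"` reflects a design with equal nominal depth per sample.
#' @param gate_method passed to [significance_gate()].
#' @param out_dir when given, result tables and the manifest JSON are
#'   written under it.
#' @return list of class `specuniq_run` with elements `mixture`,
#'   `peptides`, `groups`, `matrices`, `quant`, `partition`, `enrichment`,
#'   `network`, `psm_q` (named per-target-PSM q-values), `manifest`.
#' @export
run_pipeline <- function(psms, db, samples, config = specuniq_config(),
                         kb = knowledge_base(), gmt = NULL,
                         normalization = "none",
                         gate_method = "two_way_anova",
                         out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  digests <- character(0)
  if (is.character(psms)) {
    digests["psms"] <- unname(tools::md5sum(psms))
    psms <- read_psm_table(psms, decoy_prefix = config$decoy_prefix)
  }
  if (is.character(db)) {
    digests["db"] <- unname(tools::md5sum(db))
    db <- read_fasta_db(db, decoy_prefix = config$decoy_prefix)
  }
  if (is.character(samples)) {
    digests["samples"] <- unname(tools::md5sum(samples))
    samples <- read_sample_sheet(samples)
  }
  if (is.character(gmt)) {
    digests["gmt"] <- unname(tools::md5sum(gmt))
    gmt <- read_gmt(gmt)
  }
  timings <- c(load = proc.time()[["elapsed"]] - t0)

  # 1. scoring
  t0 <- proc.time()[["elapsed"]]
  mixture <- NULL
  if (anyNA(psms$posterior)) {
    mixture <- fit_score_mixture(psms$score, psms$is_decoy)
  }
  peptides <- filter_and_rollup(psms, mixture, config)
  q_all <- qvalues_from_decoys(psms$score, psms$is_decoy,
                               decoy_ratio = config$decoy_ratio)
  psm_q <- stats::setNames(q_all[!psms$is_decoy],
                           psms$spectrum_id[!psms$is_decoy])
  timings["score"] <- proc.time()[["elapsed"]] - t0

  # 2. inference
  t0 <- proc.time()[["elapsed"]]
  pepmap <- map_peptides(unique(peptides$peptide_seq), db)
  groups <- parsimony_groups(pepmap, peptides, db, config)
  mats <- accepted_matrix(groups, samples)
  timings["infer"] <- proc.time()[["elapsed"]] - t0

  # 3. quantitation
  t0 <- proc.time()[["elapsed"]]
  quant <- quantify(mats$counts, samples, config,
                    normalization = normalization,
                    gate_method = gate_method)
  timings["quantify"] <- proc.time()[["elapsed"]] - t0

  # 4. partition + novelty
  t0 <- proc.time()[["elapsed"]]
  partition <- partition_proteins(mats, samples, kb, config)
  timings["partition"] <- proc.time()[["elapsed"]] - t0

  # 5. enrichment
  t0 <- proc.time()[["elapsed"]]
  enrichment <- NULL; network <- NULL
  universe <- c(partition$atrophic_only, partition$cancer_only,
                partition$common)
  if (!is.null(gmt)) {
    enrichment <- hypergeom_enrich(partition$cancer_only, gmt, universe)
    novel <- names(partition$category_of)[
      partition$category_of %in% c("novel_with_literature",
                                   "novel_no_literature")]
    network <- network_table(partition$subtype_of[novel], gmt)
  } else {
    warning("no annotation sets supplied: enrichment skipped")
  }
  timings["enrich"] <- proc.time()[["elapsed"]] - t0

  n_present <- length(universe)
  bookkeeping_ok <- length(partition$atrophic_only) +
    length(partition$cancer_only) + length(partition$common) == n_present &&
    length(partition$category_of) == length(partition$cancer_only)
  if (!bookkeeping_ok) stop("partition bookkeeping identity violated")

  manifest <- list(
    config = unclass(config),
    input_digests = as.list(digests),
    timings = as.list(round(timings, 3)),
    counts = list(
      n_psms = nrow(psms),
      n_peptides = length(unique(peptides$peptide_seq)),
      n_protein_groups = length(unique(groups$group_id)),
      n_present_any_arm = n_present,
      n_atrophic_only = length(partition$atrophic_only),
      n_cancer_only = length(partition$cancer_only),
      n_common = length(partition$common),
      n_duplicates_removed = nrow(partition$duplicates_removed),
      n_upregulated = sum(quant$upregulated, na.rm = TRUE),
      n_infinite_fold = sum(quant$infinite_fold, na.rm = TRUE),
      n_novel = sum(partition$category_of %in%
                      c("novel_with_literature", "novel_no_literature")),
      n_novel_with_literature = sum(partition$category_of ==
                                      "novel_with_literature"),
      enrichment_skipped = is.null(enrichment)),
    bookkeeping_ok = bookkeeping_ok)

  run <- structure(list(mixture = mixture, peptides = peptides,
                        groups = groups, matrices = mats, quant = quant,
                        partition = partition, enrichment = enrichment,
                        network = network, psm_q = psm_q,
                        manifest = manifest),
                   class = "specuniq_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.specuniq_run <- function(x, ...) {
  cn <- x$manifest$counts
  cat("specuniq pipeline run\n")
  cat(sprintf("  %d PSMs -> %d accepted peptides -> %d protein groups\n",
              cn$n_psms, cn$n_peptides, cn$n_protein_groups))
  cat(sprintf("  partition: %d atrophic-only + %d common + %d cancer-only = %d present\n",
              cn$n_atrophic_only, cn$n_common, cn$n_cancer_only,
              cn$n_present_any_arm))
  cat(sprintf("  %d up-regulated (finite fold), %d infinite-fold, %d novel candidates\n",
              cn$n_upregulated, cn$n_infinite_fold, cn$n_novel))
  invisible(x)
}

#' Write run outputs
#'
#' Writes `peptides.tsv`, `groups.tsv`, `quant.tsv`, `partition.tsv`,
#' `enrichment.tsv`, `network.tsv` (when computed) and `manifest.json`.
#'
#' @param run a `specuniq_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(run$peptides, file.path(dir, "peptides.tsv"))
  write_tsv(run$groups, file.path(dir, "groups.tsv"))
  write_tsv(run$quant, file.path(dir, "quant.tsv"))
  part <- run$partition
  set_of <- c(stats::setNames(rep("atrophic_only",
                                  length(part$atrophic_only)),
                              part$atrophic_only),
              stats::setNames(rep("cancer_only", length(part$cancer_only)),
                              part$cancer_only),
              stats::setNames(rep("common", length(part$common)),
                              part$common))
  ptab <- data.frame(
    symbol = names(set_of), set = unname(set_of),
    subtype = unname(part$subtype_of[names(set_of)]),
    category = unname(part$category_of[names(set_of)]),
    stringsAsFactors = FALSE)
  q <- run$quant
  ptab$fold_change <- q$fold_change[match(ptab$symbol, q$gene_symbol)]
  ptab$upregulated <- q$upregulated[match(ptab$symbol, q$gene_symbol)]
  write_tsv(ptab, file.path(dir, "partition.tsv"))
  if (!is.null(run$enrichment)) {
    write_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(run$network)) {
    write_tsv(run$network, file.path(dir, "network.tsv"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
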