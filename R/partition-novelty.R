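# The "all or nothing" analysis: presence calls per arm, the three-way
# Venn partition (control-only / cancer-only / common), gene-level
# deduplication of the cancer-only list, attribution of cancer-associated
# proteins to histological subtypes, and knowledge-list screening that
# nominates novel candidates.

#' Presence call for one group
#'
#' A protein is present in a group when it is accepted in at least
#' `config$presence_min_samples` samples of that group.
#'
#' @param accepted logical acceptance matrix (proteins x samples).
#' @param samples sample sheet.
#' @param group `"atrophic"` or `"cancer"`.
#' @param config a [specuniq_config()].
#' @return named logical vector over proteins.
#' @export
presence_call <- function(accepted, samples, group,
                          config = specuniq_config()) {
  if (!group %in% c("atrophic", "cancer")) stop("unknown group: ", group)
  cols <- samples$sample_id[samples$group == group]
  rowSums(accepted[, cols, drop = FALSE]) >= config$presence_min_samples
}

#' Three-way presence/absence partition
#'
#' Classifies each protein as atrophic-only, cancer-only or common from
#' its two presence calls; proteins absent from both arms are dropped.
#'
#' @param present_atrophic,present_cancer logical vectors named by row
#'   (accession or symbol), aligned.
#' @param symbols gene symbols aligned with the calls (defaults to names).
#' @return list of class `venn_partition` with character-vector elements
#'   `atrophic_only`, `cancer_only`, `common` (of the row keys), plus
#'   `symbols` carrying the key -> symbol map.
#' @export
venn_partition <- function(present_atrophic, present_cancer,
                           symbols = names(present_atrophic)) {
  stopifnot(length(present_atrophic) == length(present_cancer))
  keys <- names(present_atrophic)
  if (is.null(keys)) keys <- symbols
  a <- present_atrophic; c_ <- present_cancer
  structure(list(
    atrophic_only = keys[a & !c_],
    cancer_only = keys[!a & c_],
    common = keys[a & c_],
    symbols = stats::setNames(symbols, keys)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("All-or-nothing partition\n")
  cat(sprintf("  atrophic-only: %d\n  cancer-only:   %d\n  common:        %d\n",
              length(x$atrophic_only), length(x$cancer_only),
              length(x$common)))
  invisible(x)
}

#' Deduplicate a protein list at the gene level
#'
#' Multiple accessions can map to one gene symbol; one entry is kept per
#' symbol (the one with the most total spectra; ties broken by
#' lexicographic accession) and the dropped accessions are logged.
#'
#' @param accessions character vector of accessions (or group keys).
#' @param symbols gene symbols aligned with `accessions`.
#' @param total_spectra numeric total spectral counts aligned.
#' @return list with `kept` (accessions), `symbols` (their symbols) and
#'   `dropped` (data.frame of symbol, accession logged per removal).
#' @export
deduplicate_genes <- function(accessions, symbols, total_spectra) {
  ord <- order(symbols, -total_spectra, accessions)
  first <- !duplicated(symbols[ord])
  kept <- accessions[ord][first]
  dropped <- data.frame(symbol = symbols[ord][!first],
                        accession = accessions[ord][!first],
                        stringsAsFactors = FALSE)
  list(kept = kept, symbols = symbols[ord][first], dropped = dropped)
}

#' Subtype attribution within the cancer arm
#'
#' Attributes each cancer-associated protein to the endometrioid (type 1)
#' or serous (type 2) subtype, or both, from per-sample acceptance in the
#' cancer samples: `type1_only` when present (at least
#' `config$presence_min_samples` samples) in type 1 and not in type 2,
#' `type2_only` symmetrically, `both` otherwise.
#'
#' @param accepted logical acceptance matrix.
#' @param samples sample sheet.
#' @param keys rows to attribute (default all rows of `accepted`).
#' @param config a [specuniq_config()].
#' @return named character vector: `type1_only` / `type2_only` / `both`.
#' @export
subtype_attribution <- function(accepted, samples,
                                keys = rownames(accepted),
                                config = specuniq_config()) {
  t1 <- samples$sample_id[samples$subtype == "type1"]
  t2 <- samples$sample_id[samples$subtype == "type2"]
  m <- config$presence_min_samples
  in1 <- rowSums(accepted[keys, t1, drop = FALSE]) >= m
  in2 <- rowSums(accepted[keys, t2, drop = FALSE]) >= m
  stats::setNames(ifelse(in1 & !in2, "type1_only",
                         ifelse(in2 & !in1, "type2_only", "both")), keys)
}

#' Categorize cancer-only proteins against knowledge lists
#'
#' Sequential elimination mirroring the discovery workflow: a symbol
#' already reported in endometrial cancer is `known_ec`; otherwise one
#' reported in another cancer is `known_other_cancer`; otherwise one with
#' any supporting literature is `novel_with_literature`; the remainder are
#' `novel_no_literature`. The categories partition the input exactly.
#'
#' @param symbols character vector of cancer-only gene symbols.
#' @param kb a [knowledge_base()].
#' @return named character vector of categories.
#' @export
categorize_novelty <- function(symbols, kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  s <- toupper(symbols)
  stats::setNames(
    ifelse(s %in% kb$known_ec, "known_ec",
           ifelse(s %in% kb$known_other_cancer, "known_other_cancer",
                  ifelse(s %in% kb$has_literature, "novel_with_literature",
                         "novel_no_literature"))),
    symbols)
}

#' Full presence/absence partition with novelty screening
#'
#' Chains [presence_call()], [venn_partition()], [deduplicate_genes()],
#' [subtype_attribution()] and [categorize_novelty()] over an acceptance
#' matrix.
#'
#' @param mats output of [accepted_matrix()].
#' @param samples sample sheet.
#' @param kb a [knowledge_base()] (optional; empty by default).
#' @param config a [specuniq_config()].
#' @return list of class `partition_result`: the `venn_partition` (on
#'   deduplicated gene symbols), `duplicates_removed`, `subtype_of` (for
#'   cancer-associated symbols), `category_of` (for cancer-only symbols).
#' @export
partition_proteins <- function(mats, samples, kb = knowledge_base(),
                               config = specuniq_config()) {
  acc <- mats$accepted
  rownames(acc) <- make.unique(rownames(mats$accepted), sep = "\r")
  symbols <- mats$meta$gene_symbol
  total_spectra <- rowSums(mats$counts)

  pa <- presence_call(acc, samples, "atrophic", config)
  pc <- presence_call(acc, samples, "cancer", config)

  # deduplicate at the gene level before partitioning so each symbol is
  # represented by its best-supported accession
  dd <- deduplicate_genes(rownames(acc), symbols, total_spectra)
  keep <- rownames(acc) %in% dd$kept
  sym_of <- stats::setNames(symbols, rownames(acc))

  part <- venn_partition(pa[keep], pc[keep], symbols = sym_of[keep])
  to_sym <- function(k) unname(sort(sym_of[k]))
  sets <- list(atrophic_only = to_sym(part$atrophic_only),
               cancer_only = to_sym(part$cancer_only),
               common = to_sym(part$common))

  cancer_assoc <- c(part$cancer_only, part$common)
  subtype_of <- subtype_attribution(acc, samples, keys = cancer_assoc,
                                    config = config)
  names(subtype_of) <- unname(sym_of[cancer_assoc])
  category_of <- categorize_novelty(sets$cancer_only, kb)

  structure(list(atrophic_only = sets$atrophic_only,
                 cancer_only = sets$cancer_only,
                 common = sets$common,
                 duplicates_removed = dd$dropped,
                 subtype_of = subtype_of,
                 category_of = category_of),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  total <- length(x$atrophic_only) + length(x$cancer_only) +
    length(x$common)
  cat("Presence/absence partition (", total, " proteins present in >=1 arm)\n",
      sep = "")
  cat(sprintf("  atrophic-only %d | common %d | cancer-only %d (%d duplicates removed)\n",
              length(x$atrophic_only), length(x$common),
              length(x$cancer_only), nrow(x$duplicates_removed)))
  if (length(x$category_of)) {
    tab <- table(factor(x$category_of,
                        levels = c("known_ec", "known_other_cancer",
                                   "novel_with_literature",
                                   "novel_no_literature")))
    cat("  cancer-only categories: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
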