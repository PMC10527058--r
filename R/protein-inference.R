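# Parsimony protein inference. Accepted peptides are mapped to every
# target protein containing them (I/L indistinguishable by mass), proteins
# with identical evidence are merged, subsumed proteins removed, remaining
# shared peptides resolved by greedy minimal set cover, and groups linked
# into clusters by shared-peptide connectivity.

il_canon <- function(x) gsub("L", "I", x, fixed = TRUE)

#' Map peptides to database proteins
#'
#' A peptide maps to every target protein whose sequence contains it as an
#' exact substring, treating isoleucine and leucine as equivalent (they are
#' isobaric and indistinguishable by MS/MS). Peptides matching only decoy
#' entries are discarded; peptides matching nothing are returned as
#' orphans.
#'
#' @param peptides character vector of distinct peptide sequences.
#' @param db protein database data.frame from [read_fasta_db()].
#' @return list with `pep2prot` (named list: peptide -> accessions),
#'   `prot2pep` (accession -> peptides) and `orphans` (unmatched peptides).
#' @export
map_peptides <- function(peptides, db) {
  if (!nrow(db)) stop("empty protein database")
  peptides <- unique(peptides)
  targets <- db[!db$is_decoy, , drop = FALSE]
  seqs <- il_canon(targets$sequence)
  pep_canon <- il_canon(peptides)
  hits <- lapply(pep_canon, function(p) {
    targets$accession[grepl(p, seqs, fixed = TRUE)]
  })
  names(hits) <- peptides
  orphans <- peptides[lengths(hits) == 0L]
  pep2prot <- hits[lengths(hits) > 0L]
  prot2pep <- split(
    rep(names(pep2prot), lengths(pep2prot)),
    unlist(pep2prot, use.names = FALSE)
  )
  list(pep2prot = pep2prot, prot2pep = lapply(prot2pep, unique),
       orphans = orphans)
}

#' Protein probability from peptide posteriors
#'
#' Noisy-OR over the distinct peptides of a protein: the protein is present
#' unless every supporting peptide identification is wrong, so
#' `P = 1 - prod(1 - p_i)` with `p_i` the best posterior of each distinct
#' peptide. An empty peptide list gives probability 0.
#'
#' @param peptide_posteriors numeric vector of per-peptide best posteriors.
#' @return probability in \[0, 1\].
#' @export
#' @examples
#' protein_probability(c(0.95, 0.95))  # 0.9975
protein_probability <- function(peptide_posteriors) {
  if (!length(peptide_posteriors)) return(0)
  1 - prod(1 - peptide_posteriors)
}

# deterministic tie-break for greedy cover and dedup: more distinct
# peptides, then more total spectra, then lexicographically first accession
pick_best <- function(acc, n_pep, n_spec) {
  ord <- order(-n_pep, -n_spec, acc)
  acc[ord[1]]
}

#' Parsimony protein grouping
#'
#' Resolves shared peptide evidence into protein groups:
#' \enumerate{
#'   \item proteins with identical accepted-peptide sets are merged as
#'     indistinguishable;
#'   \item proteins whose peptide set is a strict subset of another's are
#'     removed (subsumed);
#'   \item remaining shared peptides are assigned to a single protein each
#'     by greedy minimal set cover (ties: more distinct peptides, more
#'     total spectra, lexicographic accession);
#'   \item clusters are the connected components of the protein-peptide
#'     sharing graph;
#'   \item per sample, a group is accepted when its protein probability
#'     reaches `config$protein_prob_min` and it has at least
#'     `config$min_peptides` distinct peptides in that sample.
#' }
#' Every spectral count is credited to exactly one group.
#'
#' @param pepmap output of [map_peptides()].
#' @param peptides peptide table from [filter_and_rollup()].
#' @param db protein database data.frame (for gene symbols).
#' @param config a [specuniq_config()].
#' @return data.frame of class `protein_groups`: one row per (group,
#'   sample) with `group_id`, `representative`, `members`, `gene_symbol`,
#'   `cluster_id`, `sample_id`, `n_peptides`, `spectral_count`,
#'   `protein_prob`, `accepted`.
#' @export
parsimony_groups <- function(pepmap, peptides, db,
                             config = specuniq_config()) {
  prot2pep <- pepmap$prot2pep
  pep2prot <- pepmap$pep2prot
  if (!length(prot2pep)) {
    return(empty_groups())
  }
  pep_spectra <- tapply(peptides$spectral_count, peptides$peptide_seq, sum)

  # (1) merge indistinguishable proteins
  sig <- vapply(prot2pep, function(p) paste(sort(p), collapse = "\r"),
                character(1))
  members_of <- split(names(prot2pep), sig)
  reps <- vapply(members_of, function(acc) {
    np <- length(prot2pep[[acc[1]]])
    ns <- sum(pep_spectra[prot2pep[[acc[1]]]], na.rm = TRUE)
    pick_best(acc, rep(np, length(acc)), rep(ns, length(acc)))
  }, character(1))
  group_pep <- lapply(members_of, function(acc) prot2pep[[acc[1]]])
  names(group_pep) <- reps
  names(members_of) <- reps

  # (2) remove subsumed groups (peptide set strictly inside another's)
  keep <- rep(TRUE, length(group_pep))
  nset <- lengths(group_pep)
  ord <- order(-nset)
  for (i in seq_along(ord)) {
    gi <- ord[i]
    if (!keep[gi]) next
    for (j in seq_along(ord)) {
      gj <- ord[j]
      if (gi == gj || !keep[gj]) next
      if (nset[gj] < nset[gi] &&
          all(group_pep[[gj]] %in% group_pep[[gi]])) {
        keep[gj] <- FALSE
      }
    }
  }
  group_pep <- group_pep[keep]
  members_of <- members_of[keep]

  # (3) greedy minimal set cover over the remaining groups
  uncovered <- unique(unlist(group_pep, use.names = FALSE))
  tot_spec <- vapply(group_pep, function(p)
    sum(pep_spectra[p], na.rm = TRUE), numeric(1))
  assigned <- list()           # representative -> peptides credited to it
  remaining <- group_pep
  while (length(uncovered)) {
    gain <- vapply(remaining, function(p) sum(p %in% uncovered), integer(1))
    cand <- names(remaining)[gain == max(gain)]
    best <- pick_best(cand, lengths(group_pep[cand]), tot_spec[cand])
    newly <- intersect(group_pep[[best]], uncovered)
    assigned[[best]] <- newly
    uncovered <- setdiff(uncovered, newly)
    remaining <- remaining[names(remaining) != best]
    if (!length(remaining) && length(uncovered)) {
      stop("internal error: peptides left uncovered")  # cannot happen
    }
  }

  # (4) clusters: connected components of peptide sharing among cover groups
  cover <- names(assigned)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(cover)
  if (length(cover) > 1L) {
    # connect cover groups whose members share a peptide in the original map
    share <- lapply(pep2prot, function(acc) {
      hit <- cover[vapply(members_of[cover], function(m) any(m %in% acc),
                          logical(1))]
      if (length(hit) > 1L) t(utils::combn(sort(hit), 2L)) else NULL
    })
    pairs <- do.call(rbind, share)
    if (!is.null(pairs) && nrow(pairs)) {
      g <- igraph::add_edges(g, t(pairs))
    }
  }
  comp <- igraph::components(g)$membership
  cluster_id <- paste0("C", comp[cover])

  # (5) per-sample evidence and acceptance
  acc2sym <- stats::setNames(db$gene_symbol, db$accession)
  samples <- sort(unique(peptides$sample_id))
  pep_by_sample <- split(peptides, peptides$sample_id)
  rows <- vector("list", length(cover) * length(samples))
  k <- 0L
  for (gi in seq_along(cover)) {
    rep_acc <- cover[gi]
    peps <- assigned[[rep_acc]]
    for (s in samples) {
      tab <- pep_by_sample[[s]]
      tab <- tab[tab$peptide_seq %in% peps, , drop = FALSE]
      prob <- protein_probability(tab$best_posterior)
      k <- k + 1L
      rows[[k]] <- data.frame(
        group_id = paste0("G", gi),
        representative = rep_acc,
        members = paste(sort(members_of[[rep_acc]]), collapse = ";"),
        gene_symbol = unname(acc2sym[rep_acc]),
        cluster_id = cluster_id[gi],
        sample_id = s,
        n_peptides = nrow(tab),
        spectral_count = sum(tab$spectral_count),
        protein_prob = prob,
        accepted = prob >= config$protein_prob_min &&
          nrow(tab) >= config$min_peptides,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("protein_groups", class(out))
  out
}

empty_groups <- function() {
  out <- data.frame(group_id = character(), representative = character(),
                    members = character(), gene_symbol = character(),
                    cluster_id = character(), sample_id = character(),
                    n_peptides = integer(), spectral_count = integer(),
                    protein_prob = numeric(), accepted = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_groups", class(out))
  out
}

#' Acceptance and count matrices
#'
#' Pivots per-(group, sample) evidence into matrices keyed by gene symbol:
#' a logical acceptance matrix and an integer spectral-count matrix with
#' one column per sample.
#'
#' @param groups output of [parsimony_groups()].
#' @param samples sample sheet data.frame (defines column order).
#' @return list with `accepted` (logical matrix), `counts` (numeric
#'   matrix), both with gene-symbol rownames, and `meta` (one row per
#'   group: group_id, representative, gene_symbol, cluster_id).
#' @export
accepted_matrix <- function(groups, samples) {
  sample_ids <- samples$sample_id
  ids <- unique(groups$group_id)
  meta <- unique(groups[, c("group_id", "representative", "gene_symbol",
                            "cluster_id", "members")])
  acc <- matrix(FALSE, nrow = length(ids), ncol = length(sample_ids),
                dimnames = list(meta$gene_symbol[match(ids, meta$group_id)],
                                sample_ids))
  cnt <- matrix(0, nrow = length(ids), ncol = length(sample_ids),
                dimnames = dimnames(acc))
  if (nrow(groups)) {
    i <- match(groups$group_id, ids)
    j <- match(groups$sample_id, sample_ids)
    ok <- !is.na(j)
    acc[cbind(i[ok], j[ok])] <- groups$accepted[ok]
    cnt[cbind(i[ok], j[ok])] <- groups$spectral_count[ok]
  }
  list(accepted = acc, counts = cnt, meta = meta)
}
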