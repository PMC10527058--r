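# Annotation-set over-representation: the standard one-sided
# hypergeometric test of a query gene set against GMT annotation terms
# with Benjamini-Hochberg adjustment, plus the network membership report
# with subtype marks.

#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the query set contains more
#' term members than expected under random draws from the universe:
#' one-sided p = P(X >= k) for X hypergeometric with K term members in a
#' universe of N, drawing n = |query|. Query symbols outside the universe
#' are trimmed with a warning.
#'
#' @param query character vector of gene symbols.
#' @param sets list of annotation sets from [read_gmt()].
#' @param universe character vector of background gene symbols.
#' @return data.frame sorted by p-value with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(toupper(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query symbol(s) outside the universe trimmed")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(sets, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$term_id), ]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up control of the false discovery rate:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, order-preserving.
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Network membership report with subtype marks
#'
#' For each annotation term, lists the query proteins belonging to it with
#' their subtype mark (1 = type 1 only, 2 = type 2 only, B = both);
#' proteins in no term are gathered under an `unmapped` row.
#'
#' @param subtype_of named character vector
#'   (`type1_only`/`type2_only`/`both`) over the proteins to report.
#' @param sets annotation sets from [read_gmt()].
#' @return data.frame with `term_id`, `term_name`, `proteins` (rendered
#'   `"SYM ^mark"` entries joined by `"; "`) and `n_proteins`.
#' @export
network_table <- function(subtype_of, sets) {
  mark <- c(type1_only = "1", type2_only = "2", both = "B")
  syms <- toupper(names(subtype_of))
  render <- function(members) {
    hit <- sort(syms[syms %in% members])
    paste(sprintf("%s ^%s", hit, mark[subtype_of[match(hit, syms)]]),
          collapse = "; ")
  }
  rows <- lapply(sets, function(s) {
    hit <- intersect(syms, s$members)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               proteins = render(s$members), n_proteins = length(hit),
               stringsAsFactors = FALSE)
  })
  mapped <- unique(unlist(lapply(sets, `[[`, "members")))
  un <- syms[!syms %in% mapped]
  rows <- c(rows, list(data.frame(
    term_id = "unmapped", term_name = "not in any annotation term",
    proteins = render(un), n_proteins = length(un),
    stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
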