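# Readers and writers for the pipeline's external formats: flat TSV PSM
# tables, FASTA protein databases, GMT annotation sets, plain-text gene
# lists and the sample sheet. No science lives here.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

psm_required_cols <- c("sample_id", "spectrum_id", "peptide_seq", "charge",
                       "score", "is_decoy", "mass_error_ppm")

#' Read a PSM table
#'
#' Reads a tab-delimited table of peptide-spectrum matches. Required columns
#' (any order): `sample_id`, `spectrum_id`, `peptide_seq`, `charge`,
#' `score`, `is_decoy`, `mass_error_ppm`; an optional `posterior` column
#' carries precomputed posterior probabilities in \[0, 1\]. The decoy flag
#' may be given as a logical/0-1 column, or, if `is_decoy` is absent but a
#' `protein` column is present, it is derived from the accession prefix.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param decoy_prefix accession prefix identifying decoys when the flag is
#'   derived from a `protein` column.
#' @return A data.frame with one row per PSM and the columns above
#'   (`posterior` is `NA` when not supplied).
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"is_decoy" %in% names(df) && "protein" %in% names(df)) {
    df$is_decoy <- startsWith(df$protein, decoy_prefix)
  }
  missing <- setdiff(psm_required_cols, names(df))
  if (length(missing)) {
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"posterior" %in% names(df)) df$posterior <- NA_real_
  if (nrow(df) == 0L) {
    return(df[, c(psm_required_cols, "posterior")])
  }

  score_num <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score_num) & !is.na(df$score))
  if (length(bad)) {
    stop(sprintf("non-numeric score at line %d of %s", bad[1] + 1L, path))
  }
  df$score <- score_num
  df$charge <- as.integer(df$charge)
  df$mass_error_ppm <- as.numeric(df$mass_error_ppm)
  df$is_decoy <- as.logical(df$is_decoy)
  df$peptide_seq <- toupper(df$peptide_seq)
  df$posterior <- as.numeric(df$posterior)

  validate_psms(df)
  df[, c(psm_required_cols, "posterior",
         setdiff(names(df), c(psm_required_cols, "posterior")))]
}

validate_psms <- function(df) {
  if (any(!nzchar(df$peptide_seq))) stop("empty peptide sequence")
  letters_ok <- !grepl(sprintf("[^%s]", paste(AA20, collapse = "")),
                       df$peptide_seq)
  if (any(!letters_ok)) {
    stop("peptide sequence outside the 20-amino-acid alphabet: ",
         df$peptide_seq[!letters_ok][1])
  }
  if (any(!is.na(df$charge) & df$charge < 1L)) stop("charge must be >= 1")
  p <- df$posterior
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("posterior outside [0, 1]: ", p[!is.na(p) & (p < 0 | p > 1)][1])
  }
  invisible(df)
}

#' @rdname read_psm_table
#' @param psms a PSM data.frame as returned by `read_psm_table`.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA database
#'
#' Headers follow the dialect `accession|gene_symbol description`; when no
#' gene symbol can be parsed the symbol falls back to the accession. Decoy
#' entries are recognized by their accession prefix.
#'
#' @param path FASTA file.
#' @param decoy_prefix accession prefix marking decoy entries.
#' @param symbol_regex regex with one capture group extracting the gene
#'   symbol from the part of the header after the accession.
#' @return data.frame with columns `accession`, `gene_symbol`, `sequence`,
#'   `is_decoy`.
#' @export
read_fasta_db <- function(path, decoy_prefix = "DECOY_",
                          symbol_regex = "^\\|?([A-Za-z0-9_.-]+)") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("[| ].*$", "", headers)
  rest <- substring(headers, nchar(accession) + 1L)
  m <- regmatches(rest, regexec(symbol_regex, rest))
  gene_symbol <- vapply(m, function(g) if (length(g) >= 2) g[2] else "",
                        character(1))
  gene_symbol <- toupper(ifelse(nzchar(gene_symbol), gene_symbol, accession))
  sequence <- toupper(as.character(aa))
  if (anyDuplicated(accession)) {
    stop("duplicate accession in FASTA: ",
         accession[duplicated(accession)][1])
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for accession ", accession[!nzchar(sequence)][1])
  }
  data.frame(accession = accession, gene_symbol = gene_symbol,
             sequence = sequence,
             is_decoy = startsWith(accession, decoy_prefix),
             stringsAsFactors = FALSE)
}

#' @rdname read_fasta_db
#' @param db a protein database data.frame.
#' @export
write_fasta_db <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- paste0(db$accession, "|", db$gene_symbol)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene-set (GMT) and gene-list files
#'
#' GMT lines are `term_id TAB term_name TAB member1 TAB member2 ...`; gene
#' lists carry one symbol per line with `#` comments. Symbols are
#' upper-cased and deduplicated.
#'
#' @param path file path.
#' @return `read_gmt` returns a list of annotation sets, each a list with
#'   `term_id`, `term_name` and `members`; `read_gene_list` returns a
#'   character vector of unique symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields: ", ln)
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT term with no members: ", f[1])
    list(term_id = f[1], term_name = f[2], members = members)
  })
}

#' @rdname read_gmt
#' @param sets a list of annotation sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(toupper(lines))
}

#' @rdname read_gmt
#' @param symbols character vector of gene symbols.
#' @export
write_gene_list <- function(symbols, path) {
  writeLines(unique(toupper(symbols)), path)
  invisible(path)
}

#' Assemble a knowledge base from three gene lists
#'
#' The three lists drive novelty categorization of cancer-only proteins:
#' symbols already reported in endometrial cancer, symbols reported in
#' other cancers, and symbols with any supporting literature.
#'
#' @param known_ec,known_other_cancer,has_literature character vectors of
#'   gene symbols (or paths when `from_files = TRUE`).
#' @param from_files read the three arguments as gene-list files.
#' @return list of class `knowledge_base` with upper-cased, deduplicated
#'   symbol sets.
#' @export
knowledge_base <- function(known_ec = character(),
                           known_other_cancer = character(),
                           has_literature = character(),
                           from_files = FALSE) {
  if (from_files) {
    known_ec <- read_gene_list(known_ec)
    known_other_cancer <- read_gene_list(known_other_cancer)
    has_literature <- read_gene_list(has_literature)
  }
  structure(list(known_ec = unique(toupper(known_ec)),
                 known_other_cancer = unique(toupper(known_other_cancer)),
                 has_literature = unique(toupper(has_literature))),
            class = "knowledge_base")
}

#' Read a sample sheet
#'
#' Tab-delimited with columns `sample_id`, `group` (atrophic/cancer),
#' `subtype` (none/type1/type2), `age`, `bmi`. The subtype must be `none`
#' exactly for atrophic samples.
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "group", "subtype", "age", "bmi")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$group %in% c("atrophic", "cancer"))) {
    stop("group must be 'atrophic' or 'cancer'")
  }
  if (!all(df$subtype %in% c("none", "type1", "type2"))) {
    stop("subtype must be 'none', 'type1' or 'type2'")
  }
  bad <- (df$group == "atrophic") != (df$subtype == "none")
  if (any(bad)) {
    stop("subtype must be 'none' iff group is 'atrophic' (sample ",
         df$sample_id[bad][1], ")")
  }
  df$age <- as.numeric(df$age)
  df$bmi <- as.numeric(df$bmi)
  df[, need]
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a generic result table
#'
#' @param df data.frame.
#' @param path file path.
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
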