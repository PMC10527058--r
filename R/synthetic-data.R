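# Synthetic PSM generator with planted ground truth. Emulates the study
# design the pipeline was built for: 4 atrophic controls vs 4 cancers
# (2 endometrioid/type 1 + 2 serous/type 2), proteins planted in
# presence/abundance classes, Poisson spectral counts, tryptic-like
# peptides with designated shared-peptide paralog families, and a
# two-Gaussian correct/incorrect PSM score model with 1:1 decoys.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: the 4-vs-4 design with two
#' cancer subtypes, a planted proteome of 200 proteins split into
#' presence/abundance classes, an expected sequencing depth of 30 spectra
#' per present protein per sample, a planted fold change of 3 for the
#' common up-regulated class, correct scores ~ N(4, 1) vs incorrect
#' ~ N(0, 1), correct precursor mass errors ~ N(0, 3 ppm) vs incorrect
#' ~ Uniform(-20, 20 ppm), and incorrect PSMs (half decoy, half target,
#' the 1:1 target-decoy convention) at 30% of the correct PSM count.
#'
#' @param n_atrophic,n_type1,n_type2 samples per arm/subtype.
#' @param n_common_eq,n_common_up,n_cancer_only,n_atrophic_only,n_type1_only,n_type2_only
#'   planted protein class sizes.
#' @param n_paralog_families protein pairs sharing peptides (exercises
#'   parsimony).
#' @param true_fold planted cancer/control fold change of the common
#'   up-regulated class (> 1).
#' @param depth expected spectra per present protein per sample.
#' @param lambda_pep peptides per protein are `2 + Poisson(lambda_pep)`.
#' @param shared_peptide_rate fraction of a paralog pair's peptides that
#'   are shared.
#' @param mu_correct,sd_correct,mu_incorrect,sd_incorrect score model.
#' @param mass_sd_correct SD (ppm) of correct precursor mass errors.
#' @param mass_range_incorrect half-width (ppm) of the uniform incorrect
#'   mass-error distribution.
#' @param incorrect_psm_rate expected incorrect PSMs per correct PSM.
#' @param abundance_sdlog log-normal spread of per-protein abundance.
#' @param seed integer RNG seed; the whole bundle is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_atrophic = 4L, n_type1 = 2L, n_type2 = 2L,
                       n_common_eq = 60L, n_common_up = 40L,
                       n_cancer_only = 50L, n_atrophic_only = 30L,
                       n_type1_only = 10L, n_type2_only = 10L,
                       n_paralog_families = 5L,
                       true_fold = 3, depth = 30,
                       lambda_pep = 3, shared_peptide_rate = 0.05,
                       mu_correct = 4, sd_correct = 1,
                       mu_incorrect = 0, sd_incorrect = 1,
                       mass_sd_correct = 3, mass_range_incorrect = 20,
                       incorrect_psm_rate = 0.3,
                       abundance_sdlog = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  sizes <- unlist(cfg[c("n_common_eq", "n_common_up", "n_cancer_only",
                        "n_atrophic_only", "n_type1_only", "n_type2_only")])
  if (any(sizes < 0)) stop("class sizes must be >= 0")
  if (sum(sizes) == 0) stop("at least one protein class must be non-empty")
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$true_fold <= 1) stop("true_fold must be > 1")
  structure(cfg, class = "sim_config")
}

sim_classes <- c("common_eq", "common_up", "cancer_only", "atrophic_only",
                 "type1_only", "type2_only")

# tryptic-like peptide: 7-13 residues then K or R; unique after I/L
# canonicalization
random_peptides <- function(n, existing_canon = character()) {
  out <- character(0)
  seen <- existing_canon
  while (length(out) < n) {
    len <- sample(7:13, n, replace = TRUE)
    body <- vapply(len, function(l)
      paste(sample(AA20, l, replace = TRUE), collapse = ""), character(1))
    pep <- paste0(body, sample(c("K", "R"), n, replace = TRUE))
    canon <- il_canon(pep)
    ok <- !duplicated(canon) & !(canon %in% seen)
    out <- c(out, pep[ok])
    seen <- c(seen, canon[ok])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with planted truth
#'
#' Produces everything the pipeline consumes plus the generating truth:
#' a PSM table over all samples, a target+decoy FASTA database, the sample
#' sheet (the study's published ages/BMIs), knowledge lists consistent
#' with the planted classes, a GMT annotation fixture, and a truth bundle
#' (per-protein class and fold, peptide->protein origin, per-PSM
#' correct/incorrect label).
#'
#' Counts per (protein, sample) are Poisson with mean
#' `depth * a_p * fold_ps`, where `a_p ~ logNormal(0, abundance_sdlog)`
#' and `fold_ps` encodes the planted class (0 when absent, `true_fold`
#' for common-up proteins in cancer samples, 1 otherwise); counts are
#' spread over the protein's peptides multinomially. Every emitted
#' spectrum yields a correct PSM; incorrect PSMs (targets and decoys in
#' equal proportion) are added at `incorrect_psm_rate`.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with `psms`, `db`, `samples`,
#'   `truth`, `kb`, `gmt`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  samples <- if (config$n_atrophic == 4L && config$n_type1 == 2L &&
                 config$n_type2 == 2L) {
    table1_samples()
  } else {
    n <- c(config$n_atrophic, config$n_type1, config$n_type2)
    validate_sample_sheet(data.frame(
      sample_id = c(sprintf("A%02d", seq_len(n[1])),
                    sprintf("E%02d", seq_len(n[2])),
                    sprintf("S%02d", seq_len(n[3]))),
      group = rep(c("atrophic", "cancer", "cancer"), n),
      subtype = rep(c("none", "type1", "type2"), n),
      age = 60, bmi = 25, stringsAsFactors = FALSE))
  }

  sizes <- unlist(config[paste0("n_", sim_classes)])
  n_prot <- sum(sizes)
  cls <- rep(sim_classes, sizes)
  accession <- sprintf("P%05d", seq_len(n_prot))
  symbol <- sprintf("SYN%04d", seq_len(n_prot))

  # peptides per protein; paralog families share a slice of their peptides
  n_pep <- 2L + stats::rpois(n_prot, config$lambda_pep)
  pep_sets <- vector("list", n_prot)
  canon_seen <- character(0)
  for (i in seq_len(n_prot)) {
    pep_sets[[i]] <- random_peptides(n_pep[i], canon_seen)
    canon_seen <- c(canon_seen, il_canon(pep_sets[[i]]))
  }
  fam_of <- rep(NA_integer_, n_prot)
  eq_idx <- which(cls == "common_eq")
  n_fam <- min(config$n_paralog_families, length(eq_idx) %/% 2L)
  if (n_fam > 0) {
    picked <- sample(eq_idx, 2L * n_fam)
    for (f in seq_len(n_fam)) {
      a <- picked[2 * f - 1]; b <- picked[2 * f]
      fam_of[c(a, b)] <- f
      n_share <- max(1L, round(config$shared_peptide_rate *
                                 length(pep_sets[[a]])))
      n_share <- min(n_share, length(pep_sets[[a]]) - 2L)  # keep 2 unique
      if (n_share >= 1L) {
        shared <- pep_sets[[a]][seq_len(n_share)]
        pep_sets[[b]] <- c(shared, pep_sets[[b]])
      }
    }
  }

  db <- data.frame(
    accession = accession, gene_symbol = symbol,
    sequence = vapply(pep_sets, paste, character(1), collapse = ""),
    is_decoy = FALSE, stringsAsFactors = FALSE)
  decoys <- data.frame(
    accession = paste0("DECOY_", accession),
    gene_symbol = paste0("DECOY_", symbol),
    sequence = vapply(strsplit(db$sequence, ""), function(ch)
      paste(rev(ch), collapse = ""), character(1)),
    is_decoy = TRUE, stringsAsFactors = FALSE)
  db <- rbind(db, decoys)

  # planted per-(protein, sample) Poisson means
  a_p <- stats::rlnorm(n_prot, 0, config$abundance_sdlog)
  grp <- samples$group; sub <- samples$subtype
  fold_of <- function(class, g, st) {
    switch(class,
      common_eq = 1,
      common_up = if (g == "cancer") config$true_fold else 1,
      cancer_only = if (g == "cancer") 1 else 0,
      atrophic_only = if (g == "atrophic") 1 else 0,
      type1_only = if (st == "type1") 1 else 0,
      type2_only = if (st == "type2") 1 else 0)
  }

  psm_rows <- list()
  psm_truth <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    lam <- config$depth * a_p *
      vapply(cls, fold_of, numeric(1), g = grp[s], st = sub[s])
    counts <- stats::rpois(n_prot, lam)
    pep <- character(0); prot_of <- integer(0)
    for (i in which(counts > 0L)) {
      alloc <- stats::rmultinom(1, counts[i],
                                rep(1, length(pep_sets[[i]])))[, 1]
      pep <- c(pep, rep(pep_sets[[i]], alloc))
      prot_of <- c(prot_of, rep(i, counts[i]))
    }
    n_cor <- length(pep)
    n_inc <- stats::rpois(1, config$incorrect_psm_rate * n_cor)
    if (n_cor + n_inc == 0L) {
      psm_rows[[s]] <- NULL; psm_truth[[s]] <- NULL
      next
    }
    inc_decoy <- seq_len(n_inc) <= round(n_inc / 2)
    inc_pep <- random_peptides(max(n_inc, 1L), canon_seen)[seq_len(n_inc)]
    df <- data.frame(
      sample_id = sid,
      spectrum_id = sprintf("%s.%06d", sid, seq_len(n_cor + n_inc)),
      peptide_seq = c(pep, inc_pep),
      charge = sample(2:3, n_cor + n_inc, replace = TRUE),
      score = c(stats::rnorm(n_cor, config$mu_correct, config$sd_correct),
                stats::rnorm(n_inc, config$mu_incorrect,
                             config$sd_incorrect)),
      is_decoy = c(rep(FALSE, n_cor), inc_decoy),
      mass_error_ppm = c(stats::rnorm(n_cor, 0, config$mass_sd_correct),
                         stats::runif(n_inc, -config$mass_range_incorrect,
                                      config$mass_range_incorrect)),
      posterior = NA_real_,
      stringsAsFactors = FALSE)
    psm_rows[[s]] <- df
    psm_truth[[s]] <- data.frame(
      spectrum_id = df$spectrum_id,
      correct = c(rep(TRUE, n_cor), rep(FALSE, n_inc)),
      stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, psm_rows)
  rownames(psms) <- NULL

  # knowledge lists over the cancer-only-side symbols; the novel set is
  # what survives the sequential elimination
  conly <- symbol[cls %in% c("cancer_only", "type1_only", "type2_only")]
  n_c <- length(conly)
  kb_class <- sample(rep(c("known_ec", "known_other_cancer",
                           "novel_with_literature", "novel_no_literature"),
                         length.out = n_c))
  kb <- knowledge_base(
    known_ec = conly[kb_class == "known_ec"],
    known_other_cancer = conly[kb_class == "known_other_cancer"],
    has_literature = conly[kb_class == "novel_with_literature"])

  # GMT fixture: background terms plus one term enriched in cancer-only
  gmt <- lapply(1:6, function(i) {
    list(term_id = sprintf("T%02d", i),
         term_name = sprintf("synthetic term %02d", i),
         members = sample(symbol, min(25L, n_prot)))
  })
  if (n_c >= 5L) {
    gmt <- c(gmt, list(list(
      term_id = "T_CANCER", term_name = "planted cancer-only term",
      members = sample(conly, max(5L, n_c %/% 2L)))))
  }

  truth <- list(
    class_of = stats::setNames(cls, symbol),
    fold_of = stats::setNames(
      ifelse(cls == "common_up", config$true_fold, 1), symbol),
    peptide_protein = stats::setNames(
      rep(symbol, lengths(pep_sets))[!duplicated(unlist(pep_sets))],
      unlist(pep_sets)[!duplicated(unlist(pep_sets))]),
    psm_correct = do.call(rbind, psm_truth),
    kb_class = stats::setNames(kb_class, conly),
    sets = list(
      atrophic_only = sort(symbol[cls == "atrophic_only"]),
      cancer_only = sort(symbol[cls %in% c("cancer_only", "type1_only",
                                           "type2_only")]),
      common = sort(symbol[cls %in% c("common_eq", "common_up")])),
    novel = sort(conly[kb_class %in% c("novel_with_literature",
                                       "novel_no_literature")]))

  structure(list(psms = psms, db = db, samples = samples, truth = truth,
                 kb = kb, gmt = gmt, config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$config$seed, "): ",
      nrow(x$samples), " samples, ",
      sum(!x$db$is_decoy), " target proteins, ",
      nrow(x$psms), " PSMs\n", sep = "")
  print(table(x$truth$class_of))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Writes `psms.tsv`, `db.fasta`, `samples.tsv`, `kb_ec.txt`,
#' `kb_other_cancer.txt`, `kb_literature.txt`, `annotations.gmt` and
#' `truth.json` under `dir`.
#'
#' @param sim a [simulate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_psm_table(sim$psms, file.path(dir, "psms.tsv"))
  write_fasta_db(sim$db, file.path(dir, "db.fasta"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  write_gene_list(sim$kb$known_ec, file.path(dir, "kb_ec.txt"))
  write_gene_list(sim$kb$known_other_cancer,
                  file.path(dir, "kb_other_cancer.txt"))
  write_gene_list(sim$kb$has_literature, file.path(dir, "kb_literature.txt"))
  write_gmt(sim$gmt, file.path(dir, "annotations.gmt"))
  jsonlite::write_json(
    list(class_of = as.list(sim$truth$class_of),
         fold_of = as.list(sim$truth$fold_of),
         kb_class = as.list(sim$truth$kb_class),
         sets = sim$truth$sets, novel = sim$truth$novel),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}

#' Recovery metrics of a pipeline run against planted truth
#'
#' Compares a [run_pipeline()] result with the generating truth: per-set
#' Jaccard of the presence/absence partition, realized FDR among target
#' PSMs accepted at a q-value cut, and the relative-error distribution of
#' fold-change estimates for the planted up-regulated proteins.
#'
#' @param run a `specuniq_run` from [run_pipeline()].
#' @param truth the `truth` element of a [simulate_cohort()] bundle.
#' @param q_cut q-value acceptance threshold for the FDR metric.
#' @return list with `jaccard` (named numeric), `realized_fdr`,
#'   `n_psms_at_cut`, `fold_error` (median/mean relative error),
#'   `novel_exact` (planted novel set recovered exactly).
#' @export
evaluate_recovery <- function(run, truth, q_cut = 0.05) {
  part <- run$partition
  got <- list(atrophic_only = part$atrophic_only,
              cancer_only = part$cancer_only,
              common = part$common)
  if (!length(intersect(unlist(got), unlist(truth$sets)))) {
    stop("pipeline output and truth share no symbols")
  }
  jac <- vapply(names(truth$sets), function(nm)
    jaccard(got[[nm]], truth$sets[[nm]]), numeric(1))

  q <- run$psm_q
  lab <- truth$psm_correct$correct[match(names(q),
                                         truth$psm_correct$spectrum_id)]
  at_cut <- q <= q_cut & !is.na(lab)
  realized_fdr <- if (any(at_cut)) mean(!lab[at_cut]) else NA_real_

  up <- names(truth$fold_of)[truth$fold_of > 1]
  quant <- run$quant
  est <- quant$fold_change[match(up, quant$gene_symbol)]
  tru <- truth$fold_of[up]
  rel <- abs(est - tru) / tru
  rel <- rel[is.finite(rel)]

  novel_got <- sort(names(run$partition$category_of)[
    run$partition$category_of %in% c("novel_with_literature",
                                     "novel_no_literature")])
  list(jaccard = jac,
       realized_fdr = realized_fdr,
       n_psms_at_cut = sum(at_cut),
       fold_error = list(median = stats::median(rel), mean = mean(rel),
                         n = length(rel)),
       novel_exact = identical(novel_got, truth$novel))
}
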