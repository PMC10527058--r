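test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_common_eq = 10L, n_common_up = 5L, n_cancer_only = 5L,
                    n_atrophic_only = 5L, n_type1_only = 2L,
                    n_type2_only = 2L, seed = 99L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$psms, b$psms)
  expect_identical(a$db, b$db)
  expect_identical(a$truth, b$truth)
  # a different seed gives different spectra
  c_ <- simulate_cohort(sim_config(n_common_eq = 10L, n_common_up = 5L,
                                   n_cancer_only = 5L, n_atrophic_only = 5L,
                                   n_type1_only = 2L, n_type2_only = 2L,
                                   seed = 100L))
  expect_false(identical(a$psms$score, c_$psms$score))
})

test_that("a cancer-only-only proteome leaves atrophic samples empty", {
  cfg <- sim_config(n_common_eq = 0L, n_common_up = 0L, n_cancer_only = 20L,
                    n_atrophic_only = 0L, n_type1_only = 0L,
                    n_type2_only = 0L, n_paralog_families = 0L,
                    incorrect_psm_rate = 1e-9, seed = 13L)
  sim <- simulate_cohort(cfg)
  atro <- sim$samples$sample_id[sim$samples$group == "atrophic"]
  expect_equal(sum(sim$psms$sample_id %in% atro & !sim$psms$is_decoy), 0L)
  # every emitted peptide traces back to a cancer-only protein
  origin <- sim$truth$peptide_protein[sim$psms$peptide_seq]
  origin <- origin[!is.na(origin)]
  expect_true(all(sim$truth$class_of[origin] == "cancer_only"))
  expect_error(simulate_cohort(sim_config(n_common_eq = 0L,
    n_common_up = 0L, n_cancer_only = 0L, n_atrophic_only = 0L,
    n_type1_only = 0L, n_type2_only = 0L)), "non-empty")
})

test_that("realized depth matches the generating law for always-present proteins", {
  sim <- simulate_cohort(sim_config(seed = 1L))
  cfg <- sim$config
  eq <- names(sim$truth$class_of)[sim$truth$class_of == "common_eq"]
  correct_ids <- sim$truth$psm_correct$spectrum_id[sim$truth$psm_correct$correct]
  psms <- sim$psms[sim$psms$spectrum_id %in% correct_ids, ]
  origin <- sim$truth$peptide_protein[psms$peptide_seq]
  per_protein_sample <- sum(origin %in% eq) / (length(eq) * nrow(sim$samples))
  expected <- cfg$depth * exp(cfg$abundance_sdlog^2 / 2)
  expect_lt(abs(per_protein_sample - expected) / expected, 0.10)
})

test_that("paralog families share peptides and the truth bundle partitions the proteome", {
  sim <- small_sim()
  # shared peptides exist: at least one peptide maps to two target proteins
  pepmap <- map_peptides(unique(sim$truth$peptide_protein |> names()),
                         sim$db)
  expect_gte(max(lengths(pepmap$pep2prot)), 2L)
  # classes partition the planted proteome
  cls <- sim$truth$class_of
  expect_equal(length(cls), sum(!sim$db$is_decoy))
  expect_equal(sort(unique(names(cls))), sort(sim$db$gene_symbol[!sim$db$is_decoy]))
  sets <- sim$truth$sets
  expect_equal(sort(c(sets$atrophic_only, sets$cancer_only, sets$common)),
               sort(names(cls)))
})

test_that("fixture files round-trip through the standard readers", {
  sim <- simulate_cohort(sim_config(n_common_eq = 6L, n_common_up = 3L,
                                    n_cancer_only = 3L, n_atrophic_only = 3L,
                                    n_type1_only = 1L, n_type2_only = 1L,
                                    seed = 21L))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  psms <- read_psm_table(file.path(dir, "psms.tsv"))
  expect_equal(nrow(psms), nrow(sim$psms))
  expect_equal(psms$peptide_seq, sim$psms$peptide_seq)
  db <- read_fasta_db(file.path(dir, "db.fasta"))
  expect_equal(db$accession, sim$db$accession)
  expect_equal(db$sequence, sim$db$sequence)
  expect_equal(read_sample_sheet(file.path(dir, "samples.tsv")),
               sim$samples)
  expect_equal(read_gene_list(file.path(dir, "kb_ec.txt")),
               sim$kb$known_ec)
  gmt <- read_gmt(file.path(dir, "annotations.gmt"))
  expect_equal(length(gmt), length(sim$gmt))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$novel), sim$truth$novel)
})

test_that("recovery metrics have the right degenerate values", {
  sim <- small_sim()
  truth <- sim$truth
  perfect <- list(partition = list(atrophic_only = truth$sets$atrophic_only,
                                   cancer_only = truth$sets$cancer_only,
                                   common = truth$sets$common,
                                   category_of = stats::setNames(
                                     ifelse(truth$kb_class %in%
                                              c("novel_with_literature",
                                                "novel_no_literature"),
                                            truth$kb_class, "known_ec"),
                                     names(truth$kb_class))),
                  psm_q = stats::setNames(
                    numeric(0), character(0)),
                  quant = data.frame(gene_symbol = names(truth$fold_of),
                                     fold_change = unname(truth$fold_of)))
  rec <- evaluate_recovery(perfect, truth)
  expect_true(all(rec$jaccard == 1))
  expect_equal(rec$fold_error$median, 0)
  expect_true(rec$novel_exact)

  empty <- perfect
  empty$partition <- list(atrophic_only = character(0),
                          cancer_only = character(0),
                          common = "NOT_A_REAL_SYMBOL")
  expect_error(evaluate_recovery(empty, truth), "no symbols")
})
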