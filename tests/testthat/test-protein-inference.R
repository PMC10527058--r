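test_that("peptides map by substring with I/L equivalence", {
  db <- make_db(c("P1", "P2", "DECOY_P1"),
                c("MMMELVISKMMM", "AAAA", "KSIVLEM"),
                is_decoy = c(FALSE, FALSE, TRUE))
  m <- map_peptides(c("ELVISK", "ELVLSK", "WWWWK"), db)
  expect_equal(m$pep2prot[["ELVISK"]], "P1")
  expect_equal(m$pep2prot[["ELVLSK"]], "P1")   # I/L equivalent
  expect_equal(m$orphans, "WWWWK")
  expect_error(map_peptides("PEPK", db[0, ]), "empty")
})

test_that("a shared peptide maps to every containing paralog", {
  db <- make_db(c("P1", "P2"), c("XSHAREDKY", "ZSHAREDKW"))
  db$sequence <- c("MSHAREDKM", "ASHAREDKA")
  m <- map_peptides("SHAREDK", db)
  expect_setequal(m$pep2prot[["SHAREDK"]], c("P1", "P2"))
})

test_that("protein probability is the noisy-OR of peptide posteriors", {
  expect_equal(protein_probability(c(0.95, 0.95)), 0.9975)
  expect_equal(protein_probability(1.0), 1.0)
  expect_equal(protein_probability(rep(0.5, 4)), 0.9375)
  expect_equal(protein_probability(numeric(0)), 0)
})

make_instance_map <- function(sets, peps) {
  prot2pep <- sets
  pep2prot <- lapply(peps, function(p)
    names(sets)[vapply(sets, function(s) p %in% s, logical(1))])
  names(pep2prot) <- peps
  pep2prot <- pep2prot[lengths(pep2prot) > 0]
  list(pep2prot = pep2prot, prot2pep = prot2pep, orphans = character(0))
}

test_that("indistinguishable proteins merge and subsets are subsumed", {
  cfg <- specuniq_config(min_peptides = 1L)
  peps <- c("AAAK", "CCCK", "DDDK")
  pepdf <- make_peptides(peps)
  db <- make_db(c("P1", "P2", "P3"), rep("X", 3),
                gene_symbol = c("G1", "G2", "G3"))

  # P1 and P2 carry identical peptide sets -> one group, two members
  m <- make_instance_map(list(P1 = peps, P2 = peps), peps)
  g <- parsimony_groups(m, pepdf, db, cfg)
  expect_equal(length(unique(g$group_id)), 1L)
  expect_equal(unique(g$members), "P1;P2")

  # B = {CCCK} is a strict subset of A -> subsumed
  m <- make_instance_map(list(A = peps, B = "CCCK"), peps)
  db2 <- make_db(c("A", "B"), c("X", "X"))
  g <- parsimony_groups(m, pepdf, db2, cfg)
  expect_equal(length(unique(g$group_id)), 1L)
  expect_equal(unique(g$representative), "A")
})

test_that("greedy cover matches the exhaustive minimal cover on random instances", {
  cfg <- specuniq_config(min_peptides = 1L)
  set.seed(42)
  n_equal <- 0L
  n_inst <- 200L
  for (i in seq_len(n_inst)) {
    n_prot <- sample(3:10, 1)
    n_pep <- sample(5:15, 1)
    peps <- sprintf("PEP%02dK", seq_len(n_pep))
    sets <- lapply(seq_len(n_prot), function(j) {
      sample(peps, sample(seq_len(n_pep), 1))
    })
    names(sets) <- sprintf("PR%02d", seq_len(n_prot))
    covered <- unique(unlist(sets))
    m <- make_instance_map(sets, covered)
    db <- make_db(names(sets), rep("X", n_prot))
    g <- parsimony_groups(m, make_peptides(covered), db, cfg)
    greedy <- length(unique(g$group_id))
    oracle <- min_cover_size(sets)
    expect_gte(greedy, oracle)   # greedy can never beat the true minimum
    if (greedy == oracle) n_equal <- n_equal + 1L
  }
  expect_gte(n_equal / n_inst, 0.9)
})

test_that("grouping is invariant to protein and peptide input order", {
  cfg <- specuniq_config(min_peptides = 1L)
  peps <- c("AAAK", "CCCK", "DDDK", "EEEK")
  sets <- list(P1 = c("AAAK", "CCCK"), P2 = c("CCCK", "DDDK"),
               P3 = c("DDDK", "EEEK"))
  db <- make_db(names(sets), rep("X", 3))
  g1 <- parsimony_groups(make_instance_map(sets, peps),
                         make_peptides(peps), db, cfg)
  sets_r <- rev(sets)
  g2 <- parsimony_groups(make_instance_map(sets_r, rev(peps)),
                         make_peptides(rev(peps)), db, cfg)
  key <- function(g) {
    u <- unique(g[, c("representative", "members", "cluster_id")])
    u[order(u$representative), c("representative", "members")]
  }
  expect_equal(key(g1), key(g2), ignore_attr = TRUE)
})

test_that("shared spectra are credited to exactly one group", {
  cfg <- specuniq_config(min_peptides = 1L)
  # SHARED belongs to both; each protein also has a unique peptide
  sets <- list(P1 = c("AAAK", "SHAREDK"), P2 = c("CCCK", "SHAREDK"))
  peps <- c("AAAK", "CCCK", "SHAREDK")
  pepdf <- make_peptides(peps, spectral_count = c(2L, 3L, 5L))
  db <- make_db(names(sets), c("X", "X"))
  g <- parsimony_groups(make_instance_map(sets, peps), pepdf, db, cfg)
  expect_equal(length(unique(g$group_id)), 2L)
  # total credited spectra equal total observed spectra (no double count)
  expect_equal(sum(g$spectral_count), sum(pepdf$spectral_count))
  # both groups share a peptide -> same cluster
  expect_equal(length(unique(g$cluster_id)), 1L)
})

test_that("per-sample acceptance enforces probability and two-peptide rules", {
  db <- make_db("P1", "X", gene_symbol = "G1")
  sets <- list(P1 = c("AAAK", "CCCK"))
  peps <- c("AAAK", "CCCK")
  samples <- table1_samples()

  # one peptide per sample everywhere: never accepted under min_peptides=2
  one <- make_peptides("AAAK", sample_id = samples$sample_id[1])
  g <- parsimony_groups(make_instance_map(sets, "AAAK"), one, db,
                        specuniq_config())
  expect_false(any(g$accepted))

  # two peptides at 0.95 each: protein probability 0.9975 >= 0.95 -> accepted
  two <- make_peptides(peps, sample_id = samples$sample_id[1],
                       best_posterior = 0.95)
  g <- parsimony_groups(make_instance_map(sets, peps), two, db,
                        specuniq_config())
  acc <- g[g$sample_id == samples$sample_id[1], ]
  expect_true(acc$accepted)
  expect_equal(acc$protein_prob, 0.9975)
})

test_that("acceptance matrix pivots evidence by gene symbol", {
  samples <- table1_samples()
  db <- make_db("P1", "X", gene_symbol = "G1")
  sets <- list(P1 = c("AAAK", "CCCK"))
  peps <- rbind(
    make_peptides(c("AAAK", "CCCK"), sample_id = "012"),
    make_peptides(c("AAAK", "CCCK"), sample_id = "015"))
  g <- parsimony_groups(make_instance_map(sets, c("AAAK", "CCCK")),
                        peps, db, specuniq_config())
  m <- accepted_matrix(g, samples)
  expect_equal(rownames(m$accepted), "G1")
  expect_equal(sum(m$accepted["G1", ]), 2L)
  expect_equal(sum(m$counts["G1", ]), 4)

  # empty evidence -> empty matrices
  m0 <- accepted_matrix(empty_groups(), samples)
  expect_equal(nrow(m0$accepted), 0L)
})
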