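# Shared fixtures and independent oracles, all built in code.

# a minimal PSM data.frame with sensible defaults
make_psms <- function(peptide_seq, sample_id = "S1", score = 5,
                      is_decoy = FALSE, mass_error_ppm = 0,
                      posterior = NA_real_, charge = 2L) {
  n <- length(peptide_seq)
  data.frame(sample_id = rep_len(sample_id, n),
             spectrum_id = sprintf("sp%04d", seq_len(n)),
             peptide_seq = peptide_seq,
             charge = rep_len(charge, n),
             score = rep_len(score, n),
             is_decoy = rep_len(is_decoy, n),
             mass_error_ppm = rep_len(mass_error_ppm, n),
             posterior = rep_len(posterior, n),
             stringsAsFactors = FALSE)
}

make_db <- function(accession, sequence, gene_symbol = accession,
                    is_decoy = FALSE) {
  data.frame(accession = accession, gene_symbol = gene_symbol,
             sequence = sequence, is_decoy = rep_len(is_decoy,
                                                     length(accession)),
             stringsAsFactors = FALSE)
}

# a scored-peptide table as produced by filter_and_rollup
make_peptides <- function(peptide_seq, sample_id = "S1",
                          best_posterior = 0.99, spectral_count = 1L) {
  n <- length(peptide_seq)
  data.frame(sample_id = rep_len(sample_id, n),
             peptide_seq = peptide_seq,
             best_posterior = rep_len(best_posterior, n),
             spectral_count = rep_len(spectral_count, n),
             qvalue = 0, local_fdr = 0, stringsAsFactors = FALSE)
}

# hand-built mixture parameters (bypasses the EM)
make_mixture <- function(pi_correct, mu1, s1, mu0, s0) {
  structure(list(pi_correct = pi_correct, mu_correct = mu1,
                 sigma_correct = s1, mu_incorrect = mu0,
                 sigma_incorrect = s0, loglik_trace = numeric(0),
                 converged = TRUE, n = 0L),
            class = "score_mixture")
}

# exhaustive minimal set cover oracle: smallest number of sets covering
# the union of all sets (enumerates subsets by increasing size)
min_cover_size <- function(sets) {
  universe <- unique(unlist(sets))
  m <- length(sets)
  for (k in seq_len(m)) {
    picks <- utils::combn(m, k, simplify = FALSE)
    for (p in picks) {
      if (all(universe %in% unlist(sets[p]))) return(k)
    }
  }
  stop("uncoverable instance")
}

# exhaustive hypergeometric upper-tail oracle by direct summation
hyper_tail_oracle <- function(k, K, N, n) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a small synthetic cohort shared by planted-truth unit tests
small_sim <- function(seed = 11) {
  simulate_cohort(sim_config(
    n_common_eq = 15L, n_common_up = 10L, n_cancer_only = 12L,
    n_atrophic_only = 8L, n_type1_only = 4L, n_type2_only = 4L,
    n_paralog_families = 2L, seed = seed))
}
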