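#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults mirror the acceptance rules of the analysis the package
#' implements: peptide and protein identifications accepted above 95%
#' posterior probability, at least two distinct peptides per protein per
#' sample, precursor mass error within 10 ppm, up-regulation called at a
#' fold change of at least 1.7, and mean--SD regression outliers flagged
#' beyond 3 standardized residuals.
#'
#' @param peptide_prob_min minimum peptide posterior probability for
#'   acceptance (default 0.95).
#' @param protein_prob_min minimum protein probability for acceptance
#'   (default 0.95).
#' @param min_peptides minimum distinct peptides per protein per sample
#'   (default 2).
#' @param max_mass_error_ppm maximum absolute precursor mass error in parts
#'   per million (default 10).
#' @param fold_change_min minimum finite fold change called up-regulated
#'   (default 1.7; 1.5 is a common alternative cut-off).
#' @param outlier_sd standardized-residual threshold of the log SD vs log
#'   mean regression beyond which a protein is excluded (default 3).
#' @param presence_min_samples samples of a group a protein must be accepted
#'   in to be called present in that group (default 1).
#' @param enrichment_alpha significance level for the per-protein gate and
#'   enrichment reporting (default 0.01).
#' @param decoy_ratio target:decoy database size ratio used to scale decoy
#'   counts in FDR estimates (default 1, an equal-size decoy database).
#' @param pseudocount added to spectral counts before log transforms
#'   (default 0.5; zeros are structural in spectral counting).
#' @param decoy_prefix accession prefix marking decoy database entries.
#' @param seed integer seed recorded with the run.
#' @return A list of class `specuniq_config`.
#' @export
#' @examples
#' cfg <- specuniq_config(fold_change_min = 1.5)
#' cfg$fold_change_min
specuniq_config <- function(peptide_prob_min = 0.95,
                            protein_prob_min = 0.95,
                            min_peptides = 2L,
                            max_mass_error_ppm = 10,
                            fold_change_min = 1.7,
                            outlier_sd = 3,
                            presence_min_samples = 1L,
                            enrichment_alpha = 0.01,
                            decoy_ratio = 1,
                            pseudocount = 0.5,
                            decoy_prefix = "DECOY_",
                            seed = 1L) {
  cfg <- list(
    peptide_prob_min = peptide_prob_min,
    protein_prob_min = protein_prob_min,
    min_peptides = as.integer(min_peptides),
    max_mass_error_ppm = max_mass_error_ppm,
    fold_change_min = fold_change_min,
    outlier_sd = outlier_sd,
    presence_min_samples = as.integer(presence_min_samples),
    enrichment_alpha = enrichment_alpha,
    decoy_ratio = decoy_ratio,
    pseudocount = pseudocount,
    decoy_prefix = decoy_prefix,
    seed = as.integer(seed)
  )
  for (p in c("peptide_prob_min", "protein_prob_min")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop(sprintf("'%s' must lie in (0, 1)", p))
    }
  }
  for (p in c("min_peptides", "max_mass_error_ppm", "fold_change_min",
              "outlier_sd", "presence_min_samples", "enrichment_alpha",
              "decoy_ratio", "pseudocount")) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0) {
      stop(sprintf("'%s' must be a single strictly positive number", p))
    }
  }
  structure(cfg, class = "specuniq_config")
}

#' @export
print.specuniq_config <- function(x, ...) {
  cat("specuniq pipeline configuration\n")
  for (nm in setdiff(names(x), "decoy_prefix")) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-22s %s\n", "decoy_prefix", x$decoy_prefix))
  invisible(x)
}

#' Write / read a configuration as JSON
#'
#' @param config a [specuniq_config()] object.
#' @param path file path.
#' @return `read_config` returns a `specuniq_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "specuniq_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(specuniq_config, vals)
}
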