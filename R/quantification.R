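# Spectral-count quantitation: per-sample normalization, the log-SD vs
# log-mean outlier screen, cancer/control fold changes with an explicit
# infinite-fold sentinel, the >= fold_change_min up-regulation call, and a
# per-protein significance gate.

#' Normalize a spectral-count matrix
#'
#' `total_count` scales each sample (column) by
#' grand-mean(sample totals) / sample total, equalizing sequencing-like
#' depth differences; `none` passes counts through unchanged.
#'
#' @param counts numeric matrix, proteins x samples, non-negative.
#' @param method `"total_count"` or `"none"`.
#' @return matrix of the same shape.
#' @export
normalize_counts <- function(counts, method = c("total_count", "none")) {
  method <- match.arg(method)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (method == "none") return(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample with zero total count: ",
         colnames(counts)[totals == 0][1])
  }
  sweep(counts, 2, mean(totals) / totals, `*`)
}

#' Flag outlier proteins on the log SD vs log mean regression
#'
#' Across all samples, each protein's mean and SD of (count + pseudocount)
#' are log10-transformed and SD is regressed on mean by ordinary least
#' squares across proteins; proteins whose standardized residual exceeds
#' `config$outlier_sd` in absolute value are flagged as outliers and
#' excluded from downstream fold-change ranking (but reported). With fewer
#' than 10 proteins the regression is skipped with a warning and nothing is
#' flagged.
#'
#' @param counts normalized count matrix (proteins x samples).
#' @param config a [specuniq_config()].
#' @return data.frame with `gene_symbol`, `log_mean`, `log_sd`,
#'   `residual_z`, `outlier`.
#' @export
exclude_outliers <- function(counts, config = specuniq_config()) {
  eps <- config$pseudocount
  m <- rowMeans(counts + eps)
  s <- apply(counts + eps, 1, stats::sd)
  lm10 <- log10(m)
  ls10 <- log10(s + eps)
  out <- data.frame(gene_symbol = rownames(counts),
                    log_mean = lm10, log_sd = ls10,
                    residual_z = 0, outlier = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(counts) < 10L) {
    warning("fewer than 10 proteins: outlier regression skipped")
    return(out)
  }
  fit <- stats::lm(ls10 ~ lm10)
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (sigma < 1e-10) return(out)  # perfect fit: no outliers
  z <- stats::rstandard(fit)
  z[is.na(z)] <- 0
  out$residual_z <- as.numeric(z)
  out$outlier <- abs(out$residual_z) > config$outlier_sd
  out
}

#' Fold changes with infinite-fold handling
#'
#' Group means are computed on normalized counts without pseudocount. The
#' fold change is cancer/atrophic when the atrophic mean is positive,
#' `Inf` (the infinite-fold sentinel) when the atrophic mean is zero and
#' the cancer mean positive, and `NaN` (excluded) when both are zero.
#' `upregulated` is `TRUE` only for finite fold changes of at least
#' `config$fold_change_min`; infinite-fold proteins are tracked separately
#' since they belong to the cancer-only presence class.
#'
#' @param counts normalized count matrix.
#' @param samples sample sheet (defines group membership).
#' @param config a [specuniq_config()].
#' @return data.frame with `gene_symbol`, `mean_atrophic`, `sd_atrophic`,
#'   `mean_cancer`, `sd_cancer`, `fold_change`, `infinite_fold`,
#'   `upregulated`.
#' @export
fold_changes <- function(counts, samples, config = specuniq_config()) {
  a_cols <- samples$sample_id[samples$group == "atrophic"]
  c_cols <- samples$sample_id[samples$group == "cancer"]
  A <- counts[, a_cols, drop = FALSE]
  C <- counts[, c_cols, drop = FALSE]
  ma <- rowMeans(A); mc <- rowMeans(C)
  fc <- ifelse(ma > 0, mc / ma, ifelse(mc > 0, Inf, NaN))
  data.frame(gene_symbol = rownames(counts),
             mean_atrophic = ma,
             sd_atrophic = apply(A, 1, stats::sd),
             mean_cancer = mc,
             sd_cancer = apply(C, 1, stats::sd),
             fold_change = fc,
             infinite_fold = is.infinite(fc),
             upregulated = is.finite(fc) & fc >= config$fold_change_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Welch's t on two numeric vectors with an optional variance floor;
# shared by the significance gate and the cohort statistics.
welch_t_stat <- function(x, y, var_floor = 0) {
  n1 <- length(x); n2 <- length(y)
  v1 <- max(stats::var(x), var_floor)
  v2 <- max(stats::var(y), var_floor)
  if (v1 == 0 && v2 == 0) {
    return(list(t = if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf,
                df = n1 + n2 - 2, p = if (mean(x) == mean(y)) 1 else 0))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Per-protein significance gate
#'
#' Tests each protein's log10(count + pseudocount) response for a
#' disease-status effect. `two_way_anova` fits the two-factor linear model
#' with status (atrophic/cancer) and a subtype contrast (0 for atrophic,
#' -1 for type1, +1 for type2) and reports the status-effect p-value;
#' `welch_log` reports Welch's t-test on the log counts. A protein passes
#' the gate when p < `config$enrichment_alpha`. Groups with zero variance
#' use a variance floor of pseudocount^2 and are flagged.
#'
#' @param counts normalized count matrix.
#' @param samples sample sheet with `group` and `subtype`.
#' @param method `"two_way_anova"` or `"welch_log"`.
#' @param config a [specuniq_config()].
#' @return data.frame with `gene_symbol`, `p_gate`, `pass`,
#'   `variance_floored`.
#' @export
significance_gate <- function(counts, samples,
                              method = c("two_way_anova", "welch_log"),
                              config = specuniq_config()) {
  method <- match.arg(method)
  eps <- config$pseudocount
  logc <- log10(counts[, samples$sample_id, drop = FALSE] + eps)
  status <- factor(samples$group, levels = c("atrophic", "cancer"))
  contrast <- ifelse(samples$subtype == "type1", -1,
                     ifelse(samples$subtype == "type2", 1, 0))
  res <- t(apply(logc, 1, function(y) {
    floored <- FALSE
    if (method == "two_way_anova") {
      g1 <- y[status == "atrophic"]; g2 <- y[status == "cancer"]
      if (stats::var(g1) == 0 || stats::var(g2) == 0) floored <- TRUE
      fit <- stats::lm(y ~ status + contrast)
      an <- suppressWarnings(stats::anova(fit))
      p <- an[["Pr(>F)"]][rownames(an) == "status"]
      if (floored || !is.finite(p)) {
        # refit logic unavailable: fall back to floored Welch on status
        w <- welch_t_stat(g2, g1, var_floor = eps^2)
        p <- w$p
      }
    } else {
      g1 <- y[status == "atrophic"]; g2 <- y[status == "cancer"]
      floored <- stats::var(g1) == 0 || stats::var(g2) == 0
      w <- welch_t_stat(g2, g1, var_floor = if (floored) eps^2 else 0)
      p <- w$p
    }
    c(p = p, floored = as.numeric(floored))
  }))
  data.frame(gene_symbol = rownames(counts),
             p_gate = res[, "p"],
             pass = res[, "p"] < config$enrichment_alpha,
             variance_floored = res[, "floored"] > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the per-protein quantitation table
#'
#' Convenience wrapper chaining [normalize_counts()], [exclude_outliers()],
#' [fold_changes()] and [significance_gate()] into one table.
#'
#' @param counts raw count matrix (proteins x samples).
#' @param samples sample sheet.
#' @param config a [specuniq_config()].
#' @param normalization passed to [normalize_counts()].
#' @param gate_method passed to [significance_gate()].
#' @return data.frame, one row per protein, with all quantitation fields.
#' @export
quantify <- function(counts, samples, config = specuniq_config(),
                     normalization = "total_count",
                     gate_method = "two_way_anova") {
  norm <- normalize_counts(counts, normalization)
  ol <- exclude_outliers(norm, config)
  fc <- fold_changes(norm, samples, config)
  gate <- significance_gate(norm, samples, gate_method, config)
  out <- cbind(fc,
               ol[match(fc$gene_symbol, ol$gene_symbol),
                  c("log_mean", "log_sd", "residual_z", "outlier")],
               gate[match(fc$gene_symbol, gate$gene_symbol),
                    c("p_gate", "pass", "variance_floored")])
  rownames(out) <- NULL
  # outliers are excluded from the up-regulation ranking but kept in the table
  out$upregulated <- out$upregulated & !out$outlier
  out
}
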