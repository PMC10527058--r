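# PSM-level scoring: a transparent reimplementation of the
# PeptideProphet-style two-component Gaussian mixture, target-decoy
# q-values and a binned local FDR. The mixture models the discriminant
# score x as
#
#   f(x) = pi * N(x; mu1, sigma1^2) + (1 - pi) * N(x; mu0, sigma0^2)
#
# with component 1 = correct matches, component 0 = incorrect; the
# posterior probability that a PSM with score x is correct is
# pi f1(x) / (pi f1(x) + (1 - pi) f0(x)).

#' Fit a two-component Gaussian mixture to PSM scores
#'
#' EM fit of correct/incorrect score components. Initialization uses the
#' decoy scores for the incorrect component (decoys are incorrect by
#' construction), the top decile of target scores for the correct
#' component, and a mixing proportion of 0.5. Components are relabeled
#' after fitting, if needed, so that the correct-component mean exceeds the
#' incorrect one.
#'
#' @param scores numeric vector of search-engine discriminant scores.
#' @param is_decoy logical vector, same length.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol absolute log-likelihood change declaring convergence
#'   (default 1e-8).
#' @return An object of class `score_mixture` with elements `pi_correct`,
#'   `mu_correct`, `sigma_correct`, `mu_incorrect`, `sigma_incorrect`,
#'   `loglik_trace`, `converged`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' sc <- c(rnorm(300, 4), rnorm(300, 0))
#' fit <- fit_score_mixture(sc, rep(c(FALSE, TRUE), each = 300))
#' coef(fit)
fit_score_mixture <- function(scores, is_decoy, max_iter = 500L,
                              tol = 1e-8) {
  stopifnot(length(scores) == length(is_decoy))
  ok <- !is.na(scores)
  scores <- scores[ok]; is_decoy <- as.logical(is_decoy)[ok]
  if (length(scores) < 50L) stop("need at least 50 scores to fit the mixture")
  if (sum(is_decoy) < 5L) stop("need at least 5 decoy scores to initialize")
  if (stats::sd(scores) == 0) stop("degenerate input: all scores are equal")

  dec <- scores[is_decoy]
  tgt <- scores[!is_decoy]
  top <- tgt[tgt >= stats::quantile(tgt, 0.9)]
  mu0 <- mean(dec); s0 <- max(stats::sd(dec), 1e-3)
  mu1 <- mean(top)
  s1 <- stats::sd(top)
  # a tiny top decile leaves sigma1 undefined; start the correct
  # component narrow so it can only claim a genuine upper mode
  if (!is.finite(s1) || s1 < 1e-3) s1 <- max(s0 / 10, 1e-3)
  if (mu1 <= mu0) mu1 <- mu0 + s0  # pathological init guard
  pi1 <- 0.5

  n <- length(scores)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(scores, mu1, s1)
    d0 <- (1 - pi1) * stats::dnorm(scores, mu0, s0)
    tot <- d1 + d0
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    g <- d1 / tot                       # responsibility of the correct component
    sg <- sum(g)
    pi1 <- sg / n
    mu1 <- sum(g * scores) / sg
    mu0 <- sum((1 - g) * scores) / (n - sg)
    s1 <- sqrt(sum(g * (scores - mu1)^2) / sg)
    s0 <- sqrt(sum((1 - g) * (scores - mu0)^2) / (n - sg))
    s1 <- max(s1, 1e-6); s0 <- max(s0, 1e-6)
    pi1 <- min(max(pi1, 1e-6), 1 - 1e-6)
  }
  if (!converged) {
    warning("score mixture EM did not converge in ", max_iter, " iterations")
  }
  if (mu1 < mu0) {  # relabel so the correct component sits on top
    tmp <- c(mu0, s0); mu0 <- mu1; s0 <- s1
    mu1 <- tmp[1]; s1 <- tmp[2]; pi1 <- 1 - pi1
  }
  structure(list(pi_correct = pi1, mu_correct = mu1, sigma_correct = s1,
                 mu_incorrect = mu0, sigma_incorrect = s0,
                 loglik_trace = ll_trace, converged = converged, n = n),
            class = "score_mixture")
}

#' @export
print.score_mixture <- function(x, ...) {
  cat("Two-component Gaussian score mixture (", x$n, " PSMs)\n", sep = "")
  cat(sprintf("  correct:   pi = %.3f, mu = %.3f, sigma = %.3f\n",
              x$pi_correct, x$mu_correct, x$sigma_correct))
  cat(sprintf("  incorrect: pi = %.3f, mu = %.3f, sigma = %.3f\n",
              1 - x$pi_correct, x$mu_incorrect, x$sigma_incorrect))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              utils::tail(x$loglik_trace, 1), length(x$loglik_trace),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.score_mixture <- function(object, ...) {
  c(pi_correct = object$pi_correct,
    mu_correct = object$mu_correct, sigma_correct = object$sigma_correct,
    mu_incorrect = object$mu_incorrect,
    sigma_incorrect = object$sigma_incorrect)
}

#' @export
logLik.score_mixture <- function(object, ...) {
  val <- utils::tail(object$loglik_trace, 1)
  structure(val, df = 5L, nobs = object$n, class = "logLik")
}

#' Posterior probability that a PSM is correct
#'
#' Evaluates the mixture posterior `pi f1(x) / (pi f1(x) + (1-pi) f0(x))`.
#' When the component variances are equal the posterior is monotone
#' increasing in the score. With unequal variances the raw posterior is a
#' quadratic in the score on the log-odds scale and bends back at extreme
#' scores; values are clamped to the monotone non-decreasing envelope
#' (scores beyond the log-odds vertex keep the vertex posterior), so a
#' better score never receives a lower probability.
#'
#' @param params a fitted [fit_score_mixture()] object.
#' @param score numeric scores.
#' @return posterior probabilities in \[0, 1\].
#' @export
posterior_prob <- function(params, score) {
  stopifnot(inherits(params, "score_mixture"))
  with(params, {
    # log-odds are quadratic: a*x^2 + b*x + c
    a <- 1 / (2 * sigma_incorrect^2) - 1 / (2 * sigma_correct^2)
    x <- score
    if (abs(a) > 1e-12) {
      b <- mu_correct / sigma_correct^2 - mu_incorrect / sigma_incorrect^2
      v <- -b / (2 * a)
      if (a < 0) x <- pmin(x, v) else x <- pmax(x, v)
    }
    l1 <- log(pi_correct) + stats::dnorm(x, mu_correct, sigma_correct,
                                         log = TRUE)
    l0 <- log(1 - pi_correct) + stats::dnorm(x, mu_incorrect,
                                             sigma_incorrect, log = TRUE)
    1 / (1 + exp(l0 - l1))
  })
}

#' @export
predict.score_mixture <- function(object, newdata, ...) {
  posterior_prob(object, newdata)
}

#' Target-decoy q-values
#'
#' Sorts PSMs by decreasing score; the estimated FDR at threshold t is
#' `decoy_ratio * D(t) / max(T(t), 1)` with D and T the decoy and target
#' counts at or above t; q-values are the running minimum of the FDR from
#' the weakest score upward. Tied scores share one q-value.
#'
#' @param scores numeric PSM scores.
#' @param is_decoy logical decoy flags.
#' @param decoy_ratio target:decoy database size ratio (default 1).
#' @return numeric q-values aligned with the input order.
#' @export
qvalues_from_decoys <- function(scores, is_decoy, decoy_ratio = 1) {
  is_decoy <- as.logical(is_decoy)
  if (!any(!is_decoy)) stop("no target PSMs")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; d <- is_decoy[ord]
  D <- cumsum(d); Tn <- cumsum(!d)
  # ties share the FDR of the last tied element (counts are at-or-above)
  last_idx <- stats::ave(seq_along(s), cumsum(!duplicated(s)), FUN = max)
  fdr <- decoy_ratio * D[last_idx] / pmax(Tn[last_idx], 1)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(length(scores))
  out[ord] <- q
  out
}

#' Binned local false discovery rate
#'
#' Splits PSMs into equal-count score bins, estimates the per-bin decoy to
#' target ratio scaled by `decoy_ratio`, enforces monotonicity (local FDR
#' non-increasing in score) by isotonic regression across bins, and clips
#' to \[0, 1\].
#'
#' @inheritParams qvalues_from_decoys
#' @param n_bins number of equal-count bins (default 20).
#' @return per-PSM local FDR, aligned with the input order.
#' @export
local_fdr_binned <- function(scores, is_decoy, decoy_ratio = 1,
                             n_bins = 20L) {
  n <- length(scores)
  if (n < n_bins * 5L) {
    stop("need at least ", n_bins * 5L, " PSMs for ", n_bins, " bins")
  }
  is_decoy <- as.logical(is_decoy)
  ord <- order(scores)
  bin_of_sorted <- as.integer(cut(seq_len(n), breaks = n_bins, labels = FALSE))
  bin <- integer(n)
  bin[ord] <- bin_of_sorted
  D <- tapply(is_decoy, bin, sum)
  Tn <- tapply(!is_decoy, bin, sum)
  raw <- decoy_ratio * as.numeric(D) / pmax(as.numeric(Tn), 1)
  # isotonic in ascending-bin order must be non-increasing: fit on reversed
  iso <- stats::isoreg(rev(raw))$yf
  lfdr_bin <- pmin(pmax(rev(iso), 0), 1)
  lfdr_bin[bin]
}

#' Filter PSMs and roll up to peptides
#'
#' Applies the acceptance rules at the PSM level and aggregates to one row
#' per (sample, peptide): decoys are dropped; PSMs with absolute precursor
#' mass error above `config$max_mass_error_ppm` are dropped; PSMs with
#' posterior below `config$peptide_prob_min` are dropped; surviving spectra
#' are counted as the peptide's spectral count and the best posterior is
#' kept. Posteriors are taken from the `posterior` column when present
#' (precomputed passthrough), otherwise computed from `params`.
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @param params a fitted [fit_score_mixture()] (may be `NULL` when every
#'   PSM carries a precomputed posterior).
#' @param config a [specuniq_config()].
#' @return data.frame with columns `sample_id`, `peptide_seq`,
#'   `best_posterior`, `spectral_count`, `qvalue`, `local_fdr`.
#' @export
filter_and_rollup <- function(psms, params = NULL,
                              config = specuniq_config()) {
  post <- psms$posterior
  need <- is.na(post)
  if (any(need)) {
    if (is.null(params)) {
      stop("no precomputed posterior for some PSMs and no fitted mixture")
    }
    post[need] <- posterior_prob(params, psms$score[need])
  }
  q <- qvalues_from_decoys(psms$score, psms$is_decoy,
                           decoy_ratio = config$decoy_ratio)
  lfdr <- rep(NA_real_, nrow(psms))
  if (nrow(psms) >= 100L) {
    lfdr <- local_fdr_binned(psms$score, psms$is_decoy,
                             decoy_ratio = config$decoy_ratio)
  }
  keep <- !psms$is_decoy &
    abs(psms$mass_error_ppm) <= config$max_mass_error_ppm &
    post >= config$peptide_prob_min
  kept <- psms[keep, , drop = FALSE]
  if (!nrow(kept)) {
    return(data.frame(sample_id = character(), peptide_seq = character(),
                      best_posterior = numeric(), spectral_count = integer(),
                      qvalue = numeric(), local_fdr = numeric()))
  }
  kept$..post <- post[keep]
  kept$..q <- q[keep]
  kept$..lfdr <- lfdr[keep]
  key <- paste(kept$sample_id, kept$peptide_seq, sep = "\r")
  idx <- split(seq_len(nrow(kept)), key)
  rows <- lapply(idx, function(i) {
    best <- i[which.max(kept$..post[i])]
    data.frame(sample_id = kept$sample_id[best],
               peptide_seq = kept$peptide_seq[best],
               best_posterior = kept$..post[best],
               spectral_count = length(i),
               qvalue = min(kept$..q[i]),
               local_fdr = kept$..lfdr[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$peptide_seq), ]
}
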