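# Cohort statistics for the patient sheet: per-group mean +/- SD of age
# and BMI, and the two-group comparison. The printed p-values of the study
# this reproduces (age p = 0.188, BMI p = 0.041) are recovered by the
# unequal-variance (Welch) form, which is therefore the default; the
# pooled-variance Student form is available by flag.

#' Per-group summary of a cohort field
#'
#' @param samples sample sheet data.frame.
#' @param field `"age"` or `"bmi"`.
#' @return data.frame with `group`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator; 0 with a flag for singleton groups).
#' @export
summarize_cohort <- function(samples, field = c("age", "bmi")) {
  field <- match.arg(field)
  vals <- samples[[field]]
  if (anyNA(vals)) {
    stop("missing ", field, " for sample ",
         samples$sample_id[is.na(vals)][1])
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(samples)), samples$group),
    function(i) {
      v <- vals[i]
      data.frame(group = samples$group[i][1], n = length(v),
                 mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 singleton = length(v) == 1L,
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Two-group comparison of a cohort field
#'
#' Welch's unequal-variance t-test (default) or the pooled-variance
#' Student form, two-tailed.
#'
#' @param samples sample sheet data.frame.
#' @param field `"age"` or `"bmi"`.
#' @param pooled use the pooled-variance Student form.
#' @return list with `t`, `df`, `p` (cancer minus atrophic).
#' @export
#' @examples
#' sheet <- table1_samples()
#' welch_t(sheet, "bmi")$p  # rounds to 0.041
welch_t <- function(samples, field = c("age", "bmi"), pooled = FALSE) {
  field <- match.arg(field)
  x <- samples[[field]][samples$group == "cancer"]
  y <- samples[[field]][samples$group == "atrophic"]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 samples per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # t.test refuses constant data; the degenerate answer is exact
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2,
                p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' The study's eight-patient sample sheet
#'
#' The default cohort design: four post-menopausal atrophic (normal)
#' endometrium controls and four endometrial cancers (two endometrioid =
#' type 1, two serous = type 2), with the published ages and BMIs.
#'
#' @return sample-sheet data.frame.
#' @export
table1_samples <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("012", "015", "062", "069", "038", "075", "TA-01", "TA-02"),
    group = rep(c("atrophic", "cancer"), each = 4),
    subtype = c(rep("none", 4), "type1", "type1", "type2", "type2"),
    age = c(55, 65, 63, 57, 88, 74, 61, 61),
    bmi = c(19, 22, 26, 24, 24, 42, 38, 40),
    stringsAsFactors = FALSE))
}
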