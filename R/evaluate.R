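# Diagnostic scoring: region-majority sample diagnosis, cohort accuracy,
# and per-region concordance summaries.

#' Region-majority diagnosis of one sample
#'
#' A sample is scanned in several regions (8 at full scale); each region
#' receives a class call (or `"uncertain"`). The diagnosis is correct iff
#' strictly more than half of the standard 8 regions (> 4) agree with the
#' truth; uncertain calls count as non-agreement.
#'
#' @param region_calls character vector of per-region calls.
#' @param truth the true class.
#' @param n_regions expected number of regions (8 by default).
#' @param threshold minimum agreeing count that is still a misdiagnosis
#'   boundary: the verdict is correct iff agreement `> threshold`.
#' @return `"correct"` or `"misdiagnosis"`.
#' @export
diagnose_sample <- function(region_calls, truth, n_regions = 8L,
                            threshold = 4L) {
  if (length(region_calls) != n_regions)
    stop("expected ", n_regions, " region calls, got ", length(region_calls))
  agree <- sum(region_calls == truth)
  if (agree > threshold) "correct" else "misdiagnosis"
}

#' Cohort diagnostic accuracy
#'
#' @param diagnoses character vector of `"correct"` / `"misdiagnosis"`
#'   verdicts from [diagnose_sample()].
#' @return list with `fraction` (correct / total) and `percent` (the
#'   fraction as a percentage rounded to 1 decimal, the reporting
#'   convention for diagnostic accuracy).
#' @export
cohort_accuracy <- function(diagnoses) {
  if (length(diagnoses) == 0L) stop("no diagnoses supplied")
  frac <- mean(diagnoses == "correct")
  list(fraction = frac, percent = round(100 * frac, 1))
}

#' Per-region concordance table
#'
#' @param per_region_calls matrix `[n_samples, n_regions]` of class calls.
#' @param truths true class per sample (length `n_samples`).
#' @return list with `table` (one row per sample: agree / disagree /
#'   uncertain counts), `n_regions_total`, and the `overall` agreement
#'   fraction across all regions.
#' @export
region_concordance_table <- function(per_region_calls, truths) {
  if (!is.matrix(per_region_calls))
    per_region_calls <- matrix(per_region_calls, nrow = length(truths))
  if (nrow(per_region_calls) != length(truths))
    stop("call matrix and truth vector sizes do not match")
  n <- nrow(per_region_calls)
  tab <- data.frame(
    sample = seq_len(n), truth = truths,
    agree = vapply(seq_len(n), function(i)
      sum(per_region_calls[i, ] == truths[i]), 0L),
    uncertain = vapply(seq_len(n), function(i)
      sum(per_region_calls[i, ] == "uncertain"), 0L))
  tab$disagree <- ncol(per_region_calls) - tab$agree - tab$uncertain
  list(table = tab,
       n_regions_total = n * ncol(per_region_calls),
       overall = sum(tab$agree) / (n * ncol(per_region_calls)))
}
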