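#' Two-sided Fisher's exact test for 2x2 allele-count tables (vectorised)
#'
#' Computes the exact two-sided P-value for tables
#' `(a, b; c, d)` = (case copies, other case chromosomes; control copies,
#' other control chromosomes) by summing the hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed the
#' observed table's (the minimum-likelihood rule, the convention of the
#' classical exact test). The odds ratio is the sample `ad / bc` (possibly 0
#' or `Inf`).
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#' @return Tibble with columns `p_value`, `odds_ratio`, `testable`. A table
#'   with a zero margin (e.g. allele absent from the whole sample) has
#'   `p_value = 1`, `odds_ratio = NA`, `testable = FALSE`.
#' @export
#' @examples
#' fisher_exact(4, 1996, 0, 2000)  # ~0.1248, sum of the two extreme tables
fisher_exact <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("counts must be non-negative")
  p <- numeric(n); or <- numeric(n); testable <- logical(n)
  for (i in seq_len(n)) {
    k <- a[i] + c[i]           # first-column margin (allele copies)
    r1 <- a[i] + b[i]          # first-row margin (case chromosomes)
    tot <- r1 + c[i] + d[i]
    if (k == 0 || k == tot || r1 == 0 || r1 == tot) {
      p[i] <- 1; or[i] <- NA_real_; testable[i] <- FALSE
      next
    }
    lo <- max(0L, k - (tot - r1)); hi <- min(k, r1)
    dens <- dhyper(lo:hi, m = k, n = tot - k, k = r1)
    d_obs <- dens[a[i] - lo + 1L]
    p[i] <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
    or[i] <- (a[i] * d[i]) / (b[i] * c[i])
    testable[i] <- TRUE
  }
  tibble::tibble(p_value = p, odds_ratio = or, testable = testable)
}

#' Single-marker association tests on an ascertained cohort
#'
#' Performs the allelic Fisher's exact test per causal site: the 2x2 table
#' counts derived-allele copies versus other alleles among the `2 * n_cases`
#' case chromosomes and `2 * n_controls` control chromosomes. Sites
#' monomorphic in the combined sample are untestable (`p_value = 1`,
#' `testable = FALSE`).
#'
#' @param cohort A [make_cohort()] object.
#' @return An object of class `assoc_result`: tibble with per-site allele
#'   counts (`case_copies`, `control_copies`), `p_value`, `odds_ratio`,
#'   `testable`, `in_sample` (polymorphic in the combined sample), plus the
#'   architecture columns `s`, `p`, `alpha`; thresholds
#'   `1e-5`, `1e-2`, `5e-8` are the conventional cutoffs applied downstream.
#' @export
assoc_test <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  is_case <- cohort$phenotypes$label == "case"
  Z <- cohort$dosages
  m <- nrow(cohort$arch$sites)
  a <- cc <- numeric(m)
  a[cohort$site_index] <- colSums(Z[is_case, , drop = FALSE])
  cc[cohort$site_index] <- colSums(Z[!is_case, , drop = FALSE])
  n_case_chrom <- 2L * sum(is_case)
  n_ctrl_chrom <- 2L * sum(!is_case)
  ft <- fisher_exact(a, n_case_chrom - a, cc, n_ctrl_chrom - cc)
  res <- dplyr::bind_cols(
    cohort$arch$sites[c("site", "s", "p", "alpha")],
    tibble::tibble(case_copies = as.integer(a),
                   control_copies = as.integer(cc)),
    ft)
  res$in_sample <- (a + cc) > 0 & (a + cc) < (n_case_chrom + n_ctrl_chrom)
  class(res) <- c("assoc_result", class(res))
  res
}

#' Count significant causal SNPs at a P-value threshold
#'
#' @param results An [assoc_test()] result.
#' @param threshold P-value cutoff (the study's conventional cutoffs are
#'   `1e-5`, `1e-2` and `5e-8`).
#' @return Integer count of causal SNPs with `p_value < threshold`.
#' @export
count_significant <- function(results, threshold = 1e-5) {
  sum(results$p_value < threshold & results$testable, na.rm = TRUE)
}

#' Fraction of target additive variance explained below P-value thresholds
#'
#' For each threshold, sums `2 p (1 - p) alpha^2` (population frequencies)
#' over causal SNPs with association `p_value` below the threshold and
#' divides by the total target `V_A` over all causal SNPs. With
#' `threshold = 1` and `in_sample_only = TRUE` this is the share of `V_A`
#' carried by causal SNPs polymorphic in the case-control sample, which falls
#' short of 1 when rare causal SNPs are absent from the sample.
#'
#' @param results An [assoc_test()] result.
#' @param thresholds P-value thresholds (vector).
#' @param in_sample_only Restrict the numerator to SNPs polymorphic in the
#'   combined sample (untestable SNPs can never satisfy `p < threshold`
#'   anyway for thresholds <= 1, so this matters only at `threshold > 1`).
#' @return Tibble with `threshold`, `V_A_below`, `fraction` (of total target
#'   `V_A`); fractions are monotone non-decreasing in the threshold.
#' @export
va_explained_by_pvalue <- function(results,
                                   thresholds = c(5e-8, 1e-5, 1e-3, 0.01,
                                                  0.05, 0.1, 0.5, 1, 1.0001),
                                   in_sample_only = TRUE) {
  v <- 2 * results$p * (1 - results$p) * results$alpha^2
  V_A <- sum(v)
  sel_base <- if (in_sample_only) results$in_sample else rep(TRUE, nrow(results))
  out <- tibble::tibble(
    threshold = thresholds,
    V_A_below = vapply(thresholds, function(th)
      sum(v[sel_base & results$testable & results$p_value < th]), numeric(1)))
  # threshold > 1 means "every SNP present in the sample", testable or not
  big <- thresholds > 1
  out$V_A_below[big] <- sum(v[sel_base])
  out$fraction <- if (V_A > 0) out$V_A_below / V_A else NA_real_
  out
}

#' Detection power by site bin across replicates
#'
#' Bins causal sites by population frequency, odds ratio, or per-site
#' variance rank, and estimates, per bin, the fraction of replicates in which
#' at least one site in the bin reaches significance (conditional on the bin
#' being non-empty in that replicate).
#'
#' @param results_list List of [assoc_test()] results, one per replicate
#'   (>= 2).
#' @param bin_by `"frequency"`, `"odds_ratio"`, or `"va_rank"`.
#' @param breaks Bin breaks (frequencies, odds ratios, or rank boundaries).
#' @param threshold Significance threshold.
#' @return Tibble with `bin`, `n_replicates` (replicates with the bin
#'   occupied), `power`; bins never occupied have `power = NA`.
#' @export
power_by_bin <- function(results_list,
                         bin_by = c("frequency", "odds_ratio", "va_rank"),
                         breaks = NULL, threshold = 1e-5) {
  if (length(results_list) < 2) stop("need at least 2 replicates")
  bin_by <- match.arg(bin_by)
  breaks <- breaks %||% switch(bin_by,
    frequency = c(0, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1),
    odds_ratio = c(0, 1, 1.5, 2, 4, Inf),
    va_rank = c(0, 1, 5, 10, 25, Inf))
  per_rep <- purrr::imap_dfr(results_list, function(res, rep) {
    x <- switch(bin_by,
      frequency = res$p,
      odds_ratio = res$odds_ratio,
      va_rank = rank(-(2 * res$p * (1 - res$p) * res$alpha^2),
                     ties.method = "first"))
    tibble::tibble(
      rep = rep,
      bin = cut(x, breaks = breaks, include.lowest = TRUE),
      hit = res$p_value < threshold & res$testable)
  })
  per_rep <- per_rep[!is.na(per_rep$bin), ]
  dplyr::summarise(
    dplyr::group_by(per_rep, .data$bin, .drop = FALSE),
    n_replicates = dplyr::n_distinct(.data$rep),
    power = if (dplyr::n() == 0) NA_real_ else
      mean(vapply(split(.data$hit, .data$rep), any, logical(1))),
    .groups = "drop")
}
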