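#' Summarize a methylation-ratio distribution
#'
#' Five-number style summary of the per-site methylation ratios: n, mean,
#' minimum, maximum and the quartiles. In a coenocytic fungus with haploid
#' nuclei the per-site ratio estimates the fraction of nuclei carrying the
#' mark, so this distribution is the among-nucleus heterogeneity profile.
#' Quartiles use linear interpolation between order statistics at
#' `h = (n - 1) p + 1` (the default quantile definition of R).
#'
#' @param sites Symmetric-site data.frame, or a numeric vector of ratios.
#' @param sample_id Optional label stored alongside the summary.
#' @return data.frame with one row: `sample_id`, `n`, `mean`, `minimum`,
#'   `maximum`, `q1`, `q3`.
#' @export
summarize_ratios <- function(sites, sample_id = NA_character_) {
  r <- if (is.numeric(sites)) sites else sites$ratio
  if (length(r) == 0) stop("no ratios to summarize")
  q <- stats::quantile(r, c(0.25, 0.75), type = 7, names = FALSE)
  data.frame(sample_id = sample_id, n = length(r), mean = mean(r),
             minimum = min(r), maximum = max(r), q1 = q[1], q3 = q[2],
             stringsAsFactors = FALSE)
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact (conservative) two-sided interval for a binomial proportion via
#' beta quantiles: the lower limit at level `alpha/2` and the upper at
#' `1 - alpha/2`.
#'
#' @param k Successes (vectorized).
#' @param n Trials.
#' @param alpha Two-sided error rate (default 0.05, i.e. the 2.5% and 97.5%
#'   confidence limits).
#' @return matrix with columns `lower`, `upper`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  lower <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(lower = lower, upper = upper)
}

#' Compare per-site methylation ratios between two samples
#'
#' Sites are matched by (contig, apt_start); only shared sites are compared.
#' For each sample the effective methylated-molecule count is
#' `k = round(ratio x total coverage)` over both strands, and a
#' Clopper-Pearson interval at the `alpha/2` and `1 - alpha/2` limits is
#' computed. A site is flagged divergent iff the two intervals are disjoint.
#' No multiple-testing correction is applied by default, mirroring the raw
#' per-site rule; `adjust = "BH"` instead flags sites whose
#' Benjamini-Hochberg-adjusted two-sided Fisher p-values fall below `alpha`.
#'
#' @param sites_a,sites_b Symmetric-site data.frames.
#' @param alpha Two-sided level for the intervals (default 0.05).
#' @param adjust `"none"` (interval disjointness, default) or `"BH"`.
#' @return list with `comparisons` (one row per shared site: `contig`,
#'   `apt_start`, `ratio_a`, `ratio_b`, `ci_a_low`, `ci_a_high`, `ci_b_low`,
#'   `ci_b_high`, `divergent`), `n_shared`, and `divergent_fraction`
#'   (percent of shared sites flagged divergent).
#' @export
compare_ratios <- function(sites_a, sites_b, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- merge(sites_a, sites_b, by = c("contig", "apt_start"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared sites between the two samples")
  cov_a <- m$plus_cov_a + m$minus_cov_a
  cov_b <- m$plus_cov_b + m$minus_cov_b
  k_a <- round(m$ratio_a * cov_a)
  k_b <- round(m$ratio_b * cov_b)
  ci_a <- clopper_pearson(k_a, cov_a, alpha)
  ci_b <- clopper_pearson(k_b, cov_b, alpha)
  if (adjust == "none") {
    divergent <- ci_a[, "upper"] < ci_b[, "lower"] |
                 ci_b[, "upper"] < ci_a[, "lower"]
  } else {
    p <- vapply(seq_len(nrow(m)), function(i) {
      stats::fisher.test(matrix(c(k_a[i], cov_a[i] - k_a[i],
                                  k_b[i], cov_b[i] - k_b[i]), 2))$p.value
    }, numeric(1))
    divergent <- stats::p.adjust(p, method = "BH") < alpha
  }
  comparisons <- data.frame(contig = m$contig, apt_start = m$apt_start,
                            ratio_a = m$ratio_a, ratio_b = m$ratio_b,
                            ci_a_low = ci_a[, "lower"],
                            ci_a_high = ci_a[, "upper"],
                            ci_b_low = ci_b[, "lower"],
                            ci_b_high = ci_b[, "upper"],
                            divergent = divergent,
                            stringsAsFactors = FALSE)
  list(comparisons = comparisons, n_shared = nrow(m),
       divergent_fraction = 100 * mean(divergent))
}

#' Coverage dependence of the methylation ratio
#'
#' Kendall tau-b (with tie correction) between total site coverage and the
#' site methylation ratio, with a two-sided p-value. A negligible tau
#' indicates the ratio estimates are not an artefact of sequencing depth.
#'
#' @param sites Symmetric-site data.frame.
#' @return list with `tau`, `p`, `n`.
#' @export
ratio_coverage_dependence <- function(sites) {
  cov <- sites$plus_cov + sites$minus_cov
  n <- nrow(sites)
  if (n < 10) {
    warning("ratio_coverage_dependence on n = ", n,
            " sites; tau and p are uninformative at this size")
  }
  ct <- suppressWarnings(
    stats::cor.test(cov, sites$ratio, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, n = n)
}
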