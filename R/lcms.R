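#' Percent methylation from nucleoside quantities
#'
#' From LC-MS quantities in nM: percent 6mA is
#' `100 * m6dA / (dA + m6dA)` and percent 5mC is
#' `100 * m5dC / (dC + m5dC)` — methylated nucleoside over total
#' (methylated plus unmethylated) of the same base. Both are invariant to
#' rescaling all quantities of a replicate.
#'
#' @param quants data.frame with columns `dC_nM`, `m5dC_nM`, `dA_nM`,
#'   `m6dA_nM` (one row per replicate), e.g. from [read_nucleosides()].
#' @return data.frame `quants` with added columns `pct_6mA`, `pct_5mC`.
#' @export
percent_methylation <- function(quants) {
  denom_a <- quants$dA_nM + quants$m6dA_nM
  denom_c <- quants$dC_nM + quants$m5dC_nM
  if (any(denom_a == 0) || any(denom_c == 0)) {
    stop("replicate with zero total adenine or cytosine quantity")
  }
  quants$pct_6mA <- 100 * quants$m6dA_nM / denom_a
  quants$pct_5mC <- 100 * quants$m5dC_nM / denom_c
  quants
}

#' Aggregate replicate percentages per sample
#'
#' Computes per-replicate percentages and averages them per sample
#' (unweighted mean of percentages, which is invariant to per-replicate
#' dilution; the percentage of summed quantities is also reported for
#' comparison). Replicates with a zero denominator are excluded with a
#' warning.
#'
#' @param quants Nucleoside data.frame ([read_nucleosides()]).
#' @return data.frame with one row per sample: `sample_id`, `pct_6mA`,
#'   `pct_5mC`, `pct_6mA_pooled`, `pct_5mC_pooled`, `n_replicates`.
#' @export
aggregate_replicates <- function(quants) {
  bad <- (quants$dA_nM + quants$m6dA_nM) == 0 |
         (quants$dC_nM + quants$m5dC_nM) == 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with zero denominator excluded")
    quants <- quants[!bad, , drop = FALSE]
  }
  if (nrow(quants) == 0) stop("no usable replicates")
  pq <- percent_methylation(quants)
  out <- do.call(rbind, lapply(split(pq, pq$sample_id), function(g) {
    data.frame(sample_id = g$sample_id[1],
               pct_6mA = mean(g$pct_6mA),
               pct_5mC = mean(g$pct_5mC),
               pct_6mA_pooled = 100 * sum(g$m6dA_nM) /
                 sum(g$dA_nM + g$m6dA_nM),
               pct_5mC_pooled = 100 * sum(g$m5dC_nM) /
                 sum(g$dC_nM + g$m5dC_nM),
               n_replicates = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
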