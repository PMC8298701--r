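#' Filter modification calls by coverage and detection p-value
#'
#' Retains calls with per-strand coverage at or above `min_coverage` and
#' detection p-value at or below `max_p` (both thresholds inclusive, so a
#' call at exactly 25x / p = 0.001 survives). Raw and retained counts are
#' attached as attributes `n_raw` and `n_filtered`.
#'
#' @param calls Modification-call data.frame ([read_modcalls()]).
#' @param min_coverage Minimum per-strand coverage (default 25).
#' @param max_p Maximum detection p-value (default 0.001).
#' @return The retained subset, same columns.
#' @export
filter_calls <- function(calls, min_coverage = 25, max_p = 0.001) {
  keep <- calls$coverage >= min_coverage & calls$p_value <= max_p
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_raw") <- nrow(calls)
  attr(out, "n_filtered") <- nrow(out)
  out
}

# Split a genome into per-contig character vectors for base lookups.
genome_chars <- function(genome) {
  lapply(stats::setNames(as.character(genome), names(genome)),
         function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

#' Call symmetric ApT 6mA sites
#'
#' A plus-strand call at forward position `i` and a minus-strand call at
#' `i + 1` form one symmetric site iff the forward-strand bases at
#' `(i, i + 1)` are `A, T` — the ApT dinucleotide, whose reverse complement
#' is again ApT, so both strands carry a methylatable adenine. Each call
#' participates in at most one site (the partner position is unique, so the
#' pairing is deterministic). Remaining calls are labelled asymmetric-ApT
#' (an ApT context methylated on one strand only) or non-ApT. Calls whose
#' strand base is not an adenine (forward base not A for plus calls, not T
#' for minus calls), including calls on N, are excluded with a warning.
#'
#' The site ratio is the coverage-weighted mean of the two strand fractions;
#' `motif4` is the forward-strand 4-mer covering positions
#' `apt_start - 1 .. apt_start + 2` (N-padded at contig edges).
#'
#' @param calls Filtered modification calls.
#' @param genome [Biostrings::DNAStringSet] covering every call position.
#' @return A list with elements `sites` (data.frame: `contig`, `apt_start`,
#'   `ratio`, `motif4`, `plus_cov`, `minus_cov`, `plus_frac`, `minus_frac`),
#'   `asymmetric` and `non_apt` (call subsets), and `n_excluded`.
#' @export
call_symmetric_sites <- function(calls, genome) {
  chars <- genome_chars(genome)
  if (!all(calls$contig_id %in% names(chars))) {
    stop("call on contig absent from genome: ",
         paste(setdiff(unique(calls$contig_id), names(chars)), collapse = ", "))
  }
  clen <- vapply(chars, length, integer(1))
  if (any(calls$position < 0 | calls$position >= clen[calls$contig_id])) {
    stop("call position outside its contig")
  }
  base_at <- function(contig, pos) {
    # pos 0-based, vectorized; out-of-range -> "N"
    out <- rep("N", length(pos))
    ok <- pos >= 0 & pos < clen[contig]
    idx <- which(ok)
    if (length(idx)) {
      out[idx] <- mapply(function(ct, p) chars[[ct]][p + 1L],
                         contig[idx], pos[idx], USE.NAMES = FALSE)
    }
    out
  }
  fb <- base_at(calls$contig_id, calls$position)
  valid <- (calls$strand == "+" & fb == "A") |
           (calls$strand == "-" & fb == "T")
  n_excluded <- sum(!valid)
  if (n_excluded > 0) {
    warning(n_excluded,
            " call(s) whose strand base is not adenine were excluded")
  }
  calls <- calls[valid, , drop = FALSE]
  fb <- fb[valid]

  plus <- calls[calls$strand == "+", , drop = FALSE]
  minus <- calls[calls$strand == "-", , drop = FALSE]
  # ApT context tests on the forward strand
  plus_apt <- base_at(plus$contig_id, plus$position + 1L) == "T"
  minus_apt <- base_at(minus$contig_id, minus$position - 1L) == "A"

  pa <- plus[plus_apt, , drop = FALSE]
  ma <- minus[minus_apt, , drop = FALSE]
  key_p <- paste(pa$contig_id, pa$position, sep = ":")
  key_m <- paste(ma$contig_id, ma$position - 1L, sep = ":")
  i_p <- match(key_m, key_p)           # minus call -> its plus partner
  paired_m <- !is.na(i_p)
  pm <- i_p[paired_m]                  # row in pa for each paired minus call

  pp <- pa[pm, , drop = FALSE]
  mm <- ma[paired_m, , drop = FALSE]
  tot <- pp$coverage + mm$coverage
  ratio <- as.numeric(ifelse(
    tot > 0,
    (pp$coverage * pp$fraction + mm$coverage * mm$fraction) / tot,
    (pp$fraction + mm$fraction) / 2))
  motif4 <- paste0(base_at(pp$contig_id, pp$position - 1L),
                   base_at(pp$contig_id, pp$position),
                   base_at(pp$contig_id, pp$position + 1L),
                   base_at(pp$contig_id, pp$position + 2L))
  sites <- data.frame(contig = pp$contig_id,
                      apt_start = pp$position,
                      ratio = ratio,
                      motif4 = motif4,
                      plus_cov = pp$coverage,
                      minus_cov = mm$coverage,
                      plus_frac = pp$fraction,
                      minus_frac = mm$fraction,
                      stringsAsFactors = FALSE)
  if (nrow(sites) > 1) {
    sites <- sites[order(sites$contig, sites$apt_start), , drop = FALSE]
  }
  rownames(sites) <- NULL

  paired_p <- seq_len(nrow(pa)) %in% pm
  asym <- rbind(pa[!paired_p, , drop = FALSE], ma[!paired_m, , drop = FALSE])
  non_apt <- rbind(plus[!plus_apt, , drop = FALSE],
                   minus[!minus_apt, , drop = FALSE])
  rownames(asym) <- NULL
  rownames(non_apt) <- NULL
  list(sites = sites, asymmetric = asym, non_apt = non_apt,
       n_excluded = n_excluded)
}

#' Motif spectrum of symmetric sites
#'
#' Occurrence probability of each forward-strand 4-mer context among
#' symmetric ApT sites, sorted in decreasing abundance. AATT is
#' self-reverse-complementary; other contexts (e.g. CATT and AATG) are
#' reverse complements of each other and counted separately.
#'
#' @param sites Symmetric-site data.frame.
#' @return Named numeric vector of probabilities summing to 1 (empty for an
#'   empty site set).
#' @export
motif_spectrum <- function(sites) {
  if (nrow(sites) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(sites$motif4)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Percent of adenines methylated
#'
#' 100 x (distinct methylated adenine strand-positions) / (total adenines on
#' both strands). The denominator counts forward-strand A plus forward-strand
#' T (each T is an adenine on the reverse strand); the numerator counts
#' distinct (contig, position, strand) call coordinates among valid calls.
#'
#' @param calls Filtered modification calls.
#' @param genome [Biostrings::DNAStringSet].
#' @return Percent in `[0, 100]`.
#' @export
global_methylation_percent <- function(calls, genome) {
  freq <- Biostrings::letterFrequency(genome, c("A", "T"))
  denom <- sum(freq)
  if (denom == 0) return(0)
  if (nrow(calls) == 0) return(0)
  key <- unique(paste(calls$contig_id, calls$position, calls$strand))
  100 * length(key) / denom
}

#' Summarize a sample's 6mA methylome
#'
#' Applies [filter_calls()], calls symmetric sites, and assembles the
#' headline per-sample numbers: raw/filtered call counts, the partition of
#' filtered calls into symmetric / asymmetric-ApT / non-ApT, the percent of
#' adenines methylated, the percent of filtered calls participating in
#' symmetric ApT pairs, and the motif spectrum.
#'
#' @param calls Raw modification calls.
#' @param genome [Biostrings::DNAStringSet].
#' @param min_coverage,max_p Passed to [filter_calls()].
#' @return A list of class `methylome_summary` with fields `n_calls_raw`,
#'   `n_calls_filtered`, `n_excluded`, `n_symmetric_sites`,
#'   `n_asymmetric_calls`, `n_non_apt_calls`, `pct_adenine_methylated`,
#'   `pct_symmetric_apt`, `motif_spectrum`, `sites`.
#' @export
methylome_summary <- function(calls, genome, min_coverage = 25,
                              max_p = 0.001) {
  filt <- filter_calls(calls, min_coverage, max_p)
  res <- call_symmetric_sites(filt, genome)
  n_valid <- nrow(filt) - res$n_excluded
  out <- list(
    n_calls_raw = nrow(calls),
    n_calls_filtered = nrow(filt),
    n_excluded = res$n_excluded,
    n_symmetric_sites = nrow(res$sites),
    n_asymmetric_calls = nrow(res$asymmetric),
    n_non_apt_calls = nrow(res$non_apt),
    pct_adenine_methylated = global_methylation_percent(filt, genome),
    pct_symmetric_apt = if (n_valid > 0) 100 * 2 * nrow(res$sites) / n_valid
                        else 0,
    motif_spectrum = motif_spectrum(res$sites),
    sites = res$sites)
  class(out) <- "methylome_summary"
  out
}

#' @export
print.methylome_summary <- function(x, ...) {
  cat("6mA methylome summary\n")
  cat(sprintf("  calls: %d raw, %d pass filters (%d excluded on base check)\n",
              x$n_calls_raw, x$n_calls_filtered, x$n_excluded))
  cat(sprintf("  symmetric ApT sites: %d (%.1f%% of filtered calls paired)\n",
              x$n_symmetric_sites, x$pct_symmetric_apt))
  cat(sprintf("  asymmetric-ApT calls: %d; non-ApT calls: %d\n",
              x$n_asymmetric_calls, x$n_non_apt_calls))
  cat(sprintf("  adenines methylated: %.4f%%\n", x$pct_adenine_methylated))
  if (length(x$motif_spectrum) > 0) {
    top <- utils::head(x$motif_spectrum, 5)
    cat("  top motifs:",
        paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}
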