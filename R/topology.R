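#' Assign symmetric sites to gene regions
#'
#' Each site is placed in exactly one region relative to the annotation: for
#' a plus-strand gene spanning `[s, e)`, the promoter is the `flank` bp
#' upstream `[s - flank, s)`, the gene body `[s, e)`, and the downstream
#' region `[e, e + flank)`; for a minus-strand gene the promoter and
#' downstream windows are mirrored (upstream is rightward). Sites outside
#' every gene's extended window are intergenic. A site falling in the
#' windows of several genes is assigned to the gene with the nearest
#' annotated start (leftmost gene on ties); the number of overlapping genes
#' is kept in `n_genes_overlapping`.
#'
#' @param sites Symmetric-site data.frame.
#' @param genes Gene-model data.frame ([read_genes()]).
#' @param flank Promoter/downstream window width in bp (default 500).
#' @return data.frame with `contig`, `apt_start`, `region` (one of
#'   `promoter`, `gene_body`, `downstream`, `intergenic`), `gene_id`
#'   (NA for intergenic) and `n_genes_overlapping`. Region fractions are
#'   attached as attribute `region_fractions`.
#' @export
assign_regions <- function(sites, genes, flank = 500) {
  n <- nrow(sites)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  n_over <- integer(n)
  if (n > 0 && nrow(genes) > 0) {
    for (ctg in unique(sites$contig)) {
      si <- which(sites$contig == ctg)
      gi <- which(genes$contig_id == ctg)
      if (length(gi) == 0) next
      g <- genes[gi, , drop = FALSE]
      q <- IRanges::IRanges(start = sites$apt_start[si] + 1L, width = 1L)
      w <- IRanges::IRanges(start = pmax(g$start - flank, 0L) + 1L,
                            end = g$end + flank)
      hits <- IRanges::findOverlaps(q, w)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      if (length(qh) == 0) next
      n_over[si] <- tabulate(qh, nbins = length(si))
      # pick the gene with the nearest annotated start per site
      pos <- sites$apt_start[si][qh]
      d <- abs(pos - g$start[sh])
      ord <- order(qh, d, g$start[sh])
      keep <- ord[!duplicated(qh[ord])]
      qs <- qh[keep]; gs <- sh[keep]
      p <- sites$apt_start[si][qs]
      s <- g$start[gs]; e <- g$end[gs]; str <- g$strand[gs]
      reg <- ifelse(p >= s & p < e, "gene_body",
             ifelse(p < s,
                    ifelse(str == "+", "promoter", "downstream"),
                    ifelse(str == "+", "downstream", "promoter")))
      region[si[qs]] <- reg
      gene_id[si[qs]] <- g$gene_id[gs]
    }
  }
  out <- data.frame(contig = sites$contig, apt_start = sites$apt_start,
                    region = region, gene_id = gene_id,
                    n_genes_overlapping = n_over, stringsAsFactors = FALSE)
  lev <- c("promoter", "gene_body", "downstream", "intergenic")
  frac <- if (n > 0) as.numeric(table(factor(region, lev))) / n
          else rep(NA_real_, 4)
  attr(out, "region_fractions") <- stats::setNames(frac, lev)
  out
}

#' Per-gene methylation calls
#'
#' A gene is considered methylated iff it harbors at least one symmetric ApT
#' site within its annotated body; the methylation density is the number of
#' body sites divided by the gene length in bp. Promoter-window sites are
#' counted separately and do not make a gene methylated (flip with
#' `include_promoter = TRUE`).
#'
#' @param sites Symmetric-site data.frame.
#' @param genes Gene-model data.frame.
#' @param flank Promoter window width used for the promoter count.
#' @param include_promoter If TRUE, promoter sites also count toward the
#'   methylated call (not toward density).
#' @return data.frame with `gene_id`, `n_apt_sites` (body), `n_promoter_sites`,
#'   `length`, `density` (sites per bp), `methylated`. The percent of genes
#'   methylated is attached as attribute `pct_genes_methylated`.
#' @export
call_gene_methylation <- function(sites, genes, flank = 500,
                                  include_promoter = FALSE) {
  n_body <- integer(nrow(genes))
  n_prom <- integer(nrow(genes))
  for (ctg in unique(genes$contig_id)) {
    gi <- which(genes$contig_id == ctg)
    si <- which(sites$contig == ctg)
    if (length(si) == 0) next
    p <- sites$apt_start[si]
    g <- genes[gi, , drop = FALSE]
    q <- IRanges::IRanges(start = p + 1L, width = 1L)
    body <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    hb <- IRanges::findOverlaps(q, body)
    n_body[gi] <- tabulate(S4Vectors::subjectHits(hb), nbins = length(gi))
    prom <- IRanges::IRanges(
      start = ifelse(g$strand == "+", pmax(g$start - flank, 0L), g$end) + 1L,
      end = ifelse(g$strand == "+", g$start, g$end + flank))
    hp <- IRanges::findOverlaps(q, prom)
    n_prom[gi] <- tabulate(S4Vectors::subjectHits(hp), nbins = length(gi))
  }
  len <- genes$end - genes$start
  methylated <- if (include_promoter) n_body + n_prom >= 1 else n_body >= 1
  out <- data.frame(gene_id = genes$gene_id, n_apt_sites = n_body,
                    n_promoter_sites = n_prom, length = len,
                    density = n_body / len, methylated = methylated,
                    stringsAsFactors = FALSE)
  attr(out, "pct_genes_methylated") <-
    if (nrow(out) > 0) 100 * mean(out$methylated) else NA_real_
  out
}

#' Compare methylated gene sets across samples
#'
#' Computes every exclusive region of the k-sample Venn diagram of
#' methylated gene ids, plus the union and the core (genes methylated in all
#' samples).
#'
#' @param gene_sets Named list of character vectors (methylated gene ids per
#'   sample), or a named list of [call_gene_methylation()] frames.
#' @return list with `regions` (named counts, names like `"a&b"` for genes
#'   exactly in samples a and b), `union`, `core`, `set_sizes`.
#' @export
compare_gene_sets <- function(gene_sets) {
  sets <- lapply(gene_sets, function(x) {
    if (is.data.frame(x)) unique(x$gene_id[x$methylated]) else unique(x)
  })
  k <- length(sets)
  if (k < 2) stop("need at least two gene sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("s", seq_len(k))
  }
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  regions <- table(pattern)
  # order patterns by number of samples then name, all 2^k - 1 listed
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  counts[names(regions)] <- as.integer(regions)
  list(regions = counts,
       union = length(all_ids),
       core = sum(rowSums(member) == k),
       set_sizes = vapply(sets, length, integer(1)))
}

#' Methylation density versus expression
#'
#' Kendall's tau-b (with tie correction) between gene-body 6mA density and
#' FPKM over methylated genes, with a two-sided p-value (exact small-sample
#' distribution where available, tie-corrected normal approximation
#' otherwise). Also tabulates methylated/unmethylated gene counts above and
#' below the `fpkm_high` expression cutoff. Genes without an expression
#' record are dropped (count attached).
#'
#' @param gene_meth [call_gene_methylation()] frame.
#' @param expr Expression data.frame (`gene_id`, `fpkm`).
#' @param fpkm_high Expression cutoff for the group table (default 5).
#' @return list with `tau`, `p`, `n` (methylated genes tested), `groups`
#'   (2x2 counts), `n_dropped`.
#' @export
expression_link <- function(gene_meth, expr, fpkm_high = 5) {
  m <- merge(gene_meth, expr, by = "gene_id")
  n_dropped <- nrow(gene_meth) - nrow(m)
  meth <- m[m$methylated, , drop = FALSE]
  if (nrow(meth) < 2) stop("fewer than 2 methylated genes with expression")
  ct <- suppressWarnings(
    stats::cor.test(meth$density, meth$fpkm, method = "kendall"))
  groups <- table(methylated = m$methylated,
                  high_expression = m$fpkm > fpkm_high)
  list(tau = unname(ct$estimate), p = ct$p.value, n = nrow(meth),
       groups = groups, n_dropped = n_dropped)
}
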