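#' Filter an SV callset
#'
#' Removes translocations (class TRA) and variants with low read support
#' (`read_support < min_support`; the inequality is strict, so RE = 15
#' survives the default). Removed counts are attached as attributes
#' `n_dropped_tra` and `n_dropped_support`.
#'
#' @param svs SV data.frame ([read_sv_vcf()]).
#' @param min_support Minimum read support (default 15).
#' @return Filtered SV data.frame.
#' @export
filter_svs <- function(svs, min_support = 15) {
  is_tra <- svs$sv_class == "TRA"
  low <- svs$read_support < min_support
  out <- svs[!is_tra & !low, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_tra") <- sum(is_tra)
  attr(out, "n_dropped_support") <- sum(low & !is_tra)
  out
}

#' Match two SV callsets by reciprocal overlap
#'
#' Records are treated as intervals `[position, position + length)`
#' (insertions included, using their SVLEN-derived length). A pair matches
#' when both records are on the same contig, of the same class, and the
#' shared span is at least `reciprocal` of BOTH lengths. Matching is greedy
#' one-to-one in descending overlap order (ties broken by leftmost
#' position), so no record is counted twice.
#'
#' @param a,b Filtered SV data.frames.
#' @param reciprocal Minimum reciprocal overlap fraction (default 0.8).
#' @return data.frame with `sv_id_a`, `sv_id_b`, `overlap_bp`, `frac_a`,
#'   `frac_b`.
#' @export
match_callsets <- function(a, b, reciprocal = 0.8) {
  empty <- data.frame(sv_id_a = character(), sv_id_b = character(),
                      overlap_bp = integer(), frac_a = numeric(),
                      frac_b = numeric(), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  ia <- rep(seq_len(nrow(a)), times = nrow(b))
  ib <- rep(seq_len(nrow(b)), each = nrow(a))
  same <- a$contig_id[ia] == b$contig_id[ib] &
          a$sv_class[ia] == b$sv_class[ib]
  ia <- ia[same]; ib <- ib[same]
  if (length(ia) == 0) return(empty)
  sa <- a$position[ia]; ea <- sa + a$length[ia]
  sb <- b$position[ib]; eb <- sb + b$length[ib]
  ov <- pmin(ea, eb) - pmax(sa, sb)
  fa <- ov / a$length[ia]
  fb <- ov / b$length[ib]
  keep <- ov > 0 & fa >= reciprocal & fb >= reciprocal
  ia <- ia[keep]; ib <- ib[keep]; ov <- ov[keep]
  fa <- fa[keep]; fb <- fb[keep]
  if (length(ia) == 0) return(empty)
  ord <- order(-ov, pmin(a$position[ia], b$position[ib]), ia, ib)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  take <- logical(length(ord))
  for (j in ord) {
    if (!used_a[ia[j]] && !used_b[ib[j]]) {
      take[j] <- TRUE
      used_a[ia[j]] <- TRUE
      used_b[ib[j]] <- TRUE
    }
  }
  data.frame(sv_id_a = a$sv_id[ia[take]], sv_id_b = b$sv_id[ib[take]],
             overlap_bp = ov[take], frac_a = fa[take], frac_b = fb[take],
             stringsAsFactors = FALSE)
}

#' Pairwise Jaccard distances between SV callsets
#'
#' For callsets A and B with m matched variants, the distance is
#' `1 - m / (|A| + |B| - m)`; identical callsets give 0, disjoint callsets 1.
#'
#' @param callsets Named list of filtered SV data.frames.
#' @param reciprocal Passed to [match_callsets()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jaccard_matrix <- function(callsets, reciprocal = 0.8) {
  k <- length(callsets)
  if (is.null(names(callsets))) names(callsets) <- paste0("s", seq_len(k))
  d <- matrix(0, k, k, dimnames = list(names(callsets), names(callsets)))
  if (k < 2) return(d)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m <- nrow(match_callsets(callsets[[i]], callsets[[j]], reciprocal))
      u <- nrow(callsets[[i]]) + nrow(callsets[[j]]) - m
      d[i, j] <- d[j, i] <- if (u == 0) 0 else 1 - m / u
    }
  }
  d
}

#' Locus-presence matrix across SV callsets
#'
#' Groups variants from all callsets into shared loci: each variant joins
#' the first existing locus whose representative interval it matches (same
#' contig and class, reciprocal overlap at least `reciprocal`), otherwise it
#' founds a new locus. The result is a samples x loci 0/1 matrix used for
#' bootstrap resampling.
#'
#' @param callsets Named list of filtered SV data.frames.
#' @param reciprocal Reciprocal-overlap threshold.
#' @return Binary matrix, rows = samples, columns = loci.
#' @export
sv_presence_matrix <- function(callsets, reciprocal = 0.8) {
  k <- length(callsets)
  if (is.null(names(callsets))) names(callsets) <- paste0("s", seq_len(k))
  reps <- data.frame(contig_id = character(), sv_class = character(),
                     position = integer(), length = integer(),
                     stringsAsFactors = FALSE)
  pres <- list()
  for (s in seq_len(k)) {
    cs <- callsets[[s]]
    hit <- integer(0)
    for (r in seq_len(nrow(cs))) {
      cand <- which(reps$contig_id == cs$contig_id[r] &
                    reps$sv_class == cs$sv_class[r])
      loc <- 0L
      if (length(cand) > 0) {
        sa <- cs$position[r]; ea <- sa + cs$length[r]
        sb <- reps$position[cand]; eb <- sb + reps$length[cand]
        ov <- pmin(ea, eb) - pmax(sa, sb)
        ok <- ov > 0 & ov / cs$length[r] >= reciprocal &
              ov / reps$length[cand] >= reciprocal
        if (any(ok)) loc <- cand[which(ok)[1]]
      }
      if (loc == 0L) {
        reps <- rbind(reps, data.frame(contig_id = cs$contig_id[r],
                                       sv_class = cs$sv_class[r],
                                       position = cs$position[r],
                                       length = cs$length[r],
                                       stringsAsFactors = FALSE))
        loc <- nrow(reps)
      }
      hit <- c(hit, loc)
    }
    pres[[s]] <- unique(hit)
  }
  mat <- matrix(0L, k, nrow(reps),
                dimnames = list(names(callsets), NULL))
  for (s in seq_len(k)) mat[s, pres[[s]]] <- 1L
  mat
}

jaccard_from_presence <- function(pres) {
  k <- nrow(pres)
  d <- matrix(0, k, k, dimnames = list(rownames(pres), rownames(pres)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      inter <- sum(pres[i, ] & pres[j, ])
      uni <- sum(pres[i, ] | pres[j, ])
      d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
    }
  }
  d
}

hclust_bipartitions <- function(hc) {
  # tip-label sets under each internal node of an hclust tree
  labs <- hc$labels
  n <- length(labs)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- function(x) {
      if (x < 0) return(labs[-x])
      c(sets[[x]])
    }
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

#' Cluster SV callsets with bootstrap support
#'
#' Average-linkage hierarchical clustering of samples on their Jaccard
#' distances, with node support estimated by an ordinary bootstrap over SV
#' loci: locus columns of the presence matrix are resampled with
#' replacement, Jaccard distances and the tree are recomputed, and a node's
#' support is the percent of resamples in which the same sample bipartition
#' recurs. (This approximates, but is not identical to, multiscale bootstrap
#' procedures.)
#'
#' @param dist_matrix Jaccard distance matrix ([jaccard_matrix()]).
#' @param presence Locus-presence matrix ([sv_presence_matrix()]).
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed for the resampling.
#' @return list with `hclust`, `phylo` (an [ape::phylo] whose node labels
#'   are support percentages), and `support` (named by the node's sample
#'   set, e.g. `"a+b"`).
#' @export
cluster_with_bootstrap <- function(dist_matrix, presence, n_boot = 10000,
                                   seed = 1) {
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  parts <- hclust_bipartitions(hc)
  keys <- vapply(parts, paste, character(1), collapse = "+")
  hits <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  n_loci <- ncol(presence)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(n_loci, n_loci, replace = TRUE)
    db <- jaccard_from_presence(presence[, cols, drop = FALSE])
    hb <- stats::hclust(stats::as.dist(db), method = "average")
    kb <- vapply(hclust_bipartitions(hb), paste, character(1),
                 collapse = "+")
    hits[keys %in% kb] <- hits[keys %in% kb] + 1
  }
  support <- 100 * hits / n_boot
  phy <- ape::as.phylo(hc)
  # ape orders internal nodes in its own way; map via clade membership
  phy_parts <- ape::prop.part(phy)
  phy_keys <- vapply(phy_parts, function(idx)
    paste(sort(phy$tip.label[idx]), collapse = "+"), character(1))
  phy$node.label <- sprintf("%.0f", support[phy_keys])
  list(hclust = hc, phylo = phy, support = support)
}

#' Annotate SVs against interval annotations and genes
#'
#' A variant is TE-related iff either breakpoint (`position` or
#' `position + length`) falls within an annotated repeat interval — span
#' overlap without a contained breakpoint does not qualify. Gene hits are
#' genes whose annotated span intersects the SV interval.
#'
#' @param svs Filtered SV data.frame.
#' @param annotations Interval data.frame (`contig_id`, `start`, `end`;
#'   0-based half-open, e.g. from [read_bed()]).
#' @param genes Optional gene-model data.frame.
#' @return `svs` with added columns `te_related` and (when `genes` given)
#'   `gene_hits` (comma-separated ids, `""` when none).
#' @export
annotate_svs <- function(svs, annotations, genes = NULL) {
  in_interval <- function(contig, pos) {
    vapply(seq_along(pos), function(i) {
      any(annotations$contig_id == contig[i] &
          annotations$start <= pos[i] & pos[i] < annotations$end)
    }, logical(1))
  }
  bp2 <- svs$position + svs$length
  svs$te_related <- in_interval(svs$contig_id, svs$position) |
                    in_interval(svs$contig_id, bp2)
  if (!is.null(genes)) {
    svs$gene_hits <- vapply(seq_len(nrow(svs)), function(i) {
      hit <- genes$contig_id == svs$contig_id[i] &
             genes$start < svs$position[i] + svs$length[i] &
             svs$position[i] < genes$end
      paste(genes$gene_id[hit], collapse = ",")
    }, character(1))
  }
  svs
}
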