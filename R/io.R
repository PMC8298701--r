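#' Read a genome from FASTA
#'
#' Loads every record of a FASTA file as an uppercase DNA sequence. Contig
#' ids are taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names, sequences
#'   uppercased.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate contig id(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) < 1)) {
    stop("zero-length sequence in ", path)
  }
  # DNAStringSet is already uppercase by construction
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Retains features of type `gene` and converts the 1-based inclusive GFF3
#' coordinates to the package-internal 0-based half-open convention
#' (`start = GFF start - 1`, `end = GFF end`).
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_genes <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  id <- if (is.null(g$ID)) rep(NA_character_, nrow(g)) else as.character(g$ID)
  if (any(is.na(id) | id == "")) {
    stop("gene feature without an ID attribute in ", path)
  }
  if (any(g$end < g$start)) {
    stop("gene with end < start in ", path, ": ",
         paste(id[g$end < g$start], collapse = ", "))
  }
  if (anyDuplicated(id)) stop("duplicate gene id(s) in ", path)
  out <- data.frame(gene_id = id,
                    contig_id = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene models to GFF3
#'
#' Inverse of [read_genes()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive.
#'
#' @param genes Gene model data.frame as returned by [read_genes()].
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmethApT\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig_id, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

modcall_cols <- c("contig_id", "position", "strand", "mod_type",
                  "coverage", "p_value", "fraction")

validate_modcalls <- function(calls) {
  if (any(calls$coverage < 0)) stop("modification call with negative coverage")
  bad <- is.na(calls$fraction) | calls$fraction < 0 | calls$fraction > 1
  if (any(bad)) {
    stop("modification call with fraction outside [0,1] (record ",
         which(bad)[1], ")")
  }
  if (any(is.na(calls$p_value) | calls$p_value <= 0 | calls$p_value > 1)) {
    stop("modification call with p_value outside (0,1]")
  }
  if (!all(calls$strand %in% c("+", "-"))) {
    stop("modification call with strand outside {+,-}")
  }
  calls
}

#' Read per-site modification calls
#'
#' Two dialects are supported. `"gff"` is the kineticsTools
#' `modifications.gff` layout: 1-based single-base features typed by
#' modification (e.g. `m6A`), with `coverage` and `frac` attributes and the
#' detection score in the score column as a Phred QV. A `pValue` (or
#' `p_value`) attribute is used directly when present; otherwise the score is
#' converted as `p = 10^(-score/10)`. `"tsv"` is the package's canonical
#' tab-separated layout with header
#' `contig, pos0, strand, mod, coverage, p_value, fraction` and 0-based
#' positions.
#'
#' Records whose modification type is not `mod_type` are dropped; the count
#' of dropped records is attached as attribute `n_dropped_modtype`.
#'
#' @param path Input path.
#' @param dialect `"gff"` or `"tsv"`; `"auto"` picks by file extension.
#' @param mod_type Modification type to retain (default `"m6A"`).
#' @return data.frame with columns `contig_id`, `position` (0-based bp of the
#'   forward-strand base; for minus-strand calls the base whose complement is
#'   the methylated adenine), `strand`, `mod_type`, `coverage`, `p_value`,
#'   `fraction`.
#' @export
read_modcalls <- function(path, dialect = c("auto", "gff", "tsv"),
                          mod_type = "m6A") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff" else "tsv"
  }
  if (dialect == "gff") {
    g <- as.data.frame(rtracklayer::readGFF(path))
    n_dropped <- sum(g$type != mod_type)
    g <- g[g$type == mod_type, , drop = FALSE]
    cov <- suppressWarnings(as.integer(as.character(g$coverage)))
    if (nrow(g) > 0 && (is.null(g$coverage) || any(is.na(cov)))) {
      stop("modification record without a usable coverage attribute in ", path)
    }
    frac <- suppressWarnings(as.numeric(as.character(g$frac)))
    if (nrow(g) > 0 && (is.null(g$frac) || any(is.na(frac)))) {
      stop("modification record without a usable frac attribute in ", path)
    }
    pv_attr <- g[["pValue"]]
    if (is.null(pv_attr)) pv_attr <- g[["p_value"]]
    if (!is.null(pv_attr)) {
      pv <- suppressWarnings(as.numeric(as.character(pv_attr)))
    } else {
      pv <- 10^(-as.numeric(g$score) / 10)
    }
    calls <- data.frame(contig_id = as.character(g$seqid),
                        position = as.integer(g$start) - 1L,
                        strand = as.character(g$strand),
                        mod_type = as.character(g$type),
                        coverage = cov,
                        p_value = pv,
                        fraction = frac,
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("contig", "pos0", "strand", "mod", "coverage", "p_value",
              "fraction")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0) {
      stop("modcall TSV missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    n_dropped <- sum(tab$mod != mod_type)
    tab <- tab[tab$mod == mod_type, , drop = FALSE]
    calls <- data.frame(contig_id = as.character(tab$contig),
                        position = as.integer(tab$pos0),
                        strand = as.character(tab$strand),
                        mod_type = as.character(tab$mod),
                        coverage = as.integer(tab$coverage),
                        p_value = as.numeric(tab$p_value),
                        fraction = as.numeric(tab$fraction),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  calls <- validate_modcalls(calls)
  attr(calls, "n_dropped_modtype") <- n_dropped
  calls
}

#' Write modification calls
#'
#' Inverse of [read_modcalls()] for both dialects. The GFF writer emits the
#' kineticsTools layout with the detection p-value carried both as a
#' `pValue` attribute and as a Phred score.
#'
#' @param calls Modification-call data.frame.
#' @param path Output path.
#' @param dialect `"gff"` or `"tsv"`.
#' @export
write_modcalls <- function(calls, path, dialect = c("tsv", "gff")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff") {
    qv <- -10 * log10(calls$p_value)
    lines <- c("##gff-version 3",
               sprintf(
                 "%s\tkinModCall\t%s\t%d\t%d\t%.2f\t%s\t.\tcoverage=%d;frac=%.6g;pValue=%.6g",
                 calls$contig_id, calls$mod_type,
                 calls$position + 1L, calls$position + 1L,
                 qv, calls$strand, calls$coverage, calls$fraction,
                 calls$p_value))
    writeLines(lines, path)
  } else {
    tab <- data.frame(contig = calls$contig_id, pos0 = calls$position,
                      strand = calls$strand, mod = calls$mod_type,
                      coverage = calls$coverage, p_value = calls$p_value,
                      fraction = calls$fraction)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-gene expression table
#'
#' @param path TSV with header columns `gene_id` and `fpkm`.
#' @return data.frame with `gene_id`, `fpkm`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(tab))) {
    stop("expression TSV must have columns gene_id, fpkm")
  }
  if (any(tab$fpkm < 0)) stop("negative FPKM in ", path)
  tab[, c("gene_id", "fpkm")]
}

#' Read an LC-MS nucleoside quantity table
#'
#' @param path TSV with header `sample_id, replicate, dC_nM, m5dC_nM, dA_nM,
#'   m6dA_nM`; quantities in nM.
#' @return data.frame with those columns.
#' @export
read_nucleosides <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "dC_nM", "m5dC_nM", "dA_nM", "m6dA_nM")
  if (!all(need %in% names(tab))) {
    stop("nucleoside TSV must have columns ", paste(need, collapse = ", "))
  }
  q <- as.matrix(tab[, c("dC_nM", "m5dC_nM", "dA_nM", "m6dA_nM")])
  if (any(q < 0)) stop("negative nucleoside quantity in ", path)
  tab[, need]
}

#' Read a Sniffles-style SV callset from VCF
#'
#' One record per VCF line. `POS` is converted to 0-based. The SV length is
#' `|SVLEN|` when present, otherwise `END - POS`; `BND` records are mapped to
#' class `TRA`. Read support is taken from the `RE` INFO key (0 when absent).
#'
#' @param path VCF 4.x path.
#' @return data.frame with `sv_id`, `contig_id`, `position` (0-based),
#'   `sv_class` (INS/DEL/INV/DUP/TRA), `length`, `read_support`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  svtype <- vcfR::extract.info(v, "SVTYPE")
  if (any(is.na(svtype))) stop("VCF record without SVTYPE in ", path)
  svlen <- suppressWarnings(vcfR::extract.info(v, "SVLEN", as.numeric = TRUE))
  end <- suppressWarnings(vcfR::extract.info(v, "END", as.numeric = TRUE))
  re <- suppressWarnings(vcfR::extract.info(v, "RE", as.numeric = TRUE))
  re[is.na(re)] <- 0
  pos1 <- as.integer(fix[, "POS"])
  len <- ifelse(!is.na(svlen), abs(svlen), end - pos1 + 1L)
  if (any(is.na(len))) {
    stop("VCF record with neither SVLEN nor END in ", path)
  }
  cls <- ifelse(svtype == "BND", "TRA", svtype)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("sv", seq_along(pos1))[
    is.na(ids) | ids == "."]
  out <- data.frame(sv_id = as.character(ids),
                    contig_id = as.character(fix[, "CHROM"]),
                    position = pos1 - 1L,
                    sv_class = as.character(cls),
                    length = as.integer(round(len)),
                    read_support = as.integer(re),
                    stringsAsFactors = FALSE)
  if (any(out$length < 1)) stop("SV with length < 1 in ", path)
  out
}

#' Write an SV callset as a minimal Sniffles-style VCF
#'
#' Inverse of [read_sv_vcf()]: positions go back to 1-based, class TRA is
#' written as SVTYPE=BND, and length is carried in SVLEN (with END for
#' convenience).
#'
#' @param svs SV data.frame as returned by [read_sv_vcf()].
#' @param path Output path.
#' @export
write_sv_vcf <- function(svs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=methApT",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=RE,Number=1,Type=Integer,Description="Read evidence">',
           '##ALT=<ID=DEL,Description="Deletion">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  svtype <- ifelse(svs$sv_class == "TRA", "BND", svs$sv_class)
  body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;SVLEN=%d;END=%d;RE=%d",
                  svs$contig_id, svs$position + 1L, svs$sv_id, svtype, svtype,
                  svs$length, svs$position + svs$length, svs$read_support)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write symmetric-site tables
#'
#' TSV with one row per symmetric ApT site:
#' `contig, apt_start, ratio, motif4, plus_cov, minus_cov, plus_frac,
#' minus_frac`.
#'
#' @param path File path.
#' @return For `read_sites`, a symmetric-site data.frame (see
#'   [call_symmetric_sites()]).
#' @export
read_sites <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("contig", "apt_start", "ratio", "motif4", "plus_cov",
            "minus_cov", "plus_frac", "minus_frac")
  if (!all(need %in% names(tab))) {
    stop("site TSV must have columns ", paste(need, collapse = ", "))
  }
  tab[, need]
}

#' @rdname read_sites
#' @param sites Symmetric-site data.frame.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates are taken as-is.
#'
#' @param path BED3+ path (tab-separated, no header).
#' @return data.frame with `contig_id`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(contig_id = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (any(out$end <= out$start)) stop("BED interval with end <= start")
  out
}
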