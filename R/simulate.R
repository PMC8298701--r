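#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validation. The
#' defaults describe the study conditions the package is designed around: a
#' haploid genome with non-overlapping genes, a quarter of genes methylated,
#' ~10 symmetric ApT sites per methylated gene, per-site true ratios drawn
#' from Beta(2.2, 1.15) (mean ~0.657, broad spread), per-strand coverage
#' Poisson(40) truncated at 25, site placement weighted
#' promoter/body/downstream/intergenic = 0.20/0.66/0.07/0.07 (so ~86% of
#' sites fall in genes plus promoters), and a small asymmetric background
#' call rate on non-ApT adenines. The default genome length is sized so the
#' genome-wide fraction of methylated adenines comes out near 0.2%, the
#' level typical of the AMF system this emulates.
#'
#' @param seed Integer seed; every generator derives its stream from it via
#'   fixed offsets, so regenerating one file does not perturb the others.
#' @param genome_length Genome size in bp.
#' @param n_genes Number of genes.
#' @param gene_length_mean Mean gene length in bp.
#' @param frac_methylated_genes Fraction of genes carrying 6mA sites.
#' @param apt_sites_per_gene_mean Poisson mean of sites per methylated gene.
#' @param ratio_beta_alpha,ratio_beta_beta Beta law of true site ratios.
#' @param coverage_mean Per-strand Poisson coverage mean (truncated >= 25).
#' @param region_weights Length-4 simplex (promoter, gene_body, downstream,
#'   intergenic).
#' @param asymmetric_background_rate Per-adenine (per strand-position)
#'   probability of a background non-ApT call.
#' @param expression_baseline,expression_link_slope,expression_noise_sd
#'   Parameters of `log2(FPKM + 1) = baseline + slope * density_z + noise`.
#' @param divergence_shift Ratio shift planted at divergent sites for
#'   two-sample contrasts (truncated to `[0, 1]`).
#' @param divergent_site_frac Fraction of sites flagged divergent.
#' @param n_sv,sv_jitter_frac,sv_replace_frac,sv_fodder_frac SV callset
#'   geometry: base count, fraction positionally jittered in the second
#'   callset (within 15% of length, surviving the 80% reciprocal-overlap
#'   rule), fraction replaced by unrelated records, and fraction of added
#'   filter fodder (TRA / low-read-support records).
#' @param n_nuc_samples,pct_6mA_range,pct_5mC_range,nuc_noise_sd,
#'   n_nuc_replicates LC-MS table geometry: sample count, true percent
#'   ranges, multiplicative replicate noise, replicates per sample.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 2400000,
                       n_genes = 400,
                       gene_length_mean = 1500,
                       frac_methylated_genes = 0.25,
                       apt_sites_per_gene_mean = 10,
                       ratio_beta_alpha = 2.2,
                       ratio_beta_beta = 1.15,
                       coverage_mean = 40,
                       region_weights = c(promoter = 0.20, gene_body = 0.66,
                                          downstream = 0.07,
                                          intergenic = 0.07),
                       asymmetric_background_rate = 3e-4,
                       expression_baseline = 3,
                       expression_link_slope = 1,
                       expression_noise_sd = 1,
                       divergence_shift = 0.4,
                       divergent_site_frac = 0.05,
                       n_sv = 200,
                       sv_jitter_frac = 0.5,
                       sv_replace_frac = 0.1,
                       sv_fodder_frac = 0.1,
                       n_nuc_samples = 6,
                       pct_6mA_range = c(0.12, 0.17),
                       pct_5mC_range = c(32.5, 49.5),
                       nuc_noise_sd = 0.02,
                       n_nuc_replicates = 2) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$region_weights) == 4,
            all(cfg$region_weights >= 0),
            abs(sum(cfg$region_weights) - 1) < 1e-9,
            cfg$ratio_beta_alpha > 0, cfg$ratio_beta_beta > 0,
            cfg$frac_methylated_genes >= 0, cfg$frac_methylated_genes <= 1,
            cfg$coverage_mean > 0, cfg$divergent_site_frac >= 0,
            cfg$divergent_site_frac <= 1)
  names(cfg$region_weights) <- c("promoter", "gene_body", "downstream",
                                 "intergenic")
  class(cfg) <- "sim_config"
  cfg
}

# Poisson truncated from below at `lo`
rpois_trunc <- function(n, lambda, lo = 25) {
  x <- stats::rpois(n, lambda)
  while (any(low <- x < lo)) x[low] <- stats::rpois(sum(low), lambda)
  x
}

#' Simulate a genome, gene models and site ground truth
#'
#' Generates a single-contig random genome with non-overlapping genes
#' separated by at least 1000 bp (leaving room for 500-bp flanks), marks
#' `round(frac_methylated_genes * n_genes)` genes methylated, places
#' symmetric ApT site loci by the configured region weights, and writes an
#' `AATT` context into the sequence at every site locus. Output is
#' deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (gene-model data.frame), and `truth` — a list with `genes` (gene_id,
#'   methylated) and `sites` (site_id, contig, apt_start, gene_id, region,
#'   true_ratio, divergent).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  if (config$genome_length < n * (config$gene_length_mean + 1000)) {
    stop("genome_length too small to pack ", n, " genes with 1000-bp gaps; ",
         "increase genome_length to at least ",
         n * (config$gene_length_mean + 1000))
  }
  len <- pmax(300L, as.integer(round(
    stats::rgamma(n, shape = 6, rate = 6 / config$gene_length_mean))))
  spare <- config$genome_length - sum(len) - (n + 1L) * 1000L
  if (spare < 0) {
    stop("genome_length too small for the drawn gene lengths; ",
         "increase genome_length")
  }
  extra <- as.vector(stats::rmultinom(1, spare, rep(1, n + 1L)))
  gaps <- 1000L + extra
  starts <- cumsum(c(gaps[1], len[-n] + gaps[-c(1, n + 1L)]))
  # starts is 0-based; gene i spans [starts[i], starts[i] + len[i])
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                      contig_id = "ctg1",
                      start = as.integer(starts),
                      end = as.integer(starts + len),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)

  n_meth <- round(config$frac_methylated_genes * n)
  meth_ids <- sort(sample(genes$gene_id, n_meth))
  truth_genes <- data.frame(gene_id = genes$gene_id,
                            methylated = genes$gene_id %in% meth_ids,
                            stringsAsFactors = FALSE)

  # intergenic space at least `flank` away from any gene
  ig_lo <- c(2L, genes$end + 502L)
  ig_hi <- c(genes$start - 503L, config$genome_length - 4L)
  ig_ok <- ig_hi > ig_lo
  ig_lo <- ig_lo[ig_ok]; ig_hi <- ig_hi[ig_ok]
  ig_w <- ig_hi - ig_lo + 1

  used <- integer(0)
  pick_pos <- function(lo, hi) {
    # rejection-sample a position >= 5 bp from every previous site
    for (try in 1:200) {
      p <- if (hi >= lo) sample(seq.int(lo, hi), 1) else return(NA_integer_)
      if (length(used) == 0 || min(abs(used - p)) >= 5) return(p)
    }
    NA_integer_
  }
  site_rows <- list()
  regions <- names(config$region_weights)
  for (gid in meth_ids) {
    g <- genes[genes$gene_id == gid, ]
    k <- stats::rpois(1, config$apt_sites_per_gene_mean)
    if (k == 0) next
    reg <- sample(regions, k, replace = TRUE, prob = config$region_weights)
    for (r in reg) {
      if (r == "gene_body") {
        p <- pick_pos(g$start + 2L, g$end - 4L)
      } else if (r == "promoter") {
        p <- if (g$strand == "+") pick_pos(g$start - 498L, g$start - 3L)
             else pick_pos(g$end + 2L, g$end + 497L)
      } else if (r == "downstream") {
        p <- if (g$strand == "+") pick_pos(g$end + 2L, g$end + 497L)
             else pick_pos(g$start - 498L, g$start - 3L)
      } else {
        if (length(ig_w) == 0) next
        iv <- sample.int(length(ig_w), 1, prob = ig_w)
        p <- pick_pos(ig_lo[iv], ig_hi[iv])
      }
      if (is.na(p)) next
      used <- c(used, p)
      site_rows[[length(site_rows) + 1]] <-
        data.frame(contig = "ctg1", apt_start = p,
                   gene_id = if (r == "intergenic") NA_character_ else gid,
                   region = r, stringsAsFactors = FALSE)
    }
  }
  if (length(site_rows) == 0) stop("no sites placed; check the config")
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$apt_start), , drop = FALSE]
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  sites$true_ratio <- stats::rbeta(nrow(sites), config$ratio_beta_alpha,
                                   config$ratio_beta_beta)
  sites$divergent <- seq_len(nrow(sites)) %in%
    sample.int(nrow(sites), round(config$divergent_site_frac * nrow(sites)))
  rownames(sites) <- NULL
  # plant ApT contexts (positions apt_start-1 .. apt_start+2, 0-based);
  # flanking bases are AATT-weighted so AATT tops the motif spectrum with
  # CATT/GATT/AATG/AATC-style contexts present at lower abundance
  flank5 <- sample(c("A", "C", "G", "T"), nrow(sites), replace = TRUE,
                   prob = c(0.70, 0.12, 0.12, 0.06))
  flank3 <- sample(c("T", "G", "C", "A"), nrow(sites), replace = TRUE,
                   prob = c(0.70, 0.12, 0.12, 0.06))
  for (i in seq_len(nrow(sites))) {
    p <- sites$apt_start[i]
    chars[p:(p + 3)] <- c(flank5[i], "A", "T", flank3[i])
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), "ctg1"))
  list(genome = genome, genes = genes,
       truth = list(genes = truth_genes, sites = sites))
}

#' Simulate one sample's modification calls
#'
#' For each ground-truth site, both strands emit a call: per-strand coverage
#' is Poisson(`coverage_mean`) truncated at 25, the methylated-read count is
#' Binomial(coverage, true ratio) — both strands share the same true ratio —
#' and the reported fraction is count/coverage. In a divergent sample, the
#' true ratio at flagged sites is shifted by `divergence_shift` (upward when
#' it fits within `[0, 1]`, downward otherwise). Background asymmetric calls
#' are added on random non-ApT adenines at `asymmetric_background_rate`.
#'
#' @param config A [sim_config()].
#' @param genome,truth From [simulate_genome()].
#' @param sample_offset Integer stream offset so each sample gets
#'   independent draws (clones: same truth, different offsets).
#' @param divergent Apply the divergence shift at flagged sites?
#' @return Modification-call data.frame (see [read_modcalls()]).
#' @export
simulate_methylome <- function(config, genome, truth, sample_offset = 1,
                               divergent = FALSE) {
  set.seed(config$seed + 10L + sample_offset)
  s <- truth$sites
  ns <- nrow(s)
  r <- s$true_ratio
  if (divergent) {
    up <- r + config$divergence_shift <= 1
    r[s$divergent] <- ifelse(up[s$divergent],
                             r[s$divergent] + config$divergence_shift,
                             pmax(r[s$divergent] - config$divergence_shift, 0))
  }
  cov_p <- rpois_trunc(ns, config$coverage_mean)
  cov_m <- rpois_trunc(ns, config$coverage_mean)
  k_p <- stats::rbinom(ns, cov_p, r)
  k_m <- stats::rbinom(ns, cov_m, r)
  pv <- 10^(-stats::runif(2 * ns, 4, 8))
  calls <- data.frame(
    contig_id = rep(s$contig, 2),
    position = c(s$apt_start, s$apt_start + 1L),
    strand = rep(c("+", "-"), each = ns),
    mod_type = "m6A",
    coverage = c(cov_p, cov_m),
    p_value = pv,
    fraction = c(k_p / cov_p, k_m / cov_m),
    stringsAsFactors = FALSE)

  # background: one-strand calls at non-ApT adenine contexts
  chars <- genome_chars(genome)[[s$contig[1]]]
  L <- length(chars)
  n_at <- sum(chars %in% c("A", "T"))
  n_bg <- stats::rpois(1, config$asymmetric_background_rate * n_at)
  if (n_bg > 0) {
    pos <- sample.int(L - 4L, 4 * n_bg) + 1L   # 0-based candidates, padded
    str <- sample(c("+", "-"), length(pos), replace = TRUE)
    b0 <- chars[pos + 1L]
    ok <- (str == "+" & b0 == "A" & chars[pos + 2L] != "T") |
          (str == "-" & b0 == "T" & chars[pos] != "A")
    pos <- pos[ok][seq_len(min(n_bg, sum(ok)))]
    str <- str[ok][seq_len(min(n_bg, sum(ok)))]
    nb <- length(pos)
    if (nb > 0) {
      covb <- rpois_trunc(nb, config$coverage_mean)
      rb <- stats::rbeta(nb, config$ratio_beta_alpha, config$ratio_beta_beta)
      kb <- stats::rbinom(nb, covb, rb)
      calls <- rbind(calls, data.frame(
        contig_id = s$contig[1], position = pos, strand = str,
        mod_type = "m6A", coverage = covb,
        p_value = 10^(-stats::runif(nb, 4, 8)),
        fraction = kb / covb, stringsAsFactors = FALSE))
    }
  }
  calls <- calls[order(calls$contig_id, calls$position, calls$strand), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Simulate a per-gene expression table
#'
#' `log2(FPKM + 1) = baseline + slope * z(density) + Normal(0, sd)` where
#' `z(density)` is the z-score of the true gene-body site density across all
#' genes (0 for unmethylated genes before standardization). A positive slope
#' guarantees a positive population Kendall correlation between density and
#' FPKM.
#'
#' @param config A [sim_config()].
#' @param genes Gene-model data.frame.
#' @param truth Ground truth from [simulate_genome()].
#' @return Expression data.frame (`gene_id`, `fpkm`) with the true density
#'   attached as attribute `true_density`.
#' @export
simulate_expression <- function(config, genes, truth) {
  set.seed(config$seed + 211L)
  body <- truth$sites[truth$sites$region == "gene_body", , drop = FALSE]
  n_sites <- table(factor(body$gene_id, levels = genes$gene_id))
  density <- as.numeric(n_sites) / (genes$end - genes$start)
  z <- if (stats::sd(density) > 0) as.numeric(scale(density)) else density * 0
  lf <- config$expression_baseline + config$expression_link_slope * z +
    stats::rnorm(nrow(genes), 0, config$expression_noise_sd)
  fpkm <- pmax(2^lf - 1, 0)
  out <- data.frame(gene_id = genes$gene_id, fpkm = fpkm,
                    stringsAsFactors = FALSE)
  attr(out, "true_density") <- stats::setNames(density, genes$gene_id)
  out
}

sv_random_records <- function(config, n, prefix, contig = "ctg1") {
  len <- pmin(pmax(as.integer(round(exp(stats::rnorm(n, log(800), 0.7)))),
                   50L), 10000L)
  data.frame(sv_id = sprintf("%s%04d", prefix, seq_len(n)),
             contig_id = contig,
             position = as.integer(floor(stats::runif(
               n, 0, config$genome_length - len))),
             sv_class = sample(c("INS", "DEL", "INV", "DUP"), n,
                               replace = TRUE),
             length = len,
             read_support = 15L + stats::rpois(n, 25),
             stringsAsFactors = FALSE)
}

#' Simulate a pair of SV callsets with known matches
#'
#' Callset A holds `n_sv` random variants. Callset B replays A with a
#' configured fraction of records positionally jittered by less than 15% of
#' their length (guaranteed survivors of the 80% reciprocal-overlap rule), a
#' fraction replaced by unrelated records, and — in both callsets — added
#' filter fodder: translocations and records with read support below 15.
#' The ground truth records which A/B pairs must match after filtering.
#'
#' @param config A [sim_config()].
#' @return list with `a`, `b` (SV data.frames) and `truth`
#'   (`sv_id_a`, `sv_id_b` for every plant-matched pair).
#' @export
simulate_sv_callsets <- function(config) {
  set.seed(config$seed + 311L)
  n <- config$n_sv
  a <- sv_random_records(config, n, "svA")
  # enforce locus separation so reciprocal-overlap matching is unambiguous
  a$position <- as.integer(seq(1000, config$genome_length - 12000,
                               length.out = n)) +
    as.integer(stats::runif(n, 0, 500))
  b <- a
  b$sv_id <- sub("^svA", "svB", a$sv_id)
  u <- stats::runif(n)
  jitter_idx <- which(u < config$sv_jitter_frac)
  replace_idx <- which(u >= config$sv_jitter_frac &
                       u < config$sv_jitter_frac + config$sv_replace_frac)
  shift <- as.integer(round(stats::runif(length(jitter_idx), -0.15, 0.15) *
                            a$length[jitter_idx]))
  b$position[jitter_idx] <- b$position[jitter_idx] + shift
  if (length(replace_idx) > 0) {
    # replacements sit between A loci with short length and swapped class,
    # so no replacement can reciprocally overlap any retained A record
    other <- c(INS = "DEL", DEL = "INS", INV = "DUP", DUP = "INV")
    repl <- data.frame(
      sv_id = sprintf("svBr%04d", seq_along(replace_idx)),
      contig_id = "ctg1",
      position = a$position[replace_idx] + 3000L,
      sv_class = unname(other[a$sv_class[replace_idx]]),
      length = 400L,
      read_support = 15L + stats::rpois(length(replace_idx), 25),
      stringsAsFactors = FALSE)
    b[replace_idx, ] <- repl
  }
  n_fod <- round(config$sv_fodder_frac * n)
  if (n_fod > 0) {
    fod_a <- sv_random_records(config, n_fod, "svAf")
    fod_a$sv_class[seq_len(ceiling(n_fod / 2))] <- "TRA"
    fod_a$read_support[seq.int(ceiling(n_fod / 2) + 1, n_fod)] <-
      sample(0:14, n_fod - ceiling(n_fod / 2), replace = TRUE)
    fod_b <- sv_random_records(config, n_fod, "svBf")
    fod_b$sv_class[seq_len(ceiling(n_fod / 2))] <- "TRA"
    fod_b$read_support[seq.int(ceiling(n_fod / 2) + 1, n_fod)] <-
      sample(0:14, n_fod - ceiling(n_fod / 2), replace = TRUE)
    a <- rbind(a, fod_a)
    b <- rbind(b, fod_b)
  }
  matched <- setdiff(seq_len(n), replace_idx)
  truth <- data.frame(sv_id_a = sprintf("svA%04d", matched),
                      sv_id_b = sprintf("svB%04d", matched),
                      stringsAsFactors = FALSE)
  list(a = a, b = b, truth = truth)
}

#' Simulate an LC-MS nucleoside quantity table
#'
#' Per sample, true percent 6mA and percent 5mC are drawn uniformly in the
#' configured ranges; replicate quantities receive independent
#' multiplicative noise on each nucleoside (clamped at zero with a warning
#' if the noise drives a quantity negative).
#'
#' @param config A [sim_config()].
#' @return list with `quants` (nucleoside data.frame, see
#'   [read_nucleosides()]) and `truth` (`sample_id`, `true_pct_6mA`,
#'   `true_pct_5mC`).
#' @export
simulate_nucleosides <- function(config) {
  set.seed(config$seed + 411L)
  ns <- config$n_nuc_samples
  ids <- sprintf("sample%d", seq_len(ns))
  p6 <- stats::runif(ns, config$pct_6mA_range[1], config$pct_6mA_range[2])
  p5 <- stats::runif(ns, config$pct_5mC_range[1], config$pct_5mC_range[2])
  tot_a <- stats::runif(ns, 80, 120)
  tot_c <- stats::runif(ns, 80, 120)
  rows <- list()
  for (i in seq_len(ns)) {
    for (rep_i in seq_len(config$n_nuc_replicates)) {
      noise <- 1 + stats::rnorm(4, 0, config$nuc_noise_sd)
      q <- c(dC_nM = tot_c[i] * (1 - p5[i] / 100),
             m5dC_nM = tot_c[i] * p5[i] / 100,
             dA_nM = tot_a[i] * (1 - p6[i] / 100),
             m6dA_nM = tot_a[i] * p6[i] / 100) * noise
      if (any(q < 0)) {
        warning("negative simulated quantity clamped to 0 (", ids[i], ")")
        q <- pmax(q, 0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids[i], replicate = rep_i, dC_nM = q[["dC_nM"]],
        m5dC_nM = q[["m5dC_nM"]], dA_nM = q[["dA_nM"]],
        m6dA_nM = q[["m6dA_nM"]], stringsAsFactors = FALSE)
    }
  }
  quants <- do.call(rbind, rows)
  rownames(quants) <- NULL
  list(quants = quants,
       truth = data.frame(sample_id = ids, true_pct_6mA = p6,
                          true_pct_5mC = p5, stringsAsFactors = FALSE))
}

#' Write a complete synthetic demo dataset
#'
#' Emits a small three-sample study to `dir`: one genome and annotation, two
#' clone methylomes (`cloneA`, `cloneB` — identical true ratios, independent
#' sequencing draws) and one divergent methylome (`div1` — flagged sites
#' shifted by the configured divergence), an expression table linked to
#' cloneA's site density, three SV callsets (the clones share a byte-identical
#' callset; `div1` is perturbed), an LC-MS nucleoside table, and
#' ground-truth sidecars plus the configuration as JSON.
#'
#' @param dir Output directory (created if absent).
#' @param config A [sim_config()]; default `sim_config(seed = seed)`.
#' @param seed Convenience override for the default config's seed.
#' @return Invisibly, a named list of written paths.
#' @export
make_demo <- function(dir, config = sim_config(seed = seed), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  gen <- simulate_genome(config)
  write_genome_fasta(gen$genome, p("genome.fa"))
  write_genes_gff3(gen$genes, p("genes.gff3"))
  samples <- list(cloneA = list(offset = 1, divergent = FALSE),
                  cloneB = list(offset = 2, divergent = FALSE),
                  div1 = list(offset = 3, divergent = TRUE))
  for (nm in names(samples)) {
    calls <- simulate_methylome(config, gen$genome, gen$truth,
                                sample_offset = samples[[nm]]$offset,
                                divergent = samples[[nm]]$divergent)
    write_modcalls(calls, p(sprintf("modcalls_%s.gff", nm)), dialect = "gff")
  }
  expr <- simulate_expression(config, gen$genes, gen$truth)
  utils::write.table(expr, p("expression_cloneA.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  svs <- simulate_sv_callsets(config)
  write_sv_vcf(svs$a, p("sv_cloneA.vcf"))
  write_sv_vcf(svs$a, p("sv_cloneB.vcf"))
  write_sv_vcf(svs$b, p("sv_div1.vcf"))
  utils::write.table(svs$truth, p("truth_sv.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nuc <- simulate_nucleosides(config)
  utils::write.table(nuc$quants, p("nucleosides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(nuc$truth, p("truth_nucleosides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth$sites, p("truth_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    genome = p("genome.fa"), genes = p("genes.gff3"),
    modcalls = stats::setNames(
      lapply(names(samples), function(nm) p(sprintf("modcalls_%s.gff", nm))),
      names(samples)),
    expression = p("expression_cloneA.tsv"),
    sv = list(cloneA = p("sv_cloneA.vcf"), cloneB = p("sv_cloneB.vcf"),
              div1 = p("sv_div1.vcf")),
    nucleosides = p("nucleosides.tsv"),
    truth = list(sites = p("truth_sites.tsv"), genes = p("truth_genes.tsv"),
                 sv = p("truth_sv.tsv"),
                 nucleosides = p("truth_nucleosides.tsv")),
    config = p("config.json"))
  invisible(manifest)
}
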