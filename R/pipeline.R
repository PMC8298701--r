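#' Validate a run configuration
#'
#' A run configuration is a named list (or a path to a JSON file holding
#' one) with fields:
#' \describe{
#'   \item{genome}{FASTA path (required).}
#'   \item{genes}{GFF3 path (required).}
#'   \item{modcalls}{Named list: sample id -> modification-call path
#'     (required, at least one sample).}
#'   \item{expression}{Optional TSV path (gene_id, fpkm).}
#'   \item{sv}{Optional named list: sample id -> VCF path.}
#'   \item{nucleosides}{Optional TSV path.}
#'   \item{out_dir}{Output directory (required).}
#'   \item{thresholds}{Optional overrides of `min_coverage` (25), `max_p`
#'     (0.001), `flank` (500), `fpkm_high` (5), `min_support` (15),
#'     `reciprocal` (0.8), `alpha` (0.05).}
#'   \item{seed}{Seed for the SV bootstrap (default 1).}
#'   \item{n_boot}{Bootstrap iterations (default 10000).}
#' }
#'
#' @param config List or JSON path.
#' @return The validated config with thresholds filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = FALSE)
  for (field in c("genome", "genes", "modcalls", "out_dir")) {
    if (is.null(config[[field]])) stop("run config missing field: ", field)
  }
  defaults <- list(min_coverage = 25, max_p = 0.001, flank = 500,
                   fpkm_high = 5, min_support = 15, reciprocal = 0.8,
                   alpha = 0.05)
  th <- utils::modifyList(defaults, as.list(config$thresholds))
  stopifnot(th$min_coverage >= 0, th$max_p > 0, th$max_p <= 1,
            th$flank >= 0, th$min_support >= 0,
            th$reciprocal > 0, th$reciprocal <= 1,
            th$alpha > 0, th$alpha < 1)
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$n_boot)) config$n_boot <- 10000
  paths <- c(config$genome, config$genes, unlist(config$modcalls),
             config$expression, unlist(config$sv), config$nucleosides)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("run config references missing file(s): ",
         paste(missing, collapse = ", "))
  }
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full 6mA methylome pipeline
#'
#' Orchestrates, per sample: call filtering, symmetric ApT site calling and
#' motif spectra, ratio-distribution summaries, region assignment and
#' per-gene methylation; across samples: pairwise ratio divergence,
#' methylated-gene-set comparison, and (when SV callsets are given) SV
#' filtering, Jaccard distances and bootstrap clustering; plus LC-MS percent
#' methylation when a nucleoside table is given. Per-sample site tables and
#' a JSON report are written under `out_dir`.
#'
#' @param config Run configuration (list or JSON path); see
#'   [validate_run_config()].
#' @return A list of class `run_report` with elements `samples` (per-sample
#'   summaries, ratio distributions, region fractions, gene methylation),
#'   `ratio_comparisons`, `gene_set_comparison`, `sv` (Jaccard matrix,
#'   newick tree, supports), `lcms`, and `thresholds`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- run_stage("read_genome", read_genome(config$genome))
  genes <- run_stage("read_genes", read_genes(config$genes))
  sample_ids <- names(config$modcalls)

  samples <- list()
  site_tabs <- list()
  gm_tabs <- list()
  for (sid in sample_ids) {
    calls <- run_stage(paste0("read_modcalls:", sid),
                       read_modcalls(config$modcalls[[sid]]))
    summ <- run_stage(paste0("apt_caller:", sid),
                      methylome_summary(calls, genome,
                                        min_coverage = th$min_coverage,
                                        max_p = th$max_p))
    sites <- summ$sites
    site_tabs[[sid]] <- sites
    write_sites(sites, file.path(config$out_dir,
                                 sprintf("sites_%s.tsv", sid)))
    regions <- run_stage(paste0("assign_regions:", sid),
                         assign_regions(sites, genes, flank = th$flank))
    gm <- run_stage(paste0("gene_methylation:", sid),
                    call_gene_methylation(sites, genes, flank = th$flank))
    gm_tabs[[sid]] <- gm
    samples[[sid]] <- list(
      summary = summ[setdiff(names(summ), "sites")],
      ratio_distribution = summarize_ratios(sites, sample_id = sid),
      region_fractions = attr(regions, "region_fractions"),
      pct_genes_methylated = attr(gm, "pct_genes_methylated"),
      coverage_dependence = ratio_coverage_dependence(sites))
  }

  ratio_comparisons <- list()
  if (length(sample_ids) >= 2) {
    for (i in seq_len(length(sample_ids) - 1)) {
      for (j in (i + 1):length(sample_ids)) {
        key <- paste(sample_ids[i], sample_ids[j], sep = "_vs_")
        cmp <- run_stage(paste0("compare_ratios:", key),
                         compare_ratios(site_tabs[[sample_ids[i]]],
                                        site_tabs[[sample_ids[j]]],
                                        alpha = th$alpha))
        ratio_comparisons[[key]] <- list(
          n_shared = cmp$n_shared,
          divergent_fraction = cmp$divergent_fraction)
      }
    }
  }

  gene_set_comparison <- if (length(gm_tabs) >= 2) {
    run_stage("compare_gene_sets", compare_gene_sets(gm_tabs))
  } else NULL

  expression <- NULL
  if (!is.null(config$expression)) {
    expr <- run_stage("read_expression", read_expression(config$expression))
    sid <- if (!is.null(config$expression_sample)) config$expression_sample
           else sample_ids[1]
    expression <- run_stage("expression_link",
                            expression_link(gm_tabs[[sid]], expr,
                                            fpkm_high = th$fpkm_high))
    expression$groups <- as.data.frame(expression$groups)
    expression$sample <- sid
  }

  sv <- NULL
  if (!is.null(config$sv) && length(config$sv) >= 2) {
    callsets <- lapply(config$sv, function(pth)
      run_stage("read_sv_vcf", read_sv_vcf(pth)))
    filtered <- lapply(callsets, filter_svs, min_support = th$min_support)
    jm <- run_stage("jaccard_matrix",
                    jaccard_matrix(filtered, reciprocal = th$reciprocal))
    pres <- sv_presence_matrix(filtered, reciprocal = th$reciprocal)
    cl <- run_stage("cluster_with_bootstrap",
                    cluster_with_bootstrap(jm, pres, n_boot = config$n_boot,
                                           seed = config$seed))
    newick <- ape::write.tree(cl$phylo)
    writeLines(newick, file.path(config$out_dir, "sv_tree.nwk"))
    sv <- list(jaccard = jm, newick = newick, support = cl$support,
               n_filtered = vapply(filtered, nrow, integer(1)))
  }

  lcms <- NULL
  if (!is.null(config$nucleosides)) {
    quants <- run_stage("read_nucleosides",
                        read_nucleosides(config$nucleosides))
    lcms <- run_stage("lcms_quant", aggregate_replicates(quants))
  }

  report <- list(samples = samples, ratio_comparisons = ratio_comparisons,
                 gene_set_comparison = gene_set_comparison,
                 expression = expression, sv = sv, lcms = lcms,
                 thresholds = th, seed = config$seed)
  class(report) <- "run_report"
  json <- report
  json$sv$jaccard <- as.data.frame(json$sv$jaccard)
  jsonlite::write_json(
    lapply(unclass(json), function(x) x),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
  report
}
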