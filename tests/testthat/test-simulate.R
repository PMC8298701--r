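test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(region_weights = c(0.5, 0.5, 0.2, 0)))
  expect_error(sim_config(ratio_beta_alpha = -1))
  expect_error(sim_config(frac_methylated_genes = 1.5))
})

test_that("genome generation packs genes, marks the exact methylated count,
           and errors on infeasible packing", {
  cfg <- sim_config(seed = 1, n_genes = 100, genome_length = 600000,
                    frac_methylated_genes = 0.25)
  gen <- simulate_genome(cfg)
  expect_equal(sum(gen$truth$genes$methylated), 25L)
  g <- gen$genes
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] - g$end[ord][-nrow(g)] >= 1000))
  expect_true(all(g$end - g$start >= 300))
  expect_error(simulate_genome(sim_config(n_genes = 100,
                                          genome_length = 10000)),
               "increase genome_length")
})

test_that("identical configurations give byte-identical demo files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 42, n_genes = 40, genome_length = 300000)
  make_demo(d1, cfg)
  make_demo(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     label = f)
  }
})

test_that("every ground-truth site is recoverable from the emitted calls", {
  cfg <- sim_config(seed = 8, n_genes = 60, genome_length = 400000)
  gen <- simulate_genome(cfg)
  calls <- simulate_methylome(cfg, gen$genome, gen$truth, 1)
  res <- call_symmetric_sites(filter_calls(calls), gen$genome)
  key_called <- paste(res$sites$contig, res$sites$apt_start)
  key_truth <- paste(gen$truth$sites$contig, gen$truth$sites$apt_start)
  expect_true(all(key_truth %in% key_called))
  # and the planted context really is ApT with an AATT-topped spectrum
  expect_equal(setdiff(key_called, key_truth), character(0))
})

test_that("true ratios and region placement follow the configured laws", {
  # the per-seed fractions are ~2000-site multinomial draws, so the <0.03
  # bound is asserted on the mean over three independent replicates
  fracs <- ratios <- ns <- NULL
  for (seed in 17:19) {
    cfg <- sim_config(seed = seed, n_genes = 800, genome_length = 4800000)
    s <- simulate_genome(cfg)$truth$sites
    ns <- c(ns, nrow(s))
    ratios <- c(ratios, s$true_ratio)
    fracs <- rbind(fracs, as.numeric(
      table(factor(s$region, names(cfg$region_weights)))) / nrow(s))
  }
  expect_true(all(ns > 1500))
  expect_equal(mean(ratios), 2.2 / (2.2 + 1.15), tolerance = 0.02 / 0.657)
  expect_true(all(abs(colMeans(fracs) -
                        c(0.20, 0.66, 0.07, 0.07)) < 0.03))
})

test_that("near-symmetric beta limit gives fractions near one half", {
  cfg <- sim_config(seed = 3, n_genes = 40, genome_length = 300000,
                    ratio_beta_alpha = 1e6, ratio_beta_beta = 1e6)
  gen <- simulate_genome(cfg)
  calls <- simulate_methylome(cfg, gen$genome, gen$truth, 1)
  sites <- call_symmetric_sites(filter_calls(calls), gen$genome)$sites
  expect_lt(max(abs(sites$ratio - 0.5)), 0.3)     # binomial noise only
  expect_lt(abs(mean(sites$ratio) - 0.5), 0.02)
})

test_that("degenerate region weights put every call in a gene body, paired", {
  cfg <- sim_config(seed = 9, n_genes = 40, genome_length = 300000,
                    region_weights = c(0, 1, 0, 0),
                    asymmetric_background_rate = 0)
  gen <- simulate_genome(cfg)
  calls <- simulate_methylome(cfg, gen$genome, gen$truth, 1)
  res <- call_symmetric_sites(filter_calls(calls), gen$genome)
  expect_equal(nrow(res$non_apt), 0L)
  expect_equal(nrow(res$asymmetric), 0L)
  ra <- assign_regions(res$sites, gen$genes)
  expect_true(all(ra$region == "gene_body"))
})

test_that("expression generator honours its slope parameter", {
  cfg0 <- sim_config(seed = 23, expression_link_slope = 0)
  gen <- simulate_genome(cfg0)
  dens <- attr(simulate_expression(cfg0, gen$genes, gen$truth),
               "true_density")
  e0 <- simulate_expression(cfg0, gen$genes, gen$truth)
  tau0 <- suppressWarnings(cor(dens, e0$fpkm, method = "kendall"))
  expect_lt(abs(tau0), 0.1)
  cfg1 <- sim_config(seed = 23, expression_link_slope = 10,
                     expression_noise_sd = 1e-6)
  e1 <- simulate_expression(cfg1, gen$genes, gen$truth)
  meth <- dens > 0
  expect_gt(suppressWarnings(cor(dens[meth], e1$fpkm[meth],
                                 method = "kendall")), 0.95)
})

test_that("SV callset generator spans the replacement extremes", {
  cfg0 <- sim_config(seed = 31, sv_replace_frac = 0, sv_jitter_frac = 0.5)
  svs <- simulate_sv_callsets(cfg0)
  jm <- jaccard_matrix(list(a = filter_svs(svs$a), b = filter_svs(svs$b)))
  expect_equal(jm["a", "b"], 0)
  cfg1 <- sim_config(seed = 31, sv_replace_frac = 1, sv_jitter_frac = 0)
  svs1 <- simulate_sv_callsets(cfg1)
  jm1 <- jaccard_matrix(list(a = filter_svs(svs1$a),
                             b = filter_svs(svs1$b)))
  expect_equal(jm1["a", "b"], 1)
  expect_equal(nrow(svs1$truth), 0L)
})

test_that("the demo writes the full manifest of files", {
  d <- withr::local_tempdir()
  man <- make_demo(d, sim_config(seed = 2, n_genes = 30,
                                 genome_length = 250000))
  paths <- c(man$genome, man$genes, unlist(man$modcalls), man$expression,
             unlist(man$sv), man$nucleosides, unlist(man$truth), man$config)
  expect_true(all(file.exists(paths)))
  expect_length(unlist(man$modcalls), 3L)
  # clone callsets are identical files
  expect_identical(readLines(man$sv$cloneA), readLines(man$sv$cloneB))
})
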