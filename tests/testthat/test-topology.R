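mk_site_rows <- function(apt_start, contig = "c1") {
  data.frame(contig = contig, apt_start = as.integer(apt_start), ratio = 0.6,
             motif4 = "AATT", plus_cov = 30L, minus_cov = 30L,
             plus_frac = 0.6, minus_frac = 0.6, stringsAsFactors = FALSE)
}

mk_gene <- function(gene_id, start, end, strand = "+", contig = "c1") {
  data.frame(gene_id = gene_id, contig_id = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

test_that("region windows follow the 500-bp flank rule with strand
           mirroring", {
  genes <- mk_gene("g1", 1000, 2000)
  sites <- mk_site_rows(c(700, 1500, 2300, 300))
  ra <- assign_regions(sites, genes)
  expect_equal(ra$region,
               c("promoter", "gene_body", "downstream", "intergenic"))
  expect_equal(ra$gene_id, c("g1", "g1", "g1", NA))
  # minus-strand gene: upstream is rightward
  ra2 <- assign_regions(mk_site_rows(c(2300, 700)),
                        mk_gene("g1", 1000, 2000, "-"))
  expect_equal(ra2$region, c("promoter", "downstream"))
  # window boundaries: flank is exactly 500 bp
  ra3 <- assign_regions(mk_site_rows(c(499, 500, 1999, 2000, 2499, 2500)),
                        genes)
  expect_equal(ra3$region, c("intergenic", "promoter", "gene_body",
                             "downstream", "downstream", "intergenic"))
})

test_that("every site gets exactly one region and fractions sum to 1", {
  cfg <- sim_config(seed = 5, n_genes = 80, genome_length = 500000)
  gen <- simulate_genome(cfg)
  truth <- gen$truth$sites
  sites <- mk_site_rows(truth$apt_start, contig = truth$contig)
  ra <- assign_regions(sites, gen$genes)
  expect_equal(nrow(ra), nrow(sites))
  expect_true(all(ra$region %in% c("promoter", "gene_body", "downstream",
                                   "intergenic")))
  expect_equal(sum(attr(ra, "region_fractions")), 1)
  # assignments reproduce the generator's planted region labels
  expect_equal(ra$region, truth$region)
  expect_equal(ra$gene_id[truth$region != "intergenic"],
               truth$gene_id[truth$region != "intergenic"])
})

test_that("gene methylation calls count body sites only by default", {
  genes <- rbind(mk_gene("g1", 1000, 2000), mk_gene("g2", 5000, 6000))
  sites <- mk_site_rows(c(1100, 1200, 1300, 1400, 1500, 4700))
  gm <- call_gene_methylation(sites, genes)
  expect_equal(gm$n_apt_sites, c(5L, 0L))
  expect_equal(gm$density, c(5 / 1000, 0))
  expect_equal(gm$methylated, c(TRUE, FALSE))
  expect_equal(gm$n_promoter_sites, c(0L, 1L))
  expect_equal(attr(gm, "pct_genes_methylated"), 50)
  gm2 <- call_gene_methylation(sites, genes, include_promoter = TRUE)
  expect_equal(gm2$methylated, c(TRUE, TRUE))
})

test_that("percent of methylated genes recovers the generator truth", {
  cfg <- sim_config(seed = 13)
  gen <- simulate_genome(cfg)
  calls <- simulate_methylome(cfg, gen$genome, gen$truth, 1)
  sites <- call_symmetric_sites(filter_calls(calls), gen$genome)$sites
  gm <- call_gene_methylation(sites, gen$genes)
  expect_equal(attr(gm, "pct_genes_methylated"),
               100 * cfg$frac_methylated_genes, tolerance = 0.02)
})

test_that("gene-set comparison computes Venn regions, union and core", {
  cmp <- compare_gene_sets(list(a = c("g1", "g2", "g3"), b = c("g2", "g3"),
                                c = c("g2", "g4")))
  expect_equal(cmp$core, 1L)
  expect_equal(cmp$union, 4L)
  expect_equal(cmp$regions[["a&b&c"]], 1L)   # g2
  expect_equal(cmp$regions[["a&b"]], 1L)     # g3
  expect_equal(cmp$regions[["a"]], 1L)       # g1
  expect_equal(cmp$regions[["c"]], 1L)       # g4
  expect_equal(sum(cmp$regions), cmp$union)  # inclusion-exclusion partition

  same <- compare_gene_sets(list(x = c("g1", "g2"), y = c("g1", "g2")))
  expect_equal(same$core, same$union)
  disj <- compare_gene_sets(list(x = "g1", y = "g2"))
  expect_equal(disj$core, 0L)
  expect_equal(disj$union, 2L)
})

test_that("expression link reproduces exact tau values", {
  gm <- data.frame(gene_id = paste0("g", 1:3), n_apt_sites = 1:3,
                   n_promoter_sites = 0L, length = 1000L,
                   density = c(1, 2, 3) / 1000, methylated = TRUE,
                   stringsAsFactors = FALSE)
  up <- data.frame(gene_id = paste0("g", 1:3), fpkm = c(2, 4, 8))
  down <- data.frame(gene_id = paste0("g", 1:3), fpkm = c(8, 4, 2))
  expect_equal(expression_link(gm, up)$tau, 1)
  expect_equal(expression_link(gm, down)$tau, -1)
  expect_error(expression_link(gm[1, ], up), "fewer than 2")
})

test_that("tau-b with ties matches exhaustive pair enumeration", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 1, 2, 3)
  gm <- data.frame(gene_id = paste0("g", 1:4), n_apt_sites = 1L,
                   n_promoter_sites = 0L, length = 1000L, density = x,
                   methylated = TRUE, stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = paste0("g", 1:4), fpkm = y)
  el <- expression_link(gm, expr)
  expect_equal(el$tau, 5 / sqrt(30), tolerance = 1e-12)
  expect_equal(el$tau, tau_b_brute(x, y), tolerance = 1e-12)

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:120, 1)
    xd <- sample(1:8, n, replace = TRUE)   # heavy ties
    yd <- sample(1:8, n, replace = TRUE)
    gm <- data.frame(gene_id = paste0("g", 1:n), n_apt_sites = 1L,
                     n_promoter_sites = 0L, length = 1000L, density = xd,
                     methylated = TRUE, stringsAsFactors = FALSE)
    expr <- data.frame(gene_id = paste0("g", 1:n), fpkm = yd)
    expect_equal(expression_link(gm, expr)$tau, tau_b_brute(xd, yd),
                 tolerance = 1e-12)
  }
})

test_that("synthetic expression link is positive and calibrated", {
  cfg <- sim_config(seed = 2)
  gen <- simulate_genome(cfg)
  expr <- simulate_expression(cfg, gen$genes, gen$truth)
  body <- gen$truth$sites[gen$truth$sites$region == "gene_body", ]
  n_sites <- as.integer(table(factor(body$gene_id,
                                     levels = gen$genes$gene_id)))
  gm <- data.frame(gene_id = gen$genes$gene_id, n_apt_sites = n_sites,
                   n_promoter_sites = 0L,
                   length = gen$genes$end - gen$genes$start,
                   density = n_sites / (gen$genes$end - gen$genes$start),
                   methylated = n_sites >= 1, stringsAsFactors = FALSE)
  el <- expression_link(gm, expr)
  expect_gt(el$tau, 0)
  expect_lt(el$p, 0.05)
  expect_true(all(c("groups", "n_dropped") %in% names(el)))
})
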