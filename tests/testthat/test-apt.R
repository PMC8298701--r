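test_that("filter thresholds are inclusive at 25x coverage and p = 0.001", {
  calls <- mk_calls("c1", 0:3, "+",
                    coverage = c(24, 25, 40, 40),
                    p_value = c(1e-4, 1e-4, 0.001, 0.01))
  out <- filter_calls(calls)
  expect_equal(out$position, c(1L, 2L))
  expect_equal(attr(out, "n_raw"), 4L)
  expect_equal(attr(out, "n_filtered"), 2L)
  empty <- filter_calls(calls[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_raw"), 0L)
})

test_that("a plus/minus call pair at an ApT context forms one site", {
  g <- tiny_genome(c1 = "GGAATTCC")
  calls <- mk_calls("c1", c(3, 4), c("+", "-"),
                    coverage = c(30, 28), fraction = c(0.8, 0.7))
  res <- call_symmetric_sites(calls, g)
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$sites$apt_start, 3L)
  expect_equal(res$sites$motif4, "AATT")
  expect_equal(res$sites$ratio, (30 * 0.8 + 28 * 0.7) / 58)
  expect_equal(nrow(res$asymmetric), 0L)
  expect_equal(nrow(res$non_apt), 0L)
})

test_that("unpaired and non-ApT calls are classified, bad bases excluded", {
  g <- tiny_genome(c1 = "GGAATTCC")
  # plus call alone at the ApT -> asymmetric
  res <- call_symmetric_sites(mk_calls("c1", 3, "+"), g)
  expect_equal(nrow(res$sites), 0L)
  expect_equal(nrow(res$asymmetric), 1L)
  # A followed by A -> non-ApT (positions 2,3 are A,A)
  res <- call_symmetric_sites(mk_calls("c1", 2, "+"), g)
  expect_equal(nrow(res$non_apt), 1L)
  # call on a base that is not adenine on its strand -> warned exclusion
  expect_warning(
    res <- call_symmetric_sites(mk_calls("c1", c(0, 3), c("+", "+")), g),
    "not adenine")
  expect_equal(res$n_excluded, 1L)
  # call on N likewise
  gn <- tiny_genome(c1 = "GGNATTCC")
  expect_warning(res <- call_symmetric_sites(mk_calls("c1", 2, "+"), gn),
                 "not adenine")
  expect_equal(res$n_excluded, 1L)
})

test_that("motif spectrum reports sorted probabilities", {
  sites <- data.frame(contig = "c1", apt_start = 1:4, ratio = 0.5,
                      motif4 = c("AATT", "AATT", "AATT", "CATT"),
                      plus_cov = 30L, minus_cov = 30L,
                      plus_frac = 0.5, minus_frac = 0.5,
                      stringsAsFactors = FALSE)
  ms <- motif_spectrum(sites)
  expect_equal(ms, c(AATT = 0.75, CATT = 0.25))
  expect_length(motif_spectrum(sites[0, ]), 0L)
})

test_that("global methylation percent counts adenines on both strands", {
  g <- tiny_genome(c1 = "AATT")
  expect_equal(global_methylation_percent(mk_calls("c1", 0, "+"), g), 25)
  expect_equal(global_methylation_percent(mk_calls("c1", 0, "+")[0, ], g), 0)
  # duplicate coordinates count once
  expect_equal(global_methylation_percent(
    mk_calls("c1", c(0, 0), c("+", "+")), g), 25)
})

test_that("pairing matches the exhaustive pair-testing oracle exactly", {
  set.seed(42)
  for (rep in 1:8) {
    fx <- random_call_fixture(genome_len = 5000, n_calls = 150)
    res <- suppressWarnings(call_symmetric_sites(fx$calls, fx$genome))
    oracle <- brute_force_sites(fx$calls, fx$genome)
    expect_equal(res$sites$apt_start, oracle$apt_start)
    expect_equal(res$sites$ratio, oracle$ratio)
  }
})

test_that("filtered calls partition into symmetric, asymmetric and non-ApT", {
  set.seed(7)
  fx <- random_call_fixture(genome_len = 8000, n_calls = 300)
  res <- suppressWarnings(call_symmetric_sites(fx$calls, fx$genome))
  expect_equal(2 * nrow(res$sites) + nrow(res$asymmetric) +
                 nrow(res$non_apt) + res$n_excluded,
               nrow(fx$calls))
})

test_that("site calls are invariant under reverse complement", {
  set.seed(11)
  fx <- random_call_fixture(genome_len = 4000, n_calls = 120)
  res <- suppressWarnings(call_symmetric_sites(fx$calls, fx$genome))
  L <- Biostrings::width(fx$genome)[1]
  rc <- Biostrings::reverseComplement(fx$genome)
  flipped <- fx$calls
  flipped$position <- L - 1L - fx$calls$position
  flipped$strand <- ifelse(fx$calls$strand == "+", "-", "+")
  res_rc <- suppressWarnings(call_symmetric_sites(flipped, rc))
  # an ApT at (i, i+1) maps to an ApT at (L-2-i, L-1-i) on the complement
  expect_setequal(res_rc$sites$apt_start, L - 2L - res$sites$apt_start)
  m <- match(L - 2L - res$sites$apt_start, res_rc$sites$apt_start)
  expect_equal(res_rc$sites$ratio[m], res$sites$ratio)
})

test_that("methylome summary is internally consistent on simulated data", {
  cfg <- sim_config(seed = 3, n_genes = 60, genome_length = 400000)
  gen <- simulate_genome(cfg)
  calls <- simulate_methylome(cfg, gen$genome, gen$truth, 1)
  summ <- methylome_summary(calls, gen$genome)
  expect_equal(summ$n_calls_raw, nrow(calls))
  expect_equal(2 * summ$n_symmetric_sites + summ$n_asymmetric_calls +
                 summ$n_non_apt_calls + summ$n_excluded,
               summ$n_calls_filtered)
  expect_equal(sum(summ$motif_spectrum), 1, tolerance = 1e-9)
  expect_equal(names(summ$motif_spectrum)[1], "AATT")
  expect_gt(summ$pct_symmetric_apt, 50)
  expect_output(print(summ), "symmetric ApT sites")
})
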