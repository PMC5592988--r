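# MeDIP array filter cascade: log ratios, Tm-binned Z-scores, probe calling,
# gene aggregation and line-exclusive classification.

test_that("log2 ratios follow the Cy5/Cy3 convention with flooring", {
  tab <- data.frame(cy3 = c(1000, 1000, 1024, NA),
                    cy5 = c(1000, 4000, 0, 500))
  out <- compute_log_ratios(tab, floor = 1)
  expect_equal(out$log2_ratio[1], 0)
  expect_equal(out$log2_ratio[2], 2)   # fourfold = the cascade's cutoff scale
  expect_equal(out$log2_ratio[3], -10) # floored zero against 2^10
  expect_true(is.na(out$log2_ratio[4]) && out$flagged[4])
})

test_that("sample z-scores match direct mean/SD computation and the global reduction", {
  tab <- toy_probe_table(c(0, 0, 0, 0, 10), tm = rep(75, 5))
  z <- compute_tm_binned_zscores(tab, n_bins = 1, method = "sample")$z_score
  expect_equal(z[5], 8 / sd(c(0, 0, 0, 0, 10)), tolerance = 1e-12)
  expect_equal(z[5], 1.78885438, tolerance = 1e-7)

  # all ratios equal in a bin -> all zero (zero-spread rule)
  flat <- compute_tm_binned_zscores(toy_probe_table(rep(2, 6)),
                                    n_bins = 2, method = "sample")
  expect_true(all(flat$z_score == 0))

  # n_bins = 1 equals ordinary global standardisation
  set.seed(4)
  tab <- toy_probe_table(rnorm(50), tm = runif(50, 70, 90))
  z1 <- compute_tm_binned_zscores(tab, n_bins = 1, method = "sample")$z_score
  expect_equal(z1, as.vector(scale(tab$log2_ratio)), tolerance = 1e-12)
})

test_that("z-scores standardise every populated Tm bin to mean 0 / SD 1", {
  set.seed(11)
  tab <- toy_probe_table(rnorm(400), tm = runif(400, 70, 90))
  out <- compute_tm_binned_zscores(tab, n_bins = 10, method = "sample")
  for (b in unique(out$tm_bin)) {
    zb <- out$z_score[out$tm_bin == b]
    expect_gt(length(zb), 1)
    expect_equal(mean(zb), 0, tolerance = 1e-12)
    expect_equal(sd(zb), 1, tolerance = 1e-12)
  }
})

test_that("robust z-scores resist contamination and handle zero spread", {
  # 4 planted outliers among 100: sample z is bounded near sqrt(100/4) = 5,
  # robust z measures distance to the background Gaussian instead
  set.seed(2)
  ratio <- c(rep(3, 4), rnorm(96, 0, 0.3))
  tab <- toy_probe_table(ratio, tm = rep(80, 100))
  zs <- compute_tm_binned_zscores(tab, n_bins = 1, method = "sample")$z_score
  zr <- compute_tm_binned_zscores(tab, n_bins = 1, method = "robust")$z_score
  expect_lt(max(abs(zs[1:4])), 5.5)
  expect_gt(min(abs(zr[1:4])), 5)
  # noiseless background: displaced probes at +/-Inf, background exactly 0
  clean <- toy_probe_table(c(rep(0, 8), 3), tm = rep(80, 9))
  z0 <- compute_tm_binned_zscores(clean, n_bins = 1, method = "robust")$z_score
  expect_identical(z0[1:8], rep(0, 8))
  expect_identical(z0[9], Inf)
})

test_that("the cascade is a strict conjunction of fold and z cutoffs", {
  ids <- sprintf("P%03d", 1:10)
  base <- toy_probe_table(rep(0, 10), z = rep(0, 10), ids = ids)
  # identical groups -> nothing called
  none <- call_differential_probes(list(base, base), list(base, base))
  expect_false(any(none$called))
  expect_true(all(none$direction == "unchanged"))

  # planted probe at +3 with |z| = 8 -> called hyper; |z| = 4 -> vetoed
  hot <- base
  hot$log2_ratio[1] <- 3
  hot$z_score[1] <- 8
  called <- call_differential_probes(list(hot), list(base))
  expect_true(called$called[1])
  expect_identical(called$direction[1], "hyper")
  lukewarm <- hot
  lukewarm$z_score[1] <- 4
  vetoed <- call_differential_probes(list(lukewarm), list(base))
  expect_false(vetoed$called[1])
  # shift below the fold cutoff is vetoed no matter the z
  small <- base
  small$log2_ratio[2] <- 1.5
  small$z_score[2] <- 20
  expect_false(call_differential_probes(list(small), list(base))$called[2])
  expect_error(call_differential_probes(list(), list(base)), "replicate")
})

test_that("raising either cutoff never enlarges the called set", {
  set.seed(21)
  n <- 200
  a <- toy_probe_table(rnorm(n, 0, 2), z = rnorm(n, 0, 4))
  b <- toy_probe_table(rnorm(n, 0, 2), z = rnorm(n, 0, 4))
  loose <- call_differential_probes(list(a), list(b), fold_cut = 1, z_cut = 2)
  for (fc in c(1, 2, 3)) {
    for (zc in c(2, 4, 6)) {
      tight <- call_differential_probes(list(a), list(b),
                                        fold_cut = fc, z_cut = zc)
      expect_true(all(tight$probe_id[tight$called] %in%
                        loose$probe_id[loose$called]))
    }
  }
})

test_that("gene aggregation applies majority vote with tie -> unchanged + conflict", {
  calls <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P5"),
    mean_diff = c(3, 3, 3, -3, 0),
    z_driving = c(8, 8, 8, -8, 0),
    called = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = c("hyper", "hyper", "hyper", "hypo", "unchanged"),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(probe_id = c("P1", "P2", "P3", "P4", "P5"),
                    gene_id = c("gA", "gA", "gB", "gB", "gC"),
                    stringsAsFactors = FALSE)
  out <- aggregate_probes_to_genes(calls, ann)
  expect_identical(out$status[out$gene_id == "gA"], "hyper")
  expect_identical(out$status[out$gene_id == "gB"], "unchanged")
  expect_true(out$conflict[out$gene_id == "gB"])
  expect_identical(out$status[out$gene_id == "gC"], "unchanged")
  s <- attr(out, "summary")
  expect_identical(s$n_called_probes, 4L)
  expect_identical(s$n_called_loci, 1L)
})

test_that("probe-to-gene interval mapping uses half-open overlap", {
  probes <- data.frame(probe_id = c("P1", "P2", "P3"), chrom = "chr1",
                       start = c(0L, 100L, 500L), end = c(60L, 160L, 560L))
  islands <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                        start = c(0L, 100L), end = c(100L, 200L))
  ann <- map_probes_to_genes(probes, islands)
  expect_identical(ann$gene_id, c("gA", "gB", NA))
  # a probe starting exactly at an island's (half-open) end does not overlap
  edge <- data.frame(probe_id = "PX", chrom = "chr1", start = 100L, end = 160L)
  expect_identical(map_probes_to_genes(edge, islands["1", ])$gene_id,
                   NA_character_)
})

test_that("calls in one line only are all exclusive and sets partition correctly", {
  mk <- function(status) data.frame(gene_id = c("g1", "g2", "g3"),
                                    status = status, stringsAsFactors = FALSE)
  res <- classify_line_specific(list(
    mus = mk(c("hyper", "hypo", "unchanged")),
    spretus = mk(rep("unchanged", 3)),
    dunni = mk(rep("unchanged", 3)),
    pahari = mk(c("unchanged", "unchanged", "hyper"))
  ))
  expect_identical(res$exclusive$mus$hyper, "g1")
  expect_identical(res$exclusive$mus$hypo, "g2")
  expect_identical(res$exclusive$pahari$hyper, "g3")
  expect_identical(nrow(res$shared), 0L)
  # shared gene ends up in the intersection table, not any exclusive set
  res2 <- classify_line_specific(list(
    mus = mk(c("hyper", "unchanged", "unchanged")),
    spretus = mk(c("hyper", "unchanged", "unchanged")),
    dunni = mk(rep("unchanged", 3)),
    pahari = mk(rep("unchanged", 3))
  ))
  expect_identical(res2$shared$gene_id, "g1")
  expect_true(all(vapply(res2$exclusive,
                         function(e) length(c(e$hyper, e$hypo)) == 0L,
                         logical(1))))
})

test_that("swapping Cy5/Cy3 negates ratios and mirrors hyper/hypo labels", {
  cfg <- sim_config(n_genes = 60, probes_per_gene = 2, noise_sd = 0.2,
                    n_replicates = 2, rng_seed = 31L)
  set.seed(31)
  truth <- sim_array_truth(cfg, n_per_line = 3, shift = 3)
  sim <- sim_cpg_arrays(cfg, truth)
  swapped <- lapply(sim$arrays, function(reps) lapply(reps, function(tab) {
    tmp <- tab$cy3
    tab$cy3 <- tab$cy5
    tab$cy5 <- tmp
    tab
  }))
  fwd <- medip_pipeline(sim$arrays, sim$annotation)
  rev <- medip_pipeline(swapped, sim$annotation)
  for (l in names(fwd$probe_calls)) {
    expect_equal(rev$probe_calls[[l]]$mean_diff,
                 -fwd$probe_calls[[l]]$mean_diff, tolerance = 1e-12)
    expect_identical(rev$probe_calls[[l]]$called, fwd$probe_calls[[l]]$called)
    flip <- c(hyper = "hypo", hypo = "hyper", unchanged = "unchanged")
    expect_identical(unname(flip[fwd$gene_calls[[l]]$status]),
                     rev$gene_calls[[l]]$status)
  }
})

test_that("zero-noise planted simulations are recovered exactly", {
  cfg <- sim_config(n_genes = 100, probes_per_gene = 2, noise_sd = 0,
                    n_replicates = 2, rng_seed = 5L)
  set.seed(5)
  truth <- sim_array_truth(cfg, n_per_line = 5, shift = 3)
  sim <- sim_cpg_arrays(cfg, truth)
  res <- medip_pipeline(sim$arrays, sim$annotation)
  conf <- planted_confusion(res, sim)
  expect_identical(conf$sensitivity, 1)
  expect_identical(conf$specificity, 1)
  # exclusive sets match planted truth exactly
  for (l in names(res$gene_calls)) {
    for (dir in c("hyper", "hypo")) {
      want <- sort(sim$truth$gene_id[sim$truth$line == l &
                                       sim$truth$direction == dir])
      expect_identical(sort(res$line_specific$exclusive[[l]][[dir]]), want)
    }
  }
})
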