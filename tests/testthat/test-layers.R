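test_that("probes take the score of their containing bin, half-open", {
  manifest <- tibble::tibble(
    probe_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr9"),
    pos = c(50, 101, 10), cpg_relation = "OpenSea",
    genic_group = "Intergenic")
  track <- tibble::tibble(chrom = "chr1", start = c(0, 100),
                          end = c(100, 200), score = c(0.7, 0.2))
  scored <- assign_hic_scores(manifest, track)
  expect_equal(scored$score[scored$probe_id == "a"], 0.7)
  # 1-based pos 101 is 0-based 100 == first bin's end: next bin
  expect_equal(scored$score[scored$probe_id == "b"], 0.2)
  # chr9 has no coverage: dropped and counted
  expect_false("c" %in% scored$probe_id)
  expect_equal(attr(scored, "n_uncovered"), 1L)
  # overlapping bins are rejected
  bad <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 150),
                        score = 1:2)
  expect_error(assign_hic_scores(manifest, bad),
               class = "radialmeth_error_validation")
})

test_that("rank-based layering gives equal occupancy and ordered scores", {
  sc <- tibble::tibble(probe_id = sprintf("p%02d", 1:10), chrom = "chr1",
                       pos = 1:10 * 100, score = 10:1)
  model <- build_layers(sc, n_layers = 5L)
  lay <- model$assignment
  expect_equal(as.character(lay$layer[lay$score %in% c(1, 2)]), c("L1", "L1"))
  expect_equal(as.character(lay$layer[lay$score %in% c(9, 10)]), c("L5", "L5"))
  expect_equal(as.vector(table(lay$layer)), rep(2L, 5))
  expect_equal(model$boundaries[1], 1)
  expect_equal(model$boundaries[6], 10)

  # occupancy within +/- 1 for sizes not divisible by 5
  for (n in c(11, 13, 104)) {
    sci <- tibble::tibble(probe_id = sprintf("q%03d", 1:n), chrom = "chr1",
                          pos = 1:n, score = rnorm(n))
    occ <- table(build_layers(sci)$assignment$layer)
    expect_lte(max(occ) - min(occ), 1)
  }

  # all-tied scores still fill every layer by the rank tie rule
  tied <- tibble::tibble(probe_id = sprintf("t%d", 1:5), chrom = "chr1",
                         pos = 1:5, score = 0)
  expect_warning(mt <- build_layers(tied), "identical")
  expect_equal(as.vector(table(mt$assignment$layer)), rep(1L, 5))
})

test_that("layer assignment is invariant to probe input order", {
  set.seed(21)
  sc <- tibble::tibble(probe_id = sprintf("p%03d", 1:57), chrom = "chr1",
                       pos = sample.int(1e5, 57),
                       score = sample(rep(rnorm(20), length.out = 57)))
  a <- build_layers(sc)$assignment
  b <- build_layers(sc[sample.int(57), ])$assignment
  expect_equal(a, b[match(a$probe_id, b$probe_id), ], ignore_attr = TRUE)
})

test_that("layer frequency profiles are percentages summing to 100", {
  sc <- tibble::tibble(probe_id = sprintf("p%02d", 1:20), chrom = "chr1",
                       pos = 1:20, score = 1:20)
  model <- build_layers(sc)
  dmps <- tibble::tibble(probe_id = c("p01", "p02", "p05", "p06", "p09",
                                      "p10", "p13", "p14", "p17", "p18"),
                         passes = TRUE)
  prof <- layer_frequency(dmps, model)
  expect_equal(prof$pct_dmp, rep(20, 5))
  expect_equal(sum(prof$pct_dmp), 100)
  expect_equal(sum(prof$pct_background), 100)
  one <- layer_frequency(tibble::tibble(probe_id = c("p01", "p02"),
                                        passes = TRUE), model)
  expect_equal(one$pct_dmp, c(100, 0, 0, 0, 0))
})

test_that("chromosome normalization divides DMPs by probe totals", {
  manifest <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:150),
    chrom = rep(c("chr1", "chr2", "chr3"), c(100, 40, 10)),
    pos = 1:150, cpg_relation = "OpenSea", genic_group = "Intergenic")
  dmps <- tibble::tibble(probe_id = c(sprintf("p%03d", 1:2)), passes = TRUE)
  out <- chromosome_normalized_frequency(dmps, manifest)
  expect_equal(out$frequency[out$chrom == "chr1"], 0.02)
  expect_equal(out$frequency[out$chrom == "chr2"], 0)
  # scale invariance: doubling probes and DMPs proportionally
  manifest2 <- dplyr::bind_rows(
    manifest, dplyr::mutate(manifest, probe_id = paste0(probe_id, "x")))
  dmps2 <- tibble::tibble(probe_id = c(dmps$probe_id,
                                       paste0(dmps$probe_id, "x")),
                          passes = TRUE)
  out2 <- chromosome_normalized_frequency(dmps2, manifest2)
  expect_equal(out2$frequency[out2$chrom == "chr1"], 0.02)
})

test_that("per-layer chromosome cells are NA when no probes, not zero", {
  manifest <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:20),
    chrom = rep(c("chrA", "chrB"), each = 10),
    pos = rep(1:10 * 50, 2), cpg_relation = "OpenSea",
    genic_group = "Intergenic")
  # scores put all of chrA low, all of chrB high: chrA fills L1-L3 etc.
  sc <- tibble::tibble(probe_id = manifest$probe_id, chrom = manifest$chrom,
                       pos = manifest$pos, score = 1:20)
  model <- build_layers(sc)
  dmps <- tibble::tibble(probe_id = c("p01", "p02"), passes = TRUE)
  out <- per_layer_chromosome_frequency(dmps, model, manifest)
  cellA5 <- out[out$chrom == "chrA" & out$layer == "L5", ]
  expect_true(is.na(cellA5$frequency))
  cellA1 <- out[out$chrom == "chrA" & out$layer == "L1", ]
  expect_equal(cellA1$frequency, 2 / 4)
})

test_that("layer mean |delta| averages magnitudes and flags empty layers", {
  sc <- tibble::tibble(probe_id = sprintf("p%02d", 1:10), chrom = "chr1",
                       pos = 1:10, score = 1:10)
  model <- build_layers(sc)
  dmps <- tibble::tibble(probe_id = c("p01", "p02"),
                         delta_vs_control = c(1, -1), passes = TRUE)
  prof <- layer_mean_abs_change(dmps, model)
  expect_equal(prof$mean_abs_delta[prof$layer == "L1"], 1)
  expect_true(all(is.na(prof$mean_abs_delta[prof$layer != "L1"])))
})

test_that("an L3-peaked planted profile is recovered as an L3 peak", {
  cfg <- small_sim_config(seed = 320, n_probes = 6000L)
  sim <- simulate_inputs(cfg)
  ex <- as_m_scale(sim$experiment)
  sm <- ex$samples
  ga <- sm$sample_id[sm$particle == "Fe" & sm$dose_gy > 0 &
                       sm$timepoint == "48h"]
  gb <- sm$sample_id[sm$particle == "Si" & sm$dose_gy > 0 &
                       sm$timepoint == "48h"]
  dmps <- call_dmps(ex, ga, gb)
  model <- build_layers(assign_hic_scores(sim$manifest, sim$hic))
  prof <- layer_mean_abs_change(dmps, model)
  expect_equal(prof$layer[which.max(prof$mean_abs_delta)], "L3")
})
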