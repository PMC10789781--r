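test_that("peak filters apply inclusive length bounds and the score rule", {
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 1000, 3000, 6000, 9000),
    end = c(250, 1300, 5000, 6400, 9500),    # lengths 250, 300, 2000, 400, 500
    name = letters[1:5],
    score = c(50, 10, 9.99, 0, 15))
  out <- filter_peaks(peaks, score_op = "ge", score_threshold = 10)
  expect_equal(out$name, c("b", "e"))  # 250 too short; 9.99 and 0 low score
  rm <- attr(out, "removed")
  expect_equal(unname(rm["too_short"]), 1L)
  expect_equal(unname(rm["low_score"]), 2L)
  # gt rule drops score exactly 0
  out2 <- filter_peaks(peaks, score_op = "gt", score_threshold = 0)
  expect_false("d" %in% out2$name)
  # length 2000 kept when score passes
  out3 <- filter_peaks(peaks, score_op = "ge", score_threshold = 0)
  expect_true("c" %in% out3$name)
})

test_that("probe/peak overlap flags match a quadratic scan oracle", {
  set.seed(91)
  manifest <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:300),
    chrom = sample(c("chr1", "chr2"), 300, TRUE),
    pos = sample.int(50000, 300),
    cpg_relation = "OpenSea", genic_group = "Intergenic")
  mk_peaks <- function(n) {
    s <- sample.int(49000, n)
    tibble::tibble(chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = s, end = s + sample(300:2000, n, TRUE),
                   name = NA_character_, score = 1)
  }
  sets <- list(H3K4me3 = mk_peaks(40), H3K9me3 = mk_peaks(40))
  flags <- overlap_probes(sets, manifest)
  for (mark in names(sets)) {
    expect_equal(flags[[mark]],
                 overlap_oracle(manifest$chrom, manifest$pos, sets[[mark]]))
  }
  # a probe inside peaks of two marks carries both
  both <- flags$H3K4me3 & flags$H3K9me3
  if (any(both)) expect_true(all(flags$H3K4me3[both]))
})

test_that("mark layer distributions sum to 100% per mark", {
  cfg <- small_sim_config(seed = 330)
  sim <- simulate_inputs(cfg)
  model <- build_layers(assign_hic_scores(sim$manifest, sim$hic))
  flags <- overlap_probes(sim$peaks, sim$manifest)
  dist <- layer_mark_distribution(flags, model)
  sums <- tapply(dist$pct, dist$mark, sum)
  expect_equal(as.vector(sums), rep(100, 4), tolerance = 1e-9)
  # peripherally planted H3K9me3 decreases toward inner layers
  k9 <- dist$pct[dist$mark == "H3K9me3"]
  mk <- mann_kendall(k9)
  expect_lt(mk$s, 0)
  # absent mark flagged NA
  flags$empty <- FALSE
  dist2 <- layer_mark_distribution(flags, model)
  expect_true(all(is.na(dist2$pct[dist2$mark == "empty"])))
})

test_that("the enrichment ratio reproduces direct counting", {
  # worked example: 10 of 100 DMPs in-region-in-layer, 200 of 1000 region
  # probes in the layer -> 0.1 / 0.2 = 0.5
  n <- 2000
  ids <- sprintf("p%04d", 1:n)
  model <- build_layers(tibble::tibble(probe_id = ids, chrom = "chr1",
                                       pos = 1:n, score = 1:n))
  l3_ids <- model$assignment$probe_id[model$assignment$layer == "L3"]
  other <- setdiff(ids, l3_ids)
  region <- c(l3_ids[1:200], other[1:800])            # 200/1000 in L3
  dmps <- tibble::tibble(probe_id = c(l3_ids[1:10], other[801:890]),
                         passes = TRUE)               # 10/100 in region&L3
  flags <- tibble::tibble(probe_id = ids, region = ids %in% region)
  out <- dmp_enrichment_ratio(dmps, flags, model)
  expect_equal(out$ratio[out$layer == "L3"], 0.5)

  # random instances against the brute-force oracle
  set.seed(92)
  layer_of <- setNames(as.character(model$assignment$layer),
                       model$assignment$probe_id)
  for (i in 1:20) {
    dmp_ids <- sample(ids, 150)
    region_ids <- sample(ids, 500)
    fl <- tibble::tibble(probe_id = ids, region = ids %in% region_ids)
    got <- dmp_enrichment_ratio(tibble::tibble(probe_id = dmp_ids,
                                               passes = TRUE), fl, model)
    for (ly in paste0("L", 1:5)) {
      expect_equal(got$ratio[got$layer == ly],
                   enrichment_oracle(dmp_ids, region_ids, layer_of, ly),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment satisfies the weighted-average identity and null value", {
  set.seed(93)
  n <- 1000
  ids <- sprintf("p%04d", 1:n)
  model <- build_layers(tibble::tibble(probe_id = ids, chrom = "chr1",
                                       pos = 1:n, score = rnorm(n)))
  region_ids <- sample(ids, 400)
  dmp_ids <- sample(ids, 200)
  fl <- tibble::tibble(probe_id = ids, region = ids %in% region_ids)
  out <- dmp_enrichment_ratio(tibble::tibble(probe_id = dmp_ids,
                                             passes = TRUE), fl, model)
  # sum over layers of ratio x (layer region fraction) = overall ratio
  lhs <- sum(out$ratio * out$n_region / length(region_ids))
  rhs <- mean(dmp_ids %in% region_ids) / 1  # region covers all layers
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # DMPs distributed exactly like the region probes -> ratio 1 everywhere
  out1 <- dmp_enrichment_ratio(tibble::tibble(probe_id = region_ids,
                                              passes = TRUE), fl, model)
  expect_equal(out1$ratio, rep(1, 5), tolerance = 1e-12)
  # empty layer denominators are NA, not zero
  fl2 <- tibble::tibble(probe_id = ids,
                        region = ids %in% model$assignment$probe_id[
                          model$assignment$layer == "L1"])
  out2 <- dmp_enrichment_ratio(tibble::tibble(probe_id = dmp_ids,
                                              passes = TRUE), fl2, model)
  expect_true(all(is.na(out2$ratio[out2$layer != "L1"])))
})

test_that("regulatory groups partition TSS regions and exclude genic enhancers", {
  tss <- tibble::tibble(chrom = "chr1", pos0 = c(10000, 50000, 90000, 130000),
                        gene_id = paste0("g", 1:4))
  bodies <- tibble::tibble(chrom = "chr1", start = tss$pos0,
                           end = tss$pos0 + 20000, name = tss$gene_id)
  k4 <- tibble::tibble(chrom = "chr1", start = c(9000, 89000),
                       end = c(9500, 89500), name = NA, score = 20)
  k27 <- tibble::tibble(chrom = "chr1",
                        start = c(49000, 89600, 300000, 135000),
                        end = c(49400, 90100, 300500, 135400),
                        name = NA, score = 20)
  gr <- build_regulatory_groups(tss, bodies, k4, k27, tss_halfwidth = 2000)
  expect_equal(gr$k4_promoters$name, "g1")
  expect_equal(gr$k27ac_promoters$name, "g2")
  expect_equal(gr$dual_promoters$name, "g3")
  expect_equal(gr$bare_promoters$name, "g4")   # k27 at 135000 is 3 kb past TSS
  # the four classes partition the TSS set
  expect_equal(nrow(gr$k4_promoters) + nrow(gr$k27ac_promoters) +
                 nrow(gr$dual_promoters) + nrow(gr$bare_promoters),
               nrow(tss))
  # enhancer: the K27ac peak at 300000 is outside every TSS region and body;
  # the peak at 135000 is inside g4's gene body, hence not an enhancer
  expect_equal(gr$k27ac_enhancers$start, 300000)
})

test_that("group methylation change averages |delta| within group x layer", {
  ids <- sprintf("p%02d", 1:10)
  manifest <- tibble::tibble(probe_id = ids, chrom = "chr1",
                             pos = 1:10 * 1000, cpg_relation = "OpenSea",
                             genic_group = "Intergenic")
  model <- build_layers(tibble::tibble(probe_id = ids, chrom = "chr1",
                                       pos = manifest$pos, score = 1:10))
  dmps <- tibble::tibble(probe_id = c("p01", "p02"), passes = TRUE,
                         delta_vs_control = c(0.6, 1.0))
  groups <- list(g = tibble::tibble(chrom = "chr1", start = 0, end = 2500))
  ctrl <- tibble::tibble(probe_id = ids, control_m = rep(2, 10),
                         n_control = 3)
  out <- group_methylation_change(dmps, groups, model, manifest,
                                  control = ctrl)
  cell <- out[out$group == "g" & out$layer == "L1", ]
  expect_equal(cell$mean_abs_delta, 0.8)
  expect_equal(cell$mean_baseline_m, 2)
  expect_true(is.na(out$mean_abs_delta[out$layer == "L5"]))
})
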