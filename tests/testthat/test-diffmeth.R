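test_that("Beta/M transform matches closed form and round trips", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  x <- seq(1e-6, 1 - 1e-6, length.out = 101)
  expect_equal(m_to_beta(beta_to_m(x)), x, tolerance = 1e-12)
  expect_warning(b <- beta_to_m(c(0, 1)), "clamped")
  expect_equal(b, beta_to_m(c(1e-6, 1 - 1e-6)))
  expect_error(beta_to_m(1.2), class = "radialmeth_error_validation")
})

test_that("pooled control is the mean over all dose-zero samples", {
  m <- matrix(c(-1, 0, 1, 5, 5, 5), nrow = 1,
              dimnames = list("p001", sprintf("s%02d", 1:6)))
  ex <- make_experiment(m, n_control = 3L)
  expect_equal(define_control(ex)$control_m, 0)

  # pairwise exclusion of a missing control value
  m2 <- matrix(c(-1, NA, 1, 3, 3, 3), nrow = 1,
               dimnames = list("p001", sprintf("s%02d", 1:6)))
  ctrl <- define_control(make_experiment(m2, n_control = 3L))
  expect_equal(ctrl$control_m, 0)
  expect_equal(ctrl$n_control, 2)

  ex_no_ctrl <- make_experiment(m, n_control = 0L)
  expect_error(define_control(ex_no_ctrl),
               class = "radialmeth_error_config")
})

test_that("per-probe F test agrees with a brute-force ANOVA oracle", {
  set.seed(401)
  n <- 100
  m <- matrix(rnorm(n * 8), nrow = n,
              dimnames = list(sprintf("p%03d", 1:n), sprintf("s%02d", 1:8)))
  ex <- make_experiment(m, n_control = 2L)
  res <- call_dmps(ex, group_a = colnames(m)[3:5], group_b = colnames(m)[6:8])
  p_oracle <- vapply(seq_len(n), function(i) {
    anova_p_oracle(m[i, 3:5], m[i, 6:8])
  }, numeric(1))
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  expect_equal(res$av_diff, rowMeans(m[, 3:5]) - rowMeans(m[, 6:8]),
               ignore_attr = TRUE)
})

test_that("identical and degenerate groups are handled by the stated rules", {
  m <- rbind(p1 = c(0, 0, 1, 1, 1, 1, 1, 1),
             p2 = c(0, 0, 1, 1, 1, 2, 2, 2),
             p3 = c(0, 0, rnorm(6, sd = 1e-3)))
  colnames(m) <- sprintf("s%02d", 1:8)
  ex <- make_experiment(m, n_control = 2L)
  res <- call_dmps(ex, colnames(m)[3:5], colnames(m)[6:8])
  # identical groups: zero variance, equal means
  expect_true(res$degenerate[1])
  expect_equal(res$p[1], 1)
  expect_equal(res$av_diff[1], 0)
  expect_false(res$passes[1])
  # zero variance, different means
  expect_true(res$degenerate[2])
  expect_equal(res$p[2], 0)
  expect_equal(res$f_stat[2], Inf)
})

test_that("separated groups with tiny jitter give a huge F statistic", {
  set.seed(77)
  m <- matrix(c(rnorm(3, 0, 0.01), rnorm(3, 1, 0.01)), nrow = 1,
              dimnames = list("p001", sprintf("s%02d", 1:6)))
  ex <- make_experiment(cbind(m, `s07` = 0, `s08` = 0)[, c(7:8, 1:6), drop = FALSE],
                        n_control = 2L)
  res <- call_dmps(ex, sprintf("s%02d", 1:3), sprintf("s%02d", 4:6))
  expect_gt(res$f_stat, 1000)
  expect_lt(res$p, 1e-6)
  expect_equal(res$p, anova_p_oracle(m[1, 1:3], m[1, 4:6]),
               tolerance = 1e-10)
})

test_that("direction subgroups follow the sign conventions", {
  ctrl <- tibble::tibble(probe_id = c("a", "b", "c"),
                         control_m = c(-2, 2, 0), n_control = 3)
  dmps <- tibble::tibble(probe_id = c("a", "b", "c"),
                         delta_vs_control = c(1.5, -1.5, 0.7))
  out <- classify_subgroups(dmps, ctrl)
  expect_equal(out$baseline_state, c("hypo", "hyper", "hyper"))
  expect_equal(out$direction, c("up", "down", "up"))
  expect_equal(out$baseline_tie, c(FALSE, FALSE, TRUE))
})

test_that("DMR chaining reproduces the worked gap arithmetic", {
  dmps <- tibble::tibble(probe_id = c("a", "b", "c"), chrom = "chr1",
                         pos = c(100, 600, 2000), passes = TRUE,
                         delta_vs_control = c(1, 2, 3))
  res <- build_dmrs(dmps, lambda = 1000, min_probes = 2L)
  expect_equal(nrow(res$dmrs), 1L)
  expect_equal(res$dmrs$probe_ids[[1]], c("a", "b"))
  expect_equal(res$dmrs$start, 99)
  expect_equal(res$dmrs$end, 600)
  expect_equal(res$dmrs$mean_delta, 1.5)
  expect_equal(res$fraction_inside, 2 / 3)

  # single DMP and degenerate bandwidth
  expect_equal(build_dmrs(dmps[1, ])$fraction_inside, 0)
  expect_equal(nrow(build_dmrs(dmps, lambda = 0)$dmrs), 0L)
  # empty set is not an error
  empty <- build_dmrs(dmps[dmps$pos > 1e9, ])
  expect_equal(nrow(empty$dmrs), 0L)
  expect_true(is.na(empty$fraction_inside))
})

test_that("DMR construction is invariant to input order and partitions DMPs", {
  set.seed(11)
  dmps <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:60),
    chrom = sample(c("chr1", "chr2"), 60, TRUE),
    pos = sample.int(50000, 60), passes = TRUE,
    delta_vs_control = rnorm(60))
  a <- build_dmrs(dmps)
  b <- build_dmrs(dmps[sample.int(60), ])
  expect_equal(a$dmrs, b$dmrs)
  expect_equal(a$fraction_inside, b$fraction_inside)
  expect_equal(sum(a$assignment$in_dmr) + sum(!a$assignment$in_dmr),
               nrow(dmps))
})

test_that("CpG-island distance classes use inclusive 2/4 kb boundaries", {
  islands <- tibble::tibble(chrom = "chr1", start = 10000, end = 11000)
  # 1-based pos such that the 0-based point sits at a known distance
  pos_at <- function(d) 10000 - d + 1  # d bp left of the island start
  cases <- c(inside = 10500, d1500 = pos_at(1500), d2000 = pos_at(2000),
             d2001 = pos_at(2001), d4000 = pos_at(4000),
             d4001 = pos_at(4001), far = pos_at(9000))
  got <- classify_cpg_relation(rep("chr1", length(cases)), cases, islands)
  expect_equal(unname(got),
               c("Island", "Shore", "Shore", "Shelf", "Shelf", "OpenSea",
                 "OpenSea"))
  got3 <- classify_cpg_relation(rep("chr1", length(cases)), cases, islands,
                                levels = 3)
  expect_equal(unname(got3[2]), "ShoreShelf")
  # chromosome with no islands is open sea
  expect_equal(classify_cpg_relation("chr9", 500, islands), "OpenSea")
})

test_that("fraction tables are normalized counts", {
  df <- tibble::tibble(cls = c(rep("Island", 1), rep("Shore", 3),
                               rep("OpenSea", 6)))
  out <- fraction_table(df, "cls")
  expect_equal(sum(out$fraction), 1, tolerance = 1e-12)
  expect_equal(out$fraction[out$cls == "OpenSea"], 0.6)
  expect_equal(fraction_table(df[1, ], "cls")$fraction, 1)
  expect_error(fraction_table(df[0, ], "cls"),
               class = "radialmeth_error_validation")
})

test_that("null M-value data yields uniform p values matching the oracle", {
  set.seed(42)
  n <- 4000
  m <- matrix(rnorm(n * 8, sd = 0.15), nrow = n,
              dimnames = list(sprintf("p%04d", 1:n), sprintf("s%02d", 1:8)))
  ex <- make_experiment(m, n_control = 2L)
  res <- call_dmps(ex, colnames(m)[3:5], colnames(m)[6:8])
  expect_gt(mean(res$p < 0.05), 0.04)
  expect_lt(mean(res$p < 0.05), 0.06)
  idx <- sample.int(n, 50)
  p_oracle <- vapply(idx, function(i) anova_p_oracle(m[i, 3:5], m[i, 6:8]),
                     numeric(1))
  expect_equal(res$p[idx], p_oracle, tolerance = 1e-10)
})
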