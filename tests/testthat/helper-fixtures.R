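# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package (stats::lm/aov loops,
# explicit permutation enumeration, quadratic scans) so that agreement is
# informative.

# A small experiment built directly from an M-value matrix: probes on one
# chromosome at the given positions, first `n_control` samples dose 0.
make_experiment <- function(m, positions = NULL, n_control = 0L,
                            particle = "Fe", scale = "m") {
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%03d", seq_len(n))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(positions)) positions <- seq_len(n) * 1000
  manifest <- tibble::tibble(
    probe_id = rownames(m), chrom = "chr1", pos = positions,
    cpg_relation = "OpenSea", genic_group = "Intergenic")
  samples <- tibble::tibble(
    sample_id = colnames(m), particle = particle,
    dose_gy = c(rep(0, n_control), rep(1, ncol(m) - n_control)),
    timepoint = "48h", replicate = seq_len(ncol(m)))
  meth_experiment(m, samples, manifest, scale = scale)
}

# Per-probe two-group ANOVA p value through stats::anova(lm(...)).
anova_p_oracle <- function(a, b) {
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  anova(lm(y ~ g))[["Pr(>F)"]][1]
}

# Step-up BH computed from the definition q_(i) = min_{j >= i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q_sorted[i] <- min(1, min(m * p[o][j] / j))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# All permutations of a vector (n <= 7).
all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

mk_s_stat <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    for (j in (i + 1):length(x)) s <- s + sign(x[j] - x[i])
  }
  s
}

# Exact one/two-sided Mann-Kendall p by brute-force enumeration.
mk_oracle <- function(x) {
  s_obs <- mk_s_stat(x)
  s_null <- vapply(all_perms(x), mk_s_stat, numeric(1))
  list(s = s_obs,
       p_greater = mean(s_null >= s_obs),
       p_less = mean(s_null <= s_obs),
       p = min(1, 2 * min(mean(s_null >= s_obs), mean(s_null <= s_obs))))
}

# Quadratic point-in-interval scan.
overlap_oracle <- function(chrom, pos, intervals) {
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] - 1 & pos[i] - 1 < intervals$end)
  }, logical(1))
}

# Direct set-counting route for the layer enrichment ratio.
enrichment_oracle <- function(dmp_ids, region_ids, layer_of, layer) {
  region_layers <- layer_of[region_ids]
  dmp_layers <- layer_of[dmp_ids]
  num <- sum(dmp_ids %in% region_ids & !is.na(dmp_layers) &
               dmp_layers == layer) / length(dmp_ids)
  den <- sum(region_layers == layer, na.rm = TRUE) /
    sum(!is.na(region_layers))
  if (den == 0) return(NA_real_)
  num / den
}

small_sim_config <- function(seed, ...) {
  args <- list(n_probes = 2000L, n_chroms = 2L, chrom_length = 1e6,
               n_peaks_per_mark = 300L, n_genes = 400L, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}
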