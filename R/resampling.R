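#' Permute probe labels over value rows
#'
#' Reassigns probe ids to the rows of the value matrix by a uniform random
#' permutation. The multiset of value rows is untouched; only the mapping
#' from genomic coordinates (via the manifest) to methylation values is
#' destroyed, which is exactly the null needed to test whether DMPs
#' cluster in the genome more than chance.
#'
#' @param experiment A [meth_experiment()].
#' @param seed Integer seed.
#' @return The experiment with permuted probe ids.
#' @export
permute_probe_labels <- function(experiment, seed) {
  stopifnot(inherits(experiment, "meth_experiment"))
  with_seed(seed, {
    ids <- rownames(experiment$values)
    perm <- sample.int(length(ids))
    rownames(experiment$values) <- ids[perm]
    experiment
  })
}

#' Permutation test of the DMP-in-DMR fraction
#'
#' Observed statistic: the fraction of passing DMPs that fall inside DMRs
#' (from [call_dmps()] then [build_dmrs()]). The null redistributes probe
#' ids uniformly over value rows and recomputes the statistic B times; the
#' empirical p uses the add-one rule for the chosen tail. Under the
#' paper-style question ("do radiation-induced DMPs cluster?") the
#' alternative is `tail = "greater"`.
#'
#' Permuting probe names leaves every per-row statistic (F, p, q, avDiff,
#' delta vs control) unchanged and only remaps coordinates, so the default
#' `method = "coordinate"` computes the probe-level tests once and reuses
#' them, drawing the same permutations as the naive `method = "full"`
#' pipeline; both give identical results for identical seeds.
#'
#' @inheritParams call_dmps
#' @param B Number of permutation replicates (1000 to match the study
#'   design; 200 is a practical fast mode).
#' @param lambda,min_probes DMR chaining parameters, as [build_dmrs()].
#' @param tail `"greater"`, `"less"` or `"two"`.
#' @param seed Integer seed.
#' @param method `"coordinate"` (fast, exact) or `"full"` (naive
#'   recompute; for verification).
#' @return A `perm_test` object: `observed`, `null` (length B),
#'   `empirical_p`, `B`, `tail`, `n_zero_replicates`.
#' @export
dmr_fraction_permutation_test <- function(experiment, group_a, group_b,
                                          control = NULL, B = 1000,
                                          lambda = 1000, min_probes = 2L,
                                          q_max = 0.05, d_min = 0.58,
                                          tail = c("greater", "less", "two"),
                                          seed,
                                          method = c("coordinate", "full")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  experiment <- as_m_scale(experiment)
  dmps <- call_dmps(experiment, group_a, group_b, control = control,
                    q_max = q_max, d_min = d_min)
  obs_res <- build_dmrs(dmps, lambda = lambda, min_probes = min_probes)
  observed <- obs_res$fraction_inside
  if (is.na(observed)) {
    stop_validation("no passing DMPs in the observed comparison; nothing to test")
  }
  ids <- rownames(experiment$values)
  n <- length(ids)
  ord <- match(ids, dmps$probe_id)
  pass_rows <- which(dmps$passes[ord])      # row indices of passing probes
  coords <- experiment$manifest[match(ids, experiment$manifest$probe_id), ]
  n_zero <- 0L
  null_stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sample.int(n)
      if (method == "coordinate") {
        take <- perm[pass_rows]
        frac <- chain_fraction(coords$chrom[take], coords$pos[take],
                               lambda, min_probes)
      } else {
        pexp <- experiment
        rownames(pexp$values) <- ids[perm]
        pd <- call_dmps(pexp, group_a, group_b, control = NULL,
                        q_max = q_max, d_min = d_min)
        frac <- build_dmrs(pd, lambda = lambda,
                           min_probes = min_probes)$fraction_inside
      }
      if (is.na(frac)) { n_zero <<- n_zero + 1L; frac <- 0 }
      frac
    }, numeric(1))
  })
  p_greater <- (1 + sum(null_stats >= observed)) / (B + 1)
  p_less <- (1 + sum(null_stats <= observed)) / (B + 1)
  empirical_p <- switch(tail, greater = p_greater, less = p_less,
                        two = min(1, 2 * min(p_greater, p_less)))
  structure(list(observed = observed, null = null_stats,
                 empirical_p = empirical_p, B = B, tail = tail,
                 n_zero_replicates = n_zero),
            class = "perm_test")
}

# Fraction of points that sit in a chain of >= min_probes consecutive
# points with gaps <= lambda (the DMR membership rule).
chain_fraction <- function(chrom, pos, lambda, min_probes) {
  n <- length(pos)
  if (n == 0L) return(NA_real_)
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  new_chain <- c(TRUE, diff(pos) > lambda | chrom[-1] != chrom[-n])
  chain_id <- cumsum(new_chain)
  size <- tabulate(chain_id)
  sum(size[size >= min_probes]) / n
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> observed %.4f vs %d permutations (tail %s)\n",
              x$observed, x$B, x$tail))
  cat(sprintf("  empirical p = %.4g; null median %.4f [%.4f, %.4f]\n",
              x$empirical_p, median(x$null), min(x$null), max(x$null)))
  invisible(x)
}

#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, empirical_p = x$empirical_p, B = x$B,
         tail = x$tail, null_median = median(x$null),
         null_min = min(x$null), null_max = max(x$null))
}

#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: step-up q values,
#' monotone in p and capped at 1.
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA passed through).
#' @return Vector of q values.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_validation("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Mann-Kendall trend test
#'
#' `S = sum_{i<j} sign(x_j - x_i)` over the ordered series, Kendall's
#' tau-b, and a p value: exact (full enumeration of the tie-free null
#' distribution of S) for n <= 9 without ties, otherwise the normal
#' approximation with continuity and tie correction. Requires at least
#' `min_n` points.
#'
#' @param values Ordered numeric vector (time order).
#' @param min_n Minimum series length (default 4).
#' @return A list: `s`, `tau`, `p` (two-sided), `p_greater`, `p_less`,
#'   `n`, `method`.
#' @export
mann_kendall <- function(values, min_n = 4L) {
  n <- length(values)
  if (n < min_n) {
    stop_validation(sprintf(
      "Mann-Kendall trend analysis needs at least %d data points (got %d)",
      min_n, n))
  }
  d <- outer(values, values, "-")
  s <- sum(sign(d[lower.tri(d)])) # row i > col j, so d = x_j - x_i over i < j
  ties <- table(values)
  n0 <- n * (n - 1) / 2
  tie_term <- sum(ties * (ties - 1) / 2)
  tau_den <- sqrt((n0 - tie_term) * n0)
  tau <- if (tau_den > 0) s / tau_den else NA_real_
  has_ties <- any(ties > 1)
  if (n <= 9 && !has_ties) {
    dist <- mk_exact_distribution(n)
    p_greater <- sum(dist$prob[dist$s >= s])
    p_less <- sum(dist$prob[dist$s <= s])
    method <- "exact"
  } else {
    var_s <- (n * (n - 1) * (2 * n + 5) -
                sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (var_s > 0) (s - sign(s)) / sqrt(var_s) else 0
    if (s == 0) z <- 0
    p_greater <- pnorm(z, lower.tail = FALSE)
    p_less <- pnorm(z)
    method <- "normal"
  }
  list(s = s, tau = tau, p = min(1, 2 * min(p_greater, p_less)),
       p_greater = p_greater, p_less = p_less, n = n, method = method)
}

# Exact tie-free null distribution of S for series length n: S = n(n-1)/2 -
# 2 * (number of inversions), and the inversion counts over all n!
# permutations follow the Mahonian recurrence (iterated convolution with a
# uniform block) -- an exact enumeration without materializing n! cases.
mk_exact_distribution <- function(n) {
  counts <- 1
  for (k in 2:n) {
    new <- numeric(length(counts) + k - 1)
    for (shift in 0:(k - 1)) {
      idx <- seq_along(counts) + shift
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  inv <- seq_along(counts) - 1
  tibble(s = n * (n - 1) / 2 - 2 * inv, prob = counts / sum(counts))
}

#' Pearson chi-squared test of homogeneity
#'
#' Wrapper over `stats::chisq.test` without continuity correction; refuses
#' tables with any zero expected count.
#'
#' @param table An r x c matrix of counts.
#' @return A list: `stat`, `df`, `p`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) {
    stop_validation("all expected counts must be positive")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(stat = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' ANOVA on the slope of a linear regression
#'
#' Ordinary least-squares slope of `y` on `x` and the F test of slope = 0
#' (the regression ANOVA used for trend analysis of expression
#' trajectories). A constant `y` returns slope 0 with F = 0 and p = 1.
#'
#' @param y Response vector (n >= 3).
#' @param x Ordered numeric predictor (not constant).
#' @return A list: `slope`, `f`, `p`.
#' @export
slope_anova <- function(y, x) {
  if (length(y) < 3L) stop_validation("slope_anova() needs n >= 3")
  if (length(unique(x)) < 2L) stop_validation("`x` must not be constant")
  if (length(unique(y)) == 1L) return(list(slope = 0, f = 0, p = 1))
  fit <- lm(y ~ x)
  # an exact linear fit triggers a precision warning inside anova.lm; the
  # resulting p is still the correct limit (effectively zero)
  a <- suppressWarnings(anova(fit))
  list(slope = unname(coef(fit)[2]), f = a[["F value"]][1],
       p = a[["Pr(>F)"]][1])
}
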