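#' TMM normalization factors
#'
#' Per-sample scaling factors from the weighted trimmed mean of M values
#' (log expression ratios) against an automatically chosen reference (the
#' sample whose upper quartile is closest to the mean upper quartile),
#' scaled to geometric mean 1. Computed by `edgeR::calcNormFactors`, the
#' same normalizer the original sequencing analyses use.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @return A tibble (`sample_id`, `norm_factor`, `lib_size`,
#'   `effective_lib_size`).
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2L) stop_validation("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop_validation(sprintf("sample(s) with zero total count: %s",
                            paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  tibble(sample_id = colnames(counts), norm_factor = unname(f),
         lib_size = unname(lib), effective_lib_size = unname(lib * f))
}

#' Filter microarray genes by median intensity
#'
#' Keeps genes whose median normalized intensity across samples is at
#' least `min_median` (boundary inclusive).
#'
#' @param intensities Genes x samples matrix of normalized intensities.
#' @param min_median Threshold (default 3).
#' @return Character vector of retained gene ids.
#' @export
filter_microarray <- function(intensities, min_median = 3) {
  med <- apply(intensities, 1, median, na.rm = TRUE)
  keep <- rownames(intensities)[med >= min_median]
  if (length(keep) == 0L) {
    warn("no genes pass the median-intensity filter")
  }
  keep
}

#' Default astronaut timepoint pairing
#'
#' The shipped mapping from ten single-replicate mission timepoints to five
#' analysis groups of two pseudo-replicates each: pre-flight control,
#' early in-flight, late in-flight, early post-flight, late post-flight
#' (L = launch, R = return).
#'
#' @return A tibble (`raw_label`, `group`).
#' @export
astronaut_default_pairing <- function() {
  tibble(
    raw_label = c("L-112", "L-56", "L+5", "L+30", "L+60/120", "R-8",
                  "R+3", "R+30", "R+60", "R+120"),
    group = rep(c("control", "inflight_early", "inflight_late",
                  "postflight_early", "postflight_late"), each = 2))
}

#' Group single-replicate timepoints into pseudo-replicated groups
#'
#' Astronaut expression series come as one mean profile per raw timepoint;
#' consecutive timepoints are paired into groups of two pseudo-replicates
#' so that differential testing is possible. The first group is the
#' pre-flight control.
#'
#' @param samples Tibble (`sample_id`, `raw_label`) of the raw series.
#' @param pairing Tibble (`raw_label`, `group`); default
#'   [astronaut_default_pairing()].
#' @param allow_unbalanced Permit groups with a membership other than 2.
#' @return A timepoint sheet tibble (`sample_id`, `raw_label`, `group`)
#'   with attribute `control_group` (the first group in pairing order).
#' @export
group_astronaut_timepoints <- function(samples,
                                       pairing = astronaut_default_pairing(),
                                       allow_unbalanced = FALSE) {
  check_columns(samples, c("sample_id", "raw_label"), "sample table")
  check_columns(pairing, c("raw_label", "group"), "pairing")
  unmapped <- setdiff(samples$raw_label, pairing$raw_label)
  if (length(unmapped) > 0L) {
    stop_validation(sprintf("raw timepoint label(s) not in pairing: %s",
                            paste(unmapped, collapse = ", ")))
  }
  out <- dplyr::left_join(samples, pairing, by = "raw_label")
  sizes <- table(out$group)
  if (!allow_unbalanced && any(sizes != 2L)) {
    bad <- names(sizes)[sizes != 2L]
    stop_validation(sprintf(
      "group(s) with membership != 2 under the default pairing: %s (set allow_unbalanced = TRUE to override)",
      paste(bad, collapse = ", ")))
  }
  attr(out, "control_group") <- pairing$group[1]
  out
}

# log2 counts-per-million on TMM-corrected library sizes, 0.5 pseudo-count.
log_cpm <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$effective_lib_size[match(colnames(counts),
                                          factors$sample_id)]
  log2(t(t(counts + 0.5) / (eff + 1)) * 1e6)
}

#' Gate genes on first-timepoint differential expression
#'
#' Per-gene two-group moderated t test (limma linear fit with empirical
#' Bayes variance shrinkage, mean-variance trend for count data) between
#' the first post-exposure timepoint and control, on TMM-normalized
#' log-CPM for counts or on intensities for microarray data, with BH (or,
#' for microarray designs, Bonferroni) adjustment; a gene enters the gated
#' set when its adjusted p is below `fdr_max`. Variance moderation is what
#' makes a 3-versus-3 design usable: an unmoderated pooled t test at 2
#' residual degrees of freedom per group pair has essentially no power
#' after multiple-testing control.
#'
#' @param values Genes x samples matrix: raw counts (`platform =
#'   "rnaseq"`) or normalized intensities (`"microarray"`).
#' @param control_samples,first_samples Character vectors of sample ids
#'   (>= 2 each).
#' @param platform `"rnaseq"` or `"microarray"`.
#' @param fdr_max Gate threshold (default 0.05).
#' @param adjustment `"bh"` or `"bonferroni"`.
#' @return A tibble (`gene`, `logfc`, `p`, `fdr`, `gated`, `degenerate`).
#' @export
de_gate <- function(values, control_samples, first_samples,
                    platform = c("rnaseq", "microarray"), fdr_max = 0.05,
                    adjustment = c("bh", "bonferroni")) {
  platform <- match.arg(platform)
  adjustment <- match.arg(adjustment)
  if (length(control_samples) < 2L || length(first_samples) < 2L) {
    stop_validation("both groups need at least 2 replicates")
  }
  expr <- if (platform == "rnaseq") log_cpm(values) else values
  a <- expr[, first_samples, drop = FALSE]
  b <- expr[, control_samples, drop = FALSE]
  diff <- rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE)
  s2 <- (rowSums((a - rowMeans(a, na.rm = TRUE))^2, na.rm = TRUE) +
           rowSums((b - rowMeans(b, na.rm = TRUE))^2, na.rm = TRUE)) /
    (rowSums(!is.na(a)) + rowSums(!is.na(b)) - 2)
  degenerate <- is.finite(s2) & s2 == 0
  design <- cbind(intercept = 1,
                  group = rep(c(0, 1), c(length(control_samples),
                                         length(first_samples))))
  fit <- limma::eBayes(
    limma::lmFit(expr[, c(control_samples, first_samples), drop = FALSE],
                 design),
    trend = platform == "rnaseq")
  p <- fit$p.value[, "group"]
  fdr <- if (adjustment == "bh") adjust_fdr(p) else
    p.adjust(p, method = "bonferroni")
  tibble(gene = rownames(values), logfc = unname(diff), p = unname(p),
         fdr = unname(fdr), gated = unname(!is.na(fdr) & fdr < fdr_max),
         degenerate = unname(degenerate))
}

#' Log fold-change trajectories of gated genes
#'
#' Per-gene logFC versus control at every ordered timepoint group, an
#' up/down class from the sign of the first-timepoint logFC, per-class
#' mean trajectories, and trend statistics (regression-slope ANOVA always;
#' Mann-Kendall when there are at least 4 timepoints).
#'
#' @param values Genes x samples matrix (counts or intensities).
#' @param gate Output of [de_gate()]; only gated genes are tracked.
#' @param sample_groups Tibble (`sample_id`, `group`).
#' @param group_order Character vector: control group first, then the
#'   ordered post-exposure groups.
#' @param platform `"rnaseq"` or `"microarray"`.
#' @return A list: `trajectories` (long tibble `gene`, `class`,
#'   `timepoint`, `logfc`), `class_means` (tibble `class`, `timepoint`,
#'   `mean_logfc`), `trends` (per class: slope ANOVA and Mann-Kendall on
#'   the mean trajectory).
#' @export
logfc_trajectory <- function(values, gate, sample_groups, group_order,
                             platform = c("rnaseq", "microarray")) {
  platform <- match.arg(platform)
  genes <- gate$gene[gate$gated]
  if (length(genes) == 0L) stop_validation("gated gene set is empty")
  expr <- if (platform == "rnaseq") log_cpm(values) else values
  expr <- expr[genes, , drop = FALSE]
  control_group <- group_order[1]
  tps <- group_order[-1]
  group_mean <- function(g) {
    ids <- sample_groups$sample_id[sample_groups$group == g]
    rowMeans(expr[, ids, drop = FALSE], na.rm = TRUE)
  }
  ctrl <- group_mean(control_group)
  lfc <- vapply(tps, function(g) group_mean(g) - ctrl,
                numeric(length(genes)))
  lfc <- matrix(lfc, nrow = length(genes),
                dimnames = list(genes, tps))
  class <- ifelse(lfc[, 1] > 0, "up", "down")
  traj <- tibble(gene = rep(genes, times = length(tps)),
                 class = rep(class, times = length(tps)),
                 timepoint = rep(tps, each = length(genes)),
                 logfc = as.vector(lfc))
  class_means <- traj |>
    dplyr::group_by(.data$class, .data$timepoint) |>
    dplyr::summarise(mean_logfc = mean(.data$logfc), .groups = "drop") |>
    dplyr::mutate(timepoint = factor(.data$timepoint, levels = tps)) |>
    dplyr::arrange(.data$class, .data$timepoint)
  trends <- purrr::map_dfr(unique(class), function(cl) {
    y <- class_means$mean_logfc[class_means$class == cl]
    sa <- slope_anova(y, seq_along(y))
    mk <- if (length(y) >= 4) mann_kendall(y) else NULL
    tibble(class = cl, n_genes = sum(class == cl), slope = sa$slope,
           slope_f = sa$f, slope_p = sa$p,
           mk_s = mk$s %||% NA_real_, mk_p = mk$p %||% NA_real_)
  })
  list(trajectories = traj, class_means = class_means, trends = trends)
}

#' Mean absolute expression change per nuclear layer
#'
#' Maps each gated gene to a radial layer through its TSS position and the
#' layer model, then averages |logFC| at the first timepoint per layer.
#' Genes without a layer (TSS not covered by the score track) are counted
#' and excluded.
#'
#' @param gate Output of [de_gate()] (or any tibble with `gene`, `logfc`,
#'   `gated`).
#' @param gene_tss Tibble (`gene_id`, `chrom`, `pos0`) of TSS points.
#' @param track Hi-C score interval tibble.
#' @param model Optional prebuilt [build_layers()] model for the gene set;
#'   built from `track` when omitted.
#' @return A `layer_profile` tibble (`layer`, `n`, `mean_abs_logfc`) with
#'   attribute `n_unmapped`.
#' @export
layer_expression_change <- function(gate, gene_tss, track, model = NULL) {
  sub <- gate[gate$gated, , drop = FALSE]
  tss <- gene_tss[match(sub$gene, gene_tss$gene_id), ]
  pseudo <- tibble(probe_id = sub$gene, chrom = tss$chrom,
                   pos = tss$pos0 + 1)
  known <- !is.na(pseudo$chrom)
  scored <- assign_hic_scores(pseudo[known, ], track)
  n_unmapped <- sum(!known) + attr(scored, "n_uncovered")
  if (is.null(model)) model <- build_layers(scored)
  layer <- layer_of_probes(sub$gene, model)
  all_layers <- levels(model$assignment$layer)
  df <- tibble(layer = factor(layer, levels = all_layers),
               abs_lfc = abs(sub$logfc)) |>
    dplyr::filter(!is.na(.data$layer)) |>
    dplyr::group_by(.data$layer, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_logfc = mean(.data$abs_lfc),
                     .groups = "drop") |>
    dplyr::mutate(layer = as.character(.data$layer),
                  mean_abs_logfc = dplyr::if_else(.data$n > 0,
                                                  .data$mean_abs_logfc,
                                                  NA_real_))
  out <- new_layer_profile(df, metric = "mean |logFC| at first timepoint")
  attr(out, "n_unmapped") <- n_unmapped
  out
}
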