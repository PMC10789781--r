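#' Per-probe pooled control methylation level
#'
#' The control level of every probe is the arithmetic mean M value over all
#' dose-zero samples pooled across particle batches (they share culture,
#' collection time and baseline methylation). Missing values are excluded
#' pairwise, never imputed.
#'
#' @param experiment A [meth_experiment()] (converted to M scale
#'   internally).
#' @return A tibble (`probe_id`, `control_m`, `n_control`).
#' @export
define_control <- function(experiment) {
  experiment <- as_m_scale(experiment)
  ctrl_ids <- experiment$samples$sample_id[experiment$samples$dose_gy == 0]
  if (length(ctrl_ids) == 0L) {
    stop_config("no dose-zero (control) samples in the experiment")
  }
  ctrl <- experiment$values[, ctrl_ids, drop = FALSE]
  tibble(probe_id = rownames(ctrl),
         control_m = unname(rowMeans(ctrl, na.rm = TRUE)),
         n_control = unname(rowSums(!is.na(ctrl))))
}

#' Call differentially methylated probes between two sample groups
#'
#' Per-probe two-group one-way ANOVA F test on M values (equivalent to the
#' squared pooled-variance t statistic), Benjamini-Hochberg q values, and
#' the study's three filters: `q < q_max`, `|avDiff| >= d_min` (mean M of
#' group A minus group B) and `|delta vs control| >= d_min` (group A mean
#' minus the pooled control mean). Group A is the focal condition: both
#' effect columns are signed from its point of view.
#'
#' Probes with zero within-group variance are flagged `degenerate` and get
#' `p = 0` when the group means differ, `p = 1` when identical.
#'
#' @param experiment A [meth_experiment()].
#' @param group_a,group_b Character vectors of sample ids (each >= 2).
#' @param control Optional control table from [define_control()]; computed
#'   from the experiment's dose-zero samples when omitted.
#' @param q_max,d_min Filter thresholds (defaults 0.05 and 0.58).
#' @return A tibble with one row per probe: `probe_id`, `chrom`, `pos`,
#'   `f_stat`, `p`, `q`, `av_diff`, `delta_vs_control`, `passes`,
#'   `degenerate`, `baseline_state`, `direction`, `baseline_tie`.
#' @export
call_dmps <- function(experiment, group_a, group_b, control = NULL,
                      q_max = 0.05, d_min = 0.58) {
  experiment <- as_m_scale(experiment)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_validation("both groups need at least 2 samples")
  }
  bad <- setdiff(c(group_a, group_b), colnames(experiment$values))
  if (length(bad) > 0L) {
    stop_validation(sprintf("unknown sample id(s): %s",
                            paste(bad, collapse = ", ")))
  }
  if (is.null(control)) control <- define_control(experiment)
  a <- experiment$values[, group_a, drop = FALSE]
  b <- experiment$values[, group_b, drop = FALSE]
  n_a <- rowSums(!is.na(a)); n_b <- rowSums(!is.na(b))
  mean_a <- rowMeans(a, na.rm = TRUE); mean_b <- rowMeans(b, na.rm = TRUE)
  ss <- rowSums((a - mean_a)^2, na.rm = TRUE) +
    rowSums((b - mean_b)^2, na.rm = TRUE)
  df2 <- n_a + n_b - 2
  s2 <- ss / df2
  diff <- mean_a - mean_b
  f_stat <- diff^2 / (s2 * (1 / n_a + 1 / n_b))
  p <- pf(f_stat, 1, df2, lower.tail = FALSE)
  degenerate <- is.finite(s2) & s2 == 0
  p[degenerate] <- ifelse(diff[degenerate] != 0, 0, 1)
  f_stat[degenerate] <- ifelse(diff[degenerate] != 0, Inf, 0)
  q <- adjust_fdr(p)
  ctrl_m <- control$control_m[match(rownames(a), control$probe_id)]
  delta_ctrl <- mean_a - ctrl_m
  res <- tibble(
    probe_id = rownames(a),
    f_stat = unname(f_stat), p = unname(p), q = unname(q),
    av_diff = unname(diff), delta_vs_control = unname(delta_ctrl),
    passes = unname(!is.na(q) & q < q_max & abs(diff) >= d_min &
      abs(delta_ctrl) >= d_min),
    degenerate = unname(degenerate))
  res <- dplyr::left_join(
    res, experiment$manifest[, c("probe_id", "chrom", "pos")],
    by = "probe_id")
  res <- dplyr::relocate(res, "chrom", "pos", .after = "probe_id")
  classify_subgroups(res, control)
}

#' Label DMPs by baseline methylation state and direction of change
#'
#' `baseline_state` follows the sign of the pooled control M value (hypo
#' when negative, hyper otherwise; an exact zero is labelled hyper by
#' convention and flagged in `baseline_tie`); `direction` is `"up"` when
#' the change versus control is positive, `"down"` otherwise.
#'
#' @param dmps A DMP tibble with `probe_id` and `delta_vs_control`.
#' @param control Control table from [define_control()].
#' @return `dmps` with `baseline_state`, `direction`, `baseline_tie` filled.
#' @export
classify_subgroups <- function(dmps, control) {
  ctrl_m <- control$control_m[match(dmps$probe_id, control$probe_id)]
  dmps$baseline_state <- ifelse(ctrl_m < 0, "hypo", "hyper")
  dmps$baseline_tie <- !is.na(ctrl_m) & ctrl_m == 0
  dmps$direction <- ifelse(dmps$delta_vs_control > 0, "up", "down")
  dmps
}

#' Group passing DMPs into differentially methylated regions
#'
#' Distance-chaining DMR construction: per chromosome, passing DMPs are
#' sorted by position and consecutive probes are chained while the gap is
#' at most `lambda` bp; chains with at least `min_probes` members become
#' DMRs spanning first to last probe. A DMR's mean methylation change is
#' the unweighted mean of its members' `delta_vs_control`.
#'
#' @param dmps DMP tibble from [call_dmps()] (needs `probe_id`, `chrom`,
#'   `pos`, `passes`, `delta_vs_control`).
#' @param lambda Maximum gap between consecutive DMPs in a region (bp).
#' @param min_probes Minimum probes per region.
#' @return A list: `dmrs` (tibble `chrom`, `start`, `end` 0-based
#'   half-open, `n_probes`, `mean_delta`, `probe_ids` list-column),
#'   `assignment` (passing DMPs with `in_dmr` flag), and
#'   `fraction_inside` (in-DMR passing DMPs / all passing DMPs).
#' @export
build_dmrs <- function(dmps, lambda = 1000, min_probes = 2L) {
  check_columns(dmps, c("probe_id", "chrom", "pos", "passes"), "DMP table")
  pass <- dmps[dmps$passes, , drop = FALSE]
  if (nrow(pass) == 0L) {
    return(list(dmrs = tibble(chrom = character(), start = numeric(),
                              end = numeric(), n_probes = integer(),
                              mean_delta = numeric(), probe_ids = list()),
                assignment = dplyr::mutate(pass, in_dmr = logical(0)),
                fraction_inside = NA_real_))
  }
  pass <- dplyr::arrange(pass, .data$chrom, .data$pos, .data$probe_id)
  new_chain <- c(TRUE, diff(pass$pos) > lambda) |
    c(TRUE, pass$chrom[-1] != pass$chrom[-nrow(pass)])
  chain_id <- cumsum(new_chain)
  size <- table(chain_id)[as.character(chain_id)]
  pass$in_dmr <- as.vector(size) >= min_probes
  delta <- if ("delta_vs_control" %in% names(pass)) pass$delta_vs_control else
    rep(NA_real_, nrow(pass))
  keep <- which(pass$in_dmr)
  dmrs <- if (length(keep) > 0L) {
    sp <- split(keep, chain_id[keep])
    purrr::map_dfr(sp, function(i) {
      tibble(chrom = pass$chrom[i[1]],
             start = min(pass$pos[i]) - 1,
             end = max(pass$pos[i]),
             n_probes = length(i),
             mean_delta = mean(delta[i], na.rm = TRUE),
             probe_ids = list(pass$probe_id[i]))
    })
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           n_probes = integer(), mean_delta = numeric(), probe_ids = list())
  }
  list(dmrs = dmrs, assignment = pass,
       fraction_inside = sum(pass$in_dmr) / nrow(pass))
}

#' Classify probe positions relative to CpG islands
#'
#' Distance is measured in bp from the probe point to the nearest island
#' edge on its chromosome (0 inside an island). Islands classify at 0 bp,
#' shores up to 2 kb (inclusive), shelves from 2 to 4 kb (inclusive), and
#' everything farther is open sea. The 3-level variant merges shores and
#' shelves into one class, as the downstream fraction comparisons use.
#'
#' @param chrom,pos Probe chromosome and 1-based position vectors.
#' @param islands Island interval tibble (0-based half-open,
#'   non-overlapping per chromosome).
#' @param levels `4` (Island/Shore/Shelf/OpenSea) or `3`
#'   (Island/ShoreShelf/OpenSea).
#' @return Character vector of classes.
#' @export
classify_cpg_relation <- function(chrom, pos, islands, levels = 4) {
  d <- point_interval_distance(chrom, pos, islands)
  d[is.na(d)] <- Inf
  out <- dplyr::case_when(
    d == 0 ~ "Island",
    d <= 2000 ~ "Shore",
    d <= 4000 ~ "Shelf",
    TRUE ~ "OpenSea")
  if (levels == 3) out[out %in% c("Shore", "Shelf")] <- "ShoreShelf"
  out
}

#' Per-category counts and fractions
#'
#' @param x A data frame.
#' @param category Column name (string) to tabulate.
#' @return A tibble (`category` value, `n`, `fraction`); fractions sum
#'   to 1.
#' @export
fraction_table <- function(x, category) {
  if (nrow(x) == 0L) stop_validation("fraction_table() needs a nonempty input")
  x |>
    dplyr::count(.data[[category]], name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}
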