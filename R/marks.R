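#' Filter a histone peak set by length and alignment score
#'
#' Keeps peaks whose length lies in `[min_len, max_len]` (both inclusive)
#' and whose score satisfies the source-specific rule (`ge` for thresholds
#' like "score >= 10", `gt` for "score > 0"). Removal counts by reason are
#' attached as the `removed` attribute.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `score`, ...).
#' @param min_len,max_len Allowed peak length range in bp.
#' @param score_op `"ge"` or `"gt"`.
#' @param score_threshold Numeric score threshold.
#' @return The filtered peak tibble.
#' @export
filter_peaks <- function(peaks, min_len = 300, max_len = 2000,
                         score_op = c("ge", "gt"), score_threshold = 0) {
  score_op <- match.arg(score_op)
  check_columns(peaks, c("chrom", "start", "end", "score"), "peak set")
  len <- peaks$end - peaks$start
  ok_len <- len >= min_len & len <= max_len
  ok_score <- if (score_op == "ge") peaks$score >= score_threshold else
    peaks$score > score_threshold
  ok_score[is.na(ok_score)] <- FALSE
  out <- peaks[ok_len & ok_score, , drop = FALSE]
  attr(out, "removed") <- c(too_short = sum(len < min_len),
                            too_long = sum(len > max_len),
                            low_score = sum(ok_len & !ok_score))
  out
}

#' Flag probes overlapping each histone mark's peaks
#'
#' A probe carries a mark when its point position lies inside any peak of
#' that mark; a probe may carry several marks.
#'
#' @param peak_sets Named list of (filtered) peak tibbles, one per mark.
#' @param manifest Probe manifest.
#' @return A tibble with `probe_id` plus one logical column per mark.
#' @export
overlap_probes <- function(peak_sets, manifest) {
  out <- tibble(probe_id = manifest$probe_id)
  for (mark in names(peak_sets)) {
    out[[mark]] <- point_in_intervals(manifest$chrom, manifest$pos,
                                      peak_sets[[mark]])
  }
  out
}

#' Distribution of each histone mark across nuclear layers
#'
#' For every mark, the percentage of its probe carriers falling in each
#' layer (sums to 100 per mark). Marks with no carriers are flagged with
#' NA profiles.
#'
#' @param flags Output of [overlap_probes()].
#' @param model A [build_layers()] model.
#' @return A long tibble (`mark`, `layer`, `n`, `pct`).
#' @export
layer_mark_distribution <- function(flags, model) {
  marks <- setdiff(names(flags), "probe_id")
  all_layers <- levels(model$assignment$layer)
  purrr::map_dfr(marks, function(mark) {
    ids <- flags$probe_id[flags[[mark]]]
    layer <- layer_of_probes(ids, model)
    layer <- layer[!is.na(layer)]
    n <- table(factor(layer, levels = all_layers))
    total <- sum(n)
    tibble(mark = mark, layer = all_layers, n = as.integer(n),
           pct = if (total > 0) 100 * as.integer(n) / total else NA_real_)
  })
}

#' DMP-occurrence enrichment ratio within a layer
#'
#' The probability ratio
#' `(DMPs in the region class within the layer / all DMPs) /
#'  (region-class probes in the layer / all region-class probes)`;
#' 1 means DMPs distribute over layers exactly like the region class. A
#' zero denominator yields NA (undefined), never 0.
#'
#' @param dmps DMP tibble (passing rows are the DMP set).
#' @param region_flags Logical vector or tibble column marking which
#'   manifest probes belong to the region class; must be named by probe id
#'   or be a 2-column tibble (`probe_id`, flag).
#' @param model A [build_layers()] model.
#' @return A tibble (`layer`, `n_dmp_in_region`, `n_region`, `ratio`).
#' @export
dmp_enrichment_ratio <- function(dmps, region_flags, model) {
  if (is.data.frame(region_flags)) {
    flag_col <- setdiff(names(region_flags), "probe_id")[1]
    region_ids <- region_flags$probe_id[region_flags[[flag_col]]]
  } else {
    region_ids <- names(region_flags)[region_flags]
  }
  ids <- dmp_ids(dmps)
  assign <- model$assignment
  all_layers <- levels(assign$layer)
  layered_ids <- assign$probe_id
  dmp_layer <- layer_of_probes(ids, model)
  in_region <- ids %in% region_ids
  region_layer <- layer_of_probes(intersect(region_ids, layered_ids), model)
  n_all_dmp <- length(ids)
  n_all_region <- length(region_layer)
  purrr::map_dfr(all_layers, function(ly) {
    n_dmp_in <- sum(in_region & !is.na(dmp_layer) & dmp_layer == ly)
    n_reg <- sum(region_layer == ly, na.rm = TRUE)
    num <- if (n_all_dmp > 0) n_dmp_in / n_all_dmp else NA_real_
    den <- if (n_all_region > 0) n_reg / n_all_region else NA_real_
    tibble(layer = ly, n_dmp_in_region = n_dmp_in, n_region = n_reg,
           ratio = if (!is.na(den) && den > 0 && !is.na(num)) num / den
                   else NA_real_)
  })
}

#' Build the five regulatory-region groups
#'
#' TSS regions (`[TSS - halfwidth, TSS + halfwidth)`) are partitioned into
#' four promoter classes by which of H3K4me3 / H3K27ac overlap them
#' (>= 1 bp): K4-only, K27ac-only, dual, or bare. Enhancers are H3K27ac
#' peaks sharing no base with any TSS region or gene body.
#'
#' @param tss Tibble (`chrom`, `pos0` 0-based TSS point, `gene_id`).
#' @param gene_bodies Interval tibble of gene bodies.
#' @param k4,k27ac Filtered peak tibbles for H3K4me3 and H3K27ac.
#' @param tss_halfwidth Promoter half-width in bp (default 2000).
#' @return A `regulatory_groups` list of five interval tibbles:
#'   `k4_promoters`, `k27ac_promoters`, `dual_promoters`, `bare_promoters`,
#'   `k27ac_enhancers`.
#' @export
build_regulatory_groups <- function(tss, gene_bodies, k4, k27ac,
                                    tss_halfwidth = 2000) {
  regions <- tibble(chrom = tss$chrom,
                    start = pmax(tss$pos0 - tss_halfwidth, 0),
                    end = tss$pos0 + tss_halfwidth,
                    name = tss$gene_id)
  has_k4 <- interval_overlaps_any(regions, k4)
  has_k27 <- interval_overlaps_any(regions, k27ac)
  enh_blocked <- interval_overlaps_any(k27ac, regions) |
    interval_overlaps_any(k27ac, gene_bodies)
  structure(list(
    k4_promoters = regions[has_k4 & !has_k27, , drop = FALSE],
    k27ac_promoters = regions[!has_k4 & has_k27, , drop = FALSE],
    dual_promoters = regions[has_k4 & has_k27, , drop = FALSE],
    bare_promoters = regions[!has_k4 & !has_k27, , drop = FALSE],
    k27ac_enhancers = k27ac[!enh_blocked, , drop = FALSE]),
    class = "regulatory_groups")
}

# >= 1 bp overlap between each query interval and any subject interval.
interval_overlaps_any <- function(query, subject) {
  hit <- logical(nrow(query))
  if (nrow(subject) == 0L) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sv <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sv) == 0L) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = sv$start + 1L, end = sv$end)
    hit[qi] <- IRanges::countOverlaps(q, s) > 0L
  }
  hit
}

#' @export
print.regulatory_groups <- function(x, ...) {
  cat("<regulatory_groups>\n")
  for (g in names(x)) cat(sprintf("  %s: %d regions\n", g, nrow(x[[g]])))
  invisible(x)
}

#' Methylation change and baseline level per group and layer
#'
#' For each region group (or mark flag column) and nuclear layer: member
#' DMP count, mean |delta versus control| and mean baseline (control) M
#' value. Empty cells carry NA.
#'
#' @param dmps DMP tibble from [call_dmps()] (passing rows used).
#' @param groups A `regulatory_groups` object or named list of interval
#'   tibbles.
#' @param model A [build_layers()] model.
#' @param manifest Probe manifest (for probe coordinates).
#' @param control Optional control table from [define_control()] for the
#'   baseline column.
#' @return A tibble (`group`, `layer`, `n`, `mean_abs_delta`,
#'   `mean_baseline_m`).
#' @export
group_methylation_change <- function(dmps, groups, model, manifest,
                                     control = NULL) {
  sub <- if ("passes" %in% names(dmps)) dmps[dmps$passes, ] else dmps
  layer <- layer_of_probes(sub$probe_id, model)
  all_layers <- levels(model$assignment$layer)
  ctrl_m <- if (!is.null(control)) {
    control$control_m[match(sub$probe_id, control$probe_id)]
  } else rep(NA_real_, nrow(sub))
  coords <- manifest[match(sub$probe_id, manifest$probe_id), ]
  purrr::map_dfr(names(groups), function(g) {
    inside <- point_in_intervals(coords$chrom, coords$pos, groups[[g]])
    purrr::map_dfr(all_layers, function(ly) {
      i <- which(inside & !is.na(layer) & layer == ly)
      tibble(group = g, layer = ly, n = length(i),
             mean_abs_delta = if (length(i) > 0)
               mean(abs(sub$delta_vs_control[i])) else NA_real_,
             mean_baseline_m = if (length(i) > 0 && !all(is.na(ctrl_m[i])))
               mean(ctrl_m[i], na.rm = TRUE) else NA_real_)
    })
  })
}
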