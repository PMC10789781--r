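#' Assign Hi-C bin scores to probes
#'
#' Each probe takes the score of the (single) track interval containing its
#' position; the score proxies radial nuclear depth, higher = deeper.
#' Probes not covered by any bin are dropped from spatial analyses and
#' counted in the `n_uncovered` attribute. Bin membership follows the
#' 0-based half-open convention: a probe whose 0-based position equals a
#' bin's `end` belongs to the next bin.
#'
#' @param manifest Probe manifest tibble.
#' @param track Score interval tibble (`chrom`, `start`, `end`, `score`),
#'   non-overlapping per chromosome.
#' @return A tibble (`probe_id`, `chrom`, `pos`, `score`) of covered
#'   probes, with attribute `n_uncovered`.
#' @export
assign_hic_scores <- function(manifest, track) {
  check_columns(track, c("chrom", "start", "end", "score"), "score track")
  score <- rep(NA_real_, nrow(manifest))
  for (ch in unique(manifest$chrom)) {
    iv <- track[track$chrom == ch, , drop = FALSE]
    idx <- which(manifest$chrom == ch)
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      stop_validation(sprintf("overlapping track intervals on %s", ch))
    }
    p0 <- manifest$pos[idx] - 1
    k <- findInterval(p0, iv$start)
    inside <- k >= 1L & p0 < iv$end[pmax(k, 1L)]
    score[idx[inside]] <- iv$score[k[inside]]
  }
  covered <- !is.na(score)
  out <- tibble(probe_id = manifest$probe_id[covered],
                chrom = manifest$chrom[covered],
                pos = manifest$pos[covered],
                score = score[covered])
  attr(out, "n_uncovered") <- sum(!covered)
  out
}

#' Build equal-occupancy radial nuclear layers from probe scores
#'
#' Probes are ranked by `(score, chrom, pos)` ascending and the ranks are
#' split into `n_layers` contiguous blocks of equal size (within one
#' probe), so every layer holds the same amount of DNA even under score
#' ties. L1 holds the lowest scores (outermost), L5 the highest (deepest).
#' The reported boundaries are the empirical 0/20/40/60/80/100% quantiles
#' of the scores.
#'
#' @param scores A tibble from [assign_hic_scores()] (`probe_id`, `chrom`,
#'   `pos`, `score`).
#' @param n_layers Number of layers (default 5).
#' @return A `layer_model`: list with `assignment` (tibble `probe_id`,
#'   `score`, `layer`), `boundaries` (n_layers + 1 quantile scores), and
#'   `n_layers`.
#' @export
build_layers <- function(scores, n_layers = 5L) {
  check_columns(scores, c("probe_id", "chrom", "pos", "score"), "score table")
  n <- nrow(scores)
  if (n < n_layers) {
    stop_validation(sprintf("need at least %d scored probes", n_layers))
  }
  if (length(unique(scores$score)) == 1L) {
    warn("all scores identical; layers assigned purely by rank tie-break")
  }
  ord <- order(scores$score, scores$chrom, scores$pos)
  block_sizes <- diff(floor(seq(0, n, length.out = n_layers + 1L)))
  layer_sorted <- rep(layer_levels(n_layers), times = block_sizes)
  layer <- character(n)
  layer[ord] <- layer_sorted
  structure(list(
    assignment = tibble(probe_id = scores$probe_id, score = scores$score,
                        layer = factor(layer, levels = layer_levels(n_layers))),
    boundaries = unname(quantile(scores$score,
                                 probs = seq(0, 1, length.out = n_layers + 1L))),
    n_layers = as.integer(n_layers)), class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  occ <- table(x$assignment$layer)
  cat(sprintf("<layer_model> %d probes in %d layers (L1 outer .. L%d inner)\n",
              nrow(x$assignment), x$n_layers, x$n_layers))
  cat("  occupancy:", paste(sprintf("%s=%d", names(occ), occ), collapse = " "),
      "\n")
  cat("  score boundaries:",
      paste(sprintf("%.3f", x$boundaries), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy layer_model
#' @export
tidy.layer_model <- function(x, ...) {
  x$assignment
}

#' @method glance layer_model
#' @export
glance.layer_model <- function(x, ...) {
  occ <- table(x$assignment$layer)
  tibble(n_probes = nrow(x$assignment), n_layers = x$n_layers,
         min_occupancy = min(occ), max_occupancy = max(occ),
         score_min = x$boundaries[1],
         score_max = x$boundaries[length(x$boundaries)])
}

layer_of_probes <- function(probe_ids, model) {
  model$assignment$layer[match(probe_ids, model$assignment$probe_id)]
}

new_layer_profile <- function(df, metric) {
  structure(dplyr::as_tibble(df), metric = metric,
            class = c("layer_profile", class(df)))
}

#' Frequency of DMPs per nuclear layer
#'
#' Percentage of all passing DMPs falling in each layer (sums to 100), with
#' the same profile for all non-DMP layered probes as reference.
#'
#' @param dmps DMP tibble from [call_dmps()]; only rows with
#'   `passes == TRUE` are counted (pass a pre-filtered tibble to override).
#' @param model A [build_layers()] model.
#' @return A `layer_profile` tibble (`layer`, `n_dmp`, `pct_dmp`,
#'   `n_background`, `pct_background`).
#' @export
layer_frequency <- function(dmps, model) {
  ids <- dmp_ids(dmps)
  layer <- layer_of_probes(ids, model)
  if (anyNA(layer)) {
    stop_validation("some DMPs have no layer assignment")
  }
  all_layers <- levels(model$assignment$layer)
  n_dmp <- table(factor(layer, levels = all_layers))
  bg <- model$assignment$probe_id[!model$assignment$probe_id %in% ids]
  n_bg <- table(factor(layer_of_probes(bg, model), levels = all_layers))
  new_layer_profile(tibble(
    layer = all_layers,
    n_dmp = as.integer(n_dmp),
    pct_dmp = 100 * as.integer(n_dmp) / max(sum(n_dmp), 1L),
    n_background = as.integer(n_bg),
    pct_background = 100 * as.integer(n_bg) / max(sum(n_bg), 1L)),
    metric = "frequency (%)")
}

dmp_ids <- function(dmps) {
  if ("passes" %in% names(dmps)) dmps$probe_id[dmps$passes] else dmps$probe_id
}

#' Chromosome-normalized DMP frequency
#'
#' DMP count per chromosome divided by that chromosome's probe count,
#' correcting for array design bias; chromosomes are ranked by the value.
#'
#' @param dmps DMP tibble (passing rows are counted).
#' @param manifest Probe manifest.
#' @return A tibble (`chrom`, `n_dmp`, `n_probes`, `frequency`, `rank`).
#' @export
chromosome_normalized_frequency <- function(dmps, manifest) {
  ids <- dmp_ids(dmps)
  if (anyNA(match(ids, manifest$probe_id))) {
    stop_validation("some DMPs are absent from the manifest")
  }
  manifest |>
    dplyr::count(.data$chrom, name = "n_probes") |>
    dplyr::left_join(
      manifest |>
        dplyr::filter(.data$probe_id %in% ids) |>
        dplyr::count(.data$chrom, name = "n_dmp"),
      by = "chrom") |>
    dplyr::mutate(n_dmp = dplyr::coalesce(.data$n_dmp, 0L),
                  frequency = .data$n_dmp / .data$n_probes,
                  rank = rank(-.data$frequency, ties.method = "min")) |>
    dplyr::relocate("n_dmp", .after = "chrom") |>
    dplyr::arrange(.data$rank)
}

#' Within-layer chromosomal DMP frequencies
#'
#' Cell (chromosome, layer) = DMPs of that chromosome in the layer divided
#' by probes of that chromosome in the layer; cells with no probes are
#' flagged missing (NA), not zero.
#'
#' @inheritParams chromosome_normalized_frequency
#' @param model A [build_layers()] model.
#' @return A tibble (`chrom`, `layer`, `n_dmp`, `n_probes`, `frequency`).
#' @export
per_layer_chromosome_frequency <- function(dmps, model, manifest) {
  ids <- dmp_ids(dmps)
  assign <- model$assignment |>
    dplyr::left_join(manifest[, c("probe_id", "chrom")], by = "probe_id")
  grid <- tidyr::expand_grid(chrom = unique(manifest$chrom),
                             layer = levels(model$assignment$layer))
  probes <- assign |> dplyr::count(.data$chrom, .data$layer,
                                   name = "n_probes", .drop = FALSE)
  dmp <- assign |>
    dplyr::filter(.data$probe_id %in% ids) |>
    dplyr::count(.data$chrom, .data$layer, name = "n_dmp", .drop = FALSE)
  grid |>
    dplyr::left_join(dplyr::mutate(probes, layer = as.character(.data$layer)),
                     by = c("chrom", "layer")) |>
    dplyr::left_join(dplyr::mutate(dmp, layer = as.character(.data$layer)),
                     by = c("chrom", "layer")) |>
    dplyr::mutate(
      n_probes = dplyr::coalesce(.data$n_probes, 0L),
      n_dmp = dplyr::coalesce(.data$n_dmp, 0L),
      frequency = dplyr::if_else(.data$n_probes > 0,
                                 .data$n_dmp / .data$n_probes, NA_real_))
}

#' Mean absolute methylation change per nuclear layer
#'
#' Arithmetic mean of |delta versus control| over the passing DMPs of each
#' layer; empty layers are flagged with NA and excluded from trend tests.
#'
#' @param dmps DMP tibble with `delta_vs_control` (passing rows counted).
#' @param model A [build_layers()] model.
#' @return A `layer_profile` tibble (`layer`, `n`, `mean_abs_delta`).
#' @export
layer_mean_abs_change <- function(dmps, model) {
  sub <- if ("passes" %in% names(dmps)) dmps[dmps$passes, ] else dmps
  layer <- layer_of_probes(sub$probe_id, model)
  all_layers <- levels(model$assignment$layer)
  df <- tibble(layer = factor(layer, levels = all_layers),
               abs_delta = abs(sub$delta_vs_control)) |>
    dplyr::filter(!is.na(.data$layer)) |>
    dplyr::group_by(.data$layer, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_delta = mean(.data$abs_delta), .groups = "drop") |>
    dplyr::mutate(layer = as.character(.data$layer),
                  mean_abs_delta = dplyr::if_else(.data$n > 0,
                                                  .data$mean_abs_delta,
                                                  NA_real_))
  new_layer_profile(df, metric = "mean |delta M| vs control")
}
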