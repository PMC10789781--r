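#' Run the full analysis pipeline on simulated inputs
#'
#' Orchestrates the three analyses end to end: (1) differential
#' methylation — per-probe tests for each comparison pair, the three
#' filters, direction subgroups, DMR chaining and the probe-label
#' permutation null; (2) spatial layering — equal-occupancy radial layers
#' from the Hi-C track with frequency, chromosome-normalized and
#' mean-|delta| profiles plus histone-mark and regulatory-region
#' enrichment; (3) expression validation — first-timepoint DE gating and
#' logFC trajectories for persistent and decaying planted kinetics.
#' Every stage's tables are written under `out_dir` together with a
#' machine-readable `summary.json` and a run manifest (seed + config).
#'
#' @param config A [sim_config()], or the path to a YAML file whose
#'   `simulate:` block holds `sim_config()` fields and whose optional
#'   `thresholds:` / `comparisons:` blocks override defaults.
#' @param out_dir Output directory (created if needed).
#' @param comparisons List of two-element lists naming focal and reference
#'   particles, e.g. `list(list(a = "Fe", b = "Si"))`. Defaults to the
#'   first particle versus each other particle.
#' @param q_max,d_min,lambda,min_probes,n_layers,B,tss_halfwidth,fdr_max
#'   Stage thresholds (defaults: 0.05, 0.58, 1000, 2, 5, 200, 2000, 0.05).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary list (also serialized as JSON).
#' @export
run_pipeline <- function(config, out_dir, comparisons = NULL,
                         q_max = 0.05, d_min = 0.58, lambda = 1000,
                         min_probes = 2L, n_layers = 5L, B = 200,
                         tss_halfwidth = 2000, fdr_max = 0.05,
                         quiet = FALSE) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    sim_cfg <- do.call(sim_config, raw$simulate)
    th <- raw$thresholds %||% list()
    for (nm in intersect(names(th), c("q_max", "d_min", "lambda",
                                      "min_probes", "n_layers", "B",
                                      "tss_halfwidth", "fdr_max"))) {
      assign(nm, th[[nm]])
    }
    if (!is.null(raw$comparisons)) comparisons <- raw$comparisons
  } else {
    sim_cfg <- config
  }
  stopifnot(inherits(sim_cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)

  say("stage simulate: generating inputs (seed %d)", sim_cfg$seed)
  sim <- simulate_inputs(sim_cfg)
  particles <- vapply(sim_cfg$particles, `[[`, character(1), "name")
  if (is.null(comparisons)) {
    comparisons <- lapply(particles[-1],
                          function(b) list(a = particles[1], b = b))
  }

  exp_m <- as_m_scale(sim$experiment)
  control <- define_control(exp_m)
  scored <- assign_hic_scores(sim$manifest, sim$hic)
  model <- build_layers(scored, n_layers = n_layers)
  flags <- overlap_probes(sim$peaks, sim$manifest)
  mark_dist <- layer_mark_distribution(flags, model)
  groups <- build_regulatory_groups(sim$tss, sim$gene_bodies,
                                    filter_peaks(sim$peaks$H3K4me3),
                                    filter_peaks(sim$peaks$H3K27ac),
                                    tss_halfwidth = tss_halfwidth)

  summary <- list(seed = sim_cfg$seed,
                  n_probes = nrow(sim$manifest),
                  n_layer_assigned = nrow(scored),
                  comparisons = list())
  first_tp <- sim_cfg$timepoints[1]
  for (cmp in comparisons) {
    label <- sprintf("%s_vs_%s", cmp$a, cmp$b)
    ga <- select_samples(exp_m$samples, particle = cmp$a,
                         timepoint = first_tp)
    ga <- intersect(ga, exp_m$samples$sample_id[exp_m$samples$dose_gy > 0])
    gb <- select_samples(exp_m$samples, particle = cmp$b,
                         timepoint = first_tp)
    gb <- intersect(gb, exp_m$samples$sample_id[exp_m$samples$dose_gy > 0])
    if (length(ga) < 2L || length(gb) < 2L) {
      abort(sprintf("stage diffmeth: comparison %s has no irradiated samples for one side",
                    label), class = "radialmeth_error_config")
    }
    say("stage diffmeth: %s (%d vs %d samples)", label, length(ga), length(gb))
    dmps <- call_dmps(exp_m, ga, gb, control = control,
                      q_max = q_max, d_min = d_min)
    dmr <- build_dmrs(dmps, lambda = lambda, min_probes = min_probes)
    readr::write_tsv(dmps, p(sprintf("dmps_%s.tsv", label)), progress = FALSE)
    readr::write_tsv(dplyr::select(dmr$dmrs, -"probe_ids"),
                     p(sprintf("dmrs_%s.tsv", label)), progress = FALSE)
    pass <- dmps[dmps$passes, ]
    cpg3 <- classify_cpg_relation(pass$chrom, pass$pos, sim$islands,
                                  levels = 3)
    perm <- dmr_fraction_permutation_test(
      exp_m, ga, gb, control = control, B = B, lambda = lambda,
      min_probes = min_probes, q_max = q_max, d_min = d_min,
      tail = "greater", seed = derive_seed(sim_cfg$seed, label))
    freq <- layer_frequency(dmps, model)
    mad <- layer_mean_abs_change(dmps, model)
    chromfreq <- chromosome_normalized_frequency(dmps, sim$manifest)
    enrich <- purrr::map_dfr(names(sim$peaks), function(mark) {
      dplyr::mutate(dmp_enrichment_ratio(dmps, flags[, c("probe_id", mark)],
                                         model), mark = mark, .before = 1)
    })
    gmc <- group_methylation_change(dmps, groups, model, sim$manifest,
                                    control = control)
    readr::write_tsv(freq, p(sprintf("layer_frequency_%s.tsv", label)),
                     progress = FALSE)
    readr::write_tsv(mad, p(sprintf("layer_mean_abs_change_%s.tsv", label)),
                     progress = FALSE)
    readr::write_tsv(enrich, p(sprintf("mark_enrichment_%s.tsv", label)),
                     progress = FALSE)
    readr::write_tsv(gmc, p(sprintf("group_methylation_%s.tsv", label)),
                     progress = FALSE)
    summary$comparisons[[label]] <- list(
      n_dmps = sum(dmps$passes), n_dmrs = nrow(dmr$dmrs),
      fraction_inside_dmrs = dmr$fraction_inside,
      permutation_p = perm$empirical_p,
      permutation_null_max = max(perm$null),
      cpg_island_fraction = mean(cpg3 == "Island"),
      layer_pct_dmp = setNames(freq$pct_dmp, freq$layer),
      layer_mean_abs_delta = setNames(mad$mean_abs_delta, mad$layer),
      top_chromosome = chromfreq$chrom[1])
  }

  say("stage expression: DE gate and trajectories")
  expr_summary <- list()
  for (kin in c("persistent", "decaying")) {
    cs <- if (kin == "persistent") sim$counts else sim$counts_decaying
    ctrl_ids <- cs$samples$sample_id[cs$samples$timepoint == "control"]
    first_ids <- cs$samples$sample_id[cs$samples$timepoint == first_tp]
    gate <- de_gate(cs$counts, ctrl_ids, first_ids, platform = "rnaseq",
                    fdr_max = fdr_max)
    if (sum(gate$gated) == 0L) {
      warn(sprintf("no genes pass the %s DE gate; trajectory skipped", kin))
      expr_summary[[kin]] <- list(n_gated = 0L,
                                  last_to_first_ratio = NA_real_,
                                  trends = NULL)
      next
    }
    traj <- logfc_trajectory(cs$counts, gate,
                             dplyr::rename(cs$samples, group = "timepoint"),
                             group_order = c("control", sim_cfg$timepoints),
                             platform = "rnaseq")
    readr::write_tsv(traj$class_means,
                     p(sprintf("expression_trajectory_%s.tsv", kin)),
                     progress = FALSE)
    last_tp <- sim_cfg$timepoints[length(sim_cfg$timepoints)]
    ratio <- traj$class_means |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(ratio = abs(.data$mean_logfc[.data$timepoint == last_tp]) /
                         abs(.data$mean_logfc[.data$timepoint == first_tp]),
                       .groups = "drop")
    expr_summary[[kin]] <- list(
      n_gated = sum(gate$gated),
      last_to_first_ratio = mean(ratio$ratio),
      trends = traj$trends)
  }
  summary$expression <- expr_summary

  mark_path <- p("mark_layer_distribution.tsv")
  readr::write_tsv(mark_dist, mark_path, progress = FALSE)
  summary$run <- list(
    thresholds = list(q_max = q_max, d_min = d_min, lambda = lambda,
                      min_probes = min_probes, n_layers = n_layers, B = B,
                      tss_halfwidth = tss_halfwidth, fdr_max = fdr_max),
    config_hash = sum(utf8ToInt(paste(deparse(unclass(sim_cfg)),
                                      collapse = ""))))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  say("done: %s", p("summary.json"))
  invisible(summary)
}
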