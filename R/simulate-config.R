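#' Define a simulated radiation particle
#'
#' Encodes the qualitative exposure contrast the pipeline is designed to
#' detect: iron-like ions plant a persistent methylation increase, while
#' silicon-like ions and X-rays plant a decrease that decays back toward
#' baseline over time.
#'
#' @param name Particle label (e.g. `"Fe"`, `"Si"`, `"X"`).
#' @param dose_gy Delivered dose in gray (> 0 for irradiated samples).
#' @param effect_direction `+1` (methylation increase) or `-1` (decrease).
#' @param effect_size_m Planted |delta M| at the reference layer (layer
#'   weights scale it per probe).
#' @param persistence `"persistent"` (constant across timepoints) or
#'   `"decaying"` (shrinks geometrically by `decay_ratio` per timepoint).
#' @param decay_ratio Geometric ratio for decaying effects.
#' @return A `particle_spec` list.
#' @export
particle_spec <- function(name, dose_gy = 1.0, effect_direction = 1L,
                          effect_size_m = 1.5,
                          persistence = c("persistent", "decaying"),
                          decay_ratio = 0.5) {
  persistence <- match.arg(persistence)
  if (!effect_direction %in% c(-1L, 1L)) {
    stop_config("`effect_direction` must be +1 or -1")
  }
  if (effect_size_m <= 0) stop_config("`effect_size_m` must be positive")
  structure(list(name = name, dose_gy = dose_gy,
                 effect_direction = as.integer(effect_direction),
                 effect_size_m = effect_size_m, persistence = persistence,
                 decay_ratio = decay_ratio),
            class = "particle_spec")
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults are the
#' desk-scale stand-in for the 450K-array study design: 20,000 probes on 4
#' chromosomes, 3 replicates per condition, 5% planted DMPs with an
#' L3-peaked layer effect profile, and three exposure particles (persistent
#' Fe-like increase; decaying Si-like and X-like decreases).
#'
#' @param n_probes Total probe count.
#' @param n_chroms Number of chromosomes (`chr1..chrN`).
#' @param chrom_length Chromosome length in bp.
#' @param replicates_per_condition Replicates per particle/dose/timepoint.
#' @param particles List of [particle_spec()] objects.
#' @param dmp_fraction Fraction of probes planted as true DMPs per particle.
#' @param layer_effect_profile Five non-negative multipliers of
#'   `effect_size_m`, one per radial layer L1..L5.
#' @param clustered_fraction Fraction of each particle's true DMPs placed
#'   inside tight (1 kb) genomic windows; the rest scatter uniformly.
#' @param timepoints Ordered character vector of post-exposure timepoints.
#' @param noise_sd_m Replicate noise standard deviation on the M scale.
#' @param bin_width Hi-C track bin width in bp.
#' @param n_peaks_per_mark Peaks generated per histone mark.
#' @param n_genes Genes in the simulated count matrix.
#' @param de_fraction Fraction of genes planted as differentially expressed.
#' @param expr_logfc Planted |logFC| at the first timepoint.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param seed Mandatory integer seed; all generators derive their streams
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_chroms = 4L,
                       chrom_length = 5e6,
                       replicates_per_condition = 3L,
                       particles = list(
                         particle_spec("Fe", 1.0, +1L, 1.5, "persistent"),
                         particle_spec("Si", 1.0, -1L, 1.5, "decaying"),
                         particle_spec("X",  1.0, -1L, 1.5, "decaying")
                       ),
                       dmp_fraction = 0.05,
                       layer_effect_profile = c(0.5, 0.8, 1.0, 0.8, 0.6),
                       clustered_fraction = 0.5,
                       timepoints = c("48h", "2w", "8w"),
                       noise_sd_m = 0.15,
                       bin_width = 25000,
                       n_peaks_per_mark = 2000L,
                       n_genes = 2000L,
                       de_fraction = 0.05,
                       expr_logfc = 2,
                       nb_dispersion = 0.1,
                       seed) {
  if (missing(seed)) stop_config("`seed` is mandatory in sim_config()")
  if (n_probes < 10 * n_chroms) {
    stop_config("`n_probes` must be at least 10 x n_chroms")
  }
  if (length(layer_effect_profile) != 5L || any(layer_effect_profile < 0)) {
    stop_config("`layer_effect_profile` must be 5 non-negative weights")
  }
  if (dmp_fraction <= 0 && dmp_fraction != 0) {
    stop_config("`dmp_fraction` must be in [0, 1)")
  }
  if (dmp_fraction < 0 || dmp_fraction >= 1) {
    stop_config("`dmp_fraction` must be in [0, 1)")
  }
  if (clustered_fraction < 0 || clustered_fraction > 1) {
    stop_config("`clustered_fraction` must be in [0, 1]")
  }
  if (!all(vapply(particles, inherits, logical(1), "particle_spec"))) {
    stop_config("`particles` must be a list of particle_spec() objects")
  }
  structure(list(
    n_probes = as.integer(n_probes), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length,
    replicates_per_condition = as.integer(replicates_per_condition),
    particles = particles, dmp_fraction = dmp_fraction,
    layer_effect_profile = layer_effect_profile,
    clustered_fraction = clustered_fraction, timepoints = timepoints,
    noise_sd_m = noise_sd_m, bin_width = bin_width,
    n_peaks_per_mark = as.integer(n_peaks_per_mark),
    n_genes = as.integer(n_genes), de_fraction = de_fraction,
    expr_logfc = expr_logfc, nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d probes / %d chroms x %g bp, seed %d\n",
              x$n_probes, x$n_chroms, x$chrom_length, x$seed))
  for (p in x$particles) {
    cat(sprintf("  %s %.1f Gy: dir %+d, |dM| %.2f, %s\n", p$name, p$dose_gy,
                p$effect_direction, p$effect_size_m, p$persistence))
  }
  cat(sprintf("  dmp_fraction %.3f, clustered %.2f, layer profile (%s)\n",
              x$dmp_fraction, x$clustered_fraction,
              paste(x$layer_effect_profile, collapse = ", ")))
  invisible(x)
}
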