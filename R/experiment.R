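#' Construct a methylation experiment
#'
#' Bundles a probes-by-samples value matrix with its sample sheet and probe
#' manifest, tracking whether values are on the Beta or M scale. All
#' differential-methylation verbs accept this object and return tibbles.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param samples Sample sheet tibble (`sample_id`, `particle`, `dose_gy`,
#'   `timepoint`, `replicate`).
#' @param manifest Probe manifest tibble.
#' @param scale `"beta"` or `"m"`.
#' @return A `meth_experiment` object.
#' @export
meth_experiment <- function(values, samples, manifest,
                            scale = c("beta", "m")) {
  scale <- match.arg(scale)
  samples <- validate_sample_sheet(samples)
  manifest <- validate_manifest(manifest)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("`values` must carry probe rownames and sample colnames")
  }
  if (!setequal(colnames(values), samples$sample_id)) {
    stop_validation("matrix columns and sample sheet ids must match")
  }
  missing_probes <- setdiff(rownames(values), manifest$probe_id)
  if (length(missing_probes) > 0L) {
    stop_validation(sprintf("%d matrix probe(s) absent from manifest (e.g. %s)",
                            length(missing_probes), missing_probes[1]))
  }
  if (scale == "beta" && any(values <= 0 | values >= 1, na.rm = TRUE)) {
    stop_validation("Beta-scale values must lie strictly in (0, 1)")
  }
  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values, samples = samples, manifest = manifest,
                 scale = scale),
            class = "meth_experiment")
}

#' Convert an experiment's values to the M scale
#'
#' @param experiment A [meth_experiment()].
#' @return The experiment with `scale = "m"` (no-op if already M).
#' @export
as_m_scale <- function(experiment) {
  stopifnot(inherits(experiment, "meth_experiment"))
  if (experiment$scale == "m") return(experiment)
  experiment$values <- beta_to_m(experiment$values)
  experiment$scale <- "m"
  experiment
}

#' @export
print.meth_experiment <- function(x, ...) {
  cat(sprintf("<meth_experiment> %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  tp <- unique(x$samples$timepoint)
  cat(sprintf("  particles: %s | timepoints: %s\n",
              paste(unique(x$samples$particle), collapse = ", "),
              paste(tp, collapse = ", ")))
  invisible(x)
}

#' @export
dim.meth_experiment <- function(x) dim(x$values)

# Resolve a condition selector (particle, dose, timepoint) to sample ids.
select_samples <- function(samples, particle = NULL, dose_gy = NULL,
                           timepoint = NULL) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(particle)) keep <- keep & samples$particle %in% particle
  if (!is.null(dose_gy)) keep <- keep & samples$dose_gy %in% dose_gy
  if (!is.null(timepoint)) keep <- keep & samples$timepoint %in% timepoint
  samples$sample_id[keep]
}
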