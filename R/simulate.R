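#' Generate a synthetic probe manifest with CpG-island and gene annotation
#'
#' Probes are placed uniformly along each chromosome; CpG islands and genes
#' are laid out first and every probe's `cpg_relation` / `genic_group` is
#' derived from its distance to the generated features, so annotation and
#' coordinates are consistent by construction.
#'
#' @param config A [sim_config()].
#' @return A list with `manifest` (probe tibble), `islands`, `tss`,
#'   `gene_bodies` (0-based half-open interval tibbles; `tss` has a
#'   0-based `pos0` point per gene).
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "manifest"), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    len <- config$chrom_length
    place_features <- function(n_target, width_range, min_gap) {
      cand <- sort(sample.int(len - width_range[2] - 1L, n_target * 3L))
      widths <- round(runif(length(cand), width_range[1], width_range[2]))
      keep_s <- numeric(0); keep_e <- numeric(0); last_end <- -Inf
      for (i in seq_along(cand)) {
        if (length(keep_s) >= n_target) break
        if (cand[i] >= last_end + min_gap) {
          keep_s <- c(keep_s, cand[i]); keep_e <- c(keep_e, cand[i] + widths[i])
          last_end <- cand[i] + widths[i]
        }
      }
      tibble(start = keep_s, end = keep_e)
    }
    islands <- purrr::map_dfr(chroms, function(ch) {
      f <- place_features(max(1L, round(len / 1e5)), c(500, 1500), 9000)
      dplyr::mutate(f, chrom = ch, .before = 1)
    })
    genes <- purrr::map_dfr(chroms, function(ch) {
      f <- place_features(max(1L, round(len / 2e5)), c(10000, 100000), 25000)
      dplyr::mutate(f, chrom = ch, .before = 1)
    })
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    tss <- tibble(chrom = genes$chrom, pos0 = genes$start,
                  gene_id = genes$gene_id)
    gene_bodies <- tibble(chrom = genes$chrom, start = genes$start,
                          end = genes$end, name = genes$gene_id)

    per_chrom <- diff(floor(seq(0, config$n_probes,
                                length.out = config$n_chroms + 1L)))
    manifest <- purrr::map2_dfr(chroms, per_chrom, function(ch, n) {
      tibble(chrom = ch, pos = sort(sample.int(len, n)))
    })
    manifest <- dplyr::mutate(manifest,
                              probe_id = sprintf("cg%08d", dplyr::row_number()),
                              .before = 1)
    manifest$cpg_relation <- classify_cpg_relation(
      manifest$chrom, manifest$pos, islands, levels = 4)
    manifest$genic_group <- classify_genic_group(
      manifest$chrom, manifest$pos, tss, gene_bodies)
    list(manifest = validate_manifest(manifest), islands = islands,
         tss = tss, gene_bodies = gene_bodies)
  })
}

# Genic classification with fixed precedence: Promoter (TSS +/- 2 kb) >
# Body > Upstream (2-10 kb before TSS) > Downstream (10 kb past gene end) >
# Intergenic.
classify_genic_group <- function(chrom, pos, tss, gene_bodies,
                                 promoter_halfwidth = 2000,
                                 flank = 10000) {
  prom <- tibble(chrom = tss$chrom,
                 start = pmax(tss$pos0 - promoter_halfwidth, 0),
                 end = tss$pos0 + promoter_halfwidth)
  upst <- tibble(chrom = tss$chrom,
                 start = pmax(tss$pos0 - flank, 0),
                 end = pmax(tss$pos0 - promoter_halfwidth, 0))
  upst <- upst[upst$end > upst$start, , drop = FALSE]
  down <- tibble(chrom = gene_bodies$chrom, start = gene_bodies$end,
                 end = gene_bodies$end + flank)
  out <- rep("Intergenic", length(pos))
  out[point_in_intervals(chrom, pos, down)] <- "Downstream"
  out[point_in_intervals(chrom, pos, upst)] <- "Upstream"
  out[point_in_intervals(chrom, pos, gene_bodies)] <- "Body"
  out[point_in_intervals(chrom, pos, prom)] <- "Promoter"
  out
}

#' Generate a synthetic Hi-C score track
#'
#' Contiguous fixed-width bins tile every chromosome, so each probe falls in
#' exactly one bin. Chromosomes receive distinct radial preferences (evenly
#' spaced per-chromosome mean shifts) plus within-chromosome Gaussian noise,
#' emulating whole-chromosome territories at different nuclear depths.
#'
#' @param config A [sim_config()].
#' @return An interval tibble (`chrom`, `start`, `end`, `name`, `score`).
#' @export
generate_hic_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "hic"), {
    shifts <- seq(-1, 1, length.out = config$n_chroms)
    purrr::map_dfr(seq_len(config$n_chroms), function(i) {
      starts <- seq(0, config$chrom_length - 1, by = config$bin_width)
      ends <- pmin(starts + config$bin_width, config$chrom_length)
      tibble(chrom = paste0("chr", i), start = starts, end = ends,
             name = NA_character_,
             score = shifts[i] + rnorm(length(starts), 0, 0.5))
    })
  })
}

#' Generate a synthetic methylation experiment with planted ground truth
#'
#' Baseline Beta values come from a bimodal mixture (hypomethylated mode
#' near 0.1, hypermethylated near 0.9) shared across samples. For each
#' particle, a `dmp_fraction` subset of probes receives a planted M-scale
#' shift `effect_direction * effect_size_m * layer_weight`, where the
#' probe's planted layer is its equal-occupancy quantile stratum of the
#' generated Hi-C scores. Decaying particles shrink the shift geometrically
#' at later timepoints; a `clustered_fraction` of true DMPs is packed into
#' 1 kb windows. Replicate noise is Gaussian on the M scale; values are
#' returned on the Beta scale.
#'
#' @param config A [sim_config()].
#' @param manifest Probe manifest from [generate_manifest()].
#' @param hic Score track from [generate_hic_track()].
#' @return A list with `experiment` (a [meth_experiment()], Beta scale) and
#'   `truth` (tibbles `dmps` and `layers`, per-particle planted effects).
#' @export
generate_methylation <- function(config, manifest, hic) {
  stopifnot(inherits(config, "sim_config"))
  scored <- assign_hic_scores(manifest, hic)
  model <- build_layers(scored, n_layers = 5L)
  layer_of <- setNames(model$assignment$layer, model$assignment$probe_id)

  with_seed(derive_seed(config$seed, "methylation"), {
    n <- nrow(manifest)
    hypo <- runif(n) < 0.5
    beta0 <- ifelse(hypo, rbeta(n, 5, 45), rbeta(n, 45, 5))
    m0 <- log2(beta0 / (1 - beta0))

    samples <- purrr::map_dfr(config$particles, function(p) {
      ctrl <- tibble(
        sample_id = sprintf("%s_0Gy_%s_r%d", p$name, config$timepoints[1],
                            seq_len(config$replicates_per_condition)),
        particle = p$name, dose_gy = 0, timepoint = config$timepoints[1],
        replicate = seq_len(config$replicates_per_condition))
      irr <- purrr::map_dfr(config$timepoints, function(tp) {
        tibble(
          sample_id = sprintf("%s_%gGy_%s_r%d", p$name, p$dose_gy, tp,
                              seq_len(config$replicates_per_condition)),
          particle = p$name, dose_gy = p$dose_gy, timepoint = tp,
          replicate = seq_len(config$replicates_per_condition))
      })
      dplyr::bind_rows(ctrl, irr)
    })

    n_dmp <- round(config$dmp_fraction * n)
    chrom_pos <- split(seq_len(n), manifest$chrom)
    pick_truth <- function() {
      if (n_dmp == 0L) {
        return(list(clustered = integer(0), scattered = integer(0)))
      }
      n_clu <- round(config$clustered_fraction * n_dmp)
      sel <- integer(0)
      iter <- 0L
      while (length(sel) < n_clu && iter < 50L * n_dmp) {
        iter <- iter + 1L
        ch <- sample(names(chrom_pos), 1L,
                     prob = lengths(chrom_pos) / n)
        idx <- chrom_pos[[ch]]
        w0 <- runif(1, 0, config$chrom_length - 1000)
        members <- idx[manifest$pos[idx] - 1 >= w0 &
                         manifest$pos[idx] - 1 < w0 + 1000]
        members <- setdiff(members, sel)
        if (length(members) >= 2L) {
          sel <- c(sel, head(members, n_clu - length(sel)))
        }
      }
      n_rest <- n_dmp - length(sel)
      rest <- sample(setdiff(seq_len(n), sel), n_rest)
      list(clustered = sel, scattered = rest)
    }

    mat <- matrix(NA_real_, nrow = n, ncol = nrow(samples),
                  dimnames = list(manifest$probe_id, samples$sample_id))
    truth_rows <- list()
    for (p in config$particles) {
      tr <- pick_truth()
      idx <- c(tr$clustered, tr$scattered)
      layer_num <- match(layer_of[manifest$probe_id[idx]], layer_levels(5))
      weight <- config$layer_effect_profile[layer_num]
      weight[is.na(weight)] <- 1
      delta <- p$effect_direction * p$effect_size_m * weight
      if (length(idx) > 0L) {
        truth_rows[[p$name]] <- tibble(
          particle = p$name, probe_id = manifest$probe_id[idx],
          planted_delta_m = delta,
          direction = ifelse(p$effect_direction > 0, "up", "down"),
          clustered = seq_along(idx) <= length(tr$clustered),
          layer = layer_of[manifest$probe_id[idx]])
      }
      for (s in which(samples$particle == p$name)) {
        col <- m0
        if (samples$dose_gy[s] > 0 && length(idx) > 0L) {
          ti <- match(samples$timepoint[s], config$timepoints)
          fac <- if (p$persistence == "persistent") 1 else p$decay_ratio^(ti - 1)
          col[idx] <- col[idx] + delta * fac
        }
        mat[, s] <- col + rnorm(n, 0, config$noise_sd_m)
      }
    }
    beta <- m_to_beta(mat)
    truth <- list(
      dmps = if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else
        tibble(particle = character(), probe_id = character(),
               planted_delta_m = numeric(), direction = character(),
               clustered = logical(), layer = character()),
      layers = model$assignment[, c("probe_id", "layer")])
    list(experiment = meth_experiment(beta, samples, manifest, "beta"),
         truth = truth)
  })
}

#' Generate synthetic histone-mark peak sets
#'
#' Four marks with widths in \[300, 2000\] bp and a per-peak alignment
#' score. H3K9me3 placement probability decreases with the local Hi-C score
#' (peripheral heterochromatin), H3K27ac increases with it, H3K4me3 and
#' H3K27me3 are flat.
#'
#' @param config A [sim_config()].
#' @param hic Score track from [generate_hic_track()].
#' @param marks Character vector of marks to generate (default all four).
#' @return Named list of peak tibbles (`chrom`, `start`, `end`, `name`,
#'   `score`), one per requested mark.
#' @export
generate_peaks <- function(config, hic,
                           marks = c("H3K4me3", "H3K27ac", "H3K27me3",
                                     "H3K9me3")) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "peaks"), {
    out <- list()
    for (mark in marks) {
      w <- switch(mark,
                  H3K9me3 = stats::plogis(-2 * hic$score),
                  H3K27ac = stats::plogis(2 * hic$score),
                  rep(1, nrow(hic)))
      bins <- sample.int(nrow(hic), config$n_peaks_per_mark,
                         replace = TRUE, prob = w)
      width <- round(runif(config$n_peaks_per_mark, 300, 2000))
      offset <- floor(runif(config$n_peaks_per_mark) *
                        pmax(1, (hic$end[bins] - hic$start[bins]) - width))
      start <- hic$start[bins] + offset
      out[[mark]] <- tibble(
        chrom = hic$chrom[bins], start = start, end = start + width,
        name = sprintf("%s_%04d", mark, seq_along(bins)),
        score = round(runif(config$n_peaks_per_mark, 0, 42), 2)) |>
        dplyr::arrange(.data$chrom, .data$start)
    }
    out
  })
}

#' Generate a synthetic expression count matrix with planted trajectories
#'
#' Negative-binomial counts for a control group plus the configured ordered
#' timepoints. A planted `de_fraction` of genes carries |logFC| =
#' `expr_logfc` at the first timepoint (half up, half down) which either
#' persists or decays geometrically. Library sizes vary by a factor drawn
#' uniformly from \[0.5, 2\].
#'
#' @param config A [sim_config()].
#' @param persistence `"persistent"` or `"decaying"` planted kinetics.
#' @param decay_ratio Geometric ratio for decaying trajectories.
#' @param genes Optional character vector of gene ids to use (defaults to
#'   `gene0001..`); lets callers tie counts to a generated annotation.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `samples` (sample_id, timepoint, replicate), and `truth` (gene,
#'   class, planted logFC per timepoint, long format).
#' @export
generate_counts <- function(config,
                            persistence = c("persistent", "decaying"),
                            decay_ratio = 0.5, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  persistence <- match.arg(persistence)
  if (config$replicates_per_condition < 2L) {
    stop_config("need >= 2 replicates per timepoint group")
  }
  with_seed(derive_seed(config$seed, paste0("counts_", persistence)), {
    ng <- config$n_genes
    if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(ng))
    ng <- length(genes)
    groups <- c("control", config$timepoints)
    reps <- config$replicates_per_condition
    samples <- tidyr::expand_grid(timepoint = groups,
                                  replicate = seq_len(reps)) |>
      dplyr::mutate(sample_id = sprintf("%s_r%d", .data$timepoint,
                                        .data$replicate), .before = 1)
    base_mu <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
    n_de <- round(config$de_fraction * ng)
    de_idx <- sample.int(ng, n_de)
    lfc <- numeric(ng)
    lfc[de_idx] <- config$expr_logfc *
      rep_len(c(1, -1), n_de)
    tp_factor <- function(tp) {
      if (tp == "control") return(0)
      ti <- match(tp, config$timepoints)
      if (persistence == "persistent") 1 else decay_ratio^(ti - 1)
    }
    lib <- runif(nrow(samples), 0.5, 2)
    counts <- matrix(0L, nrow = ng, ncol = nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      mu <- base_mu * lib[s] * 2^(lfc * tp_factor(samples$timepoint[s]))
      counts[, s] <- rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
    }
    truth <- tidyr::expand_grid(gene = genes[de_idx],
                                timepoint = config$timepoints) |>
      dplyr::mutate(
        planted_lfc = lfc[match(.data$gene, genes)] *
          vapply(.data$timepoint, tp_factor, numeric(1), USE.NAMES = FALSE),
        class = ifelse(lfc[match(.data$gene, genes)] > 0, "up", "down"))
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Generate every pipeline input from one configuration
#'
#' Convenience wrapper running all generators on independent RNG streams
#' derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list: `manifest`, `islands`, `tss`, `gene_bodies`, `hic`,
#'   `experiment`, `truth`, `peaks`, `counts` (persistent kinetics) and
#'   `counts_decaying`.
#' @export
simulate_inputs <- function(config) {
  ann <- generate_manifest(config)
  hic <- generate_hic_track(config)
  meth <- generate_methylation(config, ann$manifest, hic)
  peaks <- generate_peaks(config, hic)
  counts <- generate_counts(config, "persistent")
  counts_dec <- generate_counts(config, "decaying")
  list(manifest = ann$manifest, islands = ann$islands, tss = ann$tss,
       gene_bodies = ann$gene_bodies, hic = hic,
       experiment = meth$experiment, truth = meth$truth, peaks = peaks,
       counts = counts, counts_decaying = counts_dec)
}

#' Write a simulated input bundle to disk
#'
#' Emits every input kind in its interchange format: manifest and matrices
#' as TSV, islands/TSS/gene bodies/peaks as BED, the Hi-C track as
#' bedGraph, and the planted truth as TSV.
#'
#' @param sim Output of [simulate_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_manifest(sim$manifest, p("manifest.tsv"))
  write_intervals(sim$islands, p("islands.bed"), "bed")
  write_intervals(tibble(chrom = sim$tss$chrom, start = sim$tss$pos0,
                         end = sim$tss$pos0 + 1, name = sim$tss$gene_id),
                  p("tss.bed"), "bed")
  write_intervals(sim$gene_bodies, p("gene_bodies.bed"), "bed")
  write_intervals(sim$hic, p("hic.bedgraph"), "bedgraph")
  write_matrix(sim$experiment$values, p("beta.tsv"), id_column = "probe_id")
  write_sample_sheet(sim$experiment$samples, p("samples.tsv"))
  for (mark in names(sim$peaks)) {
    write_intervals(sim$peaks[[mark]], p(sprintf("peaks_%s.bed", mark)), "bed")
  }
  write_matrix(sim$counts$counts, p("counts.tsv"), id_column = "gene")
  readr::write_tsv(sim$counts$samples, p("count_samples.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$dmps, p("truth_dmps.tsv"), progress = FALSE)
  invisible(dir)
}
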