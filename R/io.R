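#' Read genomic intervals from BED or bedGraph
#'
#' Intervals are kept in the file's native 0-based half-open convention.
#' BED column 5 (score) and the bedGraph value column both map to `score`;
#' BED column 4 maps to `name` (a literal `"."` is read as missing).
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to a tab-separated BED (>= 3 columns) or bedGraph
#'   (4 columns) file.
#' @param format Either `"bed"` or `"bedgraph"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   one row per input line in file order.
#' @export
read_intervals <- function(path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_min <- if (format == "bedgraph") 4L else 3L
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < n_min) {
      stop_parse(sprintf("line %d: expected >= %d tab-separated fields, got %d",
                         i, n_min, length(f)))
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      stop_parse(sprintf("line %d: non-numeric start/end ('%s', '%s')",
                         i, f[2], f[3]))
    }
    if (end <= start) {
      stop_validation(sprintf("line %d: interval end (%s) must exceed start (%s)",
                              i, f[3], f[2]))
    }
    if (format == "bedgraph") {
      score <- suppressWarnings(as.numeric(f[4]))
      if (is.na(score)) {
        stop_parse(sprintf("line %d: non-numeric bedGraph value '%s'", i, f[4]))
      }
      name <- NA_character_
    } else {
      name <- if (length(f) >= 4L && f[4] != ".") f[4] else NA_character_
      score <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_
    }
    if (!is.na(score) && !is.finite(score)) {
      stop_validation(sprintf("line %d: non-finite score", i))
    }
    out[[i]] <- list(chrom = f[1], start = start, end = end,
                     name = name, score = score)
  }
  res <- dplyr::bind_rows(lapply(out, tibble::as_tibble_row))
  if (nrow(res) == 0L) {
    res <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric())
  }
  res
}

#' Write genomic intervals as BED or bedGraph
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score` (bedGraph requires `score`). Missing names are written as `"."`.
#' @param path Output path (`.gz` suffix compresses).
#' @param format Either `"bed"` or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  check_columns(x, c("chrom", "start", "end"), "interval table")
  fmt_num <- function(v) {
    ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
           format(v, scientific = FALSE, trim = TRUE, digits = 15))
  }
  if (format == "bedgraph") {
    check_columns(x, "score", "bedGraph table")
    lines <- paste(x$chrom, fmt_num(x$start), fmt_num(x$end),
                   fmt_num(x$score), sep = "\t")
  } else {
    name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else NULL
    score <- if ("score" %in% names(x)) x$score else NULL
    cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
    if (!is.null(score) && any(!is.na(score))) {
      cols <- c(cols, list(if (is.null(name)) rep(".", nrow(x)) else name),
                list(fmt_num(score)))
    } else if (!is.null(name)) {
      cols <- c(cols, list(name))
    }
    lines <- do.call(paste, c(cols, sep = "\t"))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a probe manifest
#'
#' Expects a TSV with header columns `probe_id`, `chrom`, `pos` (1-based
#' point coordinate), `cpg_relation` (Island/Shore/Shelf/OpenSea) and
#' `genic_group` (Promoter/Upstream/Downstream/Body/Intergenic).
#'
#' @param path Path to the manifest TSV.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("probe_id", "chrom", "pos", "cpg_relation", "genic_group"),
                "manifest")
  df$pos <- suppressWarnings(as.numeric(df$pos))
  validate_manifest(df)
}

validate_manifest <- function(df) {
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0L) {
    stop_validation(sprintf("duplicated probe id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (anyNA(df$pos) || any(df$pos < 1) || any(df$pos != round(df$pos))) {
    stop_validation("manifest `pos` must be integer and >= 1 (1-based)")
  }
  bad_cpg <- setdiff(unique(df$cpg_relation), cpg_levels)
  if (length(bad_cpg) > 0L) {
    stop_validation(sprintf("unknown cpg_relation value(s): %s",
                            paste(bad_cpg, collapse = ", ")))
  }
  bad_gen <- setdiff(unique(df$genic_group), genic_levels)
  if (length(bad_gen) > 0L) {
    stop_validation(sprintf("unknown genic_group value(s): %s",
                            paste(bad_gen, collapse = ", ")))
  }
  tibble(probe_id = df$probe_id, chrom = df$chrom, pos = as.numeric(df$pos),
         cpg_relation = df$cpg_relation, genic_group = df$genic_group)
}

#' @rdname read_manifest
#' @param x Manifest tibble to write.
#' @export
write_manifest <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' First column holds row identifiers, the header row sample identifiers.
#' Cells `NA`/empty are recorded as missing (never as zero).
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_parse("matrix file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  samples <- header[-1]
  n <- length(fields) - 1L
  m <- matrix(NA_real_, nrow = n, ncol = length(samples))
  row_ids <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expected) {
      stop_parse(sprintf("row %d ('%s'): expected %d fields, got %d (ragged row)",
                         i, f[1], ncol_expected, length(f)))
    }
    row_ids[i] <- f[1]
    vals <- f[-1]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")))
    if (length(bad) > 0L) {
      stop_parse(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                         f[1], samples[bad[1]], vals[bad[1]]))
    }
    m[i, ] <- num
  }
  rownames(m) <- row_ids
  colnames(m) <- samples
  m
}

#' @rdname read_matrix
#' @param x Numeric matrix with dimnames to write.
#' @param id_column Header name for the row-identifier column.
#' @export
write_matrix <- function(x, path, id_column = "id") {
  df <- tibble::as_tibble(x, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Expects TSV columns `sample_id`, `particle`, `dose_gy`, `timepoint`,
#' `replicate`. Dose-zero samples are the controls of their batch.
#'
#' @param path Path to the sample-sheet TSV.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  check_columns(df, c("sample_id", "particle", "dose_gy", "timepoint", "replicate"),
                "sample sheet")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0L) {
    stop_validation(sprintf("duplicated sample id(s): %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (any(df$dose_gy < 0)) stop_validation("dose_gy must be >= 0")
  tibble::as_tibble(df)
}

#' @rdname read_sample_sheet
#' @param x Sample sheet tibble to write.
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
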