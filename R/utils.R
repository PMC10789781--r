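# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generators funnel through this so that
# identical config + seed gives byte-identical output regardless of what the
# session did before.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.",
          class = "radialmeth_error_config")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream label,
# so that independent generators never share an RNG stream.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_validation <- function(msg) {
  abort(msg, class = "radialmeth_error_validation")
}

stop_parse <- function(msg) {
  abort(msg, class = "radialmeth_error_parse")
}

stop_config <- function(msg) {
  abort(msg, class = "radialmeth_error_config")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_validation(sprintf("%s is missing required column(s): %s",
                            what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

cpg_levels <- c("Island", "Shore", "Shelf", "OpenSea")
genic_levels <- c("Promoter", "Upstream", "Downstream", "Body", "Intergenic")
mark_levels <- c("H3K4me3", "H3K27ac", "H3K27me3", "H3K9me3")
layer_levels <- function(n = 5L) paste0("L", seq_len(n))
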