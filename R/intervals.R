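# Point-vs-interval overlap helpers. Intervals are 0-based half-open
# tibbles (chrom, start, end); probe/TSS positions are 1-based points, so a
# point `pos` falls in [start, end) iff start <= pos - 1 < end. All overlap
# queries go through IRanges.

# Logical: does each point lie inside any interval (per chromosome)?
point_in_intervals <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  hit <- logical(length(pos))
  if (nrow(intervals) == 0L || length(pos) == 0L) return(hit)
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(iv) == 0L) next
    q <- IRanges::IRanges(start = pos[idx], width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hit[idx] <- IRanges::countOverlaps(q, s) > 0L
  }
  hit
}

# bp distance from each point to the nearest interval edge on its
# chromosome (0 if inside); NA where the chromosome has no intervals.
point_interval_distance <- function(chrom, pos, intervals) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(iv) == 0L) next
    iv <- iv[order(iv$start), , drop = FALSE]
    p0 <- pos[idx] - 1
    k <- findInterval(p0, iv$start)
    d <- rep(Inf, length(p0))
    inside <- k >= 1L & p0 < iv$end[pmax(k, 1L)]
    d[inside] <- 0
    left <- !inside & k >= 1L
    d[left] <- p0[left] - (iv$end[k[left]] - 1)
    right_idx <- pmin(k + 1L, nrow(iv))
    has_right <- k < nrow(iv)
    cand <- ifelse(has_right, iv$start[right_idx] - p0, Inf)
    d <- pmin(d, pmax(cand, 0))
    out[idx] <- d
  }
  out
}
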