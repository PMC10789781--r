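#' Convert between Beta and M methylation scales
#'
#' `beta_to_m()` maps Beta values (methylated intensity fraction, in (0,1))
#' to M values, `m = log2(beta / (1 - beta))`; `m_to_beta()` is the inverse
#' logistic map. Effects in this package are thresholded on the M scale.
#' Beta values of exactly 0 or 1 are clamped to `eps` / `1 - eps` before the
#' transform (with a warning), since the M value is unbounded there.
#'
#' @param beta,m Numeric vectors (or matrices) of values to transform.
#' @param eps Clamp width for boundary Beta values.
#' @return Numeric object of the same shape.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' m_to_beta(beta_to_m(0.3))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop_validation("Beta values must lie in [0, 1]")
  }
  n_clamped <- sum(beta <= 0 | beta >= 1, na.rm = TRUE)
  if (n_clamped > 0L) {
    warn(sprintf("%d Beta value(s) at 0 or 1 clamped to [%g, %g]",
                 n_clamped, eps, 1 - eps))
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
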