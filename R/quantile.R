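#' Linear-interpolation quantile
#'
#' Single quantile implementation shared by every thresholding step in the
#' package (footprint RPKM / coverage background cut-offs and the intergenic
#' conservation cut-off), so all percentile-based rules use one convention:
#' linear interpolation between order statistics. For a sorted sample
#' \eqn{x_{(1)} \le \dots \le x_{(n)}} and probability \eqn{p}, the quantile is
#' taken at rank \eqn{h = (n-1)p + 1}, interpolating between the flanking
#' order statistics.
#'
#' @param x numeric vector, finite, non-empty.
#' @param probs probabilities in \[0, 1\] (vectorized).
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' quantile_linear(1:10, 0.9) # 9.1
quantile_linear <- function(x, probs) {
  if (length(x) == 0L) stop("quantile_linear: empty input")
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("quantile_linear: input must be finite numeric")
  }
  if (any(probs < 0 | probs > 1)) stop("quantile_linear: probs must lie in [0, 1]")
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * probs
  lo <- floor(h)
  frac <- h - lo
  x[lo + 1L] * (1 - frac) + x[pmin(lo + 2L, n)] * frac
}

#' Median excluding undefined values
#'
#' Plain sample median with `NA` (undefined, e.g. gated translational
#' efficiencies) dropped; returns `NA` when nothing remains.
#' @param x numeric vector possibly containing `NA`.
#' @return scalar median or `NA`.
#' @export
median_defined <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}
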