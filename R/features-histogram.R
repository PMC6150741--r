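#' First-order histogram features
#'
#' Whole-tumor first-order statistics, computed without any spatial
#' information. Mean, median and SD (and the moment-based skewness and
#' kurtosis) are computed on the original in-mask intensities carried by the
#' quantized volume, so they live in physical intensity units; entropy and
#' energy (uniformity) are computed on the G-bin gray-level histogram.
#' Moments use n denominators; skewness/kurtosis follow the Fisher
#' convention (excess kurtosis 0 for a Gaussian). Entropy is in bits with
#' `0 log 0 = 0`.
#'
#' @param q a `quantized_volume` from [quantize()].
#' @return named list: `hist_mean`, `hist_median`, `hist_sd`,
#'   `hist_skewness`, `hist_kurtosis`, `hist_entropy`, `hist_energy`, with
#'   attribute `flags` naming any degenerate features (reported as 0).
#' @export
histogram_features <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  x <- q$intensities
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  flags <- character(0)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
    flags <- c(flags, "hist_skewness", "hist_kurtosis")
  }
  p <- tabulate(q$data[q$mask], nbins = q$G) / n
  p <- p[p > 0]
  structure(list(
    hist_mean = mu,
    hist_median = stats::median(x),
    hist_sd = sqrt(m2),
    hist_skewness = skew,
    hist_kurtosis = kurt,
    hist_entropy = -sum(p * log2(p)),
    hist_energy = sum(p^2)
  ), flags = flags)
}
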