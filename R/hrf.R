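#' Canonical double-gamma hemodynamic response function
#'
#' Returns the canonical HRF (difference of two gamma densities: response
#' peak at 6 s, undershoot at 16 s, peak-to-undershoot ratio 6) sampled at
#' the scanner repetition time. By default the kernel is normalized to unit
#' sum, so convolving a sustained boxcar of amplitude 1 yields a plateau of
#' 1; a single-scan impulse then peaks at roughly half its amplitude.
#'
#' @param tr sampling interval in seconds (fMRI repetition time).
#' @param duration kernel support in seconds.
#' @param peak,undershoot gamma shape parameters (seconds to peak of the
#'   positive and negative lobes, with unit rate).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param normalize `"sum"` (default, unit area), `"peak"` (unit maximum)
#'   or `"none"`.
#' @return numeric vector of kernel samples at `0, tr, 2*tr, ...`.
#' @export
#' @examples
#' h <- canonical_hrf(2.1)
#' round(sum(h), 6)
canonical_hrf <- function(tr, duration = 32, peak = 6, undershoot = 16,
                          ratio = 6, normalize = c("sum", "peak", "none")) {
  stopifnot(tr > 0, duration > 0)
  normalize <- match.arg(normalize)
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio
  switch(normalize,
    sum = h / sum(h),
    peak = h / max(h),
    none = h
  )
}

## causal convolution of each column of X with kernel h, truncated to nrow(X)
convolve_columns <- function(X, h) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- apply(X, 2L, function(x) {
    convolve(c(x, numeric(length(h))), rev(h), type = "open")[seq_len(n)]
  })
  matrix(out, nrow = n, dimnames = dimnames(X))
}
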