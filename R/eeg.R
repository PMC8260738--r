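#' Per-epoch log band power of single-channel EEG
#'
#' Welch-style time course of spectral power: the signal is cut into 4-s
#' epochs advancing by 2 s; each epoch is Hamming-windowed and its modified
#' periodogram computed; band power is the band-integrated spectral density
#' (sum of in-band bins times the bin width, lower band edge inclusive,
#' upper exclusive), reported as log10.
#'
#' @param signal numeric EEG vector.
#' @param fs sampling rate in Hz; must be at least twice the top band edge.
#' @param epoch_len epoch length in seconds (default 4).
#' @param overlap epoch overlap in seconds (default 2).
#' @param bands band definition data.frame (default [eeg_bands()]).
#' @param mask optional logical vector per epoch; `FALSE` epochs (arousals,
#'   movement artifacts) are dropped from the output.
#' @return object of class `band_power`: list with `times` (epoch centers,
#'   s), `log_power` (epochs x bands, log10), `bands`.
#' @export
epoch_band_power <- function(signal, fs, epoch_len = 4, overlap = 2,
                             bands = eeg_bands(), mask = NULL) {
  stopifnot(fs >= 2 * max(bands$hi), overlap < epoch_len)
  nper <- round(epoch_len * fs)
  step <- round((epoch_len - overlap) * fs)
  if (length(signal) < nper) stop("signal shorter than one epoch")
  n_ep <- floor((length(signal) - nper) / step) + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nper - 1L)) / (nper - 1L))
  wnorm <- fs * sum(w^2)
  df <- fs / nper
  freqs <- (0:(nper %/% 2)) * df

  starts <- (seq_len(n_ep) - 1L) * step
  segs <- vapply(starts, function(s0) signal[(s0 + 1L):(s0 + nper)] * w,
                 numeric(nper))
  FT <- stats::mvfft(segs)
  P <- Mod(FT[seq_along(freqs), , drop = FALSE])^2 / wnorm
  ## one-sided density: double everything but DC (and Nyquist when even)
  dbl <- rep(2, length(freqs))
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[length(freqs)] <- 1
  P <- P * dbl

  bp <- matrix(NA_real_, n_ep, nrow(bands),
               dimnames = list(NULL, bands$band))
  for (i in seq_len(nrow(bands))) {
    sel <- freqs >= bands$lo[i] & freqs < bands$hi[i]
    pw <- colSums(P[sel, , drop = FALSE]) * df
    if (any(pw <= 0))
      stop("zero band power (log undefined) at epoch ",
           which(pw <= 0)[1L], ", band ", bands$band[i])
    bp[, i] <- log10(pw)
  }
  times <- starts / fs + epoch_len / 2
  if (!is.null(mask)) {
    stopifnot(length(mask) == n_ep)
    bp <- bp[mask, , drop = FALSE]
    times <- times[mask]
  }
  structure(list(times = times, log_power = bp, bands = bands,
                 freqs = freqs, total_power = colSums(P) * df),
            class = "band_power")
}

#' Resample band-power series to fMRI scan times
#'
#' Linear interpolation of each band's log-power series at scan onsets
#' `0, tr, 2*tr, ...`, with constant extrapolation at the edges.
#'
#' @param bp a `band_power` object.
#' @param tr repetition time in seconds.
#' @param n_scans number of scans to produce.
#' @return matrix `n_scans` x bands of log10 power.
#' @export
resample_to_scans <- function(bp, tr, n_scans) {
  stopifnot(inherits(bp, "band_power"))
  if (!is.numeric(n_scans) || n_scans <= 0)
    stop("n_scans must be a positive count")
  xout <- (seq_len(n_scans) - 1L) * tr
  out <- apply(bp$log_power, 2L, function(y) {
    approx(bp$times, y, xout = xout, rule = 2)$y
  })
  matrix(out, nrow = n_scans,
         dimnames = list(NULL, colnames(bp$log_power)))
}

#' Read / write a hypnogram file
#'
#' Plain text, one stage code (W, N1, N2, N3) per line, 20-s epochs.
#'
#' @param path file path.
#' @export
read_hypnogram <- function(path) {
  ep <- readLines(path)
  ep <- ep[nzchar(ep)]
  bad <- setdiff(unique(ep), SLEEP_STAGES)
  if (length(bad)) stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  structure(list(epochs = ep, epoch_len = 20), class = "hypnogram")
}

#' @rdname read_hypnogram
#' @param hyp a `hypnogram`.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  writeLines(hyp$epochs, path)
  invisible(path)
}
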