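#' Decode brain-state likelihoods from sleep fMRI
#'
#' Standardizes the sleep ROI time series with the training-session stats
#' and returns per-scan posterior state marginals from the trained CRF
#' (uniform transitions by default, so the task's temporal structure is not
#' imposed on sleep).
#'
#' @param model fitted `crf_model` (its `train_stats` are used unless
#'   `stats` is supplied).
#' @param sleep_ts scans x ROIs matrix; same ROI set and order as training.
#' @param stats optional `crf_features` standardization override.
#' @return `state_lik` matrix, scans x states.
#' @export
decode_sleep <- function(model, sleep_ts, stats = model$train_stats) {
  sleep_ts <- as.matrix(sleep_ts)
  if (ncol(sleep_ts) != ncol(model$mu) - 1L)
    stop("ROI mismatch: model expects ", ncol(model$mu) - 1L,
         " ROIs, got ", ncol(sleep_ts))
  if (!is.null(stats) && !is.null(colnames(sleep_ts)) &&
      !is.null(names(stats$center))) {
    bad <- which(colnames(sleep_ts) != names(stats$center))
    if (length(bad))
      stop("ROI name/order mismatch at column(s): ",
           paste(head(bad, 5L), collapse = ", "))
  }
  fe <- if (is.null(stats)) featurize(sleep_ts)
        else featurize(sleep_ts, stats)
  posterior_marginals(model, fe)
}

## sleep stage of each scan: stage of the 20-s epoch containing its onset
stage_of_scans <- function(hyp, n_scans, tr) {
  onsets <- (seq_len(n_scans) - 1L) * tr
  idx <- floor(onsets / hyp$epoch_len) + 1L
  if (any(idx > length(hyp$epochs)))
    stop("scan onset beyond hypnogram end")
  hyp$epochs[idx]
}

#' Mean state likelihood per sleep stage
#'
#' Assigns each scan the stage of its containing 20-s epoch and averages
#' the reward-mapped likelihood columns within each stage. Stages with no
#' scans are returned with `NA` means and `n_scans = 0` (missing, not
#' zero).
#'
#' @param lik `state_lik` matrix from [decode_sleep()].
#' @param hyp a `hypnogram` covering the scan span.
#' @param mapping a [reward_mapping()].
#' @param tr repetition time in seconds.
#' @return data.frame with columns `stage`, `state`, `mean_likelihood`,
#'   `n_scans`.
#' @export
stage_mean_likelihood <- function(lik, hyp, mapping, tr) {
  m <- apply_reward_mapping(as.matrix(unclass(lik)), mapping)
  stage <- stage_of_scans(hyp, nrow(m), tr)
  out <- expand.grid(stage = SLEEP_STAGES, state = colnames(m),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_likelihood <- NA_real_
  out$n_scans <- 0L
  for (st in SLEEP_STAGES) {
    rows <- stage == st
    sel <- out$stage == st
    out$n_scans[sel] <- sum(rows)
    if (any(rows))
      out$mean_likelihood[sel] <-
        colMeans(m[rows, , drop = FALSE])[out$state[sel]]
  }
  out
}

#' Correlate state likelihoods with EEG band power
#'
#' Spearman rank correlation between each (reward-mapped) state-likelihood
#' time course and each band's per-scan log power, with the Fisher
#' z-transform (`atanh`, `|rho|` clamped below 1) applied for averaging and
#' testing.
#'
#' @param lik `state_lik` matrix (already reward-mapped or not; columns are
#'   used as-is).
#' @param band_scan matrix scans x bands, e.g. from [resample_to_scans()].
#' @return data.frame `state`, `band`, `rho`, `z` (`NA` where a series has
#'   zero variance).
#' @export
likelihood_band_correlation <- function(lik, band_scan) {
  lik <- as.matrix(unclass(lik))
  band_scan <- as.matrix(band_scan)
  if (nrow(lik) != nrow(band_scan) || nrow(lik) < 10L)
    stop("series must have equal length >= 10")
  out <- expand.grid(state = colnames(lik), band = colnames(band_scan),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rho <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- lik[, out$state[i]]
    y <- band_scan[, out$band[i]]
    if (sd(x) > 0 && sd(y) > 0)
      out$rho[i] <- cor(x, y, method = "spearman")
  }
  out$z <- fisher_z(out$rho)
  out
}

#' Correlate a seed region's time course with each state likelihood
#'
#' Pearson correlation between an anatomically-defined seed region's BOLD
#' series (e.g. bilateral hippocampus or VTA) and each state-likelihood
#' column.
#'
#' @param seed_ts numeric vector, one value per scan.
#' @param lik `state_lik` matrix, same number of scans.
#' @return named numeric vector of Pearson rho per state (`NA` if a series
#'   has zero variance).
#' @export
roi_state_correlation <- function(seed_ts, lik) {
  lik <- as.matrix(unclass(lik))
  if (length(seed_ts) != nrow(lik)) stop("length mismatch")
  vapply(colnames(lik), function(s) {
    y <- lik[, s]
    if (sd(seed_ts) == 0 || sd(y) == 0) NA_real_ else cor(seed_ts, y)
  }, 0)
}

#' ROI-level regression of BOLD on state likelihoods
#'
#' Ordinary least squares of each ROI's series on an intercept plus the
#' chosen state-likelihood regressors (pre-cue states excluded by default,
#' matching their negligible occurrence in sleep), with a two-state
#' contrast t statistic. Optionally convolves the regressors with the
#' canonical HRF first.
#'
#' @param ts scans x ROIs matrix.
#' @param lik `state_lik` matrix.
#' @param regressors likelihood columns entering the design
#'   (default Face, Maze, Rest).
#' @param contrast character pair `c(plus, minus)` within `regressors`
#'   (default Face - Rest).
#' @param convolve convolve regressors with the HRF (default FALSE).
#' @param tr repetition time, needed when `convolve = TRUE`.
#' @return data.frame `roi`, one `beta_*` column per regressor, `t`
#'   (contrast t), `df`.
#' @export
likelihood_regression <- function(ts, lik, regressors = c("Face", "Maze", "Rest"),
                                  contrast = c("Face", "Rest"),
                                  convolve = FALSE, tr = 2.1) {
  ts <- as.matrix(ts)
  lik <- as.matrix(unclass(lik))
  stopifnot(all(regressors %in% colnames(lik)),
            all(contrast %in% regressors), length(contrast) == 2L)
  R <- lik[, regressors, drop = FALSE]
  if (convolve) R <- convolve_columns(R, canonical_hrf(tr))
  X <- cbind(intercept = 1, R)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  B <- qr.coef(qx, ts)                      ## (p x n_roi)
  res <- ts - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  cvec <- setNames(numeric(ncol(X)), colnames(X))
  cvec[contrast[1L]] <- 1
  cvec[contrast[2L]] <- -1
  XtXinv <- chol2inv(qr.R(qx))
  cvar <- drop(t(cvec) %*% XtXinv %*% cvec)
  tstat <- drop(cvec %*% B) / sqrt(sigma2 * cvar)
  out <- data.frame(roi = colnames(ts) %||% seq_len(ncol(ts)),
                    t(B[regressors, , drop = FALSE]), t = tstat, df = df,
                    row.names = NULL)
  names(out)[2:(1 + length(regressors))] <- paste0("beta_", regressors)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum-statistic conjunction at ROI granularity
#'
#' ROIs significant in both a wake contrast and a sleep contrast: the set
#' intersection.
#'
#' @param wake_sig,sleep_sig character vectors of ROI names over the same
#'   universe.
#' @return character vector (possibly empty).
#' @export
conjunction <- function(wake_sig, sleep_sig) {
  intersect(as.character(wake_sig), as.character(sleep_sig))
}
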