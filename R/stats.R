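#' Repeated-measures ANOVA
#'
#' Univariate repeated-measures ANOVA with subject error strata, computed
#' through `stats::aov` with an `Error(subject/(...))` term. Supports one
#' or two within-subject factors and at most one between-subjects factor.
#' The design must be complete and balanced (every subject contributes the
#' same number of observations to every within cell). Degrees of freedom
#' are uncorrected by default, with an optional Greenhouse-Geisser
#' correction for single-within-factor designs.
#'
#' @param data long-format data.frame.
#' @param dv name of the value column.
#' @param subject name of the subject id column.
#' @param within character vector of within-subject factor columns (1 or 2).
#' @param between optional between-subjects factor column.
#' @param sphericity `"none"` (default) or `"GG"` (Greenhouse-Geisser;
#'   single within factor only).
#' @return data.frame with `effect`, `df1`, `df2`, `F`, `p` (and `epsilon`
#'   under GG).
#' @export
rm_anova <- function(data, dv = "value", subject = "subject",
                     within, between = NULL,
                     sphericity = c("none", "GG")) {
  sphericity <- match.arg(sphericity)
  stopifnot(length(within) >= 1L, length(within) <= 2L,
            all(c(dv, subject, within, between) %in% names(data)))
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (w in c(within, between)) d[[w]] <- factor(d[[w]])

  ## balance: every subject x within-cell must appear equally often
  cell <- do.call(interaction,
                  c(list(d[[subject]]), lapply(within, function(w) d[[w]]),
                    list(drop = FALSE)))
  counts <- table(cell)
  if (length(unique(as.integer(counts))) != 1L) {
    bad <- names(counts)[counts != max(counts)][1L]
    stop("unbalanced or missing cell: ", bad)
  }
  if (!is.null(between)) {
    ## each subject must sit in exactly one between level
    nlev <- tapply(d[[between]], d[[subject]],
                   function(x) length(unique(x)))
    if (any(nlev != 1L)) stop("a subject appears in several between levels")
  }

  wterm <- paste(within, collapse = "*")
  fixed <- if (is.null(between)) wterm else paste(between, "*", wterm)
  fml <- stats::as.formula(paste(dv, "~", fixed,
                                 "+ Error(", subject, "/(", wterm, "))"))
  fit <- aov(fml, data = d)
  res <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1L]]
    rn <- trimws(rownames(tab))
    resid_i <- which(rn == "Residuals")
    if (!length(resid_i)) next
    df2 <- tab$Df[resid_i]
    ms_err <- tab$`Mean Sq`[resid_i]
    for (i in setdiff(seq_len(nrow(tab)), resid_i)) {
      Fv <- tab$`F value`[i]
      pv <- tab$`Pr(>F)`[i]
      ## a zero-variance effect is a null effect even when the error
      ## stratum is also degenerate (0/0)
      if (tab$`Sum Sq`[i] < 1e-12) { Fv <- 0; pv <- 1 }
      res[[length(res) + 1L]] <- data.frame(
        effect = rn[i], df1 = tab$Df[i], df2 = df2, F = Fv, p = pv)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (sphericity == "GG") {
    if (length(within) != 1L)
      stop("Greenhouse-Geisser correction implemented for one within factor")
    eps <- gg_epsilon(d, dv, subject, within)
    out$epsilon <- NA_real_
    hit <- grepl(within, out$effect, fixed = TRUE)
    out$epsilon[hit] <- eps
    out$p[hit] <- pf(out$F[hit], out$df1[hit] * eps, out$df2[hit] * eps,
                     lower.tail = FALSE)
  }
  out
}

## Box/Greenhouse-Geisser epsilon from the double-centered covariance of
## the subject x level score matrix
gg_epsilon <- function(d, dv, subject, within) {
  M <- tapply(d[[dv]], list(d[[subject]], d[[within[1L]]]), mean)
  S <- stats::cov(M)
  k <- ncol(S)
  C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  tr <- sum(diag(C))
  eps <- tr^2 / ((k - 1) * sum(C^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' Planned pairwise comparison within a repeated-measures design
#'
#' Paired contrast between two levels of a within-subject factor,
#' optionally at fixed levels of other factors (e.g. Reward vs. No-Reward
#' within stage N3). The statistic is the squared paired t,
#' `F(1, n - 1) = t^2`, two-sided.
#'
#' @param data long-format data.frame.
#' @param dv,subject column names.
#' @param factor_name within factor containing the two levels.
#' @param levels character pair to compare (first minus second).
#' @param at optional named list fixing other columns,
#'   e.g. `list(stage = "N3")`.
#' @return list `F`, `df1`, `df2`, `p`, `mean_diff`, `n`.
#' @export
planned_comparison <- function(data, dv = "value", subject = "subject",
                               factor_name, levels, at = NULL) {
  stopifnot(length(levels) == 2L)
  d <- data
  for (nm in names(at)) d <- d[d[[nm]] == at[[nm]], , drop = FALSE]
  d <- d[d[[factor_name]] %in% levels, , drop = FALSE]
  a <- tapply(d[[dv]][d[[factor_name]] == levels[1L]],
              d[[subject]][d[[factor_name]] == levels[1L]], mean)
  b <- tapply(d[[dv]][d[[factor_name]] == levels[2L]],
              d[[subject]][d[[factor_name]] == levels[2L]], mean)
  common <- intersect(names(a), names(b))
  miss <- setdiff(unique(as.character(d[[subject]])), common)
  if (length(miss))
    stop("subject(s) missing a level: ", paste(miss, collapse = ", "))
  a <- a[common]; b <- b[common]
  n <- length(common)
  if (n < 2L) stop("need at least 2 subjects")
  diffs <- a - b
  if (sd(diffs) == 0) {
    return(list(F = 0, df1 = 1L, df2 = n - 1L, p = 1,
                mean_diff = mean(diffs), n = n))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(F = unname(tt$statistic)^2, df1 = 1L, df2 = n - 1L,
       p = tt$p.value, mean_diff = mean(diffs), n = n)
}

#' Spearman rank correlation with significance
#'
#' Rank correlation using midranks for ties. The two-sided p-value is
#' computed by exact permutation enumeration for n <= 7 and by the t
#' approximation (`t = rho * sqrt((n-2)/(1-rho^2))`) otherwise.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list `rho`, `p`, `n`, `defined`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7L) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(rho^2, 1 - 1e-12)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    rest <- seq_len(n)[-i]
    out[r + seq_len(rows), 1L] <- i
    out[r + seq_len(rows), -1L] <- matrix(rest[sub], rows)
    r <- r + rows
  }
  out
}

#' Fisher z-transform of a correlation
#'
#' `atanh(rho)` with `|rho|` clamped to `1 - 1e-7` so band or likelihood
#' correlations of exactly 1 remain finite for averaging and ANOVA.
#'
#' @param rho numeric vector of correlations.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(rho) {
  atanh(clamp(rho, -1 + 1e-7, 1 - 1e-7))
}
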