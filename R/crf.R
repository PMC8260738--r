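#' Standardize ROI time courses into a feature matrix
#'
#' Per-ROI z-scoring. When `stats` (a previous featurization) is supplied,
#' its training means/sds are reused — this is how sleep or held-out data
#' are projected into the training feature space. Zero-variance ROIs are
#' set to zero with a warning.
#'
#' @param ts numeric matrix, scans x ROIs.
#' @param stats optional `crf_features` object providing `center`/`scale`.
#' @param standardize set `FALSE` to pass features through untouched.
#' @return object of class `crf_features`: list with `values` (matrix),
#'   `center`, `scale`.
#' @export
featurize <- function(ts, stats = NULL, standardize = TRUE) {
  ts <- as.matrix(ts)
  if (!all(is.finite(ts))) stop("non-finite values in ROI time series")
  if (!standardize) {
    return(structure(list(values = ts, center = rep(0, ncol(ts)),
                          scale = rep(1, ncol(ts))), class = "crf_features"))
  }
  if (is.null(stats)) {
    center <- colMeans(ts)
    scale <- apply(ts, 2L, sd)
  } else {
    stopifnot(inherits(stats, "crf_features"))
    if (length(stats$center) != ncol(ts))
      stop("ROI count does not match the supplied training stats")
    center <- stats$center
    scale <- stats$scale
  }
  zero <- scale <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance ROI column(s) set to 0")
    scale[zero] <- 1
  }
  z <- sweep(sweep(ts, 2L, center), 2L, scale, "/")
  z[, zero] <- 0
  structure(list(values = z, center = center, scale = scale),
            class = "crf_features")
}

feature_values <- function(feats) {
  if (inherits(feats, "crf_features")) feats$values else as.matrix(feats)
}

#' Construct a linear-chain CRF model
#'
#' The model has transition weights `lambda` (S x S, weight on moving from
#' state i at scan t-1 to state j at scan t) and state weights `mu`
#' (S x (N+1): per-state linear weights over the N ROI features plus a bias
#' column). With `transitions_uniform = TRUE` (the configuration used for
#' sleep decoding, where the task's temporal structure is meaningless)
#' `lambda` is fixed at 0 and the chain factorizes over scans.
#'
#' @param states ordered character vector of state labels (the order defines
#'   Viterbi tie-breaking: lower index wins).
#' @param n_features number of ROI features N.
#' @param lambda,mu optional initial weights (default zeros).
#' @param transitions_uniform logical.
#' @param l2 ridge penalty strength used at fit time.
#' @return object of class `crf_model`.
#' @export
crf_model <- function(states, n_features, lambda = NULL, mu = NULL,
                      transitions_uniform = TRUE, l2 = 1e-3) {
  stopifnot(length(states) >= 2, n_features >= 1, l2 >= 0)
  S <- length(states)
  if (is.null(lambda)) lambda <- matrix(0, S, S)
  if (is.null(mu)) mu <- matrix(0, S, n_features + 1L)
  stopifnot(all(dim(lambda) == c(S, S)), all(dim(mu) == c(S, n_features + 1L)))
  if (transitions_uniform && any(lambda != lambda[1L]))
    stop("uniform transitions require constant lambda (canonically 0)")
  dimnames(lambda) <- list(states, states)
  rownames(mu) <- states
  structure(list(states = states, lambda = lambda, mu = mu,
                 transitions_uniform = transitions_uniform, l2 = l2,
                 train_stats = NULL, convergence = NULL),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("Linear-chain CRF:", length(x$states), "states,",
      ncol(x$mu) - 1L, "features;",
      if (x$transitions_uniform) "uniform transitions" else "free transitions",
      "\n")
  if (!is.null(x$convergence))
    cat("  fit:", x$convergence$iterations, "objective evaluations, final |grad| =",
        format(x$convergence$grad_norm, digits = 3), "\n")
  invisible(x)
}

## node potentials E[t, s] = mu_s . [x_t, 1]
node_scores <- function(model, feats) {
  X <- feature_values(feats)
  if (ncol(X) != ncol(model$mu) - 1L)
    stop("feature dimension does not match the model")
  cbind(X, 1) %*% t(model$mu)
}

#' Linear score of a labeled sequence
#'
#' Computes the inner product of the weight vector with the feature counts
#' of one `(x, y)` pair: the sum of transition weights along consecutive
#' label pairs (no transition term at t = 1) plus the sum of state scores
#' `mu_y_t . [x_t, 1]`. Exponentiating this score and normalizing by the
#' partition function gives the sequence's conditional probability.
#'
#' @param model a `crf_model`.
#' @param feats feature matrix or `crf_features`.
#' @param labels character labels, all valid model states (`"Excluded"`
#'   scans must be filtered out upstream).
#' @return scalar score.
#' @export
sequence_score <- function(model, feats, labels) {
  labels <- as.character(labels)
  if (any(labels == "Excluded"))
    stop("Excluded labels present; filter them before scoring")
  yi <- match(labels, model$states)
  if (anyNA(yi)) stop("labels outside model states")
  E <- node_scores(model, feats)
  if (nrow(E) != length(labels)) stop("labels/features length mismatch")
  s <- sum(E[cbind(seq_along(yi), yi)])
  if (length(yi) > 1L)
    s <- s + sum(model$lambda[cbind(yi[-length(yi)], yi[-1L])])
  s
}

#' Log-partition function of the chain
#'
#' `log Z(x)`, the log of the sum of exponentiated scores over all `S^T`
#' label sequences, computed by the forward recursion in log space.
#'
#' @inheritParams sequence_score
#' @return scalar `log Z`.
#' @export
log_partition <- function(model, feats) {
  E <- node_scores(model, feats)
  forward_backward(E, model$lambda, what = "logZ")$logZ
}

## forward-backward in log space. E: T x S node scores, lambda: S x S.
## what: "logZ" | "marginals" | "all" (adds summed pairwise marginals)
forward_backward <- function(E, lambda, what = "marginals") {
  T_ <- nrow(E); S <- ncol(E)
  uniform <- all(lambda == lambda[1L])
  if (uniform) {
    ## chain factorizes: add the constant transition mass analytically
    const <- lambda[1L]
    lse <- apply(E, 1L, logsumexp)
    logZ <- sum(lse) + (T_ - 1L) * (const + 0)  ## constant lambda shifts logZ
    ## note: with constant lambda=c, every sequence gains (T-1)c, cancelling
    ## in all marginals
    out <- list(logZ = logZ)
    if (what != "logZ") {
      P <- row_softmax(E)
      out$marginals <- P
      if (what == "all") {
        ## summed pairwise marginals: outer products of consecutive marginals
        pair <- matrix(0, S, S)
        if (T_ > 1L)
          pair <- crossprod(P[-T_, , drop = FALSE], P[-1L, , drop = FALSE])
        out$pairwise <- pair
      }
    }
    return(out)
  }
  la <- matrix(-Inf, T_, S)
  la[1L, ] <- E[1L, ]
  for (t in 2:T_) {
    for (j in seq_len(S)) la[t, j] <- E[t, j] + logsumexp(la[t - 1L, ] + lambda[, j])
  }
  logZ <- logsumexp(la[T_, ])
  out <- list(logZ = logZ)
  if (what != "logZ") {
    lb <- matrix(0, T_, S)
    for (t in seq(T_ - 1L, 1L)) {
      for (i in seq_len(S))
        lb[t, i] <- logsumexp(lambda[i, ] + E[t + 1L, ] + lb[t + 1L, ])
    }
    out$marginals <- exp(la + lb - logZ)
    if (what == "all") {
      pair <- matrix(0, S, S)
      if (T_ > 1L) {
        for (t in 2:T_) {
          lp <- outer(la[t - 1L, ], E[t, ] + lb[t, ], "+") + lambda - logZ
          pair <- pair + exp(lp)
        }
      }
      out$pairwise <- pair
    }
  }
  out
}

#' Penalized log-likelihood and gradient of a CRF on a training set
#'
#' The objective maximized at fit time:
#' `L = sum_k [score(x_k, y_k) - log Z(x_k)] - l2 * ||theta||^2 / 2`,
#' with gradient equal to empirical minus expected feature counts (expected
#' counts via forward-backward) minus `l2 * theta`.
#'
#' @param model a `crf_model`.
#' @param data list of sequences, each a list with `feats` (matrix or
#'   `crf_features`) and `labels` (character).
#' @param l2 ridge strength; defaults to the model's.
#' @return list with `value`, `grad_lambda` (S x S), `grad_mu` (S x (N+1)).
#' @export
log_likelihood <- function(model, data, l2 = model$l2) {
  stopifnot(length(data) >= 1)
  S <- length(model$states)
  grad_lambda <- matrix(0, S, S)
  grad_mu <- matrix(0, S, ncol(model$mu))
  value <- 0
  for (seq_k in data) {
    X <- feature_values(seq_k$feats)
    labels <- as.character(seq_k$labels)
    yi <- match(labels, model$states)
    if (anyNA(yi)) stop("labels outside model states")
    Z1 <- cbind(X, 1)
    E <- node_scores(model, X)
    fb <- forward_backward(E, model$lambda, what = "all")
    value <- value + sum(E[cbind(seq_along(yi), yi)]) - fb$logZ
    emp_pair <- matrix(0, S, S)
    if (length(yi) > 1L) {
      tab <- table(factor(yi[-length(yi)], levels = seq_len(S)),
                   factor(yi[-1L], levels = seq_len(S)))
      emp_pair <- matrix(as.numeric(tab), S, S)
      value <- value + sum(model$lambda * emp_pair)
    }
    grad_lambda <- grad_lambda + emp_pair - fb$pairwise
    Y <- matrix(0, nrow(Z1), S)
    Y[cbind(seq_along(yi), yi)] <- 1
    grad_mu <- grad_mu + t(Y - fb$marginals) %*% Z1
  }
  value <- value - l2 / 2 * (sum(model$lambda^2) + sum(model$mu^2))
  grad_lambda <- grad_lambda - l2 * model$lambda
  grad_mu <- grad_mu - l2 * model$mu
  if (model$transitions_uniform) grad_lambda[] <- 0
  list(value = value, grad_lambda = grad_lambda, grad_mu = grad_mu)
}

#' Fit a linear-chain CRF by penalized maximum likelihood
#'
#' Maximizes the (ridge-penalized) conditional log-likelihood by L-BFGS-B
#' with analytic gradients. With `transitions_uniform = TRUE` only the state
#' weights `mu` are estimated and the objective reduces to a multinomial
#' logistic regression over scans; the transition weights stay at 0.
#'
#' @param data list of training sequences (`feats`, `labels`); `"Excluded"`
#'   labels are dropped (sequences are split around them when transitions
#'   are free, so no spurious transition spans a gap).
#' @param states state labels; default: sorted union of observed labels.
#' @param transitions_uniform fix transitions constant (default TRUE).
#' @param l2 ridge strength (default 1e-3).
#' @param maxit maximum optimizer iterations (default 500).
#' @param tol gradient max-norm declared converged (default 1e-5).
#' @param train_stats optional `crf_features` recording the standardization
#'   used, stored on the model for later decoding.
#' @return fitted `crf_model` with a `convergence` diagnostic.
#' @export
fit_crf <- function(data, states = NULL, transitions_uniform = TRUE,
                    l2 = 1e-3, maxit = 500L, tol = 1e-5,
                    train_stats = NULL) {
  data <- lapply(data, function(s) {
    list(feats = feature_values(s$feats), labels = as.character(s$labels))
  })
  data <- unlist(lapply(data, split_excluded), recursive = FALSE)
  if (!length(data)) stop("no usable training scans")
  obs <- sort(unique(unlist(lapply(data, `[[`, "labels"))))
  if (is.null(states)) states <- obs
  missing_states <- setdiff(states, obs)
  if (length(missing_states))
    stop("training data missing state(s): ",
         paste(missing_states, collapse = ", "))
  S <- length(states)
  N <- ncol(data[[1L]]$feats)
  model <- crf_model(states, N, transitions_uniform = transitions_uniform,
                     l2 = l2)
  n_mu <- S * (N + 1L)

  unpack <- function(theta) {
    m <- model
    if (!transitions_uniform) {
      m$lambda <- matrix(theta[seq_len(S * S)], S, S,
                         dimnames = dimnames(model$lambda))
      theta <- theta[-seq_len(S * S)]
    }
    m$mu <- matrix(theta, S, N + 1L, dimnames = dimnames(model$mu))
    m
  }
  evals <- 0L
  if (transitions_uniform) {
    ## fast pooled path: i.i.d. multinomial logistic objective
    Z1 <- do.call(rbind, lapply(data, function(s) cbind(s$feats, 1)))
    yi <- match(unlist(lapply(data, `[[`, "labels")), states)
    Y <- matrix(0, nrow(Z1), S)
    Y[cbind(seq_along(yi), yi)] <- 1
    tYZ <- crossprod(Y, Z1)
    fn <- function(theta) {
      evals <<- evals + 1L
      mu <- matrix(theta, S, N + 1L)
      E <- Z1 %*% t(mu)
      m <- apply(E, 1L, max)
      -(sum(E * Y) - sum(m + log(rowSums(exp(E - m)))) - l2 / 2 * sum(mu^2))
    }
    gr <- function(theta) {
      mu <- matrix(theta, S, N + 1L)
      P <- row_softmax(Z1 %*% t(mu))
      -(as.numeric(tYZ - crossprod(P, Z1)) - l2 * as.numeric(mu))
    }
    theta0 <- numeric(n_mu)
  } else {
    fn <- function(theta) {
      evals <<- evals + 1L
      -log_likelihood(unpack(theta), data, l2)$value
    }
    gr <- function(theta) {
      g <- log_likelihood(unpack(theta), data, l2)
      -c(as.numeric(g$grad_lambda), as.numeric(g$grad_mu))
    }
    theta0 <- numeric(S * S + n_mu)
  }
  opt <- optim(theta0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = tol, factr = 1e7))
  fitted <- unpack(opt$par)
  gfin <- max(abs(gr(opt$par)))
  fitted$convergence <- list(objective = -opt$value, iterations = evals,
                             grad_norm = gfin, optim_code = opt$convergence)
  if (opt$convergence != 0 && gfin > max(tol, 1e-3) * (1 + abs(opt$value)))
    stop(structure(class = c("crf_fit_error", "error", "condition"),
                   list(message = paste0("CRF fit did not converge (optim code ",
                                         opt$convergence, ", |grad| = ",
                                         format(gfin, digits = 4), ")"),
                        call = sys.call(-1), model = fitted)))
  fitted$train_stats <- train_stats
  fitted
}

## split one sequence into chains at Excluded scans
split_excluded <- function(s) {
  keep <- s$labels != "Excluded"
  if (all(keep)) return(list(s))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    out[[length(out) + 1L]] <- list(feats = s$feats[idx, , drop = FALSE],
                                    labels = s$labels[idx])
  }
  out
}

#' Posterior per-scan state marginals
#'
#' `p(y_t = s | x)` for every scan, via forward-backward. These are the
#' continuous 0-1 "brain-state likelihoods" reported per fMRI volume. With
#' uniform transitions they equal the per-scan softmax of the state scores.
#'
#' @inheritParams sequence_score
#' @return matrix scans x states (class `state_lik`), rows summing to 1.
#' @export
posterior_marginals <- function(model, feats) {
  E <- node_scores(model, feats)
  P <- forward_backward(E, model$lambda, what = "marginals")$marginals
  colnames(P) <- model$states
  class(P) <- c("state_lik", class(P))
  P
}

#' Most probable state sequence (Viterbi)
#'
#' Max-product dynamic programming over the chain; exact ties are broken
#' toward the lower state index. With uniform transitions the path equals
#' the per-scan argmax of the state scores.
#'
#' @inheritParams sequence_score
#' @return character vector of decoded states.
#' @export
viterbi_decode <- function(model, feats) {
  E <- node_scores(model, feats)
  S <- ncol(E); T_ <- nrow(E)
  if (all(model$lambda == model$lambda[1L])) {
    return(model$states[max.col(E, ties.method = "first")])
  }
  delta <- E[1L, ]
  back <- matrix(1L, T_, S)
  for (t in 2:T_) {
    prev <- delta + model$lambda  ## S x S: prev state i -> cand j
    best <- apply(prev, 2L, which.max)  ## which.max: first (lowest) index on ties
    delta <- prev[cbind(best, seq_len(S))] + E[t, ]
    back[t, ] <- best
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  for (t in seq(T_ - 1L, 1L)) path[t] <- back[t + 1L, path[t + 1L]]
  model$states[path]
}

#' Leave-one-subject-out cross-validation of the game-state classifier
#'
#' For each subject, a CRF is trained on all other subjects' game sessions
#' and the held-out subject's scans are Viterbi-decoded (`"Excluded"` scans
#' dropped). Confusion is pooled over folds.
#'
#' @param cohort list of subjects, each a list with `roits` (scans x ROIs)
#'   and `labels`; optionally `id`.
#' @param states state set (default the five game states).
#' @param transitions_uniform,l2,maxit passed to [fit_crf()].
#' @param standardize z-score features with training-fold stats.
#' @return object of class `crf_cv`: `confusion` (true x predicted),
#'   `per_state_accuracy` (recall), `n_folds`.
#' @export
cross_validate <- function(cohort, states = GAME_STATES,
                           transitions_uniform = TRUE, l2 = 1e-3,
                           maxit = 500L, standardize = TRUE) {
  n <- length(cohort)
  if (n < 2L) stop("cross-validation needs at least 2 subjects")
  S <- length(states)
  conf <- matrix(0L, S, S, dimnames = list(true = states, predicted = states))
  for (k in seq_len(n)) {
    train <- cohort[-k]
    pooled <- do.call(rbind, lapply(train, function(s) as.matrix(s$roits)))
    tr_stats <- featurize(pooled, standardize = standardize)
    data_k <- lapply(train, function(s) {
      list(feats = featurize(as.matrix(s$roits), tr_stats,
                             standardize = standardize)$values,
           labels = as.character(s$labels))
    })
    obs <- unique(unlist(lapply(data_k, function(s)
      setdiff(s$labels, "Excluded"))))
    if (!all(states %in% obs)) {
      id <- if (!is.null(cohort[[k]]$id)) cohort[[k]]$id else k
      stop("fold holding out subject ", id, " lacks training state(s): ",
           paste(setdiff(states, obs), collapse = ", "))
    }
    model <- fit_crf(data_k, states = states,
                     transitions_uniform = transitions_uniform, l2 = l2,
                     maxit = maxit, train_stats = tr_stats)
    te <- cohort[[k]]
    keep <- as.character(te$labels) != "Excluded"
    fe <- featurize(as.matrix(te$roits), tr_stats,
                    standardize = standardize)$values
    pred <- viterbi_decode(model, fe[keep, , drop = FALSE])
    truth <- as.character(te$labels)[keep]
    conf <- conf + table(factor(truth, states), factor(pred, states))
  }
  acc <- diag(conf) / pmax(rowSums(conf), 1L)
  structure(list(confusion = conf, per_state_accuracy = acc, n_folds = n),
            class = "crf_cv")
}

#' @export
print.crf_cv <- function(x, ...) {
  cat("Leave-one-subject-out cross-validation over", x$n_folds, "folds\n")
  print(x$confusion)
  cat("per-state accuracy:\n")
  print(round(x$per_state_accuracy, 3))
  invisible(x)
}

#' Serialize / restore a CRF model as JSON
#'
#' @param model fitted `crf_model`.
#' @param path file path.
#' @export
save_crf_model <- function(model, path) {
  obj <- list(states = model$states, lambda = model$lambda, mu = model$mu,
              transitions_uniform = model$transitions_uniform, l2 = model$l2,
              train_center = model$train_stats$center,
              train_scale = model$train_stats$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_crf_model
#' @param path file path.
#' @export
load_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- crf_model(obj$states, ncol(obj$mu) - 1L,
                 lambda = matrix(as.numeric(obj$lambda), length(obj$states)),
                 mu = matrix(as.numeric(obj$mu), length(obj$states)),
                 transitions_uniform = obj$transitions_uniform, l2 = obj$l2)
  if (!is.null(obj$train_center))
    m$train_stats <- structure(list(values = NULL, center = obj$train_center,
                                    scale = obj$train_scale),
                               class = "crf_features")
  m
}
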