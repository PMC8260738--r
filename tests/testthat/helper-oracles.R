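# Independent oracles used across tests.

## brute-force chain quantities by enumeration over all S^T sequences,
## built only on sequence_score (itself checked by hand arithmetic)
brute_chain <- function(model, feats) {
  S <- length(model$states)
  T_ <- nrow(as.matrix(if (inherits(feats, "crf_features")) feats$values else feats))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  scores <- apply(seqs, 1L, function(y)
    sequence_score(model, feats, model$states[y]))
  logZ <- {
    m <- max(scores)
    m + log(sum(exp(scores - m)))
  }
  post <- exp(scores - logZ)
  marg <- matrix(0, T_, S)
  for (t in seq_len(T_)) for (s in seq_len(S))
    marg[t, s] <- sum(post[seqs[, t] == s])
  ## lexicographically-first argmax (state 1 smallest)
  best <- which(scores == max(scores))
  best <- best[order(apply(seqs[best, , drop = FALSE], 1L, paste,
                           collapse = ""))][1L]
  list(logZ = logZ, marginals = marg, viterbi = model$states[seqs[best, ]])
}

random_crf_instance <- function(T_, S, N, scale = 0.7) {
  m <- crf_model(LETTERS[seq_len(S)], N, transitions_uniform = FALSE)
  m$lambda <- matrix(rnorm(S * S, 0, scale), S, S,
                     dimnames = dimnames(m$lambda))
  m$mu <- matrix(rnorm(S * (N + 1), 0, scale), S, N + 1,
                 dimnames = dimnames(m$mu))
  list(model = m, feats = matrix(rnorm(T_ * N), T_, N))
}

## small noiseless two-subject cohort for classifier tests
tiny_cohort <- function(n_subjects = 2, n_roi = 8, n_blocks = 2,
                        noise_sd = 0, seed = 11) {
  pat <- default_state_patterns(n_roi = n_roi, seed = seed)
  lapply(seq_len(n_subjects), function(i) {
    d <- build_game_schedule(n_game_blocks_per_type = n_blocks,
                             won_game = "face", seed = seed + i)
    g <- simulate_game_session(d, pat, noise_sd = noise_sd, seed = seed + i)
    list(roits = g$roits, labels = g$labels, id = paste0("S", i))
  })
}

## direct sums-of-squares oracle for a balanced two-way within design
## (subject x A x B, one observation per cell)
rm_anova_oracle_2w <- function(d, dv, subject, A, B) {
  y <- d[[dv]]
  s <- factor(d[[subject]]); a <- factor(d[[A]]); b <- factor(d[[B]])
  n <- nlevels(s); ka <- nlevels(a); kb <- nlevels(b)
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_sa <- tapply(y, list(s, a), mean); m_sb <- tapply(y, list(s, b), mean)
  m_ab <- tapply(y, list(a, b), mean)
  ss_total <- sum((y - gm)^2)
  ss_s <- ka * kb * sum((m_s - gm)^2)
  ss_a <- n * kb * sum((m_a - gm)^2)
  ss_b <- n * ka * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_sa <- kb * sum((m_sa - outer(m_s - gm, m_a - gm, "+") - gm)^2)
  ss_sb <- ka * sum((m_sb - outer(m_s - gm, m_b - gm, "+") - gm)^2)
  ss_res <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_sa - ss_sb
  F_a <- (ss_a / (ka - 1)) / (ss_sa / ((n - 1) * (ka - 1)))
  F_b <- (ss_b / (kb - 1)) / (ss_sb / ((n - 1) * (kb - 1)))
  F_ab <- (ss_ab / ((ka - 1) * (kb - 1))) /
    (ss_res / ((n - 1) * (ka - 1) * (kb - 1)))
  list(F_a = F_a, F_b = F_b, F_ab = F_ab)
}
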