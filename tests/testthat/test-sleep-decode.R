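test_that("decoding validates the ROI space and normalizes rows", {
  cohort <- tiny_cohort(2, noise_sd = 0.5)
  pooled <- rbind(cohort[[1]]$roits, cohort[[2]]$roits)
  st <- featurize(pooled)
  m <- fit_crf(lapply(cohort, function(s)
    list(feats = featurize(s$roits, st)$values, labels = s$labels)),
    states = GAME_STATES, train_stats = st)
  lik <- decode_sleep(m, cohort[[1]]$roits)
  expect_true(all(abs(rowSums(lik) - 1) < 1e-9))
  expect_error(decode_sleep(m, cohort[[1]]$roits[, 1:3]), "ROI mismatch")
  ## a model with zero weights is indifferent: every state at 1/5
  m0 <- crf_model(GAME_STATES, ncol(cohort[[1]]$roits))
  m0$train_stats <- st
  lik0 <- decode_sleep(m0, cohort[[1]]$roits)
  expect_true(all(abs(lik0 - 0.2) < 1e-12))
})

test_that("replaying a training block through the decoder recovers its state", {
  cohort <- tiny_cohort(2, noise_sd = 0)
  pooled <- rbind(cohort[[1]]$roits, cohort[[2]]$roits)
  st <- featurize(pooled)
  m <- fit_crf(lapply(cohort, function(s)
    list(feats = featurize(s$roits, st)$values, labels = s$labels)),
    states = GAME_STATES, train_stats = st)
  lik <- decode_sleep(m, cohort[[1]]$roits)
  lab <- as.character(cohort[[1]]$labels)
  ## block-interior Face scans (skip HRF rise: 5 scans in)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  interior <- unlist(lapply(which(runs$values == "Face"), function(i)
    seq(starts[i] + 5, ends[i])))
  expect_true(mean(max.col(unclass(lik)[interior, ]) ==
                     which(GAME_STATES == "Face")) > 0.95)
})

test_that("stage aggregation averages the right scans and flags gaps", {
  hyp <- structure(list(epochs = c("W", "N3", "N3"), epoch_len = 20),
                   class = "hypnogram")
  ## tr = 10 s: scans 1-2 in W, 3-6 in N3
  lik <- matrix(0.2, 6, 5, dimnames = list(NULL, GAME_STATES))
  face <- c(0.5, 0.7, 0.5, 0.7)
  lik[3:6, ] <- cbind(face, (1 - face) / 4, (1 - face) / 4,
                      (1 - face) / 4, (1 - face) / 4)
  tab <- stage_mean_likelihood(lik, hyp, reward_mapping("face"), tr = 10)
  n3_r <- tab$mean_likelihood[tab$stage == "N3" & tab$state == "Reward"]
  expect_equal(n3_r, 0.6)
  w_rows <- tab[tab$stage == "W", ]
  expect_true(all(abs(w_rows$mean_likelihood - 0.2) < 1e-12))
  ## absent stages are missing, not zero
  n1 <- tab[tab$stage == "N1", ]
  expect_true(all(is.na(n1$mean_likelihood)))
  expect_true(all(n1$n_scans == 0))
  ## per-stage means still sum to one across states
  for (stg in c("W", "N3"))
    expect_equal(sum(tab$mean_likelihood[tab$stage == stg]), 1,
                 tolerance = 1e-9)
  ## scan past the hypnogram end errors
  expect_error(stage_mean_likelihood(rbind(lik, lik), hyp,
                                     reward_mapping("face"), tr = 10),
               "beyond")
})

test_that("stage aggregation ignores scan order within a stage", {
  hyp <- structure(list(epochs = rep("N2", 5), epoch_len = 20),
                   class = "hypnogram")
  set.seed(20)
  lik <- matrix(runif(50), 10, 5, dimnames = list(NULL, GAME_STATES))
  lik <- lik / rowSums(lik)
  t1 <- stage_mean_likelihood(lik, hyp, reward_mapping("face"), tr = 10)
  t2 <- stage_mean_likelihood(lik[sample(10), ], hyp,
                              reward_mapping("face"), tr = 10)
  expect_equal(t1$mean_likelihood, t2$mean_likelihood, tolerance = 1e-12)
})

test_that("band correlations respect rank invariance and tie handling", {
  set.seed(21)
  delta <- cumsum(rnorm(60))
  lik <- cbind(Reward = exp(delta / 3),  # monotone transform of delta
               NoReward = runif(60), Rest = runif(60))
  lik <- lik / rowSums(lik)
  ## renormalization can break monotonicity; rebuild the column
  lik[, "Reward"] <- rank(delta)
  bands <- cbind(low_delta = delta, beta = rnorm(60))
  out <- likelihood_band_correlation(lik, bands)
  expect_equal(out$rho[out$state == "Reward" & out$band == "low_delta"], 1)
  expect_equal(out$z[out$state == "Reward" & out$band == "low_delta"],
               atanh(1 - 1e-7))
  ## ties: midrank Spearman must match cor.test's estimate
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 9)
  out2 <- likelihood_band_correlation(cbind(S = x), cbind(B = y))
  expect_equal(out2$rho,
               unname(suppressWarnings(
                 stats::cor.test(x, y, method = "spearman")$estimate)))
  expect_error(likelihood_band_correlation(cbind(S = 1:5), cbind(B = 1:5)),
               ">= 10")
})

test_that("seed-region correlations isolate the driving state", {
  set.seed(22)
  lik <- matrix(runif(3000), 600, 5, dimnames = list(NULL, MAPPED_STATES))
  lik <- lik / rowSums(lik)
  rho <- roi_state_correlation(3 * lik[, "Reward"] + 1, lik)
  expect_equal(unname(rho["Reward"]), 1, tolerance = 1e-12)
  ## independent noise seed decorrelates at long T
  noise <- rnorm(600)
  rho2 <- roi_state_correlation(noise, lik)
  expect_true(all(abs(rho2) < 0.15))
  flat <- roi_state_correlation(rep(1, 600), lik)
  expect_true(all(is.na(flat)))
})

test_that("likelihood regression recovers betas and matches normal equations", {
  ## orthogonal design: distinct indicators plus an all-off block so the
  ## regressors are not collinear with the intercept
  lik <- cbind(Face = rep(c(1, 0, 0, 0), each = 4),
               Maze = rep(c(0, 1, 0, 0), each = 4),
               Rest = rep(c(0, 0, 1, 0), each = 4))
  ts <- cbind(r1 = lik[, "Face"], r2 = 0.5 * lik[, "Rest"])
  out <- likelihood_regression(ts, lik)
  expect_equal(out$beta_Face, c(1, 0), tolerance = 1e-10)
  expect_equal(out$beta_Rest, c(0, 0.5), tolerance = 1e-10)
  ## toy 6-scan problem vs explicit normal-equations oracle
  set.seed(23)
  lik6 <- matrix(runif(18), 6, 3, dimnames = list(NULL, c("Face", "Maze", "Rest")))
  y6 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(1, lik6)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y6)
  out6 <- likelihood_regression(y6, lik6)
  expect_equal(unname(as.matrix(out6[, c("beta_Face", "beta_Maze", "beta_Rest")])),
               unname(t(beta_oracle[2:4, ])), tolerance = 1e-10)
  ## rank-deficient design is refused
  lik_bad <- cbind(Face = lik6[, 1], Maze = lik6[, 1], Rest = lik6[, 3])
  expect_error(likelihood_regression(y6, lik_bad), "rank-deficient")
})

test_that("a pure-noise ROI keeps its contrast t within sanity bounds", {
  set.seed(24)
  lik <- matrix(runif(6000), 2000, 3,
                dimnames = list(NULL, c("Face", "Maze", "Rest")))
  y <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "noise"))
  out <- likelihood_regression(y, lik)
  expect_lt(abs(out$t), 4)
})

test_that("conjunction is plain set intersection over the ROI universe", {
  expect_setequal(conjunction(c("A", "B", "C"), c("B", "C", "D")), c("B", "C"))
  expect_identical(conjunction(c("A"), c("B")), character(0))
  expect_setequal(conjunction(c("A", "B"), c("A", "B")), c("A", "B"))
})
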