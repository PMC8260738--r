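test_that("noiseless game session equals the convolved design times patterns", {
  pat <- default_state_patterns(n_roi = 6, seed = 4)
  d <- build_game_schedule(n_game_blocks_per_type = 2, seed = 4)
  g <- simulate_game_session(d, pat, noise_sd = 0, seed = 1)
  ## independent reconstruction: state boxcars from block membership,
  ## convolved with the same kernel
  lab <- labels_from_schedule(d)
  onsets <- attr(lab, "onsets")
  raw <- vapply(onsets, function(t0) {
    hit <- which(t0 >= d$blocks$onset - 1e-9 &
                   t0 < d$blocks$onset + d$blocks$duration - 1e-9)
    if (length(hit)) d$blocks$state[hit[1L]] else "Rest"
  }, "")
  h <- canonical_hrf(d$tr)
  expected <- 0 * g$roits
  for (s in rownames(pat)) {
    x <- as.numeric(raw == s)
    xc <- convolve(c(x, numeric(length(h))), rev(h), type = "open")[seq_along(x)]
    expected <- expected + outer(xc, pat[s, ])
  }
  expect_equal(unname(g$roits), unname(expected), tolerance = 1e-10)
  ## at study scale (8 blocks, unit noise) each game ROI tracks its
  ## dominant convolved regressor
  d8 <- build_game_schedule(seed = 4)
  lab8 <- labels_from_schedule(d8)
  onsets8 <- attr(lab8, "onsets")
  raw8 <- vapply(onsets8, function(t0) {
    hit <- which(t0 >= d8$blocks$onset - 1e-9 &
                   t0 < d8$blocks$onset + d8$blocks$duration - 1e-9)
    if (length(hit)) d8$blocks$state[hit[1L]] else "Rest"
  }, "")
  fc <- convolve(c(as.numeric(raw8 == "Face"), numeric(length(h))), rev(h),
                 type = "open")[seq_along(raw8)]
  best_roi <- which.max(abs(pat["Face", ]))
  g2 <- simulate_game_session(d8, pat, noise_sd = 1, seed = 2)
  expect_gt(abs(cor(g2$roits[, best_roi], fc)), 0.5)
})

test_that("game simulation is deterministic under the seed", {
  pat <- default_state_patterns(n_roi = 5, seed = 1)
  d <- build_game_schedule(n_game_blocks_per_type = 2, seed = 1)
  g1 <- simulate_game_session(d, pat, seed = 9)
  g2 <- simulate_game_session(d, pat, seed = 9)
  expect_identical(g1$roits, g2$roits)
})

test_that("hypnogram has 3 epochs per minute and honors an absorbing chain", {
  h <- simulate_hypnogram(100, min_n3_min = 10, seed = 1)
  expect_length(h$epochs, 300L)
  expect_identical(h$epoch_len, 20)
  ident <- diag(4)
  dimnames(ident) <- dimnames(default_stage_chain())
  h3 <- simulate_hypnogram(10, stage_chain = ident, min_n3_min = 10,
                           require_all_stages = FALSE, start_stage = "N3",
                           seed = 1)
  expect_true(all(h3$epochs == "N3"))
})

test_that("long-run stage proportions match the chain's stationary law", {
  P <- default_stage_chain()
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  h <- simulate_hypnogram(4000, min_n3_min = 0, require_all_stages = FALSE,
                          seed = 3)
  prop <- table(factor(h$epochs, colnames(P))) / length(h$epochs)
  expect_true(all(abs(as.numeric(prop) - stat) < 0.05))
})

test_that("hypnogram generation errors when the N3 demand is unreachable", {
  wake_only <- diag(4)
  dimnames(wake_only) <- dimnames(default_stage_chain())
  expect_error(simulate_hypnogram(10, stage_chain = wake_only,
                                  min_n3_min = 5, start_stage = "W",
                                  max_retries = 5, seed = 1),
               "generation error")
})

test_that("sleep session embeds events only in N3 and is seed-deterministic", {
  pat <- default_state_patterns(n_roi = 6, seed = 2)
  hyp <- simulate_hypnogram(30, min_n3_min = 8, seed = 2)
  s1 <- simulate_sleep_session(hyp, pat, seed = 5)
  s2 <- simulate_sleep_session(hyp, pat, seed = 5)
  expect_identical(s1$roits, s2$roits)
  expect_identical(s1$truth, s2$truth)
  stage <- hyp$epochs[floor((seq_len(nrow(s1$roits)) - 1) * s1$tr / 20) + 1]
  expect_true(all(stage[s1$truth$event_scans] == "N3"))
  ## noiseless limit: event scans carry strictly more Reward-pattern energy
  s0 <- simulate_sleep_session(hyp, pat, noise_sd = 0, band_noise_sd = 0,
                               seed = 5)
  proj <- as.numeric(s0$roits %*% pat["Face", ])
  ev <- s0$truth$event_scans
  n3_other <- setdiff(which(stage == "N3"), outer(ev, 0:8, "+"))
  near_peak <- pmin(ev + 2, nrow(s0$roits))
  expect_gt(min(proj[near_peak]), max(proj[n3_other]))
})

test_that("react_amp = 0 produces an eventless session", {
  pat <- default_state_patterns(n_roi = 4, seed = 2)
  hyp <- simulate_hypnogram(20, min_n3_min = 5, seed = 4)
  s <- simulate_sleep_session(hyp, pat, react_amp = 0, seed = 1)
  expect_length(s$truth$event_scans, 0L)
})

test_that("memory records decouple from strength when coupling is zero", {
  strengths <- rlnorm(200, log(6), 0.4)
  recs <- lapply(seq_along(strengths), function(i)
    simulate_memory(strengths[i], coupling = 0, seed = i))
  scores <- vapply(recs, `[[`, 0, "face_score")
  rho <- cor(strengths, scores, method = "spearman")
  expect_lt(abs(rho), 0.15)
})

test_that("memory is a monotone map of strength in the noiseless limit", {
  strengths <- 0:7   # within the unclamped range of both latent scores
  recs <- lapply(strengths, function(s)
    simulate_memory(s, coupling = 1, noise_sd = 0, seed = 99))
  scores <- vapply(recs, `[[`, 0, "face_score")
  dists <- vapply(recs, `[[`, 0, "maze_distance")
  expect_equal(cor(strengths, scores, method = "spearman"), 1)
  expect_equal(cor(strengths, -dists, method = "spearman"), 1)
  r1 <- simulate_memory(3, seed = 42)
  r2 <- simulate_memory(3, seed = 42)
  expect_identical(r1, r2)
})

test_that("cohorts are complete, balanced in won game, and byte-stable", {
  cfg <- modifyList(default_config(), list(
    n_rois = 8, design = list(n_blocks = 2),
    sleep = list(total_min = 20, min_n3_min = 4)))
  co <- simulate_cohort(4, cfg, seed = 13)
  expect_length(co$subjects, 4L)
  won <- vapply(co$subjects, `[[`, "", "won_game")
  expect_setequal(unique(won), c("face", "maze"))
  for (s in co$subjects) {
    expect_false(is.null(s$game$roits))
    expect_false(is.null(s$sleep$roits))
    expect_false(is.null(s$record))
    expect_equal(length(s$sleep$truth$event_scans) > 0,
                 s$sleep$truth$amplitude > 0)
  }
  co2 <- simulate_cohort(4, cfg, seed = 13)
  expect_identical(co$subjects, co2$subjects)
  ## game-session-only cohort (classifier-training population)
  co18 <- simulate_cohort(3, cfg, seed = 1, include_sleep = FALSE)
  expect_null(co18$subjects[[1]]$sleep)
})
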