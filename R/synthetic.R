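#' Default per-state ROI activation patterns
#'
#' Draws an S x N matrix of state-specific BOLD activation amplitudes for
#' the five game states. Face and Maze rows are independent Gaussian
#' patterns of amplitude `amp_game` (emulating distinct task-selective
#' networks, e.g. FFA/OFA vs. PPA); the two pre-cue rows are weak patterns
#' of amplitude `amp_pre` (a 3-s instruction screen elicits little
#' state-specific BOLD, which is why pre states end up confused with Rest);
#' the Rest row is zero by convention.
#'
#' @param n_roi number of ROIs (default 58).
#' @param amp_game,amp_pre pattern standard deviations (defaults 1.0, 0.2).
#' @param seed integer seed.
#' @return matrix with rows Face, Maze, Rest, PreFace, PreMaze.
#' @export
default_state_patterns <- function(n_roi = 58, amp_game = 1, amp_pre = 0.2,
                                   seed = 1) {
  set.seed(seed)
  W <- rbind(
    Face = rnorm(n_roi, 0, amp_game),
    Maze = rnorm(n_roi, 0, amp_game),
    Rest = rep(0, n_roi),
    PreFace = rnorm(n_roi, 0, amp_pre),
    PreMaze = rnorm(n_roi, 0, amp_pre))
  colnames(W) <- sprintf("ROI%02d", seq_len(n_roi))
  W
}

#' Simulate a game-session ROI time series
#'
#' State boxcars (one column per state, 1 while a block of that state is
#' on) are convolved with the canonical HRF and mixed through the state
#' patterns; stationary AR(1) Gaussian noise is added per ROI. The win
#' block contributes signal like any other block of its game, but its scans
#' (and its trailing rest) are labeled `"Excluded"`.
#'
#' @param design an `experiment_design` from [build_game_schedule()].
#' @param patterns S x N state-pattern matrix (rows named by state).
#' @param noise_sd marginal noise standard deviation (default 1).
#' @param ar1 AR(1) coefficient in `[0, 1)` (default 0.3).
#' @param seed integer seed.
#' @return list with `roits` (scans x ROIs), `labels`, `design`, `tr`.
#' @export
simulate_game_session <- function(design, patterns, noise_sd = 1, ar1 = 0.3,
                                  seed = 1) {
  stopifnot(ncol(patterns) >= 2, noise_sd >= 0)
  labels <- labels_from_schedule(design)
  onsets <- attr(labels, "onsets")
  states <- rownames(patterns)
  ## boxcar per state from true block identity (exclusion is a label, not
  ## a physiological gap)
  raw <- vapply(seq_along(onsets), function(i) {
    b <- design$blocks
    hit <- which(onsets[i] >= b$onset - 1e-9 &
                   onsets[i] < b$onset + b$duration - 1e-9)
    if (length(hit)) b$state[hit[1L]] else "Rest"
  }, "")
  U <- vapply(states, function(s) as.numeric(raw == s), numeric(length(raw)))
  h <- canonical_hrf(design$tr)
  X <- convolve_columns(U, h)
  set.seed(seed)
  signal <- X %*% patterns[states, , drop = FALSE]
  roits <- signal + ar1_noise(nrow(signal), ncol(signal), noise_sd, ar1)
  colnames(roits) <- colnames(patterns)
  list(roits = roits, labels = labels, design = design, tr = design$tr)
}

#' Default sleep-stage transition matrix
#'
#' Epoch-to-epoch (20 s) Markov transition probabilities over W, N1, N2,
#' N3, tuned to descend through light sleep into sustained N3 over a
#' 1-2 h scanner session (no REM: none was reached in the scanner).
#'
#' @return 4 x 4 row-stochastic matrix.
#' @export
default_stage_chain <- function() {
  m <- matrix(c(
    0.90, 0.10, 0.00, 0.00,
    0.04, 0.80, 0.16, 0.00,
    0.00, 0.04, 0.86, 0.10,
    0.00, 0.00, 0.08, 0.92), 4, 4, byrow = TRUE,
    dimnames = list(SLEEP_STAGES, SLEEP_STAGES))
  m
}

#' Simulate a scored hypnogram
#'
#' Samples a Markov chain of 20-s epochs starting from wake and resamples
#' (bounded retries) until the cumulative N3 duration reaches
#' `min_n3_min` minutes and, by default, all four stages occur — mirroring
#' inclusion of subjects with sustained N3.
#'
#' @param total_min recording length in minutes.
#' @param stage_chain 4 x 4 row-stochastic transition matrix.
#' @param min_n3_min minimum total N3 minutes (default 10).
#' @param require_all_stages demand at least one epoch of each stage.
#' @param start_stage initial stage (default `"W"`: subjects fall asleep).
#' @param max_retries resampling bound (default 100).
#' @param seed integer seed.
#' @return object of class `hypnogram`: list with `epochs` (character) and
#'   `epoch_len` (20).
#' @export
simulate_hypnogram <- function(total_min, stage_chain = default_stage_chain(),
                               min_n3_min = 10, require_all_stages = TRUE,
                               start_stage = "W", max_retries = 100L,
                               seed = 1) {
  stopifnot(total_min > 0, start_stage %in% SLEEP_STAGES)
  if (any(abs(rowSums(stage_chain) - 1) > 1e-8))
    stop("stage_chain rows must sum to 1")
  n_epochs <- round(total_min * 60 / 20)
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    ep <- character(n_epochs)
    s <- match(start_stage, SLEEP_STAGES)
    for (i in seq_len(n_epochs)) {
      ep[i] <- SLEEP_STAGES[s]
      s <- sample.int(4L, 1L, prob = stage_chain[s, ])
    }
    n3_min <- sum(ep == "N3") * 20 / 60
    ok <- n3_min >= min_n3_min &&
      (!require_all_stages || all(SLEEP_STAGES %in% ep))
    if (ok)
      return(structure(list(epochs = ep, epoch_len = 20),
                       class = "hypnogram"))
  }
  stop("generation error: no hypnogram with ", min_n3_min,
       " min of N3 in ", max_retries, " retries")
}

#' EEG band definitions
#'
#' The six analysis bands: low delta 1-2, high delta 2-4, theta 4-7,
#' alpha 8-10, sigma 12-14, beta 15-25 Hz.
#'
#' @return data.frame with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("low_delta", "high_delta", "theta", "alpha", "sigma", "beta"),
    lo = c(1, 2, 4, 8, 12, 15),
    hi = c(2, 4, 7, 10, 14, 25))
}

## mean log10 band power per stage (bands x stages); low delta rises into
## N3 (slow-wave activity), sigma peaks in N2 (spindles), alpha/beta in wake
band_stage_means <- function() {
  m <- rbind(
    low_delta = c(0.0, 0.2, 0.5, 0.9),
    high_delta = c(0.0, 0.1, 0.3, 0.5),
    theta = c(0.2, 0.3, 0.2, 0.1),
    alpha = c(0.5, 0.2, 0.1, 0.0),
    sigma = c(0.0, 0.3, 0.5, 0.2),
    beta = c(0.5, 0.2, 0.0, -0.2))
  colnames(m) <- SLEEP_STAGES
  m
}

#' Simulate a sleep session with embedded reactivation events
#'
#' Generates (i) ROI BOLD as AR(1) noise plus, at Poisson-sampled N3 scans,
#' the Reward game's activation pattern convolved with the HRF; (ii) six
#' log10 band-power series on a 2-s grid with stage-dependent levels, the
#' low-delta series additionally elevated around reactivation events in
#' proportion to `delta_coupling`; (iii) hippocampus and VTA seed channels
#' receiving an event-locked gain; and (iv) the ground-truth event list.
#'
#' @param hyp a `hypnogram`.
#' @param patterns state-pattern matrix (rows named by state).
#' @param reward_state which pattern row reactivates (`"Face"` or
#'   `"Maze"`, the subject's won game).
#' @param react_amp amplitude of each reactivation impulse in task-pattern
#'   units (0 disables reactivation; default 2).
#' @param event_rate_per_min_n3 expected events per minute of N3
#'   (default 3).
#' @param delta_coupling gain of the event-locked low-delta elevation in
#'   log10 units (default 0.5).
#' @param seed_gain amplitude of the event-locked response of the
#'   hippocampus/VTA channels (default 2).
#' @param noise_sd,ar1 ROI noise parameters (defaults 1, 0.3).
#' @param band_noise_sd log10-power noise sd on the 2-s grid (default 0.3).
#' @param tr repetition time (default 2.1 s).
#' @param seed integer seed.
#' @return list with `roits`, `bandpower` (a `band_power` object),
#'   `seeds` (list `hippocampus`, `vta`), `truth` (event onsets/amplitudes),
#'   `hypnogram`, `tr`.
#' @export
simulate_sleep_session <- function(hyp, patterns, reward_state = "Face",
                                   react_amp = 2, event_rate_per_min_n3 = 3,
                                   delta_coupling = 0.5, seed_gain = 2,
                                   noise_sd = 1, ar1 = 0.3,
                                   band_noise_sd = 0.3, tr = 2.1, seed = 1) {
  stopifnot(inherits(hyp, "hypnogram"), react_amp >= 0,
            reward_state %in% rownames(patterns))
  total_s <- length(hyp$epochs) * hyp$epoch_len
  n_scans <- floor(total_s / tr + 1e-9)
  onsets <- (seq_len(n_scans) - 1L) * tr
  stage <- hyp$epochs[floor(onsets / hyp$epoch_len) + 1L]
  set.seed(seed)

  ## Poisson reactivation events on N3 scans
  p_event <- event_rate_per_min_n3 * tr / 60
  is_n3 <- stage == "N3"
  ev <- which(is_n3 & runif(n_scans) < p_event)
  if (react_amp == 0) ev <- integer(0)
  u <- numeric(n_scans)
  u[ev] <- react_amp
  h <- canonical_hrf(tr)
  ureg <- as.numeric(convolve_columns(matrix(u), h))

  n_roi <- ncol(patterns)
  roits <- outer(ureg, patterns[reward_state, ]) +
    ar1_noise(n_scans, n_roi, noise_sd, ar1)
  colnames(roits) <- colnames(patterns)

  ## band power on the 2-s Welch grid, log10 units
  bt <- seq(2, total_s - 2, by = 2)
  bstage <- hyp$epochs[pmin(floor(bt / hyp$epoch_len) + 1L, length(hyp$epochs))]
  bm <- band_stage_means()
  bands <- eeg_bands()$band
  lp <- vapply(bands, function(b) {
    bm[b, bstage] + ar1_noise(length(bt), 1L, band_noise_sd, 0.5)[, 1L]
  }, numeric(length(bt)))
  ## event-locked low-delta elevation: unit impulses at event times,
  ## smoothed with a peak-normalized HRF on the 2-s grid
  u2 <- numeric(length(bt))
  if (length(ev)) {
    idx <- clamp(round(onsets[ev] / 2), 1, length(bt))
    u2[idx] <- 1
    k <- canonical_hrf(2, normalize = "peak")
    lp[, "low_delta"] <- lp[, "low_delta"] +
      delta_coupling * as.numeric(convolve_columns(matrix(u2), k))
  }
  bandpower <- structure(list(times = bt, log_power = lp, bands = eeg_bands()),
                         class = "band_power")

  useed <- as.numeric(convolve_columns(matrix(as.numeric(u > 0)), h))
  seeds <- list(
    hippocampus = seed_gain * useed + ar1_noise(n_scans, 1L, noise_sd, ar1)[, 1L],
    vta = seed_gain * useed + ar1_noise(n_scans, 1L, noise_sd, ar1)[, 1L])

  truth <- list(event_scans = ev, event_state = reward_state,
                amplitude = react_amp,
                n3_minutes = sum(is_n3) * tr / 60,
                delta_coupling = delta_coupling)
  list(roits = roits, bandpower = bandpower, seeds = seeds, truth = truth,
       hypnogram = hyp, tr = tr)
}

#' Random connected maze graph
#'
#' A square lattice with a random subset of extra diagonal shortcuts,
#' standing in for the game's map; node 1 is the goal. Unit edge lengths.
#'
#' @param n_side lattice side (default 6, 36 nodes).
#' @param seed integer seed.
#' @return an igraph graph with graph attribute `goal = 1`.
#' @export
make_maze <- function(n_side = 6, seed = 1) {
  set.seed(seed)
  g <- igraph::make_lattice(c(n_side, n_side))
  g <- igraph::set_graph_attr(g, "goal", 1L)
  g
}

#' Simulate a delayed-memory record
#'
#' Realizes the memory tests for one subject. The expected number of
#' exactly-placed faces and the expected proximity of the maze end position
#' to the goal both increase linearly with
#' `coupling * reactivation_strength` before integer rounding and clamping;
#' Gaussian noise of sd `noise_sd` is added to each latent score. Faces not
#' placed exactly are assigned cyclically shifted cells (wrong cells).
#'
#' @param reactivation_strength scalar, e.g. observed reactivation events
#'   per N3 minute times their amplitude.
#' @param coupling slope linking strength to memory (0 = no link).
#' @param noise_sd latent score noise (default 2).
#' @param maze maze graph from [make_maze()].
#' @param seed integer seed.
#' @return list: `face_truth`, `face_placement` (cell ids 1-18),
#'   `face_score`, `maze_position`, `maze_distance`, `strength`.
#' @export
simulate_memory <- function(reactivation_strength, coupling = 1,
                            noise_sd = 2, maze = make_maze(), seed = 1) {
  stopifnot(is.finite(coupling))
  set.seed(seed)
  truth <- seq_len(18L)
  k <- round(clamp(2 + coupling * reactivation_strength +
                     rnorm(1L, 0, noise_sd), 0, 18))
  correct <- if (k > 0) sample.int(18L, k) else integer(0)
  placement <- integer(18L)
  placement[correct] <- correct
  wrong <- setdiff(truth, correct)
  if (length(wrong) == 1L) {
    ## a single leftover face cannot avoid its own cell; swap with a correct one
    if (length(correct)) {
      swap <- correct[1L]
      placement[wrong] <- swap
      placement[swap] <- wrong
    } else placement[wrong] <- wrong
  } else if (length(wrong) > 1L) {
    placement[wrong] <- wrong[c(seq_along(wrong)[-1L], 1L)]  ## cyclic shift
  }
  face_score <- face_memory_score(truth, placement)

  dmat <- igraph::distances(maze, to = igraph::graph_attr(maze, "goal"))
  dmax <- max(dmat[is.finite(dmat)])
  ## chance-level searchers end up well inside the maze, not pinned at the
  ## farthest node, so the no-coupling baseline sits at 0.8 * dmax
  d <- round(clamp(0.8 * dmax - coupling * reactivation_strength +
                     rnorm(1L, 0, noise_sd), 0, dmax))
  avail <- sort(unique(dmat[is.finite(dmat)]))
  d <- avail[which.min(abs(avail - d))]
  node <- which(dmat == d)[1L]
  maze_res <- maze_memory_distance(maze, node)

  list(face_truth = truth, face_placement = placement,
       face_score = face_score, maze_position = node,
       maze_distance = maze_res$distance,
       strength = reactivation_strength)
}

#' Simulate a full study cohort
#'
#' Generates per-subject game sessions (and, optionally, sleep sessions and
#' memory records) under one shared set of state patterns. The won game is
#' balanced across subjects and shuffled; per-subject reactivation
#' amplitudes vary lognormally around `react_amp`, providing the
#' between-subject variance that the memory correlation feeds on. All
#' randomness flows from the master seed through derived per-subject seeds.
#'
#' @param n_subjects cohort size. Default 13, a sleep-analysis cohort with
#'   sustained N3; use 18 with `include_sleep = FALSE` for a
#'   game-session-only training cohort.
#' @param config configuration list as from [default_config()]; only the
#'   generator fields are consulted.
#' @param seed master seed (default `config$seed`).
#' @param include_sleep,include_memory generate the sleep session and the
#'   memory record (default TRUE).
#' @return list with `patterns`, `maze`, `subjects` (each: `id`,
#'   `won_game`, `game`, `sleep`, `record`), `config`.
#' @export
simulate_cohort <- function(n_subjects = 13, config = default_config(),
                            seed = config$seed, include_sleep = TRUE,
                            include_memory = TRUE) {
  stopifnot(n_subjects >= 2)
  config <- modifyList(default_config(), config)
  sds <- derive_seeds(seed, 3L * n_subjects + 2L)
  patterns <- default_state_patterns(
    n_roi = config$n_rois, amp_game = config$patterns$amp_game,
    amp_pre = config$patterns$amp_pre, seed = sds[1L])
  maze <- make_maze(seed = sds[2L])
  set.seed(sds[2L] + 1L)
  won <- sample(rep(c("face", "maze"), length.out = n_subjects))
  amp_mult <- rlnorm(n_subjects, 0, config$sleep$subject_amp_sd)

  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s_game <- sds[2L + i]
    s_sleep <- sds[2L + n_subjects + i]
    s_mem <- sds[2L + 2L * n_subjects + i]
    des <- build_game_schedule(
      n_game_blocks_per_type = config$design$n_blocks,
      game_dur = config$design$game_dur, rest_dur = config$design$rest_dur,
      pre_dur = config$design$pre_dur, tr = config$design$tr,
      n_runs = config$design$n_runs, won_game = won[i], seed = s_game)
    game <- simulate_game_session(des, patterns,
                                  noise_sd = config$noise$sd,
                                  ar1 = config$noise$ar1, seed = s_game)
    subj <- list(id = sprintf("S%02d", i), won_game = won[i], game = game)
    if (include_sleep) {
      hyp <- simulate_hypnogram(config$sleep$total_min,
                                min_n3_min = config$sleep$min_n3_min,
                                seed = s_sleep)
      reward_state <- if (won[i] == "face") "Face" else "Maze"
      subj$sleep <- simulate_sleep_session(
        hyp, patterns, reward_state = reward_state,
        react_amp = config$sleep$react_amp * amp_mult[i],
        event_rate_per_min_n3 = config$sleep$event_rate,
        delta_coupling = config$sleep$delta_coupling,
        seed_gain = config$sleep$seed_gain,
        noise_sd = config$noise$sd, ar1 = config$noise$ar1,
        band_noise_sd = config$sleep$band_noise_sd,
        tr = config$design$tr, seed = s_sleep)
      if (include_memory) {
        tr_ <- subj$sleep$truth
        strength <- if (tr_$n3_minutes > 0)
          length(tr_$event_scans) / tr_$n3_minutes * tr_$amplitude else 0
        subj$record <- simulate_memory(strength,
                                       coupling = config$memory$coupling,
                                       noise_sd = config$memory$noise_sd,
                                       maze = maze, seed = s_mem)
      }
    }
    subjects[[i]] <- subj
  }
  list(patterns = patterns, maze = maze, subjects = subjects, config = config)
}

#' Band-limited synthetic EEG
#'
#' Sums band-limited Gaussian noise components (spectral masking of white
#' noise) — a raw-EEG path for exercising the spectral analysis.
#'
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param band_amps named amplitudes (RMS) per band of [eeg_bands()].
#' @param seed integer seed.
#' @return numeric signal vector.
#' @export
simulate_band_eeg <- function(duration, fs,
                              band_amps = c(low_delta = 1, high_delta = 0.5,
                                            theta = 0.3, alpha = 0.3,
                                            sigma = 0.2, beta = 0.1),
                              seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  freqs <- (0:(n - 1)) * fs / n
  freqs <- pmin(freqs, fs - freqs)  ## two-sided
  bands <- eeg_bands()
  x <- numeric(n)
  for (i in seq_len(nrow(bands))) {
    b <- bands$band[i]
    if (is.na(band_amps[b]) || band_amps[b] == 0) next
    w <- rnorm(n)
    W <- stats::fft(w)
    W[!(freqs >= bands$lo[i] & freqs < bands$hi[i])] <- 0
    comp <- Re(stats::fft(W, inverse = TRUE)) / n
    comp <- comp / max(sd(comp), 1e-12) * band_amps[b]
    x <- x + comp
  }
  x
}
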