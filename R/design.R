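#' Build a pseudo-random two-game block schedule
#'
#' Generates the game-session experimental design: `n_game_blocks_per_type`
#' blocks of each game (face, maze) in a pseudo-random order with no more
#' than `max_run` immediate repetitions of the same game. Each game block is
#' preceded by a `pre_dur`-second cue announcing the game and followed by a
#' `rest_dur`-second rest block. The session ends with a block of the
#' to-be-won game, whose last block carries the win flag.
#'
#' @param n_game_blocks_per_type blocks per game type (default 8).
#' @param game_dur,rest_dur,pre_dur block durations in seconds
#'   (defaults 60, 90, 3).
#' @param tr repetition time in seconds (default 2.1).
#' @param n_runs number of scanner runs the blocks are split across
#'   (must divide the total number of game blocks).
#' @param won_game `"face"` or `"maze"`: which game the session is rigged
#'   to end with.
#' @param max_run maximum immediate repetitions of the same game.
#' @param seed integer seed; the block order is deterministic given the seed.
#' @return an object of class `experiment_design`: list with `blocks`
#'   (data.frame: state, onset, duration, run, is_win_block), `tr`,
#'   `n_scans_per_run`.
#' @export
#' @examples
#' d <- build_game_schedule(seed = 1)
#' sum(d$blocks$duration) # 2448 s
build_game_schedule <- function(n_game_blocks_per_type = 8, game_dur = 60,
                                rest_dur = 90, pre_dur = 3, tr = 2.1,
                                n_runs = 2, won_game = c("face", "maze"),
                                max_run = 2, seed = 1) {
  won_game <- match.arg(won_game)
  n <- as.integer(n_game_blocks_per_type)
  if (n < 1 || game_dur <= 0 || rest_dur <= 0 || pre_dur <= 0)
    stop("counts must be >= 1 and durations > 0")
  if (max_run < 1)
    stop("configuration error: max_run must be >= 1")
  n_blocks <- 2L * n
  if (n_blocks %% n_runs != 0)
    stop("configuration error: n_runs must divide the number of game blocks")

  set.seed(seed)
  won_state <- if (won_game == "face") "Face" else "Maze"
  order <- NULL
  for (try in seq_len(500L)) {
    cand <- sample_game_order(n, n, max_run)
    if (cand[n_blocks] == won_state) { order <- cand; break }
  }
  if (is.null(order))
    stop("configuration error: could not end the session with the won game")

  per_run <- n_blocks %/% n_runs
  unit <- pre_dur + game_dur + rest_dur
  run_dur <- per_run * unit
  blocks <- vector("list", n_blocks * 3L)
  for (i in seq_len(n_blocks)) {
    run <- (i - 1L) %/% per_run + 1L
    onset <- (run - 1L) * run_dur + ((i - 1L) %% per_run) * unit
    g <- order[i]
    is_win <- i == n_blocks && g == won_state
    blocks[[3L * i - 2L]] <- data.frame(
      state = paste0("Pre", g), onset = onset, duration = pre_dur,
      run = run, is_win_block = FALSE)
    blocks[[3L * i - 1L]] <- data.frame(
      state = g, onset = onset + pre_dur, duration = game_dur,
      run = run, is_win_block = is_win)
    blocks[[3L * i]] <- data.frame(
      state = "Rest", onset = onset + pre_dur + game_dur,
      duration = rest_dur, run = run, is_win_block = FALSE)
  }
  blocks <- do.call(rbind, blocks)
  des <- structure(
    list(blocks = blocks, tr = tr,
         n_scans_per_run = rep(floor(run_dur / tr + 1e-9), n_runs),
         won_game = won_game),
    class = "experiment_design")
  validate_design(des)
  des
}

## random interleaving of a Face blocks and b Maze blocks with run-length
## cap m: sequential sampling with feasibility screening, restarting on the
## rare dead end (the screen ignores trailing-run capacity interactions)
sample_game_order <- function(a, b, m) {
  free_ok <- function(a, b) max(a, b) <= (min(a, b) + 1) * m
  ## arrangement of a X's and b Y's (runs <= m) that must start with Y
  forced_ok <- function(a, b) {
    ceiling(a / m) <= b && ceiling(b / m) <= a + 1
  }
  if (!free_ok(a, b))
    stop("configuration error: block counts incompatible with max_run")
  for (attempt in seq_len(500L)) {
    out <- character(a + b)
    rem <- c(Face = a, Maze = b)
    run_type <- ""; run_len <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      cand <- names(rem)[rem > 0L]
      cand <- Filter(function(t) {
        if (t == run_type && run_len >= m) return(FALSE)
        r <- rem; r[t] <- r[t] - 1L
        new_len <- if (t == run_type) run_len + 1L else 1L
        other <- setdiff(names(r), t)
        if (new_len >= m) forced_ok(r[[t]], r[[other]])
        else free_ok(r[[t]], r[[other]])
      }, cand)
      if (!length(cand)) { ok <- FALSE; break }
      t <- if (length(cand) == 1L) cand else sample(cand, 1L)
      out[i] <- t
      run_len <- if (t == run_type) run_len + 1L else 1L
      run_type <- t
      rem[t] <- rem[t] - 1L
    }
    if (ok) return(out)
  }
  stop("configuration error: no feasible block order found")
}

validate_design <- function(des) {
  b <- des$blocks
  stopifnot(is.data.frame(b), des$tr > 0)
  for (r in unique(b$run)) {
    br <- b[b$run == r, ]
    if (is.unsorted(br$onset, strictly = TRUE))
      stop("blocks within a run must be onset-ordered")
    if (any(br$onset[-1L] < (br$onset + br$duration)[-nrow(br)] - 1e-9))
      stop("blocks within a run overlap")
  }
  if (sum(b$is_win_block) != 1L)
    stop("exactly one block must carry the win flag")
  g <- b$state[b$state %in% c("Face", "Maze")]
  rl <- rle(g)
  if (any(rl$lengths > 2L))
    stop("more than 2 consecutive blocks of the same game")
  invisible(des)
}

#' Per-scan state labels from a block schedule
#'
#' Assigns each fMRI scan the state of the block containing its onset time
#' (half-open intervals `[onset, onset + duration)`; a scan starting exactly
#' at a boundary belongs to the later block). Scans inside the win block and
#' its trailing rest block are labeled `"Excluded"` (they are dropped from
#' classifier training); scans outside any block are `"Rest"`.
#'
#' @param design an `experiment_design`.
#' @param n_scans optional total scan count; defaults to the design's
#'   per-run counts. For multi-run designs it must match their sum.
#' @param shift optional integer scan shift applied to the labels (positive
#'   values delay labels by whole scans, padding with `"Rest"`); default 0,
#'   i.e. labels follow block timing with no hemodynamic displacement.
#' @return character vector of labels with attributes `tr` and `onsets`.
#' @export
labels_from_schedule <- function(design, n_scans = NULL, shift = 0L) {
  stopifnot(inherits(design, "experiment_design"))
  b <- design$blocks
  runs <- sort(unique(b$run))
  run_starts <- vapply(runs, function(r) min(b$onset[b$run == r]), 0)
  counts <- design$n_scans_per_run
  if (!is.null(n_scans)) {
    if (length(runs) == 1L) counts <- n_scans
    else if (n_scans != sum(counts))
      stop("n_scans inconsistent with the multi-run design")
  }
  onsets <- unlist(lapply(seq_along(runs), function(i) {
    run_starts[i] + (seq_len(counts[i]) - 1L) * design$tr
  }))
  labels <- rep("Rest", length(onsets))
  excl <- rep(FALSE, length(onsets))
  win_i <- which(b$is_win_block)
  ## rest block immediately following the win block (same run)
  win_rest <- which(b$run == b$run[win_i] & b$state == "Rest" &
                      abs(b$onset - (b$onset[win_i] + b$duration[win_i])) < 1e-9)
  for (i in seq_len(nrow(b))) {
    inb <- onsets >= b$onset[i] - 1e-9 & onsets < b$onset[i] + b$duration[i] - 1e-9
    labels[inb] <- b$state[i]
    if (i == win_i || i %in% win_rest) excl[inb] <- TRUE
  }
  labels[excl] <- "Excluded"
  shift <- as.integer(shift)
  if (shift != 0L) {
    n <- length(labels)
    if (shift > 0L) labels <- c(rep("Rest", min(shift, n)),
                                labels[seq_len(max(n - shift, 0L))])
    else labels <- c(labels[-seq_len(min(-shift, n))],
                     rep("Rest", min(-shift, n)))
  }
  structure(labels, tr = design$tr, onsets = onsets)
}

#' Reward mapping of game states
#'
#' Builds the bijection relabeling the five trained states by reward status:
#' the won game becomes `Reward` (its pre-cue `PreR`), the other game
#' `NoReward` (`PreNR`), and `Rest` stays `Rest`.
#'
#' @param won_game `"face"` or `"maze"`.
#' @return object of class `reward_mapping` (list with `won_game` and the
#'   named character vector `map`).
#' @export
reward_mapping <- function(won_game) {
  if (!is.character(won_game) || length(won_game) != 1L ||
      !won_game %in% c("face", "maze"))
    stop("won_game must be \"face\" or \"maze\"")
  map <- if (won_game == "face") {
    c(Face = "Reward", Maze = "NoReward", Rest = "Rest",
      PreFace = "PreR", PreMaze = "PreNR")
  } else {
    c(Face = "NoReward", Maze = "Reward", Rest = "Rest",
      PreFace = "PreNR", PreMaze = "PreR")
  }
  structure(list(won_game = won_game, map = map), class = "reward_mapping")
}

#' Relabel states by reward status
#'
#' Applies a [reward_mapping()] to either a state-likelihood matrix (columns
#' renamed and reordered to Reward, NoReward, Rest, PreR, PreNR) or a label
#' vector. Numeric content is unchanged.
#'
#' @param x likelihood matrix with state column names, or character labels.
#' @param mapping a `reward_mapping`.
#' @return same type as `x`, relabeled.
#' @export
apply_reward_mapping <- function(x, mapping) {
  stopifnot(inherits(mapping, "reward_mapping"))
  map <- mapping$map
  if (is.matrix(x)) {
    if (!all(colnames(x) %in% names(map)))
      stop("unmapped state columns: ",
           paste(setdiff(colnames(x), names(map)), collapse = ", "))
    colnames(x) <- unname(map[colnames(x)])
    x[, intersect(MAPPED_STATES, colnames(x)), drop = FALSE]
  } else if (is.character(x)) {
    out <- x
    hit <- x %in% names(map)
    out[hit] <- unname(map[x[hit]])
    attributes(out) <- attributes(x)
    out
  } else stop("x must be a likelihood matrix or a character label vector")
}
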