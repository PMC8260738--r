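#' Default pipeline configuration
#'
#' All tunable parameters of the generator, classifier and analyses, with
#' the default study conditions: 13 subjects with sleep (18 for game-only
#' validation), 58 ROIs, 8 blocks per game (60 s game / 90 s rest / 3 s
#' pre-cue, TR 2.1 s, two runs), unit task-pattern amplitude against unit
#' AR(1) noise, ~100 min of sleep with sustained N3, reactivation events at
#' 3 per N3 minute, and a uniform-transition CRF with ridge 1e-3.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42,
    n_subjects = 13,
    n_rois = 58,
    design = list(n_blocks = 8, game_dur = 60, rest_dur = 90, pre_dur = 3,
                  tr = 2.1, n_runs = 2),
    patterns = list(amp_game = 1, amp_pre = 0.2),
    noise = list(sd = 1, ar1 = 0.3),
    sleep = list(total_min = 100, min_n3_min = 10, event_rate = 3,
                 react_amp = 2, delta_coupling = 0.5, seed_gain = 2,
                 subject_amp_sd = 0.4, band_noise_sd = 0.3),
    memory = list(coupling = 1, noise_sd = 2),
    crf = list(transitions_uniform = TRUE, l2 = 1e-3, maxit = 500,
               standardize = TRUE),
    analysis = list(loo = FALSE, convolve_regressors = FALSE,
                    label_shift = 0, network_top_k = 10,
                    sphericity = "none"),
    verbose = TRUE
  )
}

## per-subject wake GLM: HRF-convolved game boxcars against ROI series,
## t statistics for Face and Maze vs the implicit rest baseline
wake_contrast_t <- function(game, tr) {
  lab <- as.character(game$labels)
  U <- cbind(Face = as.numeric(lab %in% c("Face")),
             Maze = as.numeric(lab %in% c("Maze")),
             Pre = as.numeric(lab %in% c("PreFace", "PreMaze")))
  X <- cbind(intercept = 1, convolve_columns(U, canonical_hrf(tr)))
  qx <- qr(X)
  B <- qr.coef(qx, game$roits)
  res <- game$roits - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  list(face = B["Face", ] / sqrt(sigma2 * XtXinv[2L, 2L]),
       maze = B["Maze", ] / sqrt(sigma2 * XtXinv[3L, 3L]))
}

#' Run the full decoding analysis on a synthetic cohort
#'
#' Executes the complete pipeline: simulate a cohort, optionally
#' cross-validate the classifier, train the CRF on all game sessions,
#' decode every sleep session, aggregate likelihoods by sleep stage, couple
#' them to EEG band power, correlate hippocampus/VTA seeds with the decoded
#' states, regress sleep ROI activity on the likelihoods and form the
#' wake-sleep conjunction networks, score memory, and run the
#' repeated-measures ANOVAs and planned comparisons. Fully deterministic
#' given the configuration.
#'
#' @param config configuration list (missing fields filled from
#'   [default_config()]).
#' @param out_dir optional directory: the result tables are written there
#'   as CSV/JSON with a manifest carrying the configuration hash.
#' @return a result bundle (list); see the components in the source or the
#'   package vignette.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- modifyList(default_config(), config)
  t0 <- Sys.time()
  say <- function(...) if (isTRUE(config$verbose))
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            ...)
  tr <- config$design$tr

  say("simulating cohort of ", config$n_subjects, " subjects")
  cohort <- simulate_cohort(config$n_subjects, config, seed = config$seed)

  cv <- NULL
  if (isTRUE(config$analysis$loo)) {
    say("leave-one-subject-out cross-validation")
    cv <- cross_validate(lapply(cohort$subjects, function(s)
      list(roits = s$game$roits, labels = s$game$labels, id = s$id)),
      transitions_uniform = config$crf$transitions_uniform,
      l2 = config$crf$l2, maxit = config$crf$maxit,
      standardize = config$crf$standardize)
  }

  say("training CRF on all game sessions")
  pooled <- do.call(rbind, lapply(cohort$subjects, function(s) s$game$roits))
  tr_stats <- featurize(pooled, standardize = config$crf$standardize)
  train <- lapply(cohort$subjects, function(s) list(
    feats = featurize(s$game$roits, tr_stats,
                      standardize = config$crf$standardize)$values,
    labels = as.character(s$game$labels)))
  model <- fit_crf(train, states = GAME_STATES,
                   transitions_uniform = config$crf$transitions_uniform,
                   l2 = config$crf$l2, maxit = config$crf$maxit,
                   train_stats = tr_stats)

  say("decoding sleep sessions")
  stage_rows <- list(); band_rows <- list(); seed_rows <- list()
  wake_t <- list(); sleep_t <- list(); sleep_reg <- list()
  for (s in cohort$subjects) {
    mapping <- reward_mapping(s$won_game)
    lik <- decode_sleep(model, s$sleep$roits)
    st <- stage_mean_likelihood(lik, s$sleep$hypnogram, mapping, tr)
    st$subject <- s$id; st$won_game <- s$won_game
    stage_rows[[s$id]] <- st
    band_scan <- resample_to_scans(s$sleep$bandpower, tr, nrow(lik))
    bc <- likelihood_band_correlation(apply_reward_mapping(lik, mapping),
                                      band_scan)
    bc$subject <- s$id
    band_rows[[s$id]] <- bc
    mlik <- apply_reward_mapping(lik, mapping)
    for (region in names(s$sleep$seeds)) {
      rho <- roi_state_correlation(s$sleep$seeds[[region]], mlik)
      seed_rows[[paste(s$id, region)]] <- data.frame(
        subject = s$id, region = region, state = names(rho), rho = rho,
        row.names = NULL)
    }
    reg <- likelihood_regression(s$sleep$roits, lik,
                                 convolve = config$analysis$convolve_regressors,
                                 tr = tr)
    reg_m <- likelihood_regression(s$sleep$roits, lik,
                                   contrast = c("Maze", "Rest"),
                                   convolve = config$analysis$convolve_regressors,
                                   tr = tr)
    sleep_reg[[s$id]] <- reg
    sleep_t[[s$id]] <- list(face = setNames(reg$t, reg$roi),
                            maze = setNames(reg_m$t, reg_m$roi))
    wake_t[[s$id]] <- wake_contrast_t(s$game, tr)
  }
  stage_table <- do.call(rbind, stage_rows); rownames(stage_table) <- NULL
  band_table <- do.call(rbind, band_rows); rownames(band_table) <- NULL
  seed_table <- do.call(rbind, seed_rows); rownames(seed_table) <- NULL

  say("wake-sleep conjunction networks")
  k <- config$analysis$network_top_k
  roi_names <- colnames(cohort$patterns)
  top_k <- function(v) names(sort(v, decreasing = TRUE))[seq_len(k)]
  group_mean <- function(lst, game) {
    rowMeans(vapply(lst, function(x) x[[game]], numeric(length(roi_names))))
  }
  networks <- list(
    face = conjunction(top_k(group_mean(wake_t, "face")),
                       top_k(group_mean(sleep_t, "face"))),
    maze = conjunction(top_k(group_mean(wake_t, "maze")),
                       top_k(group_mean(sleep_t, "maze"))))

  say("memory analysis")
  strengths <- vapply(cohort$subjects, function(s) {
    net <- networks[[s$won_game]]
    reg <- sleep_reg[[s$id]]
    col <- if (s$won_game == "face") "beta_Face" else "beta_Maze"
    if (!length(net)) return(NA_real_)
    mean(reg[[col]][match(net, reg$roi)])
  }, 0)
  face_scores <- vapply(cohort$subjects, function(s) s$record$face_score, 0)
  maze_dists <- vapply(cohort$subjects, function(s) s$record$maze_distance, 0)
  mem_z <- zscore_memory(face_scores, maze_dists)
  mem_won <- ifelse(vapply(cohort$subjects, `[[`, "", "won_game") == "face",
                    mem_z$face_z, mem_z$maze_z)
  memory <- list(strengths = strengths, z = mem_z,
                 correlation = if (all(is.finite(strengths)) &&
                                   length(strengths) >= 5L)
                   reactivation_memory_correlation(strengths, mem_won)
                 else list(rho = NA_real_, p = NA_real_, defined = FALSE))

  say("group statistics")
  complete <- !is.na(stage_table$mean_likelihood)
  stats_in <- stage_table[complete, ]
  keep_subj <- names(which(tapply(complete, stage_table$subject, all)))
  stats_in <- stats_in[stats_in$subject %in% keep_subj, ]
  anova_state_stage <- rm_anova(stats_in, dv = "mean_likelihood",
                                subject = "subject",
                                within = c("state", "stage"))
  anova_game_won <- rm_anova(stats_in, dv = "mean_likelihood",
                             subject = "subject",
                             within = c("state", "stage"),
                             between = "won_game")
  planned <- lapply(setNames(SLEEP_STAGES, SLEEP_STAGES), function(stg)
    planned_comparison(stats_in, dv = "mean_likelihood",
                       subject = "subject", factor_name = "state",
                       levels = c("Reward", "NoReward"),
                       at = list(stage = stg)))
  anova_band <- rm_anova(band_table[band_table$subject %in% keep_subj, ],
                         dv = "z", subject = "subject",
                         within = c("state", "band"))
  seed_anova <- lapply(split(seed_table, seed_table$region), function(d)
    list(anova = rm_anova(d, dv = "rho", subject = "subject",
                          within = "state"),
         reward_vs_noreward = planned_comparison(
           d, dv = "rho", subject = "subject", factor_name = "state",
           levels = c("Reward", "NoReward"))))

  bundle <- list(config = config, config_hash = config_hash(config),
                 cv = cv, model = model,
                 stage_table = stage_table, band_table = band_table,
                 seed_table = seed_table, networks = networks,
                 memory = memory,
                 anova_state_stage = anova_state_stage,
                 anova_game_won = anova_game_won,
                 planned_n3 = planned$N3, planned = planned,
                 anova_band = anova_band, seed_anova = seed_anova)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  say("done")
  bundle
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a pipeline result bundle to disk
#'
#' Tidy CSV tables (stage x state means, band correlations, seed
#' correlations), JSON summaries of the ANOVAs, memory analysis and
#' networks, and a manifest with the configuration hash.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) write.csv(df, file.path(dir, name),
                                     row.names = FALSE)
  wr(bundle$stage_table, "stage_likelihood.csv")
  wr(bundle$band_table, "band_correlation.csv")
  wr(bundle$seed_table, "seed_correlation.csv")
  wr(bundle$anova_state_stage, "anova_state_stage.csv")
  wr(bundle$anova_band, "anova_band.csv")
  if (!is.null(bundle$cv))
    wr(as.data.frame(bundle$cv$confusion), "confusion.csv")
  jsonlite::write_json(
    list(planned = bundle$planned, seed_anova = bundle$seed_anova,
         networks = bundle$networks,
         memory = bundle$memory[c("strengths", "correlation")]),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  manifest <- list(config_hash = bundle$config_hash,
                   config = bundle$config,
                   files = list.files(dir))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
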