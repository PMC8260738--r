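test_that("featurize z-scores, reuses training stats, and zeroes flat ROIs", {
  set.seed(1)
  X <- cbind(rnorm(50, 5, 2), rnorm(50, -1, 0.5), rep(3, 50))
  expect_warning(fe <- featurize(X), "zero-variance")
  expect_equal(colMeans(fe$values[, 1:2]), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(fe$values[, 1:2], 2, sd), c(1, 1), tolerance = 1e-12)
  expect_true(all(fe$values[, 3] == 0))
  ## idempotence on already-standardized data
  fe2 <- featurize(fe$values[, 1:2])
  expect_equal(fe2$values, fe$values[, 1:2], tolerance = 1e-12)
  ## training stats applied to new data leave nonzero means
  Y <- cbind(rnorm(50, 8, 2), rnorm(50, 2, 0.5), rep(3, 50))
  fey <- featurize(Y, fe)
  expect_gt(abs(mean(fey$values[, 1])), 0.1)
})

test_that("sequence score matches hand arithmetic and boundary conventions", {
  m <- crf_model(c("A", "B"), 1, transitions_uniform = FALSE)
  m$lambda <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2,
                     dimnames = dimnames(m$lambda))   # lambda[i,j], row=from
  m$mu <- matrix(c(1, -1, 0.5, 0.25), 2, 2, dimnames = dimnames(m$mu))
  X <- matrix(c(2, -1, 0.5), 3, 1)
  ## A,B,B: mu_A.[2,1] + mu_B.[-1,1] + mu_B.[0.5,1] + lam[A,B] + lam[B,B]
  hand <- (1 * 2 + 0.5) + (-1 * -1 + 0.25) + (-1 * 0.5 + 0.25) +
    0.3 + 0.4
  expect_equal(sequence_score(m, X, c("A", "B", "B")), hand)
  ## single scan: no transition term
  expect_equal(sequence_score(m, X[1, , drop = FALSE], "A"), 2.5)
  ## zero weights: zero score
  m0 <- crf_model(c("A", "B"), 1, transitions_uniform = FALSE)
  expect_equal(sequence_score(m0, X, c("B", "A", "B")), 0)
  expect_error(sequence_score(m, X, c("A", "Excluded", "B")), "Excluded")
})

test_that("log-partition and marginals reduce to closed forms at zero weights", {
  m <- crf_model(LETTERS[1:5], 3)
  X <- matrix(rnorm(21), 7, 3)
  expect_equal(log_partition(m, X), 7 * log(5), tolerance = 1e-12)
  P <- posterior_marginals(m, X)
  expect_true(all(abs(P - 0.2) < 1e-12))
  d <- list(list(feats = X, labels = sample(LETTERS[1:5], 7, TRUE)))
  ll <- log_likelihood(m, d, l2 = 0)
  expect_equal(ll$value, -7 * log(5), tolerance = 1e-12)
})

test_that("adding a constant to every state bias shifts log Z by T*c", {
  set.seed(2)
  inst <- random_crf_instance(5, 3, 2)
  lz <- log_partition(inst$model, inst$feats)
  m2 <- inst$model
  m2$mu[, ncol(m2$mu)] <- m2$mu[, ncol(m2$mu)] + 1.7
  expect_equal(log_partition(m2, inst$feats), lz + 5 * 1.7, tolerance = 1e-9)
})

test_that("forward-backward agrees with enumeration on random chains", {
  set.seed(3)
  for (i in 1:30) {
    T_ <- sample(2:6, 1); S <- sample(2:3, 1); N <- sample(1:3, 1)
    inst <- random_crf_instance(T_, S, N)
    oracle <- brute_chain(inst$model, inst$feats)
    expect_equal(log_partition(inst$model, inst$feats), oracle$logZ,
                 tolerance = 1e-10)
    P <- posterior_marginals(inst$model, inst$feats)
    expect_equal(unname(unclass(P)), oracle$marginals, tolerance = 1e-10)
    expect_true(all(abs(rowSums(P) - 1) < 1e-9))
    expect_identical(viterbi_decode(inst$model, inst$feats), oracle$viterbi)
  }
})

test_that("Viterbi breaks exact ties toward the lower state index", {
  m <- crf_model(c("A", "B"), 1)   # all weights zero: everything tied
  X <- matrix(rnorm(4), 4, 1)
  expect_identical(viterbi_decode(m, X), rep("A", 4))
  ## and with saturated bias the other way
  m$mu["B", 2] <- 50
  expect_identical(viterbi_decode(m, X), rep("B", 4))
  P <- posterior_marginals(m, X)
  expect_true(all(P[, "B"] > 1 - 1e-9))
})

test_that("with uniform transitions Viterbi equals the marginal argmax", {
  set.seed(4)
  m <- crf_model(c("A", "B", "C"), 2)
  m$mu <- matrix(rnorm(9), 3, 3, dimnames = dimnames(m$mu))
  X <- matrix(rnorm(40), 20, 2)
  P <- posterior_marginals(m, X)
  expect_identical(viterbi_decode(m, X),
                   colnames(P)[max.col(unclass(P), ties.method = "first")])
})

test_that("gradient of the training objective matches finite differences", {
  set.seed(5)
  inst <- random_crf_instance(4, 2, 2, scale = 0.4)
  m <- inst$model
  data <- list(list(feats = inst$feats, labels = c("A", "B", "B", "A")),
               list(feats = matrix(rnorm(6), 3, 2), labels = c("B", "A", "B")))
  l2 <- 0.05
  pack <- function(m) c(as.numeric(m$lambda), as.numeric(m$mu))
  unpack <- function(m, th) {
    m$lambda <- matrix(th[1:4], 2, 2, dimnames = dimnames(m$lambda))
    m$mu <- matrix(th[5:10], 2, 3, dimnames = dimnames(m$mu))
    m
  }
  g <- log_likelihood(m, data, l2 = l2)
  analytic <- c(as.numeric(g$grad_lambda), as.numeric(g$grad_mu))
  th0 <- pack(m)
  eps <- 1e-5
  numeric_g <- vapply(seq_along(th0), function(j) {
    tp <- th0; tp[j] <- tp[j] + eps
    tm <- th0; tm[j] <- tm[j] - eps
    (log_likelihood(unpack(m, tp), data, l2 = l2)$value -
       log_likelihood(unpack(m, tm), data, l2 = l2)$value) / (2 * eps)
  }, 0)
  expect_equal(analytic, numeric_g, tolerance = 1e-6)
})

test_that("fitting a separable toy problem reaches perfect training accuracy", {
  set.seed(6)
  X <- rbind(matrix(rnorm(60, 3), 30, 2), matrix(rnorm(60, -3), 30, 2))
  labels <- rep(c("A", "B"), each = 30)
  m <- fit_crf(list(list(feats = X, labels = labels)), l2 = 1e-3)
  expect_identical(viterbi_decode(m, X), labels)
  ## at the fitted optimum the penalized gradient is (near) zero
  g <- log_likelihood(m, list(list(feats = X, labels = labels)))
  expect_lt(max(abs(g$grad_mu)), 1e-2)
})

test_that("fit errors when a requested state never occurs in training", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_crf(list(list(feats = X, labels = rep(c("A", "B"), 5))),
                       states = c("A", "B", "C")),
               "missing state")
})

test_that("Excluded scans are dropped and chains split around them", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  labels <- rep(c("A", "B"), each = 20)
  labels[10:12] <- "Excluded"
  m <- fit_crf(list(list(feats = X, labels = labels)),
               transitions_uniform = FALSE, l2 = 0.1)
  keep <- labels != "Excluded"
  expect_identical(viterbi_decode(m, X[keep, ]), labels[keep])
})

test_that("leave-one-subject-out bookkeeping is exact on noiseless twins", {
  cohort <- tiny_cohort(3, noise_sd = 0)
  cv <- cross_validate(cohort, maxit = 2000)
  expect_s3_class(cv, "crf_cv")
  held_counts <- Reduce(`+`, lapply(cohort, function(s)
    table(factor(s$labels[s$labels != "Excluded"], GAME_STATES))))
  expect_equal(as.numeric(rowSums(cv$confusion)), as.numeric(held_counts))
  ## noiseless duplicated-generator subjects decode perfectly for the three
  ## sustained states (pre-cue states are brief and HRF-delayed)
  expect_true(all(cv$per_state_accuracy[c("Face", "Maze", "Rest")] > 0.95))
  expect_error(cross_validate(cohort[1:1]), "at least 2")
})

test_that("a fold missing a state is reported with the fold's subject", {
  cohort <- tiny_cohort(2, noise_sd = 0)
  cohort[[2]]$labels[cohort[[2]]$labels == "PreFace"] <- "Rest"
  ## training for held-out subject 1 = subject 2, which now lacks PreFace
  expect_error(cross_validate(cohort), "S1.*PreFace")
})

test_that("model JSON serialization round-trips", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 1.5), 20, 2), matrix(rnorm(40, -1.5), 20, 2))
  labels <- rep(c("A", "B"), each = 20)
  st <- featurize(X)
  m <- fit_crf(list(list(feats = st$values, labels = labels)),
               train_stats = st)
  path <- tempfile(fileext = ".json")
  save_crf_model(m, path)
  m2 <- load_crf_model(path)
  expect_equal(m2$mu, m$mu, tolerance = 1e-12)
  expect_equal(m2$states, m$states)
  expect_equal(m2$train_stats$center, m$train_stats$center,
               tolerance = 1e-12, ignore_attr = TRUE)
  P1 <- posterior_marginals(m, st$values)
  P2 <- posterior_marginals(m2, st$values)
  expect_equal(unclass(P1), unclass(P2), tolerance = 1e-10)
})
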