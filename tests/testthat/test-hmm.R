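test_that("forward log-likelihood matches path enumeration on the toy", {
  expect_equal(log_likelihood(toy_model(), toy_obs()),
               enum_loglik(toy_model(), toy_obs()$mat),
               tolerance = 1e-12)
})

test_that("forward and Viterbi match enumeration on random small instances", {
  withr::with_seed(101, {
    for (i in 1:30) {
      K <- sample(1:3, 1)
      M <- sample(1:3, 1)
      n <- sample(1:8, 1)
      m <- random_small_model(K, M)
      mat <- matrix(rbinom(n * M, 1, 0.5), n, M,
                    dimnames = list(NULL, m$marks))
      obs <- observation_matrix(mat, m$marks)
      expect_equal(log_likelihood(m, obs), enum_loglik(m, mat),
                   tolerance = 1e-9)
      v <- decode(m, obs, "viterbi")
      best <- enum_viterbi(m, mat)
      # the returned path attains the maximal joint probability
      expect_equal(path_joint_prob(m, mat, v),
                   path_joint_prob(m, mat, best), tolerance = 1e-9)
    }
  })
})

test_that("K = 1 log-likelihood equals the Bernoulli closed form", {
  m <- state_model(pi = 1, A = matrix(1, 1, 1),
                   E = matrix(c(0.3, 0.8), 1, 2), marks = c("a", "b"))
  mat <- matrix(c(1, 0, 1, 1, 1, 0), 3, 2)
  obs <- observation_matrix(mat, c("a", "b"))
  closed <- sum(mat %*% log(c(0.3, 0.8)) + (1 - mat) %*% log(c(0.7, 0.2)))
  expect_equal(log_likelihood(m, obs), closed, tolerance = 1e-9)
})

test_that("degenerate emissions stay finite under the floor policy", {
  m <- state_model(pi = 1, A = matrix(1, 1, 1),
                   E = matrix(c(0, 1), 1, 2), marks = c("a", "b"))
  obs <- observation_matrix(matrix(c(0, 1), 1, 2), c("a", "b"))
  expect_true(is.finite(log_likelihood(m, obs)))
})

test_that("likelihood is independent of sequence processing order", {
  m <- toy_model()
  o1 <- toy_obs()
  o2 <- observation_matrix(matrix(c(0, 1, 1, 0), 4, 1), "m1")
  expect_equal(log_likelihood(m, list(o1, o2)),
               log_likelihood(m, list(o2, o1)), tolerance = 1e-12)
})

test_that("Viterbi ties break toward the lower state index", {
  # identity transitions, mass on state 2, non-informative emissions:
  # only state 2 is reachable regardless of data
  m <- state_model(pi = c(0, 1), A = diag(2),
                   E = rbind(0.5, 0.5), marks = "m1")
  obs <- observation_matrix(matrix(c(1, 0, 1), 3, 1), "m1")
  expect_equal(decode(m, obs, "viterbi"), rep(2L, 3))

  # fully symmetric model: every path ties; lowest index wins
  m2 <- state_model(pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
                    E = rbind(0.5, 0.5), marks = "m1")
  expect_equal(decode(m2, obs, "viterbi"), rep(1L, 3))
})

test_that("single-bin decoding is argmax of pi times emission", {
  m <- state_model(pi = c(0.3, 0.7), A = matrix(0.5, 2, 2),
                   E = rbind(0.9, 0.2), marks = "m1")
  obs1 <- observation_matrix(matrix(1, 1, 1), "m1")
  # pi * e = (0.27, 0.14) -> state 1
  expect_equal(decode(m, obs1, "viterbi"), 1L)
  expect_equal(decode(m, obs1, "posterior"), 1L)
  obs0 <- observation_matrix(matrix(0, 1, 1), "m1")
  # pi * e = (0.03, 0.56) -> state 2
  expect_equal(decode(m, obs0, "viterbi"), 2L)
  expect_equal(decode(m, obs0, "posterior"), 2L)
  # empty observation -> empty path
  expect_equal(decode(m, observation_matrix(matrix(0, 0, 1), "m1")),
               integer(0))
})

test_that("decoding is invariant to consistent state relabeling", {
  withr::with_seed(33, {
    m <- random_small_model(3, 2)
    mat <- matrix(rbinom(60, 1, 0.5), 30, 2,
                  dimnames = list(NULL, m$marks))
    obs <- observation_matrix(mat, m$marks)
    perm <- c(3, 1, 2)
    mp <- state_model(m$pi[perm], m$A[perm, perm], m$E[perm, ],
                      marks = m$marks)
    for (method in c("viterbi", "posterior")) {
      p1 <- decode(m, obs, method)
      p2 <- decode(mp, obs, method)
      expect_equal(match(p1, perm), p2)
    }
  })
})

test_that("one EM iteration on K = 1 recovers empirical frequencies", {
  withr::with_seed(7, {
    mat <- matrix(rbinom(400, 1, c(0.3, 0.7)), 200, 2, byrow = TRUE)
    colnames(mat) <- c("a", "b")
    obs <- observation_matrix(mat, c("a", "b"))
    m0 <- init_model(1, 2, 1, obs)
    fit <- baum_welch(m0, obs, max_iter = 2)
    expect_equal(as.numeric(fit$model$E), unname(colMeans(mat)),
                 tolerance = 1e-9)
  })
})

test_that("EM log-likelihood traces are non-decreasing", {
  # toy fixture
  fit <- baum_welch(toy_model(), toy_obs(), max_iter = 50)
  expect_true(all(diff(fit$trace) >= -1e-8))
  # the trace agrees with independently computed likelihoods: re-evaluate
  # the final model
  expect_equal(log_likelihood(fit$model, toy_obs()),
               fit$trace[length(fit$trace)], tolerance = 1e-6)

  withr::with_seed(55, {
    for (i in 1:5) {
      m <- random_small_model(3, 3)
      so <- simulate_observations(m, 500, seed = i)
      m0 <- init_model(3, 3, i, so$obs)
      fit <- baum_welch(m0, so$obs, max_iter = 60)
      expect_true(all(diff(fit$trace) >= -1e-8))
    }
  })
})

test_that("non-convergence at max_iter is flagged, not an error", {
  m <- default_true_model()
  so <- simulate_observations(m, 2000, seed = 3)
  m0 <- init_model(6, 5, 2, so$obs)
  fit <- baum_welch(m0, so$obs, tol = 0, max_iter = 5)
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 5)
  expect_s3_class(fit$model, "state_model")
})

test_that("initialization is deterministic and respects its contracts", {
  m <- default_true_model()
  so <- simulate_observations(m, 2000, seed = 9)
  m1 <- init_model(4, 5, 42, so$obs)
  m2 <- init_model(4, 5, 42, so$obs)
  expect_identical(m1, m2)
  expect_equal(sum(m1$pi), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m1$A)), rep(1, 4), tolerance = 1e-12)

  # partition strategy: emissions within observed per-mark frequency range
  # +/- the 0.2 perturbation bound
  X <- so$obs$mat
  f <- colMeans(X)
  for (mcol in seq_len(5)) {
    expect_true(all(m1$E[, mcol] >= max(0, f[mcol] - 0.25) - 0.05 &
                      m1$E[, mcol] <= f[mcol] + 0.25))
  }

  # K = 1: emissions are exactly the observed frequencies
  m_single <- init_model(1, 5, 1, so$obs)
  expect_equal(as.numeric(m_single$E), unname(colMeans(X)),
               tolerance = 1e-9)
  expect_error(init_model(0, 5, 1, so$obs), "positive integer")
})

test_that("segmentation is run-length encoding and round-trips", {
  seg <- segment_path(c(0, 0, 1, 1, 1, 0), 200, "chr1")
  expect_equal(seg$start, c(0, 400, 1000))
  expect_equal(seg$end, c(400, 1000, 1200))
  expect_equal(seg$state, c(0, 1, 0))

  seg1 <- segment_path(rep(4L, 7), 100, "chrX")
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$end - seg1$start, 700)

  withr::with_seed(77, {
    for (i in 1:20) {
      path <- sample(1:5, 500, replace = TRUE)
      seg <- segment_path(path, 200, "chr1")
      # consecutive intervals differ in state; lengths add up
      expect_true(all(diff(seg$state) != 0) || nrow(seg) == 1)
      expect_equal(sum(seg$end - seg$start), 500 * 200)
      expect_identical(expand_segments(seg, 200), as.integer(path))
    }
  })
  expect_error(segment_path(integer(0), 200, "chr1"), "non-empty")
})

test_that("model containers validate their invariants", {
  expect_error(state_model(c(0.5, 0.6), diag(2), matrix(0.5, 2, 1), "m"),
               "pi")
  expect_error(state_model(c(0.5, 0.5), matrix(1, 2, 2),
                           matrix(0.5, 2, 1), "m"), "row sums")
  expect_error(state_model(c(0.5, 0.5), diag(2), matrix(2, 2, 1), "m"),
               "E must")
  expect_error(observation_matrix(matrix(2, 1, 1), "m"), "0/1")
  expect_error(observation_matrix(matrix(1, 1, 1), c("a", "b")),
               "mark_order")
  # mark mismatch between model and observation is an input error
  expect_error(log_likelihood(toy_model(),
                              observation_matrix(matrix(1, 1, 1), "other")),
               "marks")
})
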