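# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own recursions.

# joint probability of one complete state path given model and observations
path_joint_prob <- function(model, mat, path) {
  E <- pmin(pmax(model$E, 1e-6), 1 - 1e-6)
  p <- model$pi[path[1]]
  n <- nrow(mat)
  if (n > 1) {
    for (t in 2:n) p <- p * model$A[path[t - 1], path[t]]
  }
  for (t in seq_len(n)) {
    for (m in seq_len(ncol(mat))) {
      e <- E[path[t], m]
      p <- p * if (mat[t, m] == 1) e else 1 - e
    }
  }
  p
}

# exact log-likelihood by enumerating all K^T paths
enum_loglik <- function(model, mat) {
  K <- model$K
  n <- nrow(mat)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  log(sum(apply(paths, 1, function(pp) path_joint_prob(model, mat, pp))))
}

# exact Viterbi path by enumeration; ties broken toward the path that is
# first in lexicographic order (lowest state indices first)
enum_viterbi <- function(model, mat) {
  K <- model$K
  n <- nrow(mat)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  # expand.grid varies the first column fastest; reorder rows so paths are
  # lexicographic in sequence order
  ord <- do.call(order, as.data.frame(paths[, n:1, drop = FALSE]))
  paths <- paths[ord, , drop = FALSE]
  probs <- apply(paths, 1, function(pp) path_joint_prob(model, mat, pp))
  as.integer(paths[which.max(probs), ])
}

# smallest c >= 1 with P(X >= c) <= p by explicit pmf tail summation
oracle_poisson_threshold <- function(lambda, p) {
  upper <- max(50, ceiling(lambda + 20 * sqrt(lambda) + 50))
  pmf <- exp(-lambda + (0:upper) * log(lambda) - lgamma((0:upper) + 1))
  cc <- 1
  repeat {
    tail <- 1 - sum(pmf[seq_len(cc)])  # P(X >= cc)
    if (tail <= p) return(cc)
    cc <- cc + 1
  }
}

# exact hypergeometric upper tail P(X >= x) via choose() summation
oracle_hyper_tail <- function(x, n_success, n_fail, n_draw) {
  hi <- min(n_draw, n_success)
  if (x > hi) return(0)
  ks <- x:hi
  ks <- ks[n_draw - ks <= n_fail]
  sum(exp(lchoose(n_success, ks) + lchoose(n_fail, n_draw - ks) -
            lchoose(n_success + n_fail, n_draw)))
}

# best state matching between two emission matrices (small K)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

match_states <- function(E_fit, E_true) {
  best <- Inf
  best_p <- NULL
  for (p in all_perms(seq_len(nrow(E_true)))) {
    err <- max(abs(E_fit[p, , drop = FALSE] - E_true))
    if (err < best) {
      best <- err
      best_p <- p
    }
  }
  list(perm = best_p, max_E_err = best)
}

random_small_model <- function(K, M) {
  pi <- runif(K) + 0.1
  pi <- pi / sum(pi)
  A <- matrix(runif(K * K) + 0.1, K, K)
  A <- A / rowSums(A)
  E <- matrix(runif(K * M, 0.05, 0.95), K, M)
  state_model(pi, A, E, marks = paste0("m", seq_len(M)))
}
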