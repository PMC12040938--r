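#' Multivariate Bernoulli-emission hidden Markov model
#'
#' Container for the chromatin-state model: initial state probabilities
#' `pi`, state-transition matrix `A` (rows sum to 1) and per-state per-mark
#' Bernoulli emission probabilities `E` (K states x M marks). Marks are
#' conditionally independent given the state, so the per-bin emission
#' probability is a product of Bernoulli terms.
#'
#' @param pi K-vector of initial probabilities (sums to 1).
#' @param A K x K transition matrix, each row sums to 1.
#' @param E K x M matrix of emission probabilities in `[0, 1]`.
#' @param marks ordered mark names, length M.
#' @param state_names optional state names (e.g. ground-truth labels).
#' @return list of class `state_model`.
#' @export
state_model <- function(pi, A, E, marks = colnames(E), state_names = NULL) {
  E <- as.matrix(E)
  A <- as.matrix(A)
  colnames(E) <- marks
  m <- structure(list(K = length(pi), pi = as.numeric(pi), A = A, E = E,
                      marks = as.character(marks), state_names = state_names),
                 class = "state_model")
  validate_state_model(m)
  m
}

#' @rdname state_model
#' @param model object to validate.
#' @export
validate_state_model <- function(model) {
  if (!inherits(model, "state_model")) abort_input("not a state_model")
  K <- model$K
  if (length(model$pi) != K || abs(sum(model$pi) - 1) > 1e-9) {
    abort_input("pi must be a K-vector summing to 1")
  }
  if (!all(dim(model$A) == c(K, K)) ||
      max(abs(rowSums(model$A) - 1)) > 1e-9) {
    abort_input("A must be K x K with unit row sums")
  }
  if (nrow(model$E) != K || ncol(model$E) != length(model$marks) ||
      any(model$E < 0 | model$E > 1)) {
    abort_input("E must be K x M with entries in [0, 1]")
  }
  invisible(model)
}

#' Binary observation matrix for one tissue and chromosome
#'
#' @param mat bins x marks matrix with entries in `{0, 1}`.
#' @param marks ordered mark names matching the columns.
#' @param tissue,chromosome identifiers.
#' @return list of class `observation_matrix`.
#' @export
observation_matrix <- function(mat, marks = colnames(mat), tissue = NA_character_,
                               chromosome = NA_character_) {
  mat <- as.matrix(mat)
  if (length(mat) && !all(mat %in% c(0, 1))) {
    abort_input("observation entries must be 0/1")
  }
  if (ncol(mat) != length(marks)) {
    abort_input("mark_order length must equal column count")
  }
  colnames(mat) <- marks
  structure(list(tissue = tissue, chromosome = chromosome,
                 mat = mat, marks = as.character(marks)),
            class = "observation_matrix")
}

# clamp emissions away from 0/1 so likelihoods stay finite
EM_FLOOR <- 1e-6

clamp_emissions <- function(E) pmin(pmax(E, EM_FLOOR), 1 - EM_FLOOR)

# T x K matrix of per-bin emission probabilities (product over marks)
emission_probs <- function(model, mat, log = FALSE) {
  E <- clamp_emissions(model$E)
  lp <- mat %*% t(log(E)) + (1 - mat) %*% t(log(1 - E))
  if (log) lp else exp(lp)
}

as_obs_list <- function(obs) {
  if (inherits(obs, "observation_matrix")) list(obs) else obs
}

check_obs <- function(model, obs) {
  if (!inherits(obs, "observation_matrix")) abort_input("not an observation_matrix")
  if (ncol(obs$mat) != length(model$marks) ||
      !identical(obs$marks, model$marks)) {
    abort_input("observation marks do not match model mark_order")
  }
  obs
}

#' Forward log-likelihood of binarized observations
#'
#' Scaled-forward recursion; the result does not depend on the order in
#' which independent sequences are processed (log-likelihoods add).
#'
#' @param model a [state_model()].
#' @param obs an [observation_matrix()] or a list of them (independent
#'   sequences, e.g. chromosomes/tissues).
#' @return total log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(model, obs) {
  validate_state_model(model)
  obs <- as_obs_list(obs)
  sum(vapply(obs, function(o) {
    check_obs(model, o)
    if (nrow(o$mat) == 0L) return(0)
    B <- emission_probs(model, o$mat)
    .fb_cpp(model$pi, model$A, B)$loglik
  }, numeric(1)))
}

#' Seeded model initialization
#'
#' Transitions and initial probabilities are uniform with multiplicative
#' uniform perturbation (rows renormalized). Two emission strategies:
#'
#' * `"partition"` (default): a random partition of the observed bins into
#'   K groups; per-group per-mark frequencies, jittered by +/-0.2 and
#'   clamped to `[1e-6, 1-1e-6]`.
#' * `"pattern"`: states are anchored at the K most frequent distinct
#'   observed mark patterns (ties broken lexicographically), with emissions
#'   `0.85 * pattern + 0.075` plus +/-0.05 jitter. Binary-emission
#'   likelihood surfaces have their basins at combinatorial mark patterns,
#'   so this start reliably reaches rare states (e.g. active enhancers at
#'   well under 1% of bins) that near-marginal starts tend to absorb into
#'   the quiescent state.
#'
#' With `K = 1` the emissions are exactly the observed mark frequencies.
#'
#' @param K states, `>= 1`. @param M marks, `>= 1`.
#' @param seed integer seed; identical seeds give identical models.
#' @param obs list of [observation_matrix()] supplying observed frequencies.
#' @param strategy emission initialization strategy.
#' @return a [state_model()].
#' @export
init_model <- function(K, M, seed, obs,
                       strategy = c("partition", "pattern")) {
  K <- check_positive_int(K, "K")
  M <- check_positive_int(M, "M")
  strategy <- match.arg(strategy)
  obs <- as_obs_list(obs)
  marks <- obs[[1]]$marks
  if (length(marks) != M) abort_input("M must match observation mark count")
  X <- do.call(rbind, lapply(obs, function(o) o$mat))
  if (K == 1L) {
    E <- matrix(colMeans(X), 1, M, dimnames = list(NULL, marks))
    return(state_model(pi = 1, A = matrix(1, 1, 1),
                       E = clamp_emissions(E), marks = marks))
  }
  withr::with_seed(seed, {
    pi <- rep(1, K) * (1 + runif(K, -0.2, 0.2))
    pi <- pi / sum(pi)
    A <- matrix(1, K, K) * (1 + matrix(runif(K * K, -0.2, 0.2), K, K))
    A <- A / rowSums(A)
    E <- matrix(0, K, M, dimnames = list(NULL, marks))
    grp <- sample.int(K, nrow(X), replace = TRUE)
    part_mean <- function(k) {
      rows <- grp == k
      if (any(rows)) colMeans(X[rows, , drop = FALSE]) else colMeans(X)
    }
    if (strategy == "pattern") {
      pat <- sort(table(apply(X, 1, paste, collapse = "")),
                  decreasing = TRUE)
      top <- names(pat)[seq_len(min(K, length(pat)))]
      for (k in seq_len(K)) {
        E[k, ] <- if (k <= length(top)) {
          0.85 * as.numeric(strsplit(top[k], "")[[1]]) + 0.075 +
            runif(M, -0.05, 0.05)
        } else part_mean(k) + runif(M, -0.2, 0.2)
      }
    } else {
      for (k in seq_len(K)) E[k, ] <- part_mean(k) + runif(M, -0.2, 0.2)
    }
    state_model(pi = pi, A = A, E = clamp_emissions(E), marks = marks)
  })
}

#' Baum-Welch (EM) learning of the chromatin-state model
#'
#' Independent sequences (chromosomes, tissues) share one model
#' ("concatenated" learning). The per-iteration log-likelihood trace is
#' non-decreasing (numerical slack 1e-8); iteration stops when the absolute
#' change drops below `tol` or at `max_iter` (in which case the returned
#' model is flagged `converged = FALSE`, not an error). Emission updates
#' are clamped to `[1e-6, 1-1e-6]`.
#'
#' @param model starting [state_model()].
#' @param obs_list list of [observation_matrix()] (non-empty).
#' @param tol absolute log-likelihood change at which to stop.
#' @param max_iter maximum EM iterations.
#' @return list: `model`, `trace` (log-likelihood per iteration, evaluated
#'   at the model entering that iteration), `converged`, `n_iter`.
#' @export
baum_welch <- function(model, obs_list, tol = 1e-4, max_iter = 200L) {
  validate_state_model(model)
  obs_list <- as_obs_list(obs_list)
  if (!length(obs_list)) abort_input("obs_list must be non-empty")
  lapply(obs_list, check_obs, model = model)
  obs_list <- Filter(function(o) nrow(o$mat) > 0L, obs_list)
  K <- model$K
  M <- length(model$marks)
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- NA_real_
  for (iter in seq_len(max_iter)) {
    ll <- 0
    gamma1 <- numeric(K)
    xi_sum <- matrix(0, K, K)
    gamma_tot <- numeric(K)
    ex <- matrix(0, K, M)
    for (o in obs_list) {
      B <- emission_probs(model, o$mat)
      fb <- .fb_cpp(model$pi, model$A, B)
      ll <- ll + fb$loglik
      gamma1 <- gamma1 + fb$gamma1
      xi_sum <- xi_sum + fb$xi_sum
      gamma_tot <- gamma_tot + colSums(fb$gamma)
      ex <- ex + t(fb$gamma) %*% o$mat
    }
    trace <- c(trace, ll)
    if (!is.na(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    pi_new <- gamma1 / sum(gamma1)
    A_new <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.xmin)
    A_new[rowSums(xi_sum) == 0, ] <- 1 / K
    E_new <- clamp_emissions(ex / pmax(gamma_tot, .Machine$double.xmin))
    model <- state_model(pi = pi_new, A = A_new, E = E_new,
                         marks = model$marks)
  }
  list(model = model, trace = trace, converged = converged,
       n_iter = length(trace))
}

#' Learn a model with random restarts
#'
#' Runs [init_model()] + [baum_welch()] `n_restarts` times with seeds
#' `seed + 0 .. n_restarts - 1` and keeps the fit with the best final
#' log-likelihood. The first restart uses the `"pattern"` initialization
#' (anchored at the K most frequent observed mark patterns), the remaining
#' ones the random-`"partition"` strategy; see [init_model()].
#'
#' @inheritParams baum_welch
#' @param K number of states.
#' @param seed base seed.
#' @param n_restarts random restarts (default 3).
#' @return as [baum_welch()], plus `restart_loglik`.
#' @export
learn_model <- function(obs_list, K, seed = 7L, n_restarts = 3L,
                        tol = 1e-4, max_iter = 200L) {
  obs_list <- as_obs_list(obs_list)
  M <- length(obs_list[[1]]$marks)
  fits <- lapply(seq_len(n_restarts) - 1L, function(r) {
    m0 <- init_model(K, M, seed + r, obs_list,
                     strategy = if (r == 0L) "pattern" else "partition")
    baum_welch(m0, obs_list, tol = tol, max_iter = max_iter)
  })
  lls <- vapply(fits, function(f) f$trace[length(f$trace)], numeric(1))
  best <- fits[[which.max(lls)]]
  best$restart_loglik <- lls
  best
}

#' Decode a state path
#'
#' `viterbi` returns a maximum-joint-probability path with ties broken
#' toward the lower state index; `posterior` returns the per-bin argmax of
#' the smoothed marginals (forward-backward posteriors), ties likewise to
#' the lower index.
#'
#' @param model a [state_model()].
#' @param obs an [observation_matrix()].
#' @param method `"viterbi"` or `"posterior"`.
#' @return integer vector of 1-based state indices (empty for empty input).
#' @export
decode <- function(model, obs, method = c("viterbi", "posterior")) {
  validate_state_model(model)
  method <- match.arg(method)
  check_obs(model, obs)
  if (nrow(obs$mat) == 0L) return(integer(0))
  if (method == "viterbi") {
    logB <- emission_probs(model, obs$mat, log = TRUE)
    .viterbi_cpp(log(pmax(model$pi, .Machine$double.xmin)),
                 log(pmax(model$A, .Machine$double.xmin)), logB)
  } else {
    B <- emission_probs(model, obs$mat)
    g <- .fb_cpp(model$pi, model$A, B)$gamma
    max.col(g, ties.method = "first")
  }
}

#' Run-length segmentation of a state path
#'
#' Maximal runs of constant state become 0-based half-open, bin-aligned
#' intervals.
#'
#' @param path integer state path (non-empty).
#' @param bin_size_bp bin width in bp.
#' @param chromosome chromosome name.
#' @return data.frame: chrom, start, end, state.
#' @export
segment_path <- function(path, bin_size_bp, chromosome) {
  if (!length(path)) abort_input("path must be non-empty")
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = chromosome, start = starts * bin_size_bp,
             end = ends * bin_size_bp, state = r$values,
             stringsAsFactors = FALSE)
}

#' Expand a segmentation back to a per-bin path (inverse of
#' [segment_path()]).
#'
#' @param segments data.frame from [segment_path()].
#' @param bin_size_bp bin width in bp.
#' @return integer state path.
#' @export
expand_segments <- function(segments, bin_size_bp) {
  rep(segments$state, (segments$end - segments$start) %/% bin_size_bp)
}

#' Sample observations from a state model
#'
#' Draws a Markov state path and per-bin Bernoulli mark presence — the
#' generative counterpart of the HMM, used for parameter-recovery checks.
#'
#' @param model a [state_model()].
#' @param n_bins sequence length.
#' @param seed integer seed.
#' @param tissue,chromosome identifiers for the returned matrix.
#' @return list: `obs` ([observation_matrix()]), `path` (true states).
#' @export
simulate_observations <- function(model, n_bins, seed, tissue = "sim",
                                  chromosome = "chr1") {
  validate_state_model(model)
  withr::with_seed(seed, {
    path <- sample_markov(n_bins, model$pi, model$A)
    mat <- matrix(rbinom(n_bins * length(model$marks), 1L,
                         model$E[path, ]), n_bins)
    colnames(mat) <- model$marks
    list(obs = observation_matrix(mat, model$marks, tissue, chromosome),
         path = path)
  })
}
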