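## Bayesian ICA by sequential sampling.  The generative model: hidden
## sources are independent Bernoulli(r_s dt) per bin; input neuron i
## spikes in bin k with probability
##   p_i^k = 1 - (1 - r_o dt) prod_mu [1 - q_imu sum_k' phi_k' s_mu^{k-k'}],
## with phi the discretised response kernel.  Exact marginalisation
## over source histories is intractable, so the learner samples the
## joint source state of each bin from its conditional posterior given
## the sampled past, and ascends the resulting stochastic gradient of
## the log-posterior of Q~.

#' Bayesian ICA learner state
#'
#' @param L number of input neurons.
#' @param p number of sources (<= 12; the sampler enumerates 2^p joint
#'   states per bin).
#' @param dt_bin discretisation, ms (default 5).
#' @param theta_t response-kernel timescale, ms.
#' @param nu_S source rate, Hz (prior rate r_s = nu_S * dt).
#' @param r_o baseline input rate, Hz (scalar or length-L).
#' @param eta learning rate of the stochastic gradient (default 0.001;
#'   the posterior normaliser is absorbed here).
#' @param Q0 initial estimate (default uniform 0.2).
#' @param include_current condition p_i^k on the current bin's sample
#'   y^k as well as the past (default TRUE), or on the past only.
#' @return Object of class `"ica_state"` with the discretised kernel
#'   weights `phi` (truncated where the tail mass drops below 1e-6 of
#'   the total).
#' @export
ica_state <- function(L, p, dt_bin = 5, theta_t = 2, nu_S = 10, r_o = 2,
                      eta = 0.001, Q0 = NULL, include_current = TRUE) {
  stopifnot(p >= 1, p <= 12, dt_bin > 0, theta_t > 0)
  kmax <- ceiling(20 * theta_t / dt_bin)
  k <- 0:kmax
  phi <- ((k + 0.5) * dt_bin)^2 * exp(-(k + 0.5) * dt_bin / theta_t) /
    (2 * theta_t^3)
  if (is.null(Q0)) Q0 <- matrix(0.2, L, p)
  stopifnot(nrow(Q0) == L, ncol(Q0) == p)
  r_o <- rep_len(r_o, L)
  structure(list(L = L, p = p, dt_bin = dt_bin, theta_t = theta_t,
                 nu_S = nu_S, r_s_dt = nu_S * dt_bin / 1000,
                 r_o = r_o, ro_dt = r_o * dt_bin / 1000,
                 eta = eta, phi = phi, Q = Q0,
                 include_current = include_current),
            class = "ica_state")
}

#' @export
print.ica_state <- function(x, ...) {
  cat(sprintf("ica_state: L = %d, p = %d, dt = %g ms, |phi| = %d taps, eta = %g\n",
              x$L, x$p, x$dt_bin, length(x$phi), x$eta))
  invisible(x)
}

## kernel sums A_mu = sum_{k'} phi_k' y_mu^{k-k'} for a p x nhist
## history matrix whose last column is the previous bin
kernel_sums <- function(state, y_hist) {
  if (is.null(y_hist) || ncol(y_hist) == 0) return(numeric(state$p))
  nh <- ncol(y_hist)
  kp <- seq_len(min(nh, length(state$phi) - 1))
  as.numeric(y_hist[, nh - kp + 1, drop = FALSE] %*% state$phi[kp + 1])
}

#' Per-neuron spike probability under the generative model
#'
#' @param state an [ica_state()].
#' @param A kernel sums per source (from the sampled history, plus
#'   `phi[1] * y^k` for the current bin if conditioning on it).
#' @param Q response-probability matrix (default the current estimate).
#' @return Vector of probabilities p_i in (0, 1) (guarded away from
#'   exact 0/1).
#' @export
spike_prob <- function(state, A, Q = state$Q) {
  fac <- 1 - sweep(Q, 2, A, "*")
  fac <- pmax(fac, 1e-12)
  p <- 1 - (1 - state$ro_dt) * apply(fac, 1, prod)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Posterior over joint source states for one bin (R reference)
#'
#' Enumerates all 2^p configurations of the current bin's sources and
#' returns their normalised posterior probabilities given the input
#' bin, the sampled history and the sampling matrix Q.  State s is
#' encoded with source mu active iff bit mu of s-1 is set.
#'
#' @param state an [ica_state()].
#' @param x_k 0/1 input vector of length L.
#' @param y_hist p x nhist sampled history (last column = previous
#'   bin), or NULL.
#' @param Q matrix used for the likelihood (true Q in ideal mode).
#' @return Numeric vector of length 2^p summing to 1.
#' @export
sample_step_probs <- function(state, x_k, y_hist = NULL, Q = state$Q) {
  Ah <- kernel_sums(state, y_hist)
  ns <- 2^state$p
  logw <- numeric(ns)
  for (s in 0:(ns - 1)) {
    yk <- as.numeric(bitwAnd(bitwShiftR(s, 0:(state$p - 1)), 1L))
    A <- Ah + state$phi[1] * yk
    pi <- spike_prob(state, A, Q)
    logw[s + 1] <- sum(ifelse(x_k == 1, log(pi), log(1 - pi))) +
      sum(yk * log(state$r_s_dt) + (1 - yk) * log(1 - state$r_s_dt))
  }
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Sample one source configuration (R reference)
#'
#' Draws y^k from [sample_step_probs()].
#'
#' @inheritParams sample_step_probs
#' @return 0/1 vector of length p.
#' @export
sample_step <- function(state, x_k, y_hist = NULL, Q = state$Q) {
  pr <- sample_step_probs(state, x_k, y_hist, Q)
  u <- runif(1) # single draw; cumulative walk in state order
  s <- which(u <= cumsum(pr))[1] - 1L
  as.integer(bitwAnd(bitwShiftR(s, 0:(state$p - 1)), 1L))
}

#' Gradient step on the estimated response matrix (R reference)
#'
#' Delta q_imu = eta * [x_i (1-p_i)/p_i - (1-x_i)] * A_mu / (1 - q_imu
#' A_mu), the stochastic gradient of the log-posterior with the sampled
#' history standing in for the marginalisation; the result is clipped
#' to \[0, 1\].
#'
#' @param state an [ica_state()].
#' @param x_k 0/1 input vector.
#' @param y_hist sampled history including the current bin as last
#'   column if `include_current` is set.
#' @return The state with updated `Q`; the increment is in attribute
#'   `"dQ"`.
#' @export
update_qtilde <- function(state, x_k, y_hist) {
  nh <- ncol(y_hist)
  kp0 <- seq_len(min(nh, length(state$phi)))
  A <- as.numeric(y_hist[, nh - kp0 + 1, drop = FALSE] %*% state$phi[kp0])
  if (!state$include_current) A <- kernel_sums(state, y_hist[, -nh, drop = FALSE])
  p_i <- spike_prob(state, A)
  base <- ifelse(x_k == 1, (1 - p_i) / p_i, -1)
  denom <- pmax(1 - sweep(state$Q, 2, A, "*"), 1e-6)
  dQ <- state$eta * outer(base, A) / denom
  dQ[, A <= 0] <- 0
  state$Q <- pmin(pmax(state$Q + dQ, 0), 1)
  attr(state, "dQ") <- dQ
  state
}

#' STDP-like LTP/LTD curves of the Bayesian ICA rule
#'
#' The potentiation caused by an isolated sampled source event k' bins
#' before an input spike, as a function of the lag k', and the total
#' depression caused when the input neuron stays silent:
#' LTP(k') = (1 - \[r_o^X - r_o^S q\])(1 - q phi_k') / (1 - (1 -
#' \[r_o^X - r_o^S q\])(1 - q phi_k')) * phi_k' / (1 - q phi_k'),
#' LTD = -sum_k' phi_k' / (1 - q phi_k').
#'
#' @param state an [ica_state()].
#' @param q_values weights at which to evaluate (default 0.1, 0.3, 0.5).
#' @param nu_X mean input rate, Hz.
#' @return data.frame with columns q, lag_bin, ltp and attribute
#'   `"ltd"` (named total LTD per q).
#' @export
ltp_ltd_curve <- function(state, q_values = c(0.1, 0.3, 0.5), nu_X = 10) {
  ro_dt <- nu_X * state$dt_bin / 1000
  rs_dt <- state$nu_S * state$dt_bin / 1000
  rows <- list(); ltd <- numeric(length(q_values))
  for (qi in seq_along(q_values)) {
    q <- q_values[qi]
    base <- 1 - (ro_dt - rs_dt * q)   # (1 - [ro^X - ro^S q~]) per printed rule
    noev <- base * (1 - q * state$phi)
    ltp <- noev / (1 - noev) * state$phi / (1 - q * state$phi)
    rows[[qi]] <- data.frame(q = q, lag_bin = seq_along(state$phi) - 1,
                             ltp = ltp)
    ltd[qi] <- -sum(state$phi / (1 - q * state$phi))
  }
  out <- do.call(rbind, rows)
  attr(out, "ltd") <- stats::setNames(ltd, q_values)
  out
}

#' Run the sequential-sampling learner
#'
#' Streams the binned input through the sampler and the gradient rule.
#' In `"ideal"` mode the source states are sampled using the true Q
#' (the ideal observer) while learning still updates the estimate.
#'
#' @param state an [ica_state()].
#' @param x L x K 0/1 matrix of binned input spikes.
#' @param mode `"sampled"` or `"ideal"`.
#' @param Q_true true response matrix (required for ideal mode).
#' @param seed integer seed.
#' @param snap_every snapshot cadence in bins (0 = none).
#' @return List: final `Q`, sampled `Y` (p x K), per-bin `loglik`,
#'   snapshots, and the input `state`.
#' @export
run_learning <- function(state, x, mode = c("sampled", "ideal"),
                         Q_true = NULL, seed = NULL, snap_every = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "ica_state"), nrow(x) == state$L)
  if (mode == "ideal" && is.null(Q_true))
    stop("ideal mode needs Q_true")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ica_run(x, state$Q,
                     if (is.null(Q_true)) state$Q else Q_true,
                     state$phi, mean(state$ro_dt), state$r_s_dt,
                     state$eta, mode == "ideal", state$include_current,
                     as.integer(snap_every))
  res$state <- state
  res$mode <- mode
  res
}

#' Match learned columns to true columns
#'
#' Cosine similarity between each learned column of Q~ and each column
#' of a reference matrix, maximised over source permutations.
#'
#' @param Q_hat,Q_ref L x p matrices.
#' @return List: `perm` (reference column for each learned column),
#'   `cosine` (per-column similarity under the best permutation),
#'   `mean_cosine`, and `max_abs_err` (entrywise, after permutation).
#' @export
match_columns <- function(Q_hat, Q_ref) {
  p <- ncol(Q_hat)
  cosm <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    na <- sqrt(sum(Q_hat[, a]^2)); nb <- sqrt(sum(Q_ref[, b]^2))
    cosm[a, b] <- if (na > 0 && nb > 0) sum(Q_hat[, a] * Q_ref[, b]) / (na * nb) else 0
  }
  perms <- all_permutations(p)
  best <- -Inf; bperm <- perms[[1]]
  for (pm in perms) {
    sc <- mean(cosm[cbind(seq_len(p), pm)])
    if (sc > best) { best <- sc; bperm <- pm }
  }
  list(perm = bperm, cosine = cosm[cbind(seq_len(p), bperm)],
       mean_cosine = best,
       max_abs_err = max(abs(Q_hat - Q_ref[, bperm, drop = FALSE])))
}
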