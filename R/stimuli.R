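## Input-side generators: hidden Bernoulli/Poisson sources, response
## kernels, response-probability matrices Q, rate-modulated Poisson
## input spikes.  Time is in ms internally; rates at the interface are
## in Hz.

#' Source configuration
#'
#' Describes the hidden external sources: how many there are, their
#' event rate, the correlation timescale and the shape of the response
#' kernel with which input neurons respond to each event.
#'
#' @param p number of sources (>= 1).
#' @param nu_S source event rate in Hz (default 10).
#' @param theta_t correlation timescale in ms (default 2).
#' @param kernel `"gamma3"` (gamma of shape 3, the default) or
#'   `"exponential"`.
#' @return An object of class `"source_config"`.
#' @export
source_config <- function(p, nu_S = 10, theta_t = 2, kernel = c("gamma3", "exponential")) {
  kernel <- match.arg(kernel)
  if (p < 1) stop("p must be >= 1")
  if (nu_S < 0) stop("nu_S must be >= 0")
  if (theta_t <= 0) stop("theta_t must be > 0")
  structure(list(p = as.integer(p), nu_S = nu_S, theta_t = theta_t,
                 kernel = kernel),
            class = "source_config")
}

#' @export
print.source_config <- function(x, ...) {
  cat(sprintf("source_config: p = %d, nu_S = %g Hz, theta_t = %g ms, kernel = %s\n",
              x$p, x$nu_S, x$theta_t, x$kernel))
  invisible(x)
}

#' Response kernel of input neurons
#'
#' Unit-area density with which an input neuron's firing rate responds
#' to a single source event.  The default is a gamma kernel of shape 3,
#' phi(t) = t^2 exp(-t/theta) / (2 theta^3), whose autocorrelation
#' reproduces the broad spike correlations seen in cortex; the
#' alternative is the exponential kernel exp(-t/theta)/theta.
#'
#' @param t time since the event, ms (vectorised; must be >= 0).
#' @param theta_t timescale parameter, ms.
#' @param kind `"gamma3"` or `"exponential"`.
#' @return Kernel density values (1/ms).
#' @examples
#' response_kernel(2 * 2, 2)   # mode of the gamma3 kernel is at 2*theta_t
#' @export
response_kernel <- function(t, theta_t, kind = c("gamma3", "exponential")) {
  kind <- match.arg(kind)
  if (theta_t <= 0) stop("theta_t must be > 0")
  if (any(t < 0)) stop("t must be >= 0")
  switch(kind,
    gamma3 = t^2 * exp(-t / theta_t) / (2 * theta_t^3),
    exponential = exp(-t / theta_t) / theta_t)
}

#' Sample source event trains
#'
#' Draws independent Bernoulli(nu_S * dt) event trains for each source
#' on a regular grid, the discrete-time realisation of independent
#' Poisson processes.
#'
#' @param cfg a [source_config()].
#' @param T duration in ms.
#' @param dt bin width in ms (default 0.05).
#' @param seed optional integer seed.
#' @return Integer matrix of 0/1 with `p` rows and `T/dt` columns.
#' @export
sample_source_events <- function(cfg, T, dt = 0.05, seed = NULL) {
  stopifnot(inherits(cfg, "source_config"), T > 0, dt > 0)
  pr <- cfg$nu_S * dt / 1000
  if (pr >= 1) stop("nu_S * dt >= 1: reduce dt")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(T / dt))
  matrix(rbinom(cfg$p * n, 1L, pr), nrow = cfg$p)
}

#' Response-probability matrix
#'
#' Bundles the L x p matrix of response probabilities q_{i,mu} with the
#' per-neuron baseline rates r_i^o = nu_X - sum_mu q_{i,mu} nu_S chosen
#' so that every input neuron fires at nu_X on average regardless of Q.
#'
#' @param Q numeric L x p matrix with entries in \[0, 1\].
#' @param nu_X target mean input rate, Hz (default 10).
#' @param nu_S source event rate, Hz (default 10).
#' @return Object of class `"response_matrix"` with elements `Q`,
#'   `nu_X`, `nu_S` and baseline vector `r_o` (Hz).
#' @export
response_matrix <- function(Q, nu_X = 10, nu_S = 10) {
  Q <- as.matrix(Q)
  if (any(Q < 0 | Q > 1)) stop("all q_{i,mu} must lie in [0, 1]")
  r_o <- nu_X - rowSums(Q) * nu_S
  if (any(r_o < -1e-12))
    stop("configuration needs negative baseline rate r_i^o; ",
         "lower nu_S or the response probabilities")
  r_o <- pmax(r_o, 0)
  structure(list(Q = Q, nu_X = nu_X, nu_S = nu_S, r_o = r_o),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: L = %d input neurons, p = %d sources, nu_X = %g Hz\n",
              nrow(x$Q), ncol(x$Q), x$nu_X))
  invisible(x)
}

#' Build task-specific response matrices
#'
#' Constructs the block response-probability matrices of the standard
#' tasks:
#' \describe{
#'   \item{minor_source}{two disjoint input groups of `La` neurons
#'     responding to sources A and B with probabilities `q_A`, `q_B`;
#'     remaining rows are background (all-zero).}
#'   \item{crosstalk}{two groups responding to their preferred source
#'     with `q_S` and to the other with `q_N` (off-diagonal crosstalk);
#'     remaining rows background.}
#'   \item{four_source}{four groups on a ring, each responding with
#'     `q_S` to its own source and `q_N` to the two ring neighbours.}
#' }
#'
#' @param task one of `"minor_source"`, `"crosstalk"`, `"four_source"`,
#'   `"custom"`.
#' @param L total number of input neurons.
#' @param La neurons per signal group.
#' @param q_A,q_B response probabilities for the minor-source task.
#' @param q_S,q_N preferred/non-preferred probabilities for the
#'   crosstalk and four-source tasks.
#' @param Q custom matrix (only for `task = "custom"`).
#' @param nu_X,nu_S mean input rate and source rate (Hz).
#' @return A [response_matrix()].
#' @examples
#' rm <- build_Q("minor_source", q_A = 0.6, q_B = 0.5)
#' correlation_matrix(rm, by_group = TRUE)
#' @export
build_Q <- function(task = c("minor_source", "crosstalk", "four_source", "custom"),
                    L = 400, La = 100, q_A = 0.6, q_B = 0.5,
                    q_S = 0.6, q_N = 0, Q = NULL, nu_X = 10, nu_S = 10) {
  task <- match.arg(task)
  L <- as.integer(L); La <- as.integer(La)
  ngrp <- switch(task, minor_source = 2L, crosstalk = 2L, four_source = 4L, 0L)
  if (task != "custom" && L < ngrp * La)
    stop("L must be at least ", ngrp, " * La for task ", task)
  Qm <- switch(task,
    minor_source = {
      m <- matrix(0, L, 2)
      m[seq_len(La), 1] <- q_A
      m[La + seq_len(La), 2] <- q_B
      m
    },
    crosstalk = {
      m <- matrix(0, L, 2)
      m[seq_len(La), ] <- rep(c(q_S, q_N), each = La)
      m[La + seq_len(La), ] <- rep(c(q_N, q_S), each = La)
      m
    },
    four_source = {
      m <- matrix(0, L, 4)
      for (g in 1:4) {
        rows <- (g - 1) * La + seq_len(La)
        m[rows, g] <- q_S
        m[rows, 1 + (g %% 4)] <- q_N
        m[rows, 1 + ((g - 2) %% 4)] <- q_N
      }
      m
    },
    custom = {
      if (is.null(Q)) stop("task = 'custom' requires Q")
      as.matrix(Q)
    })
  response_matrix(Qm, nu_X = nu_X, nu_S = nu_S)
}

#' Input correlation-strength matrix C = Q Q^t
#'
#' The zero-lag strength of the input cross-correlation: the full
#' temporal cross-correlation between input neurons i and l is
#' nu_S * C\[i, l\] * h(s), with h the kernel autocorrelation (see
#' [h_closed_form()]).
#'
#' @param Q a [response_matrix()] or a plain numeric matrix.
#' @param by_group if `TRUE` and `Q` has repeated identical rows per
#'   group, returns the matrix of one representative row per unique row
#'   pattern (group-level C); default `FALSE` returns the full L x L
#'   matrix.
#' @return Symmetric positive semidefinite matrix.
#' @export
correlation_matrix <- function(Q, by_group = FALSE) {
  if (inherits(Q, "response_matrix")) Q <- Q$Q
  Q <- as.matrix(Q)
  if (by_group) Q <- unique(Q)
  Q %*% t(Q)
}

## (phi * s)(t) for a sparse 0/1 event row: place the kernel at each
## event bin (events are rare, so this beats FFT/filter by a wide margin).
conv_events <- function(ev, k, n) {
  out <- numeric(n)
  klen <- length(k)
  for (b in which(ev != 0)) {
    j <- b:min(b + klen - 1L, n)
    out[j] <- out[j] + k[seq_along(j)]
  }
  out
}

## Discretised response kernel on the simulation grid, truncated at
## trunc*theta_t with a tail-mass check.
kernel_grid <- function(theta_t, dt, kind = "gamma3", trunc = 20, tol = 1e-6) {
  tmax <- trunc * theta_t
  # analytic tail mass beyond the truncation point
  loss <- switch(kind,
    gamma3 = stats::pgamma(tmax, shape = 3, scale = theta_t,
                           lower.tail = FALSE),
    exponential = exp(-tmax / theta_t))
  if (loss > tol) stop("kernel truncation mass loss ", signif(loss, 3),
                       " exceeds ", tol, "; widen the truncation window")
  response_kernel(seq(0, tmax, by = dt), theta_t, kind)
}

#' Instantaneous input firing rates
#'
#' rate_i(t) = r_i^o + sum_mu q_{i,mu} (phi * s_mu)(t): baseline plus
#' the response kernel convolved with the source event trains.
#'
#' @param rm a [response_matrix()].
#' @param events p x nbins 0/1 matrix from [sample_source_events()].
#' @param cfg the [source_config()] used to generate `events`.
#' @param dt grid step, ms.
#' @param trunc kernel truncation, in multiples of `theta_t`.
#' @return L x nbins matrix of rates in Hz.
#' @export
input_rates <- function(rm, events, cfg, dt = 0.05, trunc = 20) {
  stopifnot(inherits(rm, "response_matrix"), inherits(cfg, "source_config"))
  if (nrow(events) != ncol(rm$Q)) stop("events rows must equal number of sources")
  k <- kernel_grid(cfg$theta_t, dt, cfg$kernel, trunc)
  n <- ncol(events)
  # (phi * s_mu)(t) in 1/ms -> Hz via *1000
  conv <- t(vapply(seq_len(nrow(events)),
                   function(mu) conv_events(events[mu, ], k, n), numeric(n)))
  rm$r_o + (rm$Q %*% conv) * 1000
}

#' Sample input spike trains from rate traces
#'
#' Bernoulli thinning of the rate traces on the grid: each bin spikes
#' with probability rate * dt.  Negative rates are clipped at zero.
#'
#' @param rates L x nbins matrix of rates in Hz.
#' @param dt grid step, ms.
#' @param seed optional integer seed.
#' @return Integer 0/1 matrix of the same shape.
#' @export
sample_input_spikes <- function(rates, dt = 0.05, seed = NULL) {
  pr <- pmax(rates, 0) * dt / 1000
  if (any(pr >= 1)) stop("rate * dt >= 1 in some bin: reduce dt")
  if (!is.null(seed)) set.seed(seed)
  matrix(rbinom(length(pr), 1L, pr), nrow = nrow(rates))
}

#' Generate input spikes for long runs (sparse)
#'
#' Efficient rate-modulated Poisson sampling for long recordings:
#' input neurons sharing a row pattern of (Q, r_o) share a rate trace,
#' so the per-bin spike count of each group is Binomial(group size,
#' rate * dt) and only spiking bins materialise.  Equivalent in
#' distribution to per-neuron Bernoulli thinning of [input_rates()].
#'
#' @param rm a [response_matrix()].
#' @param cfg a [source_config()].
#' @param T duration, ms.
#' @param dt grid step, ms.
#' @param seed integer seed (sources and thinning share one stream).
#' @param events optional pre-drawn p x nbins event matrix; when given,
#'   only the thinning consumes randomness.
#' @return List with `spk` (two-column matrix: neuron index, bin index,
#'   1-based, sorted by bin), `events` (the source event train),
#'   `n_bins`, `dt`.
#' @export
generate_input_spikes <- function(rm, cfg, T, dt = 0.05, seed = NULL,
                                  events = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(T / dt))
  if (is.null(events)) {
    pr <- cfg$nu_S * dt / 1000
    if (pr >= 1) stop("nu_S * dt >= 1: reduce dt")
    events <- matrix(rbinom(cfg$p * n, 1L, pr), nrow = cfg$p)
  }
  k <- kernel_grid(cfg$theta_t, dt, cfg$kernel)
  conv <- t(vapply(seq_len(nrow(events)),
                   function(mu) conv_events(events[mu, ], k, n), numeric(n)))
  # group neurons by identical (Q row, baseline)
  key <- apply(cbind(rm$Q, rm$r_o), 1, paste, collapse = ",")
  out <- vector("list", length(unique(key)))
  ci <- 0L
  for (kk in unique(key)) {
    members <- which(key == kk)
    gsize <- length(members)
    q <- rm$Q[members[1], ]
    rate <- rm$r_o[members[1]] + as.numeric(q %*% conv) * 1000   # Hz
    p_bin <- pmax(rate, 0) * dt / 1000
    if (any(p_bin >= 1)) stop("rate * dt >= 1 in some bin: reduce dt")
    counts <- rbinom(n, gsize, p_bin)
    nz <- which(counts > 0L)
    if (!length(nz)) next
    cnz <- counts[nz]
    bins <- rep.int(nz, cnz)
    ids <- integer(length(bins))
    one <- cnz == 1L
    ids[rep.int(one, cnz)] <- members[sample.int(gsize, sum(one), replace = TRUE)]
    if (any(!one)) {                     # rare multi-spike bins
      pos <- cumsum(cnz) - cnz
      for (b in which(!one))
        ids[pos[b] + seq_len(cnz[b])] <- members[sample.int(gsize, cnz[b])]
    }
    ci <- ci + 1L
    out[[ci]] <- cbind(ids, bins)
  }
  spk <- if (ci) do.call(rbind, out[seq_len(ci)]) else matrix(integer(), 0, 2)
  spk <- spk[order(spk[, 2L], spk[, 1L]), , drop = FALSE]
  colnames(spk) <- c("neuron", "bin")
  list(spk = spk, events = events, n_bins = n, dt = dt)
}

#' Write and read configuration as YAML
#'
#' Round-trips parameter lists and response matrices through a plain
#' YAML file: `default_params()` lists are stored as named scalars, a
#' [response_matrix()] as its Q rows plus rates.
#'
#' @param obj a named list of parameters or a `"response_matrix"`.
#' @param file path.
#' @export
write_config <- function(obj, file) {
  if (inherits(obj, "response_matrix")) {
    obj <- list(type = "response_matrix", nu_X = obj$nu_X, nu_S = obj$nu_S,
                Q = apply(obj$Q, 1, as.numeric, simplify = FALSE))
  }
  yaml::write_yaml(obj, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  obj <- yaml::read_yaml(file)
  if (identical(obj$type, "response_matrix")) {
    Q <- do.call(rbind, obj$Q)
    return(response_matrix(Q, nu_X = obj$nu_X, nu_S = obj$nu_S))
  }
  obj
}
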