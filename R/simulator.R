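## R surface of the clock-driven network engine: configuration
## builders, lateral wiring, the two backends and the PSTH utility.

#' Network configuration
#'
#' Assembles sizes, weight matrices, per-synapse delays (drawn uniform
#' within the configured ranges and rounded to the grid) and PSP time
#' constants for the three connection classes: feedforward X (input ->
#' output, axonal + dendritic delay), lateral excitatory Y (output ->
#' inhibitory, axonal) and feedback inhibitory Z (inhibitory -> output,
#' axonal).
#'
#' The linear Poisson backend draws a spike per bin with probability
#' `gain_E * u * dt` (outputs) / `gain_I * u * dt` (inhibitory), with u
#' the membrane value in per-ms units; `gain_E`, `gain_I` set the
#' operating point of the bare linear gain.
#'
#' @param params parameter list from [default_params()].
#' @param L,M,N layer sizes (defaults from `params`).
#' @param La,Ma,Na subgroup sizes.
#' @param W_X,W_Y,W_Z weight matrices (M x L, N x M, M x N); defaults:
#'   W_X from [init_weights()] would be supplied by the caller, here
#'   constant `wo_X`; W_Y/W_Z structured wiring at `wo_Y`, `wo_Z`.
#' @param lateral `"structured"` or `"random"` wiring for defaults.
#' @param gain_E,gain_I linear gain scale factors.
#' @param seed seed for delay draws (and random wiring).
#' @return Object of class `"network_config"`.
#' @export
network_config <- function(params = default_params(),
                           L = params$L, M = params$M, N = params$N,
                           La = params$La, Ma = params$Ma, Na = params$Na,
                           W_X = NULL, W_Y = NULL, W_Z = NULL,
                           lateral = c("structured", "random"),
                           gain_E = 1e-3, gain_I = 1e-3, seed = NULL) {
  lateral <- match.arg(lateral)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(W_X)) W_X <- matrix(params$wo_X, M, L)
  if (is.null(W_Y) || is.null(W_Z)) {
    wired <- wire_lateral(lateral, M = M, N = N, Ma = Ma, Na = Na,
                          w_Y = params$wo_Y, w_Z = params$wo_Z)
    if (is.null(W_Y)) W_Y <- wired$W_Y
    if (is.null(W_Z)) W_Z <- wired$W_Z
  }
  stopifnot(all(dim(W_X) == c(M, L)), all(dim(W_Y) == c(N, M)),
            all(dim(W_Z) == c(M, N)),
            all(W_X >= 0), all(W_Y >= 0), all(W_Z >= 0))
  dt <- params$dt
  dbins <- function(dmin, dmax, nr, nc)
    matrix(as.integer(round((dmin + (dmax - dmin) * runif(nr * nc)) / dt)),
           nr, nc)
  structure(list(
    params = params, L = L, M = M, N = N, La = La, Ma = Ma, Na = Na,
    W_X = W_X, W_Y = W_Y, W_Z = W_Z,
    dXa = dbins(params$dXa_min, params$dXa_max, M, L),
    dXd = dbins(params$dXd_min, params$dXd_max, M, L),
    dY = dbins(params$dY_min, params$dY_max, N, M),
    dZ = dbins(params$dZ_min, params$dZ_max, M, N),
    gain_E = gain_E, gain_I = gain_I, dt = dt, lateral = lateral),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("network_config: L=%d -> M=%d (outputs) <-> N=%d (inhibitory), %s lateral wiring\n",
              x$L, x$M, x$N, x$lateral))
  invisible(x)
}

#' Lateral wiring
#'
#' Structured mode: E-to-I weights connect each output group to its own
#' inhibitory group (block-diagonal W_Y), and I-to-E weights connect
#' each inhibitory group to the *other* output groups (block-
#' off-diagonal W_Z), so inhibition is mutual between groups.  Random
#' mode: every connection present independently with probability 0.5 at
#' the same weight values.
#'
#' @param mode `"structured"` or `"random"`.
#' @param M,N layer sizes; `Ma`,`Na` subgroup sizes (must divide M, N
#'   with equal group counts).
#' @param w_Y,w_Z connection weights.
#' @param p_connect connection probability for random mode.
#' @param seed optional seed (random mode).
#' @return List with `W_Y` (N x M) and `W_Z` (M x N).
#' @export
wire_lateral <- function(mode = c("structured", "random"), M, N, Ma, Na,
                         w_Y, w_Z, p_connect = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (M %% Ma != 0 || N %% Na != 0 || M / Ma != N / Na)
    stop("group sizes must divide layer sizes with equal group counts")
  gM <- rep(seq_len(M / Ma), each = Ma)   # output-group index
  gN <- rep(seq_len(N / Na), each = Na)
  if (mode == "structured") {
    W_Y <- outer(gN, gM, "==") * w_Y
    W_Z <- outer(gM, gN, "!=") * w_Z
  } else {
    if (!is.null(seed)) set.seed(seed)
    W_Y <- matrix(rbinom(N * M, 1, p_connect), N, M) * w_Y
    W_Z <- matrix(rbinom(M * N, 1, p_connect), M, N) * w_Z
  }
  list(W_Y = W_Y, W_Z = W_Z)
}

## assemble the plasticity spec passed to the engine
engine_rule <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  stopifnot(inherits(cfg, "stdp_config"))
  if (cfg$rule == "log_stdp") {
    list(kind = "log_stdp", eta = cfg$eta, tau_p = cfg$tau_p,
         tau_d = cfg$tau_d, Cp = cfg$Cp, Cd = cfg$Cd, alpha = cfg$alpha,
         beta = cfg$beta, w_o = cfg$w_o, w_max = cfg$w_max,
         sigma = cfg$sigma_stdp)
  } else {
    co <- lateral_window_coefs(cfg$rule, cfg$gamma, cfg$tau_p, cfg$tau_d)
    list(kind = "lateral", eta = cfg$eta, tau_p = cfg$tau_p,
         tau_d = cfg$tau_d, a1 = co[["a1"]], a2 = co[["a2"]],
         b1 = co[["b1"]], b2 = co[["b2"]], w_max = cfg$w_max,
         sigma = cfg$sigma_stdp)
  }
}

run_backend <- function(net, input, T, plasticity, seed, snap_every_ms,
                        record_u, u_every, backend, lif = NULL) {
  stopifnot(inherits(net, "network_config"))
  dt <- net$dt
  n_bins <- if (!is.null(input$n_bins)) input$n_bins else as.integer(round(T / dt))
  spk <- input$spk
  stopifnot(ncol(spk) == 2)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_network(
    as.integer(spk[, 1]), as.integer(spk[, 2]), n_bins, dt,
    net$W_X, net$W_Y, net$W_Z, net$dXa, net$dXd, net$dY, net$dZ,
    c(net$params$tauA_X, net$params$tauB_X),
    c(net$params$tauA_Y, net$params$tauB_Y),
    c(net$params$tauA_Z, net$params$tauB_Z),
    net$gain_E, net$gain_I,
    engine_rule(plasticity$X), engine_rule(plasticity$Y),
    engine_rule(plasticity$Z),
    if (snap_every_ms > 0) as.integer(round(snap_every_ms / dt)) else 0L,
    record_u, as.integer(u_every), backend, lif)
  res$dt <- dt
  res$n_bins <- n_bins
  res$T <- n_bins * dt
  if (res$clamped > 0)
    warning(sprintf("%d spike probabilities were clamped at 1; the gain is too high", res$clamped))
  class(res) <- "spike_record"
  res
}

#' Run the linear Poisson network
#'
#' Clock-driven simulation of the output and lateral layers driven by
#' the given input spikes, with optional plasticity at each connection
#' class.
#'
#' @param net a [network_config()].
#' @param input list with `spk` (two-column matrix: neuron, bin) and
#'   optionally `n_bins`; see [generate_input_spikes()].
#' @param T duration in ms (used when `input$n_bins` is absent).
#' @param plasticity list with optional entries `X`, `Y`, `Z`, each an
#'   [stdp_config()] (absent = static weights).
#' @param seed integer seed.
#' @param snap_every_ms weight-snapshot cadence in simulated ms
#'   (0 = none).
#' @param record_u record output membrane values (every `u_every`-th
#'   bin); memory scales as M x n_bins / u_every.
#' @param u_every membrane recording stride in bins.
#' @return A `"spike_record"`: output/inhibitory spike data frames,
#'   final weights, snapshots, optional membrane trace `u_E`.
#' @export
run_poisson <- function(net, input, T = NULL, plasticity = list(),
                        seed = NULL, snap_every_ms = 1000,
                        record_u = FALSE, u_every = 1L) {
  run_backend(net, input, T, plasticity, seed, snap_every_ms,
              record_u, u_every, backend = 0L)
}

#' Conductance-based LIF parameters
#'
#' @param ... overrides of V_L, V_E, V_I, V_ref, V_th (mV), tau_m_E,
#'   tau_m_I, tau_s_EE, tau_s_EI, tau_s_IE, tau_s_II (ms), r_o_II (Hz),
#'   w_II (conductance jump of the background inhibition).
#' @export
lif_config <- function(...) {
  p <- list(V_L = -70, V_E = 0, V_I = -80, V_ref = -60, V_th = -50,
            tau_m_E = 20, tau_m_I = 10, tau_s_EE = 5, tau_s_EI = 2.5,
            tau_s_IE = 4, tau_s_II = 5, r_o_II = 1000, w_II = 0.005)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown LIF parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (!(p$V_I <= p$V_ref && p$V_ref < p$V_th)) stop("need V_I <= V_ref < V_th")
  p
}

#' Run the conductance-based LIF network
#'
#' Same wiring, delays and plasticity hooks as [run_poisson()], but
#' with conductance-based leaky integrate-and-fire membranes
#' (threshold V_th, reset to V_ref with a 1 ms refractory period,
#' background inhibitory Poisson drive onto the lateral neurons).
#' Fixed-step midpoint integration on the same 0.05 ms grid.
#'
#' @inheritParams run_poisson
#' @param lif parameter list from [lif_config()].
#' @export
run_lif <- function(net, input, T = NULL, plasticity = list(),
                    lif = lif_config(), seed = NULL, snap_every_ms = 1000,
                    record_u = FALSE, u_every = 1L) {
  run_backend(net, input, T, plasticity, seed, snap_every_ms,
              record_u, u_every, backend = 1L, lif = lif)
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("spike_record: T = %.1f s, %d output spikes (%.2f Hz/neuron), %d inhibitory spikes\n",
              x$T / 1000, nrow(x$out_spk),
              nrow(x$out_spk) / (x$T / 1000) / nrow(x$W_X), nrow(x$inh_spk)))
  invisible(x)
}

#' Mean firing rates of a spike record
#'
#' @param rec a `"spike_record"`.
#' @param layer `"output"` or `"inhibitory"`.
#' @param from_ms discard spikes before this time (warm-up).
#' @return Named vector of per-neuron rates in Hz.
#' @export
firing_rates <- function(rec, layer = c("output", "inhibitory"), from_ms = 0) {
  layer <- match.arg(layer)
  spk <- if (layer == "output") rec$out_spk else rec$inh_spk
  n <- if (layer == "output") nrow(rec$W_X) else nrow(rec$W_Y)
  keep <- spk$bin * rec$dt > from_ms
  counts <- tabulate(spk$neuron[keep], nbins = n)
  counts / ((rec$T - from_ms) / 1000)
}

#' Peristimulus time histogram
#'
#' Event-aligned average of one or more traces sampled on a regular
#' grid: for each event time the surrounding window is extracted and
#' averaged across events.
#'
#' @param trace numeric vector or matrix (rows = traces, columns =
#'   grid bins).
#' @param event_bins event positions (bin indices, 1-based).
#' @param window c(before, after) in bins.
#' @return Matrix (rows = traces) with `before + after + 1` columns;
#'   attribute `"lag_bins"` gives the lag axis.
#' @export
psth <- function(trace, event_bins, window = c(100, 400)) {
  if (is.null(dim(trace))) trace <- matrix(trace, nrow = 1)
  if (length(event_bins) < 1) stop("need at least one event")
  nb <- ncol(trace)
  lags <- -window[1]:window[2]
  keep <- event_bins + min(lags) >= 1 & event_bins + max(lags) <= nb
  ev <- event_bins[keep]
  if (!length(ev)) stop("no events with a complete window")
  out <- matrix(0, nrow(trace), length(lags))
  for (e in ev) out <- out + trace[, e + lags, drop = FALSE]
  out <- out / length(ev)
  attr(out, "lag_bins") <- lags
  out
}

#' Write and read spike trains as two-column text
#'
#' Plain whitespace-delimited text with columns `neuron` and `time_ms`.
#'
#' @param spk a `"spike_record"` (its output layer), or a two-column
#'   matrix/data.frame of (neuron, bin).
#' @param file path.
#' @param dt grid step used to convert bins to ms (taken from the
#'   record when available).
#' @export
write_spikes <- function(spk, file, dt = 0.05) {
  if (inherits(spk, "spike_record")) { dt <- spk$dt; spk <- spk$out_spk }
  df <- data.frame(neuron = as.integer(spk[, 1]),
                   time_ms = as.numeric(spk[, 2]) * dt)
  utils::write.table(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(file) {
  utils::read.table(file, header = TRUE)
}
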