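## End-to-end experiment drivers: reproducible presets binding
## stimuli -> simulator -> plasticity -> metrics.  Every preset exists
## at desk scale (minutes on one CPU); the full-scale settings follow
## the standing parameter table.

#' Random initial weights
#'
#' w = w_o (1 + sigma zeta) with standard-normal zeta, clipped at 0.
#'
#' @param w_o reference weight.
#' @param nrow,ncol matrix dimensions.
#' @param sigma relative spread (default 0.1).
#' @param seed optional seed.
#' @export
init_weights <- function(w_o, nrow, ncol, sigma = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pmax(matrix(w_o * (1 + sigma * rnorm(nrow * ncol)), nrow, ncol), 0)
}

#' Random synaptic delays
#'
#' Uniform on \[d_min, d_max\] (ms).
#'
#' @param d_min,d_max delay range, ms.
#' @param nrow,ncol matrix dimensions.
#' @param seed optional seed.
#' @export
init_delays <- function(d_min, d_max, nrow, ncol, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(d_min + (d_max - d_min) * runif(nrow * ncol), nrow, ncol)
}

#' Experiment presets
#'
#' Returns a fully-specified experiment: stimulus task, network sizes,
#' lateral wiring and strength, gains, plasticity, duration.  Desk
#' scale shortens the duration and (for some presets) the layers so a
#' run stays within minutes; the conditions themselves (rates,
#' response probabilities, STDP constants) are unchanged.
#'
#' Available presets:
#' \describe{
#'   \item{minor_source}{two sources q_A = 0.6, q_B = 0.5,
#'     structured strong lateral inhibition, feedforward log-STDP.}
#'   \item{weak_inhibition}{same with weak inhibitory weights.}
#'   \item{crosstalk_noise}{crosstalk or random noise at a chosen
#'     correlation timescale.}
#'   \item{lateral_stdp}{plastic lateral connections (Hebbian
#'     E-to-I and I-to-E) from random wiring.}
#'   \item{anti_hebbian}{minor-source task with anti-Hebbian
#'     I-to-E STDP.}
#' }
#'
#' @param name preset name.
#' @param scale `"desk"` or `"full"`.
#' @param seed integer seed.
#' @param ... overrides (e.g. `T_ms`, `q_B`, `theta_t`, `w_Z`,
#'   `r_noise`, `q_N`, `rule_Z`).
#' @return Object of class `"experiment_spec"`.
#' @export
experiment_preset <- function(name = c("minor_source",
                                       "weak_inhibition",
                                       "crosstalk_noise", "lateral_stdp",
                                       "anti_hebbian"),
                              scale = c("desk", "full"), seed = 1, ...) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  base <- list(
    name = name, scale = scale, seed = seed,
    params = default_params(),
    task = "minor_source", q_A = 0.6, q_B = 0.5, q_S = 0.6, q_N = 0,
    r_noise = NULL,                 # override of the background rate
    L = 400, La = 100,
    M = 20, N = 20, Ma = 10, Na = 10,
    T_ms = if (desk) 600e3 else 3000e3,
    gain_E = 1e-3, gain_I = 1e-3,
    lateral = "structured", w_Y = 100, w_Z = 50,
    plastic_X = TRUE, rule_Y = NULL, rule_Z = NULL,
    snap_every_ms = 10e3)
  ov <- switch(name,
    minor_source = list(),
    weak_inhibition = list(w_Z = 5, T_ms = if (desk) 300e3 else 3000e3),
    crosstalk_noise = list(task = "crosstalk", q_N = 0.2),
    lateral_stdp = list(lateral = "random", rule_Y = "hebbian",
                             rule_Z = "hebbian"),
    anti_hebbian = list(rule_Z = "anti_hebbian"))
  spec <- modifyList(base, ov)
  dots <- list(...)
  spec_keys <- intersect(names(dots), names(spec))
  par_keys <- setdiff(intersect(names(dots), names(spec$params)), spec_keys)
  if (length(par_keys))
    spec$params <- modifyList(spec$params, dots[par_keys])
  dots <- dots[setdiff(names(dots), par_keys)]
  if (length(dots)) {
    bad <- setdiff(names(dots), names(spec))
    if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
    spec <- modifyList(spec, dots)
  }
  # keep the parameter table consistent with the spec-level sizes
  spec$params <- modifyList(spec$params,
                            spec[c("L", "La", "M", "N", "Ma", "Na")])
  structure(spec, class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("experiment_spec '%s' (%s scale): L=%d, M=%d, T=%.0f s, seed=%d\n",
              x$name, x$scale, x$L, x$M, x$T_ms / 1000, x$seed))
  invisible(x)
}

#' Run an experiment preset
#'
#' Generates the stimulus, builds the network, runs the Poisson
#' backend with the preset's plasticity, and computes the summary
#' metrics (group-mean weights, specialisation index, delay-optimised
#' cross-correlation, mutual information).
#'
#' @param spec an [experiment_preset()].
#' @param record_u record output membranes (memory-heavy; default
#'   FALSE).
#' @return List with the spike record, the input description, metrics
#'   and the spec.
#' @export
run_experiment <- function(spec, record_u = FALSE) {
  p <- spec$params
  set.seed(spec$seed)
  ngrp <- if (spec$task == "four_source") 4L else 2L
  rmx <- if (spec$task == "minor_source")
    build_Q("minor_source", L = spec$L, La = spec$La,
            q_A = spec$q_A, q_B = spec$q_B,
            nu_X = p$nu_X, nu_S = p$nu_S)
  else
    build_Q(spec$task, L = spec$L, La = spec$La, q_S = spec$q_S,
            q_N = spec$q_N, nu_X = p$nu_X, nu_S = p$nu_S)
  if (!is.null(spec$r_noise)) rmx$r_o[] <- spec$r_noise
  cfg <- source_config(ngrp, nu_S = p$nu_S, theta_t = p$theta_t,
                       kernel = p$kernel)
  input <- generate_input_spikes(rmx, cfg, spec$T_ms, dt = p$dt)

  pars2 <- modifyList(p, list(L = spec$L, La = spec$La, M = spec$M,
                              N = spec$N, Ma = spec$Ma, Na = spec$Na,
                              wo_Y = spec$w_Y, wo_Z = spec$w_Z))
  W_X <- init_weights(p$wo_X, spec$M, spec$L, p$sigma_W_init)
  lat_wo <- list(w_Y = spec$w_Y, w_Z = spec$w_Z)
  plastic_lat <- !is.null(spec$rule_Y) || !is.null(spec$rule_Z)
  if (plastic_lat) { lat_wo$w_Y <- spec$w_Y / 2; lat_wo$w_Z <- spec$w_Z / 2 }
  wiring <- wire_lateral(spec$lateral, M = spec$M, N = spec$N,
                         Ma = spec$Ma, Na = spec$Na,
                         w_Y = lat_wo$w_Y, w_Z = lat_wo$w_Z)
  if (plastic_lat && spec$lateral == "random") {
    # plastic lateral runs start from dense connectivity at w_o/2
    wiring$W_Y <- matrix(lat_wo$w_Y, spec$N, spec$M)
    wiring$W_Z <- matrix(lat_wo$w_Z, spec$M, spec$N)
  }
  net <- network_config(pars2, L = spec$L, M = spec$M, N = spec$N,
                        La = spec$La, Ma = spec$Ma, Na = spec$Na,
                        W_X = W_X, W_Y = wiring$W_Y, W_Z = wiring$W_Z,
                        gain_E = spec$gain_E, gain_I = spec$gain_I)
  plas <- list()
  if (isTRUE(spec$plastic_X))
    plas$X <- stdp_config("log_stdp", eta = p$eta_X, tau_p = p$tau_p,
                          tau_d = p$tau_d, Cp = p$Cp, alpha = p$alpha,
                          beta = p$beta, sigma_stdp = p$sigma_stdp,
                          w_o = p$wo_X, w_max = p$wX_max)
  if (!is.null(spec$rule_Y))
    plas$Y <- stdp_config(spec$rule_Y, eta = 0.3 * p$eta_X * (spec$w_Y / 2) / p$wo_X,
                          tau_p = p$tauY_p, tau_d = p$tauY_d,
                          gamma = p$gamma_Y, w_max = p$wY_max)
  if (!is.null(spec$rule_Z))
    plas$Z <- stdp_config(spec$rule_Z, eta = 0.3 * p$eta_X * (spec$w_Z / 2) / p$wo_X,
                          tau_p = p$tauZ_p, tau_d = p$tauZ_d,
                          gamma = p$gamma_Z, w_max = p$wZ_max)

  rec <- run_poisson(net, input, plasticity = plas,
                     snap_every_ms = spec$snap_every_ms,
                     record_u = record_u)

  metrics <- experiment_metrics(rec, input, spec)
  list(record = rec, input = input, metrics = metrics, net = net,
       spec = spec)
}

#' Summary metrics of a finished run
#'
#' Group-mean feedforward weights per output group, the specialisation
#' index, and source/output cross-correlation and mutual information
#' over the post-warm-up window.
#'
#' @param rec spike record from [run_poisson()].
#' @param input input description from [generate_input_spikes()].
#' @param spec the experiment spec.
#' @param warmup_ms warm-up excluded from the activity metrics.
#' @param tau_D readout delay for the cross-correlation, ms.
#' @export
experiment_metrics <- function(rec, input, spec, warmup_ms = 60e3,
                               tau_D = 14) {
  warmup_ms <- min(warmup_ms, rec$T / 4)
  grpA <- seq_len(spec$La)
  grpB <- spec$La + seq_len(spec$La)
  out_g1 <- seq_len(spec$Ma)
  out_g2 <- spec$Ma + seq_len(spec$Ma)
  W <- rec$W_X
  w1A <- mean(W[out_g1, grpA]); w1B <- mean(W[out_g1, grpB])
  w2A <- mean(W[out_g2, grpA]); w2B <- mean(W[out_g2, grpB])
  wsi <- specialization_index(w1A, w1B, w2A, w2B)
  # activity metrics on 10 ms bins after warm-up
  keep_from <- ceiling(warmup_ms / rec$dt)
  ev <- input$events
  nb <- rec$n_bins - keep_from
  src_spk <- which(ev != 0, arr.ind = TRUE)
  src <- cbind(src_spk[, 1], src_spk[, 2] - keep_from)
  sb <- bin_spikes(src[src[, 2] >= 1, , drop = FALSE], nb, rec$dt,
                   as.list(seq_len(nrow(ev))))
  osel <- rec$out_spk$bin > keep_from
  ob <- bin_spikes(cbind(rec$out_spk$neuron[osel],
                         rec$out_spk$bin[osel] - keep_from),
                   nb, rec$dt, list(out_g1, out_g2))
  cc <- cross_correlation(sb[1:2, , drop = FALSE], ob, tau_D = tau_D)
  mi <- mutual_information(sb[1:2, , drop = FALSE], ob)
  list(w_group = c(w1A = w1A, w1B = w1B, w2A = w2A, w2B = w2B),
       w_SI = wsi, cross_correlation = as.numeric(cc),
       cc_perm = attr(cc, "perm"), mutual_information = mi,
       rate_out = mean(firing_rates(rec, "output", from_ms = warmup_ms)),
       rate_inh = mean(firing_rates(rec, "inhibitory", from_ms = warmup_ms)))
}
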