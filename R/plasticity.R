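## STDP rules.  Pairwise log-STDP at feedforward synapses; Hebbian,
## anti-Hebbian and (anti-)correlation-detector STDP at lateral
## synapses.  The R implementations here are the reference used by the
## analytic layer and the tests; the compiled simulator applies the
## same rules online.

#' STDP rule configuration
#'
#' @param rule one of `"log_stdp"`, `"hebbian"`, `"anti_hebbian"`,
#'   `"corr_detector"`, `"anti_corr_detector"`.
#' @param eta learning rate.
#' @param tau_p,tau_d LTP/LTD time constants, ms.
#' @param Cp LTP amplitude (log-STDP).
#' @param Cd LTD amplitude; default `Cp * tau_p / tau_d`, which balances
#'   total LTP and LTD around the reference weight.
#' @param alpha,beta log-STDP shape parameters (LTD log steepness,
#'   LTP soft-bound scale).
#' @param sigma_stdp multiplicative noise SD (0 disables noise).
#' @param gamma LTD/LTP balance factor for the lateral rules.
#' @param w_o reference weight.
#' @param w_min,w_max hard weight bounds.
#' @return Object of class `"stdp_config"`.
#' @export
stdp_config <- function(rule = c("log_stdp", "hebbian", "anti_hebbian",
                                 "corr_detector", "anti_corr_detector"),
                        eta = 0.125, tau_p = 17, tau_d = 34,
                        Cp = 1, Cd = Cp * tau_p / tau_d,
                        alpha = 20, beta = 50, sigma_stdp = 0,
                        gamma = 1, w_o = 2.5, w_min = 0, w_max = 25) {
  rule <- match.arg(rule)
  stopifnot(tau_p > 0, tau_d > 0, eta > 0, w_max > w_min)
  structure(list(rule = rule, eta = eta, tau_p = tau_p, tau_d = tau_d,
                 Cp = Cp, Cd = Cd, alpha = alpha, beta = beta,
                 sigma_stdp = sigma_stdp, gamma = gamma, w_o = w_o,
                 w_min = w_min, w_max = w_max),
            class = "stdp_config")
}

#' log-STDP LTP amplitude
#'
#' f_p(w) = Cp (1 + sigma xi) exp(-w / (beta w_o)): near-constant LTP
#' with a soft exponential bound at large weights.
#'
#' @param w current weight (>= 0, vectorised).
#' @param w_o reference weight.
#' @param beta soft-bound scale.
#' @param Cp amplitude.
#' @param xi standard-normal noise draw (0 for the deterministic value).
#' @param sigma noise SD.
#' @export
log_stdp_fp <- function(w, w_o = 2.5, beta = 50, Cp = 1, xi = 0, sigma = 0) {
  Cp * (1 + sigma * xi) * exp(-w / (beta * w_o))
}

#' log-STDP LTD amplitude (negative)
#'
#' f_d(w) = -Cd (1 + sigma xi) log(1 + alpha w / w_o) / log(1 + alpha):
#' LTD grows logarithmically with the weight, giving long-tailed weight
#' distributions.  Equals -Cd at w = w_o.
#'
#' @inheritParams log_stdp_fp
#' @param alpha log steepness.
#' @param Cd amplitude.
#' @export
log_stdp_fd <- function(w, w_o = 2.5, alpha = 20, Cd = 0.5, xi = 0, sigma = 0) {
  -Cd * (1 + sigma * xi) * log(1 + alpha * w / w_o) / log(1 + alpha)
}

## Branch coefficients of the weight-independent lateral windows.
## Window value: dt = t_post - t_pre.
##   dt > 0 : a1 exp(-dt/tau_p) + a2 exp(-dt/tau_d)
##   dt < 0 : b1 exp(-|dt|/tau_p) + b2 exp(-|dt|/tau_d)
lateral_window_coefs <- function(rule, gamma, tau_p, tau_d) {
  co <- switch(rule,
    hebbian            = c(a1 = 1, a2 = 0, b1 = 0, b2 = -gamma * tau_p / tau_d),
    anti_hebbian       = c(a1 = 0, a2 = -1, b1 = gamma * tau_d / tau_p, b2 = 0),
    corr_detector      = c(a1 = 1, a2 = -tau_p / tau_d,
                           b1 = gamma, b2 = -gamma * tau_p / tau_d),
    anti_corr_detector = -c(a1 = 1, a2 = -tau_p / tau_d,
                            b1 = gamma, b2 = -gamma * tau_p / tau_d),
    stop("unknown lateral rule: ", rule))
  names(co) <- c("a1", "a2", "b1", "b2")
  co
}

#' STDP window function F(w, s)
#'
#' The pairing window as a function of the at-synapse lag
#' s = t_post - t_pre: for the feedforward log-STDP rule,
#' F(s) = eta f_p(w) exp(-s/tau_p) for s >= 0 and
#' eta f_d(w) exp(s/tau_d) for s < 0 (ties fall on the LTP branch);
#' for the lateral rules the weight-independent branch sums.
#'
#' @param s lag(s), ms (vectorised).
#' @param cfg an [stdp_config()].
#' @param w synaptic weight (log-STDP only).
#' @return Window values (weight change per pairing).
#' @export
stdp_window <- function(s, cfg, w = cfg$w_o) {
  if (cfg$rule == "log_stdp") {
    fp <- log_stdp_fp(w, cfg$w_o, cfg$beta, cfg$Cp)
    fd <- log_stdp_fd(w, cfg$w_o, cfg$alpha, cfg$Cd)
    out <- ifelse(s >= 0, fp * exp(-s / cfg$tau_p), fd * exp(s / cfg$tau_d))
  } else {
    co <- lateral_window_coefs(cfg$rule, cfg$gamma, cfg$tau_p, cfg$tau_d)
    out <- ifelse(s >= 0,
                  co["a1"] * exp(-s / cfg$tau_p) + co["a2"] * exp(-s / cfg$tau_d),
                  co["b1"] * exp(s / cfg$tau_p) + co["b2"] * exp(s / cfg$tau_d))
  }
  cfg$eta * out
}

#' Window integral of the STDP rule
#'
#' F-bar(w) = integral of F(w, s) ds = eta (f_p tau_p + f_d tau_d),
#' the rate-driven (correlation-independent) drift per pre-post spike
#' pair; negative beyond the weight where LTD outweighs LTP.
#'
#' @param w weight (vectorised).
#' @param cfg an [stdp_config()].
#' @export
stdp_window_integral <- function(w, cfg) {
  if (cfg$rule == "log_stdp") {
    cfg$eta * (log_stdp_fp(w, cfg$w_o, cfg$beta, cfg$Cp) * cfg$tau_p +
               log_stdp_fd(w, cfg$w_o, cfg$alpha, cfg$Cd) * cfg$tau_d)
  } else {
    co <- lateral_window_coefs(cfg$rule, cfg$gamma, cfg$tau_p, cfg$tau_d)
    cfg$eta * ((co[["a1"]] + co[["b1"]]) * cfg$tau_p +
               (co[["a2"]] + co[["b2"]]) * cfg$tau_d)
  }
}

#' Apply pairwise STDP to one synapse (online traces)
#'
#' All-pairs pairwise STDP via online pre/post exponential traces,
#' mathematically identical to summing over every spike pair for
#' exponential windows.  Spike times must already include the
#' axonal/dendritic shifts (t_pre + d_a, t_post + d_d); simultaneous
#' at-synapse spikes pair on the LTP branch.
#'
#' @param pre,post at-synapse spike times, ms (each sorted or not).
#' @param cfg an [stdp_config()].
#' @param w initial weight.
#' @param sequential if `TRUE` (default) the weight evolves (and is
#'   clipped) update by update; if `FALSE` all amplitudes are evaluated
#'   at the initial weight and summed, matching a brute-force all-pairs
#'   sum exactly.
#' @param seed optional seed for the multiplicative noise draws.
#' @return List with `w` (final weight) and `dw` (total change).
#' @export
pair_update <- function(pre, post, cfg, w, sequential = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pre <- sort(pre); post <- sort(post)
  ## merged event stream; at ties pre is processed first so that the
  ## tied pair is seen by the LTP branch only
  ev_t <- c(pre, post)
  ev_is_post <- c(rep(FALSE, length(pre)), rep(TRUE, length(post)))
  o <- order(ev_t, ev_is_post)
  ev_t <- ev_t[o]; ev_is_post <- ev_is_post[o]
  # traces: pre decaying with tau_p (read by LTP) and tau_d is not
  # needed for log_stdp; lateral rules need both taus on both sides
  tr_pre_p <- 0; tr_pre_d <- 0; tr_post_p <- 0; tr_post_d <- 0
  t_last <- -Inf
  w0 <- w; dw_fixed <- 0
  lat <- cfg$rule != "log_stdp"
  if (lat) co <- lateral_window_coefs(cfg$rule, cfg$gamma, cfg$tau_p, cfg$tau_d)
  draw_noise <- function() {
    if (cfg$sigma_stdp > 0) {
      xi <- rnorm(1)
      xi <- max(min(xi, 1 / cfg$sigma_stdp), -1 / cfg$sigma_stdp)
      1 + cfg$sigma_stdp * xi
    } else 1
  }
  for (k in seq_along(ev_t)) {
    if (is.finite(t_last)) {
      dtk <- ev_t[k] - t_last
      dp <- exp(-dtk / cfg$tau_p); dd <- exp(-dtk / cfg$tau_d)
      tr_pre_p <- tr_pre_p * dp; tr_pre_d <- tr_pre_d * dd
      tr_post_p <- tr_post_p * dp; tr_post_d <- tr_post_d * dd
    }
    t_last <- ev_t[k]
    wcur <- if (sequential) w else w0
    if (!ev_is_post[k]) {
      ## presynaptic arrival: LTD against past post spikes
      if (lat) {
        upd <- cfg$eta * (co[["b1"]] * tr_post_p + co[["b2"]] * tr_post_d) *
          draw_noise()
      } else {
        upd <- cfg$eta * log_stdp_fd(wcur, cfg$w_o, cfg$alpha, cfg$Cd) *
          tr_post_d * draw_noise()
      }
      tr_pre_p <- tr_pre_p + 1; tr_pre_d <- tr_pre_d + 1
    } else {
      ## postsynaptic arrival: LTP against past (and tied) pre spikes
      if (lat) {
        upd <- cfg$eta * (co[["a1"]] * tr_pre_p + co[["a2"]] * tr_pre_d) *
          draw_noise()
      } else {
        upd <- cfg$eta * log_stdp_fp(wcur, cfg$w_o, cfg$beta, cfg$Cp) *
          tr_pre_p * draw_noise()
      }
      tr_post_p <- tr_post_p + 1; tr_post_d <- tr_post_d + 1
    }
    if (sequential) {
      w <- min(max(w + upd, cfg$w_min), cfg$w_max)
    } else {
      dw_fixed <- dw_fixed + upd
    }
  }
  if (sequential) list(w = w, dw = w - w0)
  else list(w = min(max(w0 + dw_fixed, cfg$w_min), cfg$w_max), dw = dw_fixed)
}

#' Lateral STDP weight change
#'
#' Convenience wrapper of [pair_update()] for the weight-independent
#' lateral rules (`hebbian`, `anti_hebbian`, `corr_detector`,
#' `anti_corr_detector`).
#'
#' @inheritParams pair_update
#' @export
lateral_stdp_update <- function(pre, post, cfg, w, sequential = TRUE,
                                seed = NULL) {
  if (cfg$rule == "log_stdp")
    stop("lateral_stdp_update expects a weight-independent lateral rule")
  pair_update(pre, post, cfg, w, sequential = sequential, seed = seed)
}
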