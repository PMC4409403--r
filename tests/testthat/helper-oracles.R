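# Independent oracles used across the suite.

# brute-force all-pairs STDP: sum the window over every (pre, post)
# pair at the initial weight (no sequential weight evolution)
brute_force_pairs <- function(pre, post, cfg, w) {
  dw <- 0
  for (tp in pre) for (tq in post) {
    s <- tq - tp                       # ties pair on the LTP branch
    dw <- dw + stdp_window(s, cfg, w)
  }
  dw
}

# Monte-Carlo estimators of the correlation-kernel coefficients.
# Lags are sampled from the (normalised) kernel densities: a
# double-exponential PSP is the sum of two exponentials, the gamma3
# autocorrelation h is the difference of two Gamma(3, theta) draws.
mc_sample_epsp <- function(n, tauA, tauB) rexp(n, 1 / tauA) + rexp(n, 1 / tauB)

mc_sample_h <- function(n, theta_t, kernel = "gamma3") {
  if (kernel == "gamma3")
    rgamma(n, 3, scale = theta_t) - rgamma(n, 3, scale = theta_t)
  else
    rexp(n, 1 / theta_t) - rexp(n, 1 / theta_t)
}

# G1X(w) = fp tau_p E[h(r - s + 2 dXd)] + fd tau_d E[h(r + s + 2 dXd)]
# with r ~ epsX, s ~ Exp(tau_p) resp. Exp(tau_d); evaluating h at the
# sampled lag integrates the remaining density in closed form.
mc_G1X <- function(w, p, n = 2e5) {
  dXd <- (p$dXd_min + p$dXd_max) / 2
  Cd <- p$Cp * p$tau_p / p$tau_d
  fp <- log_stdp_fp(w, p$wo_X, p$beta, p$Cp)
  fd <- log_stdp_fd(w, p$wo_X, p$alpha, Cd)
  r <- mc_sample_epsp(n, p$tauA_X, p$tauB_X)
  sp <- rexp(n, 1 / p$tau_p); sd_ <- rexp(n, 1 / p$tau_d)
  ltp <- h_closed_form(r - sp + 2 * dXd, p$theta_t, p$kernel)
  ltd <- h_closed_form(r + sd_ + 2 * dXd, p$theta_t, p$kernel)
  est <- p$eta_X * (fp * p$tau_p * mean(ltp) + fd * p$tau_d * mean(ltd))
  se <- p$eta_X * sqrt((fp * p$tau_p)^2 * var(ltp) +
                       (fd * p$tau_d)^2 * var(ltd)) / sqrt(n)
  list(est = est, se = se)
}

mc_G2X <- function(w, p, n = 2e5) {
  D <- (p$dXd_min + p$dXd_max) + (p$dY_min + p$dY_max) / 2 +
    (p$dZ_min + p$dZ_max) / 2
  Cd <- p$Cp * p$tau_p / p$tau_d
  fp <- log_stdp_fp(w, p$wo_X, p$beta, p$Cp)
  fd <- log_stdp_fd(w, p$wo_X, p$alpha, Cd)
  r <- mc_sample_epsp(n, p$tauA_X, p$tauB_X) +
       mc_sample_epsp(n, p$tauA_Y, p$tauB_Y) +
       mc_sample_epsp(n, p$tauA_Z, p$tauB_Z)
  sp <- rexp(n, 1 / p$tau_p); sd_ <- rexp(n, 1 / p$tau_d)
  ltp <- h_closed_form(r - sp + D, p$theta_t, p$kernel)
  ltd <- h_closed_form(r + sd_ + D, p$theta_t, p$kernel)
  est <- p$eta_X * (fp * p$tau_p * mean(ltp) + fd * p$tau_d * mean(ltd))
  se <- p$eta_X * sqrt((fp * p$tau_p)^2 * var(ltp) +
                       (fd * p$tau_d)^2 * var(ltd)) / sqrt(n)
  list(est = est, se = se)
}

# lateral coefficients: g1Y integrand h(u + r' - s - r), g1Z integrand
# h(r - s - u - r' - dY - dZ), with r, r' ~ epsX, u ~ epsY and the
# branch-decomposed lateral window
mc_lateral <- function(cfg, p, which = c("Y", "Z"), n = 2e5) {
  which <- match.arg(which)
  co <- corrspike:::lateral_window_coefs(cfg$rule, cfg$gamma, cfg$tau_p, cfg$tau_d)
  r <- mc_sample_epsp(n, p$tauA_X, p$tauB_X)
  rp <- mc_sample_epsp(n, p$tauA_X, p$tauB_X)
  u <- mc_sample_epsp(n, p$tauA_Y, p$tauB_Y)
  dYZ <- (p$dY_min + p$dY_max) / 2 + (p$dZ_min + p$dZ_max) / 2
  base <- if (which == "Y") u + rp - r else r - u - rp - dYZ
  sp <- rexp(n, 1 / cfg$tau_p); sd_ <- rexp(n, 1 / cfg$tau_d)
  terms <- rbind(
    c(co[["a1"]], cfg$tau_p), c(co[["a2"]], cfg$tau_d),   # s >= 0: h(base - s)
    c(co[["b1"]], cfg$tau_p), c(co[["b2"]], cfg$tau_d))   # s < 0:  h(base + s)
  svals <- list(sp, sd_, sp, sd_)
  signs <- c(-1, -1, 1, 1)
  est <- 0; v <- 0
  for (i in 1:4) {
    if (terms[i, 1] == 0) next
    hv <- h_closed_form(base + signs[i] * svals[[i]], p$theta_t, p$kernel)
    est <- est + cfg$eta * terms[i, 1] * terms[i, 2] * mean(hv)
    v <- v + (cfg$eta * terms[i, 1] * terms[i, 2])^2 * var(hv)
  }
  list(est = est, se = sqrt(v / n))
}
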