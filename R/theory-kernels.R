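## Analytic layer, part 1: closed-form input correlation h, PSP
## kernels, and the correlation-kernel coefficients G1X, G2X (feed-
## forward) and g1Y, g1Z (lateral), computed by grid quadrature with
## FFT convolutions.  Internal units: ms and per-ms rates.

#' Closed-form input correlation density h
#'
#' Autocorrelation of the response kernel: the temporal cross-
#' correlation between two input neurons sharing sources is
#' nu_S * sum_mu q_i q_l * h(tau).  For the gamma3 kernel,
#' h(tau) = (tau^2 + 3 theta |tau| + 3 theta^2) exp(-|tau|/theta) /
#' (16 theta^3); for the exponential kernel,
#' h_e(tau) = exp(-|tau|/theta) / (2 theta).  Symmetric with unit
#' integral.
#'
#' @param tau lag(s), ms.
#' @param theta_t correlation timescale, ms.
#' @param kernel `"gamma3"` or `"exponential"`.
#' @export
h_closed_form <- function(tau, theta_t, kernel = c("gamma3", "exponential")) {
  kernel <- match.arg(kernel)
  a <- abs(tau)
  switch(kernel,
    gamma3 = (a^2 + 3 * theta_t * a + 3 * theta_t^2) *
      exp(-a / theta_t) / (16 * theta_t^3),
    exponential = exp(-a / theta_t) / (2 * theta_t))
}

#' Double-exponential PSP kernel
#'
#' epsilon(r) = (exp(-r/tauA) - exp(-r/tauB)) / (tauA - tauB), the
#' unit-area EPSP/IPSP shape; zero at r = 0, peaking at
#' r* = tauA tauB / (tauA - tauB) * log(tauA / tauB).
#'
#' @param r times, ms (values at r < 0 are 0).
#' @param tauA,tauB decay and rise time constants, ms (tauA != tauB).
#' @export
epsp_kernel <- function(r, tauA, tauB) {
  if (tauA <= 0 || tauB <= 0) stop("time constants must be > 0")
  if (tauA == tauB) stop("tauA must differ from tauB")
  ifelse(r >= 0, (exp(-r / tauA) - exp(-r / tauB)) / (tauA - tauB), 0)
}

#' @rdname epsp_kernel
#' @export
epsp_peak_time <- function(tauA, tauB) {
  tauA * tauB / (tauA - tauB) * log(tauA / tauB)
}

## ---- grid-function toolkit ------------------------------------------------
## A grid function is list(t0, dt, v): values v[k] at t0 + (k-1) dt.

gf <- function(t0, dt, v) list(t0 = t0, dt = dt, v = v)

gf_eval <- function(g, t) {
  x <- (t - g$t0) / g$dt + 1
  n <- length(g$v)
  i <- floor(x)
  fr <- x - i
  out <- numeric(length(t))
  ok <- i >= 1 & i < n
  out[ok] <- g$v[i[ok]] * (1 - fr[ok]) + g$v[i[ok] + 1] * fr[ok]
  out[!ok & i == n & fr == 0] <- g$v[n]
  out
}

fft_conv <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, 2)
  re <- Re(stats::fft(stats::fft(c(a, numeric(nf - length(a)))) *
                      stats::fft(c(b, numeric(nf - length(b)))),
                      inverse = TRUE)) / nf
  re[seq_len(n)]
}

## convolution: (f * g)(t) = int f(u) g(t - u) du
gf_conv <- function(a, b) gf(a$t0 + b$t0, a$dt, fft_conv(a$v, b$v) * a$dt)

## cross-correlation: c(v) = int a(r) b(r + v) dr
gf_xcorr <- function(a, b) {
  ar <- gf(-(a$t0 + (length(a$v) - 1) * a$dt), a$dt, rev(a$v))
  gf_conv(ar, b)
}

## grids for the standard kernels
grid_epsp <- function(tauA, tauB, dt, tol = 1e-12) {
  tmax <- tauA * log(1 / tol) + 5 * tauB
  tt <- seq(0, tmax, by = dt)
  gf(0, dt, epsp_kernel(tt, tauA, tauB))
}

grid_h <- function(theta_t, dt, kernel = "gamma3", span = 40) {
  tmax <- span * theta_t
  tt <- seq(-tmax, tmax, by = dt)
  gf(-tmax, dt, h_closed_form(tt, theta_t, kernel))
}

## ---- correlation-kernel coefficients --------------------------------------

## int_{s>=0} e^{-s/tau_p} psi(shift - s) ds  and
## int_{s<0}  e^{s/tau_d}  psi(shift - s) ds  by trapezoid on psi's grid
window_integrals <- function(psi, shift, tau_p, tau_d, smax_mult = 10) {
  smax <- smax_mult * max(tau_p, tau_d)
  ds <- psi$dt
  s <- seq(0, smax, by = ds)
  wts <- rep(1, length(s)); wts[c(1, length(s))] <- 0.5
  Ip <- sum(exp(-s / tau_p) * gf_eval(psi, shift - s) * wts) * ds
  Id <- sum(exp(-s / tau_d) * gf_eval(psi, shift + s) * wts) * ds
  c(Ip = Ip, Id = Id)
}

#' Correlation-kernel coefficients for feedforward STDP
#'
#' Computes the building blocks of the analytic weight dynamics: the
#' direct coefficient G1X(w) (input correlation filtered through the
#' feedforward EPSP, the dendritic-delay shift and the STDP window) and
#' the inhibition-routed coefficient G2X(w) (the same correlation
#' propagated through the E-to-I and I-to-E kernels and their delays,
#' entering the weight dynamics with a minus sign).  Because the
#' log-STDP window separates as F(w, s) = f_p(w) e^(-s/tau_p) (LTP
#' side) + f_d(w) e^(s/tau_d) (LTD side), each coefficient is an exact
#' linear combination f_p(w) I_p + f_d(w) I_d of two w-independent
#' quadrature constants, which this function returns along with
#' evaluator closures.
#'
#' @param params parameter list from [default_params()]; `theta_t`,
#'   `kernel`, PSP time constants and delay midpoints are taken from it.
#' @param dt_grid quadrature grid step, ms.
#' @return Object of class `"kernel_coefs"`: quadrature constants
#'   `I1p`, `I1d`, `I2p`, `I2d`, closures `G1X(w)`, `G2X(w)`,
#'   `Fbar(w)`, the scalars `g1X = G1X(wo_X)`, `g2X = G2X(wo_X)` and
#'   `kappa = g2X / g1X`.
#' @export
kernel_coefs <- function(params = default_params(), dt_grid = 0.02) {
  p <- params
  dXd <- (p$dXd_min + p$dXd_max) / 2
  dY <- (p$dY_min + p$dY_max) / 2
  dZ <- (p$dZ_min + p$dZ_max) / 2
  eX <- grid_epsp(p$tauA_X, p$tauB_X, dt_grid)
  eY <- grid_epsp(p$tauA_Y, p$tauB_Y, dt_grid)
  eZ <- grid_epsp(p$tauA_Z, p$tauB_Z, dt_grid)
  hh <- grid_h(p$theta_t, dt_grid, p$kernel)
  ## psi1(v) = int eX(r) h(r + v) dr ; G1X = int F(s) psi1(2 dXd - s) ds
  psi1 <- gf_xcorr(eX, hh)
  i1 <- window_integrals(psi1, 2 * dXd, p$tau_p, p$tau_d)
  ## psi2 via the triple PSP convolution, shifted by D = 2 dXd + dY + dZ
  e3 <- gf_conv(gf_conv(eX, eY), eZ)
  psi2 <- gf_xcorr(e3, hh)
  i2 <- window_integrals(psi2, 2 * dXd + dY + dZ, p$tau_p, p$tau_d)
  Cd <- p$Cp * p$tau_p / p$tau_d
  fp <- function(w) log_stdp_fp(w, p$wo_X, p$beta, p$Cp)
  fd <- function(w) log_stdp_fd(w, p$wo_X, p$alpha, Cd)
  G1X <- function(w) p$eta_X * (fp(w) * i1[["Ip"]] + fd(w) * i1[["Id"]])
  G2X <- function(w) p$eta_X * (fp(w) * i2[["Ip"]] + fd(w) * i2[["Id"]])
  Fbar <- function(w) p$eta_X * (fp(w) * p$tau_p + fd(w) * p$tau_d)
  structure(list(I1p = i1[["Ip"]], I1d = i1[["Id"]],
                 I2p = i2[["Ip"]], I2d = i2[["Id"]],
                 G1X = G1X, G2X = G2X, Fbar = Fbar,
                 g1X = G1X(p$wo_X), g2X = G2X(p$wo_X),
                 kappa = G2X(p$wo_X) / G1X(p$wo_X),
                 params = p, dt_grid = dt_grid),
            class = "kernel_coefs")
}

#' @export
print.kernel_coefs <- function(x, ...) {
  cat(sprintf("kernel_coefs (theta_t = %g ms, %s kernel):\n",
              x$params$theta_t, x$params$kernel))
  cat(sprintf("  g1X = %.6g, g2X = %.6g, kappa = g2X/g1X = %.4f\n",
              x$g1X, x$g2X, x$kappa))
  invisible(x)
}

#' Feedforward correlation kernel chi1 (direct path)
#'
#' chi1(tau; w) = int_{-tau + 2 dXd}^inf F(w, s) epsX(tau + s - 2 dXd)
#' ds: the STDP window smeared by the feedforward EPSP and shifted by
#' twice the dendritic delay.  G1X(w) = int chi1(tau; w) h(tau) dtau.
#'
#' @param tau lag(s), ms.
#' @param w synaptic weight.
#' @param params parameter list from [default_params()].
#' @param dt_grid quadrature step, ms.
#' @export
chi1X <- function(tau, w, params = default_params(), dt_grid = 0.02) {
  p <- params
  dXd <- (p$dXd_min + p$dXd_max) / 2
  cfg <- stdp_config("log_stdp", eta = p$eta_X, tau_p = p$tau_p,
                     tau_d = p$tau_d, Cp = p$Cp, alpha = p$alpha,
                     beta = p$beta, w_o = p$wo_X)
  vapply(tau, function(tv) {
    r <- seq(0, p$tauA_X * 30, by = dt_grid)       # r = tau + s - 2 dXd
    s <- r - tv + 2 * dXd
    wts <- rep(1, length(r)); wts[c(1, length(r))] <- 0.5
    sum(stdp_window(s, cfg, w) * epsp_kernel(r, p$tauA_X, p$tauB_X) * wts) *
      dt_grid
  }, numeric(1))
}

#' Feedforward correlation kernel chi2 (inhibition-routed path)
#'
#' chi2(tau; w) = int F(w, s) (epsZ * epsY * epsX)(tau + s - D) ds with
#' D the accumulated loop delay 2 dXd + dY + dZ: the STDP window
#' smeared by the full inhibitory-loop PSP chain.  Enters the weight
#' dynamics with a minus sign; G2X(w) = int chi2(tau; w) h(tau) dtau.
#'
#' @inheritParams chi1X
#' @export
chi2X <- function(tau, w, params = default_params(), dt_grid = 0.02) {
  p <- params
  D <- (p$dXd_min + p$dXd_max) + (p$dY_min + p$dY_max) / 2 +
    (p$dZ_min + p$dZ_max) / 2
  e3 <- gf_conv(gf_conv(grid_epsp(p$tauA_X, p$tauB_X, dt_grid),
                        grid_epsp(p$tauA_Y, p$tauB_Y, dt_grid)),
                grid_epsp(p$tauA_Z, p$tauB_Z, dt_grid))
  cfg <- stdp_config("log_stdp", eta = p$eta_X, tau_p = p$tau_p,
                     tau_d = p$tau_d, Cp = p$Cp, alpha = p$alpha,
                     beta = p$beta, w_o = p$wo_X)
  smax <- 10 * max(p$tau_p, p$tau_d)
  s <- seq(-smax, smax, by = dt_grid)
  Fs <- stdp_window(s, cfg, w)
  wts <- rep(1, length(s)); wts[c(1, length(s))] <- 0.5
  vapply(tau, function(tv)
    sum(Fs * gf_eval(e3, tv + s - D) * wts) * dt_grid, numeric(1))
}

#' Lateral correlation-kernel coefficients g1Y and g1Z
#'
#' The first-order coefficients governing plasticity of the lateral
#' connections: g1Y > 0 predicts feature-selective E-to-I connections,
#' g1Z < 0 predicts mutual (non-reciprocal) inhibition.  Both are
#' integrals of the lateral STDP window against the input correlation
#' propagated along the respective loop (two feedforward EPSPs and one
#' lateral EPSP, with the loop delays for g1Z).
#'
#' @param params parameter list from [default_params()].
#' @param cfgY,cfgZ [stdp_config()] objects for the E-to-I and I-to-E
#'   windows (defaults: balanced Hebbian with the Methods' gamma
#'   factors and 20 ms windows).
#' @param dt_grid quadrature step, ms.
#' @return List with `g1Y` and `g1Z`.
#' @export
lateral_coefs <- function(params = default_params(),
                          cfgY = stdp_config("hebbian", eta = 1,
                                             tau_p = params$tauY_p,
                                             tau_d = params$tauY_d,
                                             gamma = params$gamma_Y),
                          cfgZ = stdp_config("hebbian", eta = 1,
                                             tau_p = params$tauZ_p,
                                             tau_d = params$tauZ_d,
                                             gamma = params$gamma_Z),
                          dt_grid = 0.02) {
  p <- params
  dY <- (p$dY_min + p$dY_max) / 2
  dZ <- (p$dZ_min + p$dZ_max) / 2
  eX <- grid_epsp(p$tauA_X, p$tauB_X, dt_grid)
  eY <- grid_epsp(p$tauA_Y, p$tauB_Y, dt_grid)
  hh <- grid_h(p$theta_t, dt_grid, p$kernel)
  B <- gf_conv(eY, eX)                  # density of u + r'
  A <- gf_conv(eX, hh)                  # A(c) = int eX(r) h(c - r) dr
  ## g1Y: h(u + r' - s - r) -> K(m) = int B(w) A(w + m) dw, m = -s
  K1 <- gf_xcorr(B, A)
  g1Y <- window_integral_signed(K1, 0, cfgY)
  ## g1Z: h(r - s - u - r' - dZ - dY) -> (B * psi1)(-s - dY - dZ)
  psi1 <- gf_xcorr(eX, hh)              # int eX(r) h(r + v) dr
  K2 <- gf_conv(B, psi1)
  g1Z <- window_integral_signed(K2, -(dY + dZ), cfgZ)
  list(g1Y = g1Y, g1Z = g1Z)
}

## int F(s) K(shift - s) ds for an arbitrary stdp_config window
window_integral_signed <- function(K, shift, cfg, smax_mult = 10) {
  smax <- smax_mult * max(cfg$tau_p, cfg$tau_d)
  ds <- K$dt
  s <- seq(0, smax, by = ds)
  wts <- rep(1, length(s)); wts[c(1, length(s))] <- 0.5
  Fp <- stdp_window(s, cfg)               # s >= 0 branch
  Fd <- stdp_window(-s, cfg)              # s < 0 branch (s = 0 unused: wt 0.5 both)
  ## avoid double-counting s = 0: it belongs to the LTP branch
  Fd[1] <- 0
  sum(Fp * gf_eval(K, shift - s) * wts) * ds +
    sum(Fd * gf_eval(K, shift + s) * wts) * ds
}

#' Sweep the correlation timescale
#'
#' Evaluates g1X, g2X and kappa = g2X/g1X over a set of correlation
#' timescales, for either response kernel.
#'
#' @param theta_values timescales, ms.
#' @param params base parameters.
#' @param kernel response-kernel kind.
#' @param dt_grid quadrature step, ms.
#' @return data.frame with columns theta_t, g1X, g2X, kappa.
#' @export
kappa_sweep <- function(theta_values = c(0.5, 1, 2, 3, 4),
                        params = default_params(),
                        kernel = params$kernel, dt_grid = 0.02) {
  rows <- lapply(theta_values, function(th) {
    kc <- kernel_coefs(modifyList(params, list(theta_t = th, kernel = kernel)),
                       dt_grid = dt_grid)
    data.frame(theta_t = th, g1X = kc$g1X, g2X = kc$g2X, kappa = kc$kappa)
  })
  do.call(rbind, rows)
}
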