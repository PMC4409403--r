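## Analytic layer, part 2: the two-source mean-field system, its
## inhibitory-rate solution, fixed points, stability and bistability
## sweeps.
##
## The four group-mean feedforward weights (w1A, w1B, w2A, w2B) evolve
## under three forces: direct correlation drive (G1X), correlation
## routed through the inhibitory loop (-G2X), and the homeostatic drift
## F-bar.  The lateral weights enter only through the dimensionless
## loop gain b = Ma wY Na wZ: every occurrence of wY and wZ in the
## reduced equations is this product, and substituting the closed-form
## inhibitory rates collapses the homeostatic bracket to
## F-bar(w) (nu_X)^2 La (S_mu - b S_mubar) / (1 - b^2),
## with S_mu = w_muA + w_muB + 2 wo_X.

#' Two-source mean-field configuration
#'
#' @param params parameter list from [default_params()].
#' @param b dimensionless lateral loop gain Ma wY Na wZ (0 <= b < 1).
#'   The printed inhibitory strengths map as b = wI / 100 (equivalently
#'   the caption weights wZ = 0.1/0.215/0.4 with Ma wY = 10 Na / ...);
#'   b also equals the I/E ratio Na wZ / (L wo_X).
#' @param q_A,q_B response probabilities of the two sources.
#' @param coefs optional precomputed [kernel_coefs()] (recomputed from
#'   `params` when missing).
#' @return Object of class `"meanfield_config"`.
#' @export
meanfield_config <- function(params = default_params(), b = 0.215,
                             q_A = 0.6, q_B = 0.5, coefs = NULL) {
  if (b < 0 || b >= 1) stop("loop gain b must lie in [0, 1)")
  if (is.null(coefs)) coefs <- kernel_coefs(params)
  structure(list(params = params, b = b, c_A = q_A^2, c_B = q_B^2,
                 q_A = q_A, q_B = q_B, coefs = coefs),
            class = "meanfield_config")
}

#' Mean-field weight velocity
#'
#' Right-hand side of the reduced weight dynamics for the state
#' (w1A, w1B, w2A, w2B).
#'
#' @param w numeric length-4 state vector, order (w1A, w1B, w2A, w2B).
#' @param cfg a [meanfield_config()].
#' @return Length-4 velocity vector (weight per ms).
#' @export
meanfield_rhs <- function(w, cfg) {
  p <- cfg$params
  nuS <- p$nu_S / 1000; nuX <- p$nu_X / 1000   # per-ms rates
  La <- p$La; b <- cfg$b; wo <- p$wo_X
  G1 <- cfg$coefs$G1X; G2 <- cfg$coefs$G2X; Fb <- cfg$coefs$Fbar
  w1A <- w[1]; w1B <- w[2]; w2A <- w[3]; w2B <- w[4]
  S1 <- w1A + w1B + 2 * wo
  S2 <- w2A + w2B + 2 * wo
  hom <- function(wmn, Sm, Smb) Fb(wmn) * nuX^2 * La * (Sm - b * Smb) / (1 - b^2)
  corr <- function(wmn, wbar, cc)
    La * nuS * cc * (G1(wmn) * wmn - b * G2(wmn) * wbar)
  c(corr(w1A, w2A, cfg$c_A) + hom(w1A, S1, S2),
    corr(w1B, w2B, cfg$c_B) + hom(w1B, S1, S2),
    corr(w2A, w1A, cfg$c_A) + hom(w2A, S2, S1),
    corr(w2B, w1B, cfg$c_B) + hom(w2B, S2, S1))
}

#' Closed-form inhibitory rates of the structured two-source network
#'
#' Solves the cross-coupled balance equations for the two inhibitory
#' group rates in the static structured network,
#' nu_mu^Z = Ma wY \[ (La w_muA + La w_muB + 2 La wo_X) nu_X -
#' Na wZ nu_mubar^Z \], and rectifies at zero.  `gain_E`/`gain_I`
#' rescale the linear gain of the output/inhibitory populations.
#'
#' @param w length-4 state (w1A, w1B, w2A, w2B).
#' @param params parameter list.
#' @param w_Y,w_Z per-synapse lateral weights.
#' @param gain_E,gain_I linear gain scale factors (1 for the bare
#'   linear gain).
#' @return Length-2 vector (nu_1^Z, nu_2^Z) in Hz.
#' @export
inhibitory_rates <- function(w, params = default_params(),
                             w_Y = params$wo_Y, w_Z = params$wo_Z,
                             gain_E = 1, gain_I = 1) {
  p <- params
  a <- gain_I * p$Ma * w_Y                 # nu^Z = a (drive - Na wZ nu^Zbar)
  g <- a * gain_E * p$Na * w_Z             # loop gain
  if (abs(1 - g^2) < 1e-12) g <- g + 1e-8  # perturb the singular balance
  drive <- function(wA, wB)
    gain_E * (p$La * wA + p$La * wB + 2 * p$La * p$wo_X) * p$nu_X
  d1 <- drive(w[1], w[2]); d2 <- drive(w[3], w[4])
  nu1 <- a * (d1 - g * d2) / (1 - g^2)
  nu2 <- a * (d2 - g * d1) / (1 - g^2)
  pmax(c(nu1, nu2), 0)
}

## damped Newton with numerical Jacobian
num_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- f(x)
  for (j in seq_len(n)) {
    dx <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + dx
    xm <- x; xm[j] <- xm[j] - dx
    J[, j] <- (f(xp) - f(xm)) / (2 * dx)
  }
  J
}

newton_root <- function(f, x0, tol = 1e-12, maxit = 80, lower = 0, upper = Inf) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- num_jacobian(f, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- pmin(pmax(x - lambda * step, lower), upper)
      if (sum(f(xn)^2) < sum(fx^2) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) < 1e-14) { x <- xn; break }
    x <- xn
  }
  if (max(abs(f(x))) < tol * 100) x else NULL
}

#' Fixed points of the mean-field system
#'
#' Multi-start damped Newton search on the 4-d weight system, with
#' deduplication and stability labels from the Jacobian eigenvalues.
#'
#' @param cfg a [meanfield_config()].
#' @param w_grid start values per coordinate (expanded as pairs of
#'   (wA, wB) for both groups).
#' @param dedup_tol distance below which two roots are merged.
#' @return data.frame with columns w1A, w1B, w2A, w2B, stable,
#'   max_re_eig, w_SI.
#' @export
find_fixed_points <- function(cfg, w_grid = c(1, 6, 12),
                              dedup_tol = 1e-3) {
  f <- function(w) meanfield_rhs(w, cfg)
  ## scale velocities to O(1) for the tolerance check
  sc <- max(abs(f(rep(cfg$params$wo_X, 4)))) + 1e-12
  fs <- function(w) f(w) / sc
  starts <- as.matrix(expand.grid(w_grid, w_grid))
  roots <- list()
  for (i in seq_len(nrow(starts))) for (j in seq_len(nrow(starts))) {
    x0 <- c(starts[i, 1], starts[i, 2], starts[j, 1], starts[j, 2])
    r <- newton_root(fs, x0, tol = 1e-10, upper = 4 * max(w_grid))
    if (is.null(r)) next
    dup <- FALSE
    for (q in roots) if (max(abs(q - r)) < dedup_tol) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    return(data.frame(w1A = numeric(0), w1B = numeric(0), w2A = numeric(0),
                      w2B = numeric(0), stable = logical(0),
                      max_re_eig = numeric(0), w_SI = numeric(0)))
  rows <- lapply(roots, function(r) {
    J <- num_jacobian(f, r)
    ## treat boundary-pinned coordinates (w = 0 pushed negative) as stable
    ## along the clipped direction
    atz <- r < 1e-8 & f(r + 1e-9) < 0
    ev <- eigen(J, only.values = TRUE)$values
    mre <- max(Re(ev))
    if (any(atz)) {
      free <- !atz
      mre <- if (any(free)) max(Re(eigen(J[free, free, drop = FALSE],
                                         only.values = TRUE)$values)) else -1
    }
    data.frame(w1A = r[1], w1B = r[2], w2A = r[3], w2B = r[4],
               stable = mre < 0, max_re_eig = mre,
               w_SI = specialization_index(r[1], r[2], r[3], r[4]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$stable, out$w1A), ]
}

#' Specialisation index
#'
#' w'_SI = (w1A - w1B)(w2B - w2A); the index is its sign: +1 when the
#' two output groups specialise on different sources (winners share
#' all), -1 when both specialise on the same source (winner takes
#' all), 0 at exact symmetry.
#'
#' @param w1A,w1B,w2A,w2B group-mean weights (or a length-4 vector in
#'   `w1A` with the rest missing).
#' @export
specialization_index <- function(w1A, w1B, w2A, w2B) {
  if (missing(w1B)) { w <- w1A; w1A <- w[1]; w1B <- w[2]; w2A <- w[3]; w2B <- w[4] }
  sign((w1A - w1B) * (w2B - w2A))
}

#' Classify the fixed-point regime and sweep the inhibition strength
#'
#' For each loop-gain value, finds the stable fixed points and labels
#' the regime: `"T-only"` (all stable points have both groups on the
#' same source), `"S+T"` (winners-share-all points coexist with
#' same-source points — multistability), `"S-only"`.  The onset of
#' multistability is the smallest b whose regime contains S and T (or,
#' once past, first S appearance).
#'
#' @param b_values loop-gain values to sweep.
#' @param params parameter list.
#' @param q_A,q_B source response probabilities.
#' @param coefs optional shared [kernel_coefs()].
#' @return data.frame with b, n_stable, n_S, n_T, n_sym, regime.
#' @export
bistability_sweep <- function(b_values = seq(0.05, 0.5, by = 0.025),
                              params = default_params(),
                              q_A = 0.6, q_B = 0.5, coefs = NULL) {
  if (is.null(coefs)) coefs <- kernel_coefs(params)
  rows <- lapply(b_values, function(b) {
    cfg <- meanfield_config(params, b = b, q_A = q_A, q_B = q_B, coefs = coefs)
    fp <- find_fixed_points(cfg)
    st <- fp[fp$stable, , drop = FALSE]
    nS <- sum(st$w_SI > 0)
    nT <- sum(st$w_SI < 0)
    nsym <- sum(st$w_SI == 0)
    regime <- if (nS > 0 && (nT + nsym) > 0) "S+T"
      else if (nS > 0) "S-only" else "T-only"
    data.frame(b = b, n_stable = nrow(st), n_S = nS, n_T = nT,
               n_sym = nsym, regime = regime)
  })
  do.call(rbind, rows)
}

#' Regime sweep along a network-property axis
#'
#' Classifies the stable fixed-point regime while varying a property
#' that reshapes the inhibition-routed correlation kernel at a fixed
#' loop gain: the mean lateral (axonal) delay, or the IPSP timescale
#' (decay and rise scaled together).
#'
#' @param axis `"lateral_delay"` (mean of dY and dZ, ms; spread kept
#'   at 0.2 ms) or `"ipsp_tau"` (multiplier on the IPSP time-constant
#'   pair).
#' @param values axis values.
#' @param b lateral loop gain.
#' @param params base parameters.
#' @param q_A,q_B source response probabilities.
#' @return data.frame with the axis value, kappa, n_S, n_T and regime.
#' @export
regime_sweep <- function(axis = c("lateral_delay", "ipsp_tau"),
                         values, b = 0.4, params = default_params(),
                         q_A = 0.6, q_B = 0.5) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    pv <- switch(axis,
      lateral_delay = modifyList(params, list(
        dY_min = v - 0.1, dY_max = v + 0.1,
        dZ_min = v - 0.1, dZ_max = v + 0.1)),
      ipsp_tau = modifyList(params, list(
        tauA_Z = params$tauA_Z * v, tauB_Z = params$tauB_Z * v)))
    kc <- kernel_coefs(pv)
    fp <- find_fixed_points(meanfield_config(pv, b = b, q_A = q_A,
                                             q_B = q_B, coefs = kc))
    st <- fp[fp$stable, ]
    nS <- sum(st$w_SI > 0); nT <- sum(st$w_SI <= 0)
    data.frame(value = v, kappa = kc$kappa, n_S = nS, n_T = nT,
               regime = if (nS > 0 && nT > 0) "S+T"
                        else if (nS > 0) "S-only" else "T-only")
  })
  do.call(rbind, rows)
}

#' Onset of multistability
#'
#' Bisects the loop gain for the smallest b at which winners-share-all
#' stable fixed points first appear alongside the same-source state.
#'
#' @param params parameter list.
#' @param q_A,q_B source response probabilities.
#' @param lower,upper bracketing loop gains.
#' @param tol bisection tolerance on b.
#' @param coefs optional shared [kernel_coefs()].
#' @return The onset loop gain b* (equal to the I/E ratio
#'   Na wZ / (L wo_X); multiply by 100 for percent).
#' @export
multistability_onset <- function(params = default_params(), q_A = 0.6,
                                 q_B = 0.5, lower = 0.05, upper = 0.4,
                                 tol = 2e-3, coefs = NULL) {
  if (is.null(coefs)) coefs <- kernel_coefs(params)
  has_S <- function(b) {
    cfg <- meanfield_config(params, b = b, q_A = q_A, q_B = q_B, coefs = coefs)
    fp <- find_fixed_points(cfg)
    any(fp$stable & fp$w_SI > 0)
  }
  if (has_S(lower)) return(lower)
  if (!has_S(upper)) return(NA_real_)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (has_S(mid)) upper <- mid else lower <- mid
  }
  upper
}
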