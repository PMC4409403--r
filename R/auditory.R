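## Synthetic auditory scenes for the blind-source-separation task:
## each source has a harmonic high-frequency spectrum and an
## exponential-oscillation low-frequency envelope; input neurons are
## tonotopic with log-spaced preferred frequencies.

#' Auditory scene parameters
#'
#' Parameters of the synthetic multi-speaker scene.  The defaults are a
#' four-source scene: each source q has characteristic frequencies
#' `f_h[[q]]` with relative amplitudes `a_h[[q]]`, harmonic weights
#' `b_h[[q]]` (k-th harmonic at k*f with Gaussian width k*sigma_h), and
#' a low-frequency envelope a_l^q(t) = exp(beta_l * sum_i a_l_i *
#' cos(2 pi f_l_i (t - delta_l_i))) / Z_l.  Input neuron i prefers
#' frequency f_i on a log-spaced grid over \[f_min, f_max\] and responds
#' with probability q_i(t) = q_o * sum_q a_l^q(t) a_h^q(f_i).
#'
#' @param f_h,a_h,b_h,f_l,a_l,delta_l per-source parameter lists.
#' @param sigma_h Gaussian width of the fundamental, Hz.
#' @param beta_l envelope sharpness.
#' @param Z_l envelope normaliser.
#' @param f_min,f_max frequency grid limits, Hz.
#' @param L number of input neurons (grid points).
#' @param q_o response gain.
#' @return Object of class `"auditory_scene"`.
#' @export
auditory_scene <- function(
    f_h = list(c(523.3, 784.0), c(587.4, 880.0), c(650.0, 830.6), c(698.5, 932.4)),
    a_h = list(c(0.6, 0.4), c(0.3, 0.7), c(0.5, 0.5), c(0.9, 0.3)),
    b_h = list(c(1.0, 0.5, 0.2, 0.1), c(1.0, 0.5, 0.3, 0.2),
               c(1.0, 0.1, 1.0, 0.8), c(1.0, 0.8, 0.1, 0.1)),
    f_l = list(c(0.4, 5.0, 10.0, 40.0, 88.0), c(0.6, 6.0, 8.0, 42.0, 86.0),
               c(0.2, 4.0, 7.5, 44.0, 84.0), c(0.3, 6.0, 7.0, 46.0, 82.0)),
    a_l = list(c(0.3, 0.4, 0.2, 0.5, 0.5), c(0.25, 0.5, 0.2, 0.5, 0.5),
               c(0.24, 0.3, 0.4, 0.5, 0.5), c(0.61, 0.2, 0.2, 0.5, 0.5)),
    delta_l = list(c(1.0, 0.25, 0.65, 0.17, 0.01), c(3.0, 0.12, 0.32, 0.13, 0.02),
                   c(7.8, 0.55, 0.40, 0.11, 0.03), c(4.5, 0.22, 0.71, 0.07, 0.05)),
    sigma_h = 20, beta_l = 5.0, Z_l = 27.24,
    f_min = 500, f_max = 4500, L = 400, q_o = 0.05) {
  nq <- length(f_h)
  stopifnot(length(a_h) == nq, length(b_h) == nq, length(f_l) == nq,
            length(a_l) == nq, length(delta_l) == nq, f_max > f_min, L >= 2)
  structure(list(f_h = f_h, a_h = a_h, b_h = b_h, f_l = f_l, a_l = a_l,
                 delta_l = delta_l, sigma_h = sigma_h, beta_l = beta_l,
                 Z_l = Z_l, f_min = f_min, f_max = f_max, L = as.integer(L),
                 q_o = q_o, n_sources = nq),
            class = "auditory_scene")
}

#' Tonotopic frequency grid
#'
#' f_i = exp(i/L (log f_max - log f_min) + log f_min), i = 1..L.
#'
#' @param scene an [auditory_scene()].
#' @return Numeric vector of length `L` (strictly increasing, Hz).
#' @export
frequency_grid <- function(scene) {
  i <- seq_len(scene$L)
  exp(i / scene$L * (log(scene$f_max) - log(scene$f_min)) + log(scene$f_min))
}

#' High-frequency spectrum of one source
#'
#' Sum of Gaussians centred on the harmonics k*f of each characteristic
#' frequency, with width k*sigma_h and weight b_h\[k\].
#'
#' @param scene an [auditory_scene()].
#' @param q source index.
#' @param f frequencies at which to evaluate (Hz).
#' @return Spectrum values.
#' @export
source_spectrum <- function(scene, q, f = frequency_grid(scene)) {
  out <- numeric(length(f))
  bh <- scene$b_h[[q]]
  for (i in seq_along(scene$f_h[[q]])) {
    for (k in seq_along(bh)) {
      sig <- k * scene$sigma_h
      out <- out + scene$a_h[[q]][i] * bh[k] / (sqrt(2 * pi) * sig) *
        exp(-(f - k * scene$f_h[[q]][i])^2 / (2 * sig^2))
    }
  }
  out
}

#' Low-frequency envelope of one source
#'
#' a_l^q(t) = exp(beta_l sum_i a_i cos(2 pi f_i (t - delta_i))) / Z_l;
#' strictly positive, periodic, and independent across sources by
#' construction (different frequencies and delays).
#'
#' @param scene an [auditory_scene()].
#' @param q source index.
#' @param t times in seconds (envelope frequencies are in Hz).
#' @return Envelope values (>= 0).
#' @export
source_envelope <- function(scene, q, t) {
  s <- numeric(length(t))
  for (i in seq_along(scene$f_l[[q]]))
    s <- s + scene$a_l[[q]][i] *
      cos(2 * pi * scene$f_l[[q]][i] * (t - scene$delta_l[[q]][i]))
  exp(scene$beta_l * s) / scene$Z_l
}

#' Synthesise an auditory scene
#'
#' Produces the per-source envelopes, per-neuron spectra, the mixed
#' waveform a(t) = sum_q a_l^q(t) sum_i a_h^q(f_i) cos(2 pi f_i (t -
#' delta_f^q)), and the time-dependent response probabilities
#' q_i(t) = q_o sum_q a_l^q(t) a_h^q(f_i) clipped to \[0, 1\].
#'
#' @param scene an [auditory_scene()].
#' @param T duration, ms.
#' @param dt_audio audio step, ms (default 0.025, > 2x Nyquist of
#'   f_max = 4500 Hz).
#' @param dt_network network grid step for the resampled q_i(t), ms.
#' @param seed seed for the per-source mixing delays delta_f^q, drawn
#'   uniformly from \[0, 1/f_min\].
#' @return List with `t_audio` (s), `envelopes` (n_sources x nt),
#'   `spectra` (n_sources x L), `waveform`, `q_t` (L x n network bins),
#'   `t_network` (s), `delta_f` and `clipped` (fraction of q values
#'   clipped at 1).
#' @export
synth_auditory_scene <- function(scene, T, dt_audio = 0.025, dt_network = 0.5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nq <- scene$n_sources
  delta_f <- runif(nq, 0, 1 / scene$f_min)
  fi <- frequency_grid(scene)
  tt <- seq(0, T / 1000, by = dt_audio / 1000)
  env <- t(vapply(seq_len(nq), function(q) source_envelope(scene, q, tt),
                  numeric(length(tt))))
  spec <- t(vapply(seq_len(nq), function(q) source_spectrum(scene, q, fi),
                   numeric(length(fi))))
  wave <- numeric(length(tt))
  for (q in seq_len(nq)) {
    carrier <- numeric(length(tt))
    for (i in seq_along(fi))
      carrier <- carrier + spec[q, i] * cos(2 * pi * fi[i] * (tt - delta_f[q]))
    wave <- wave + env[q, ] * carrier
  }
  # response probabilities on the (coarser) network grid
  tn <- seq(0, T / 1000, by = dt_network / 1000)
  envn <- t(vapply(seq_len(nq), function(q) source_envelope(scene, q, tn),
                   numeric(length(tn))))
  q_t <- scene$q_o * t(spec) %*% envn          # L x nt
  nclip <- sum(q_t > 1)
  if (nclip > 0)
    warning(sprintf("%d q_i(t) values exceeded 1 before clipping", nclip))
  q_t <- pmin(pmax(q_t, 0), 1)
  list(t_audio = tt, envelopes = env, spectra = spec, waveform = wave,
       q_t = q_t, t_network = tn, delta_f = delta_f,
       clipped = nclip / length(q_t))
}

#' Sample input spikes from a time-varying response-probability matrix
#'
#' Bernoulli sampling for the blind-source-separation task: in each
#' network bin, input neuron i fires with probability q_i(t), the
#' stimulus-driven response probability from [synth_auditory_scene()].
#'
#' @param q_t L x nbins matrix of probabilities in \[0, 1\].
#' @param seed optional seed.
#' @return Sparse two-column spike matrix (neuron, bin).
#' @export
sample_scene_spikes <- function(q_t, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spikes <- matrix(rbinom(length(q_t), 1L, q_t), nrow = nrow(q_t))
  idx <- which(spikes != 0L, arr.ind = TRUE)
  out <- cbind(neuron = idx[, 1L], bin = idx[, 2L])
  out[order(out[, 2L], out[, 1L]), , drop = FALSE]
}
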