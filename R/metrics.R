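## Evaluation statistics: delay-optimised source/output cross-
## correlation, mutual information with thresholded binarisation,
## output-group assignment, and the lateral-structure indices.

## all permutations of 1..n (n <= 8)
all_permutations <- function(n) {
  if (n > 8) stop("permutation enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}

#' Bin spike trains on a coarse grid
#'
#' Sums spikes into bins of `bin_ms`, per neuron group.
#'
#' @param spk two-column matrix/data.frame (neuron, bin) on the fine
#'   grid.
#' @param n_bins number of fine-grid bins in the recording.
#' @param dt fine-grid step, ms.
#' @param groups list of neuron index vectors (one row of output per
#'   group); a single vector bins one population.
#' @param bin_ms coarse bin width, ms (default 10).
#' @return Matrix (length(groups) x n coarse bins) of spike counts.
#' @export
bin_spikes <- function(spk, n_bins, dt, groups, bin_ms = 10) {
  if (!is.list(groups)) groups <- list(groups)
  stride <- round(bin_ms / dt)
  nc <- floor(n_bins / stride)
  out <- matrix(0, length(groups), nc)
  cb <- (as.integer(spk[, 2]) - 1L) %/% stride + 1L
  ok <- cb <= nc
  for (g in seq_along(groups)) {
    sel <- ok & (as.integer(spk[, 1]) %in% groups[[g]])
    if (any(sel)) out[g, ] <- tabulate(cb[sel], nbins = nc)
  }
  out
}

#' Delay-optimised source/output cross-correlation
#'
#' Pearson correlation between each binned source train and each
#' output-group train shifted by the readout delay tau_D, averaged
#' over pairs and maximised over all source-to-group permutations.
#'
#' @param s p x K binned source activity.
#' @param y p x K binned output-group activity (same bin grid).
#' @param tau_D readout delay, ms.
#' @param bin_ms bin width, ms.
#' @return Scalar c(tau_D); attribute `"perm"` holds the best
#'   assignment, attribute `"pairs"` the per-pair correlations.
#' @export
cross_correlation <- function(s, y, tau_D = 0, bin_ms = 10) {
  p <- nrow(s)
  stopifnot(nrow(y) == p)
  shift <- round(tau_D / bin_ms)
  K <- ncol(s)
  if (shift >= K) stop("tau_D exceeds the recording")
  # y_nu^k(tau_D) uses y(t + tau_D): align s[k] with y[k + shift]
  si <- seq_len(K - shift)
  yi <- si + shift
  cm <- matrix(0, p, p)
  for (mu in seq_len(p)) for (nu in seq_len(p)) {
    ss <- s[mu, si]; yy <- y[nu, yi]
    if (sd(ss) == 0 || sd(yy) == 0) next   # degenerate pair contributes 0
    cm[mu, nu] <- cor(ss, yy)
  }
  best <- -Inf; bperm <- seq_len(p)
  for (pm in all_permutations(p)) {
    v <- mean(cm[cbind(seq_len(p), pm)])
    if (v > best) { best <- v; bperm <- pm }
  }
  structure(best, perm = bperm, pairs = cm)
}

#' Mutual information between binarised source and output states
#'
#' Each series is binarised at mean + SD; the joint states (one bit
#' per source / per group) are then treated as discrete symbols and
#' the plug-in mutual information is computed in bits.
#'
#' @param s,y p x K binned activity matrices.
#' @return MI in bits (0 for degenerate single-state series).
#' @export
mutual_information <- function(s, y) {
  binz <- function(m) {
    thr <- rowMeans(m) + apply(m, 1, sd)
    (m > thr) + 0L
  }
  sh <- binz(s); yh <- binz(y)
  p <- nrow(sh); K <- ncol(sh)
  code <- function(m) as.integer(2^(seq_len(nrow(m)) - 1) %*% m)
  cs <- code(sh); cy <- code(yh)
  if (length(unique(cs)) < 2 || length(unique(cy)) < 2) return(0)
  joint <- table(cs, cy) / K
  ps <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (a in seq_along(ps)) for (b in seq_along(py)) {
    if (joint[a, b] > 0)
      mi <- mi + joint[a, b] * log2(joint[a, b] / (ps[a] * py[b]))
  }
  as.numeric(mi)
}

#' Assign output neurons to source groups by their weights
#'
#' Output neuron j belongs to group mu iff its mean feedforward weight
#' from mu's input neurons exceeds `alpha_th` times the best competing
#' group's mean (strict inequality); otherwise it stays unassigned.
#'
#' @param W_X M x L weight matrix.
#' @param input_groups list of input-neuron index vectors per source.
#' @param alpha_th assignment threshold (default 1.5).
#' @return Integer vector of length M: group index or NA.
#' @export
assign_output_groups <- function(W_X, input_groups, alpha_th = 1.5) {
  means <- vapply(input_groups, function(g)
    rowMeans(W_X[, g, drop = FALSE]), numeric(nrow(W_X)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  apply(means, 1, function(v) {
    mu <- which.max(v)
    if (v[mu] > alpha_th * max(v[-mu])) mu else NA_integer_
  })
}

#' Feature selectivity of E-to-I connections
#'
#' For each inhibitory neuron, the difference between its mean weight
#' from A-preferring and B-preferring output neurons, normalised by its
#' mean weight from all output neurons; aggregated as the mean of
#' per-neuron absolute values (the signed mean cancels for a
#' symmetrically clustered network), or signed with `signed = TRUE`.
#' A perfectly clustered two-group network scores 2; uniform weights
#' score 0; the index is invariant to rescaling W_Y.
#'
#' @param W_Y N x M weight matrix.
#' @param omega_A,omega_B output-neuron index sets preferring A and B.
#' @param signed aggregate signed values instead of absolute values.
#' @return Scalar selectivity phi_Y.
#' @export
feature_selectivity_phiY <- function(W_Y, omega_A, omega_B, signed = FALSE) {
  vals <- apply(W_Y, 1, function(w) {
    tot <- mean(w)
    if (tot <= 0) return(NA_real_)   # zero row: skipped
    (mean(w[omega_A]) - mean(w[omega_B])) / tot
  })
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  if (signed) mean(vals) else mean(abs(vals))
}

#' Degree of mutual (non-reciprocal) inhibition
#'
#' For each inhibitory neuron k, the L1 distance between its normalised
#' incoming-excitation profile (row k of W_Y) and its normalised
#' outgoing-inhibition profile (column k of W_Z), averaged over k.
#' Perfectly reciprocal wiring (W_Z = t(W_Y) up to scale) scores 0;
#' disjoint-support profiles score 2.
#'
#' @param W_Y N x M excitatory lateral weights.
#' @param W_Z M x N inhibitory feedback weights.
#' @return Scalar phi_Z in \[0, 2\].
#' @export
mutual_inhibition_phiZ <- function(W_Y, W_Z) {
  N <- nrow(W_Y)
  vals <- vapply(seq_len(N), function(k) {
    a <- W_Y[k, ]; b <- W_Z[, k]
    if (sum(a) <= 0 || sum(b) <= 0) return(NA_real_)
    sum(abs(a / sum(a) - b / sum(b)))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

#' Empirical cross-correlogram of two spike trains
#'
#' Count-normalised cross-correlogram density: the rate of coincidences
#' at lag s relative to independence,
#' (1/T) sum pairs delta(t_l - t_i - s) binned, minus the chance level
#' nu_i nu_l, in units of 1/ms (matching nu_S sum_mu q_i q_l h(s)).
#'
#' @param t1,t2 spike times in ms.
#' @param T recording length, ms.
#' @param max_lag maximum |lag|, ms.
#' @param bin_ms correlogram bin, ms.
#' @return data.frame with columns lag (bin centres) and density.
#' @export
spike_xcorr <- function(t1, t2, T, max_lag = 20, bin_ms = 0.5) {
  edges <- seq(-max_lag, max_lag, by = bin_ms)
  counts <- numeric(length(edges) - 1)
  t2s <- sort(t2)
  for (t in t1) {
    lo <- findInterval(t - max_lag, t2s) + 1L
    hi <- findInterval(t + max_lag, t2s)
    if (hi >= lo) {
      d <- t2s[lo:hi] - t
      idx <- floor((d + max_lag) / bin_ms) + 1L
      idx <- idx[idx >= 1 & idx <= length(counts)]
      for (i in idx) counts[i] <- counts[i] + 1
    }
  }
  dens <- counts / (T * bin_ms) - (length(t1) / T) * (length(t2) / T)
  data.frame(lag = edges[-length(edges)] + bin_ms / 2, density = dens)
}
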