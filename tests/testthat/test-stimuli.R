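test_that("response kernels are normalised densities with the right shape", {
  th <- 2
  expect_equal(response_kernel(0, th), 0)                 # t^2 factor
  tt <- seq(0, 50 * th, by = 0.002)
  wts <- rep(1, length(tt)); wts[c(1, length(tt))] <- 0.5
  for (kind in c("gamma3", "exponential")) {
    area <- sum(response_kernel(tt, th, kind) * wts) * 0.002
    expect_lt(abs(area - 1), 1e-6)
  }
  # mode of the gamma3 kernel by brute-force grid search
  grid <- seq(0, 10 * th, by = 1e-3)
  expect_equal(grid[which.max(response_kernel(grid, th))], 2 * th,
               tolerance = 1e-2)
  expect_error(response_kernel(-1, th), "t must be")
  expect_error(response_kernel(1, -2), "theta_t")
})

test_that("source event trains have Poisson statistics and independence", {
  cfg <- source_config(2, nu_S = 10, theta_t = 2)
  ev <- sample_source_events(cfg, T = 100e3, dt = 0.5, seed = 11)
  counts <- rowSums(ev)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
  # independence of the two sources on coarse bins
  k <- 200  # 100 ms bins
  c1 <- colSums(matrix(ev[1, ], nrow = k))
  c2 <- colSums(matrix(ev[2, ], nrow = k))
  expect_lt(abs(cor(c1, c2)), 3 / sqrt(length(c1)))
  expect_true(all(sample_source_events(source_config(1, nu_S = 0), 1000) == 0))
  expect_error(sample_source_events(cfg, 1000, dt = 200), "reduce dt")
})

test_that("response_matrix enforces probabilities and baseline rates", {
  Q <- rbind(c(0.6, 0), c(0, 0.5), c(0, 0))
  rmx <- response_matrix(Q, nu_X = 10, nu_S = 10)
  expect_equal(rmx$r_o, c(4, 5, 10))
  expect_error(response_matrix(matrix(1.2, 1, 1)), "\\[0, 1\\]")
  expect_error(response_matrix(matrix(c(0.8, 0.8), 1, 2)), "negative baseline")
})

test_that("input rates reduce to baseline, single-kernel bumps, and the target mean", {
  cfg <- source_config(1, nu_S = 10, theta_t = 2)
  rmx <- response_matrix(matrix(0.6, 1, 1), nu_X = 10)
  # no events -> constant baseline
  ev0 <- matrix(0L, 1, 2000)
  r0 <- input_rates(rmx, ev0, cfg, dt = 0.05)
  expect_true(all(r0 == rmx$r_o))
  # single event -> bump equal to phi on the grid (in Hz)
  ev1 <- ev0; ev1[1, 100] <- 1L
  r1 <- input_rates(rmx, ev1, cfg, dt = 0.05)
  tt <- (0:50) * 0.05
  expect_equal(r1[1, 100 + 0:50],
               rmx$r_o + 0.6 * response_kernel(tt, 2) * 1000,
               tolerance = 1e-10)
  # long-run time average equals nu_X by construction of r_o
  ev <- sample_source_events(cfg, T = 200e3, dt = 0.5, seed = 3)
  rr <- input_rates(rmx, ev, cfg, dt = 0.5)
  expect_equal(mean(rr), 10, tolerance = 0.05 * 10)
})

test_that("input spike sampling respects the rate and rejects impossible bins", {
  set.seed(5)
  rates <- matrix(10, 1, 2000e1)   # 10 Hz for 10 s at dt = 0.5
  spk <- sample_input_spikes(rates, dt = 0.5, seed = 7)
  expect_lt(abs(sum(spk) - 100), 3 * sqrt(100) + 1)
  expect_true(all(sample_input_spikes(matrix(0, 2, 100), 0.5) == 0))
  expect_error(sample_input_spikes(matrix(1e7, 1, 10), 0.5), "reduce dt")
})

test_that("build_Q lays out the task block structures", {
  rmx <- build_Q("minor_source", L = 400, La = 100, q_A = 0.6, q_B = 0.5)
  Q <- rmx$Q
  expect_true(all(Q[1:100, 1] == 0.6) && all(Q[1:100, 2] == 0))
  expect_true(all(Q[101:200, 2] == 0.5) && all(Q[101:200, 1] == 0))
  expect_true(all(Q[201:400, ] == 0))
  # crosstalk with q_N = 0 reduces to disjoint groups
  r2 <- build_Q("crosstalk", L = 40, La = 10, q_S = 0.6, q_N = 0)
  expect_equal(r2$Q, build_Q("minor_source", L = 40, La = 10,
                             q_A = 0.6, q_B = 0.6)$Q)
  expect_error(build_Q("minor_source", L = 100, La = 100), "at least")
})

test_that("C = Q Q^t reproduces the printed correlation strengths", {
  rmx <- build_Q("minor_source", q_A = 0.6, q_B = 0.5)
  C <- correlation_matrix(rmx, by_group = TRUE)
  expect_equal(C[1, 1], 0.36)
  expect_equal(C[2, 2], 0.25)
  expect_equal(C[1, 2], 0)
  expect_equal(correlation_matrix(matrix(0, 3, 2)), matrix(0, 3, 3))
  # four-source ring: diagonal of C is qS^2 + 2 qN^2, PSD and symmetric
  r4 <- build_Q("four_source", L = 80, La = 20, q_S = 0.5, q_N = 0.2)
  C4 <- correlation_matrix(r4, by_group = TRUE)
  expect_equal(unname(diag(C4)), rep(0.5^2 + 2 * 0.2^2, 4))
  expect_equal(C4, t(C4))
  expect_true(all(eigen(C4, only.values = TRUE)$values > -1e-12))
  expect_equal(C4[1, 2], 2 * 0.5 * 0.2 + 0)     # neighbours share one source
  expect_equal(C4[1, 3], 2 * 0.2^2)             # opposite pair
})

test_that("grouped sparse generation matches the dense thinning distribution", {
  cfg <- source_config(2, nu_S = 10, theta_t = 2)
  rmx <- build_Q("minor_source", L = 40, La = 10, q_A = 0.6, q_B = 0.5)
  gen <- generate_input_spikes(rmx, cfg, T = 60e3, dt = 0.5, seed = 21)
  # per-neuron rate ~ nu_X
  rate <- tabulate(gen$spk[, 1], nbins = 40) / 60
  expect_equal(mean(rate), 10, tolerance = 0.6)
  expect_true(all(abs(rate - 10) < 6))
  # determinism
  gen2 <- generate_input_spikes(rmx, cfg, T = 60e3, dt = 0.5, seed = 21)
  expect_identical(gen$spk, gen2$spk)
  # shared-source correlations: the two halves of the A group
  # co-fluctuate; A half vs background does not
  nb <- gen$n_bins
  bb <- bin_spikes(gen$spk, nb, 0.5, list(1:5, 6:10, 21:40), bin_ms = 10)
  c_within <- cor(bb[1, ], bb[2, ])
  c_bg <- cor(bb[1, ], bb[3, ])
  expect_gt(c_within, 0.05)
  expect_lt(abs(c_bg), 3 / sqrt(ncol(bb)))
})

test_that("parameter sets and response matrices round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  p <- default_params(theta_t = 0.5)
  write_config(p[c("theta_t", "nu_S", "wo_X")], f)
  back <- read_config(f)
  expect_equal(back$theta_t, 0.5)
  rmx <- build_Q("crosstalk", L = 12, La = 4, q_S = 0.6, q_N = 0.2)
  write_config(rmx, f)
  rt <- read_config(f)
  expect_equal(unname(rt$Q), unname(rmx$Q))
  expect_equal(rt$r_o, rmx$r_o)
})
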