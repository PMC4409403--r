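make_static_net <- function(p, L, M, N, La, Ma, Na, wX, wY, wZ,
                            gain = 1e-3, seed = 3, lateral = "structured") {
  network_config(p, L = L, M = M, N = N, La = La, Ma = Ma, Na = Na,
                 W_X = matrix(wX, M, L),
                 W_Y = if (is.matrix(wY)) wY else NULL,
                 W_Z = if (is.matrix(wZ)) wZ else NULL,
                 lateral = lateral, gain_E = gain, gain_I = gain, seed = seed)
}

test_that("lateral wiring builds the printed block structure", {
  w <- wire_lateral("structured", M = 20, N = 20, Ma = 10, Na = 10,
                    w_Y = 100, w_Z = 50)
  # W_Y block-diagonal: within-group E-to-I
  expect_true(all(w$W_Y[1:10, 1:10] == 100) && all(w$W_Y[1:10, 11:20] == 0))
  expect_true(all(w$W_Y[11:20, 11:20] == 100) && all(w$W_Y[11:20, 1:10] == 0))
  # W_Z block-anti-diagonal: between-group I-to-E
  expect_true(all(w$W_Z[1:10, 1:10] == 0) && all(w$W_Z[1:10, 11:20] == 50))
  expect_equal(unname(rowSums(w$W_Y)), rep(10 * 100, 20))
  # random mode: about half the connections present
  set.seed(4)
  wr <- wire_lateral("random", M = 20, N = 20, Ma = 10, Na = 10,
                     w_Y = 100, w_Z = 50)
  expect_equal(mean(wr$W_Y > 0), 0.5, tolerance = 0.1)
  expect_error(wire_lateral("structured", M = 20, N = 20, Ma = 7, Na = 10,
                            w_Y = 1, w_Z = 1), "divide")
})

test_that("a static excitatory network is a linear rate filter", {
  p <- default_params()
  rmx <- response_matrix(matrix(0, 60, 1), nu_X = 10)
  cfg <- source_config(1)
  inp <- generate_input_spikes(rmx, cfg, T = 60e3, dt = p$dt, seed = 21)
  net <- make_static_net(p, L = 60, M = 6, N = 6, La = 30, Ma = 3, Na = 3,
                         wX = 2.5, wY = matrix(0, 6, 6), wZ = matrix(0, 6, 6))
  rec <- run_poisson(net, inp, seed = 22, snap_every_ms = 0)
  # expected rate: gain * w * L * nu_X (unit-area PSP kernel)
  expected <- 1e-3 * 2.5 * 60 * 10
  got <- mean(firing_rates(rec))
  n <- nrow(rec$out_spk)
  expect_lt(abs(got - expected), 3 * sqrt(n) / (6 * 60) + 0.05)
  # silent with zero weights
  net0 <- make_static_net(p, L = 60, M = 6, N = 6, La = 30, Ma = 3, Na = 3,
                          wX = 0, wY = matrix(0, 6, 6), wZ = matrix(0, 6, 6))
  rec0 <- run_poisson(net0, inp, seed = 5, snap_every_ms = 0)
  expect_equal(nrow(rec0$out_spk), 0)
})

test_that("a single input spike arrives at the soma after the full delay", {
  p <- default_params()
  net <- make_static_net(p, L = 1, M = 2, N = 2, La = 1, Ma = 1, Na = 1,
                         wX = 2.5, wY = matrix(0, 2, 2), wZ = matrix(0, 2, 2),
                         seed = 8)
  inp <- list(spk = cbind(neuron = 1L, bin = 100L), n_bins = 1000L)
  rec <- run_poisson(net, inp, seed = 1, snap_every_ms = 0, record_u = TRUE)
  for (j in 1:2) {
    onset <- which(rec$u_E[j, ] > 0)[1]
    expect_equal(onset, 100 + net$dXa[j, 1] + net$dXd[j, 1] + 1)
  }
})

test_that("identical seeds give identical spike rasters", {
  p <- default_params()
  rmx <- build_Q("minor_source", L = 40, La = 10)
  cfg <- source_config(2)
  inp <- generate_input_spikes(rmx, cfg, T = 20e3, dt = p$dt, seed = 31)
  net <- make_static_net(p, L = 40, M = 4, N = 4, La = 10, Ma = 2, Na = 2,
                         wX = 2.5, wY = NULL, wZ = NULL)
  plas <- list(X = stdp_config("log_stdp", eta = p$eta_X,
                               sigma_stdp = 0.3, w_o = p$wo_X))
  r1 <- run_poisson(net, inp, plasticity = plas, seed = 77)
  r2 <- run_poisson(net, inp, plasticity = plas, seed = 77)
  expect_identical(r1$out_spk, r2$out_spk)
  expect_identical(r1$inh_spk, r2$inh_spk)
  expect_identical(r1$W_X, r2$W_X)
  r3 <- run_poisson(net, inp, plasticity = plas, seed = 78)
  expect_false(identical(r1$out_spk, r3$out_spk))
})

test_that("static structured-network inhibitory rates match the mean-field balance", {
  # large-population setting (the balance is a mean-field statement;
  # at small M the discreteness of output spikes creates correlated
  # inhibitory volleys whose rectification inflates rates)
  p <- default_params()
  rmx <- build_Q("minor_source", L = 200, La = 50, q_A = 0.6, q_B = 0.5)
  cfg <- source_config(2)
  inp <- generate_input_spikes(rmx, cfg, T = 60e3, dt = p$dt, seed = 41)
  p2 <- modifyList(p, list(La = 50L, Ma = 50L, Na = 50L))
  w <- wire_lateral("structured", M = 100, N = 100, Ma = 50, Na = 50,
                    w_Y = 500, w_Z = 0.4)
  net <- network_config(p2, L = 200, M = 100, N = 100, La = 50, Ma = 50,
                        Na = 50, W_X = matrix(2.5, 100, 200),
                        W_Y = w$W_Y, W_Z = w$W_Z,
                        gain_E = 1e-3, gain_I = 1e-3, seed = 42)
  rec <- run_poisson(net, inp, seed = 43, snap_every_ms = 0)
  got <- mean(firing_rates(rec, "inhibitory", from_ms = 1000))
  pred <- inhibitory_rates(c(2.5, 2.5, 2.5, 2.5), p2,
                           w_Y = 500, w_Z = 0.4,
                           gain_E = 1e-3, gain_I = 1e-3)
  expect_equal(got, pred[1], tolerance = 0.02)
})

test_that("the PSTH utility averages event-aligned windows", {
  tr <- matrix(5, 2, 1000)
  out <- psth(tr, c(300, 600), window = c(10, 20))
  expect_true(all(out == 5))
  expect_equal(ncol(out), 31)
  # single event, single trace: plain window copy
  tr2 <- matrix(seq_len(1000), 1, 1000)
  out2 <- psth(tr2, 500, window = c(2, 3))
  expect_equal(as.numeric(out2), 498:503)
  expect_error(psth(tr2, integer(0)), "at least one event")
})

test_that("the LIF backend relaxes to rest, respects reversal bounds and fires when driven", {
  p <- default_params()
  lif <- lif_config(r_o_II = 0)
  net <- make_static_net(p, L = 4, M = 2, N = 2, La = 2, Ma = 1, Na = 1,
                         wX = 0.001, wY = matrix(0, 2, 2),
                         wZ = matrix(0, 2, 2))
  # no input: relax from reset toward V_L = -70
  inp0 <- list(spk = matrix(integer(), 0, 2), n_bins = 40000L)
  rec0 <- run_lif(net, inp0, lif = lif, seed = 1, snap_every_ms = 0,
                  record_u = TRUE)
  expect_equal(rec0$u_E[1, ncol(rec0$u_E)], -70, tolerance = 1e-6)
  expect_equal(nrow(rec0$out_spk), 0)
  # strong drive: spikes, refractory floor at V_ref, v within [V_I, V_E]
  net2 <- make_static_net(p, L = 4, M = 2, N = 2, La = 2, Ma = 1, Na = 1,
                          wX = 0.02, wY = matrix(0, 2, 2),
                          wZ = matrix(0, 2, 2))
  spikes <- cbind(neuron = rep(1:4, 50), bin = rep(seq(10, 5000, by = 100), each = 4))
  rec2 <- run_lif(net2, list(spk = spikes[order(spikes[, 2]), ],
                             n_bins = 10000L),
                  lif = lif, seed = 2, snap_every_ms = 0, record_u = TRUE)
  expect_gt(nrow(rec2$out_spk), 0)
  expect_true(all(rec2$u_E >= -80 - 1e-9 & rec2$u_E <= 0 + 1e-9))
})

test_that("spike trains round-trip through two-column text", {
  spk <- cbind(neuron = c(1L, 3L, 2L), bin = c(10L, 20L, 40L))
  f <- tempfile(fileext = ".txt")
  write_spikes(spk, f, dt = 0.5)
  back <- read_spikes(f)
  expect_equal(back$neuron, c(1L, 3L, 2L))
  expect_equal(back$time_ms, c(5, 10, 20))
})
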