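test_that("the discretised kernel weights follow the printed form and sum to 1", {
  st <- ica_state(L = 10, p = 2, dt_bin = 5, theta_t = 2)
  k <- seq_along(st$phi) - 1
  expect_equal(st$phi,
               ((k + 0.5) * 5)^2 * exp(-(k + 0.5) * 5 / 2) / (2 * 2^3))
  # the printed midpoint discretisation over-counts at coarse bins;
  # the mass converges to 1 as the bin shrinks
  expect_equal(sum(st$phi) * st$dt_bin, 1, tolerance = 0.1)
  st_fine <- ica_state(L = 10, p = 2, dt_bin = 0.5, theta_t = 2)
  expect_equal(sum(st_fine$phi) * 0.5, 1, tolerance = 0.01)
})

test_that("spike probabilities reduce correctly in the edge cases", {
  st <- ica_state(L = 4, p = 2, r_o = 0)
  # no recent source events and no baseline -> (numerically) zero
  expect_true(all(spike_prob(st, c(0, 0)) < 1e-10))
  # q = 0 -> baseline only
  st2 <- ica_state(L = 4, p = 2, r_o = 4, Q0 = matrix(0, 4, 2))
  expect_equal(spike_prob(st2, c(0.1, 0.1)), rep(4 * 5 / 1000, 4))
  # single source event one bin ago with q = 0.6
  st3 <- ica_state(L = 1, p = 1, r_o = 4, Q0 = matrix(0.6, 1, 1))
  A <- st3$phi[2]                     # phi_1: event one bin in the past
  expect_equal(spike_prob(st3, A),
               1 - (1 - 4 * 5 / 1000) * (1 - 0.6 * A))
})

test_that("the joint-state posterior is normalised and matches the prior when q = 0", {
  st <- ica_state(L = 6, p = 2, r_o = 4, Q0 = matrix(0, 6, 2))
  pr <- sample_step_probs(st, x_k = rep(0, 6))
  expect_equal(sum(pr), 1)
  rs <- st$r_s_dt
  prior <- c((1 - rs)^2, rs * (1 - rs), (1 - rs) * rs, rs^2)
  expect_equal(pr, prior, tolerance = 1e-12)
})

test_that("the compiled sampler agrees with the R enumeration oracle to 1e-12", {
  set.seed(60)
  for (p in 1:3) {
    L <- 8
    st <- ica_state(L = L, p = p, r_o = 4,
                    Q0 = matrix(runif(L * p, 0, 0.7), L, p))
    y_hist <- matrix(rbinom(p * 12, 1, 0.2), p, 12)
    x_k <- rbinom(L, 1, 0.3)
    Ah <- corrspike:::kernel_sums(st, y_hist)
    pr_R <- sample_step_probs(st, x_k, y_hist)
    pr_C <- corrspike:::cpp_ica_state_probs(as.integer(x_k), st$Q, st$phi,
                                            Ah, mean(st$ro_dt), st$r_s_dt)
    expect_equal(pr_R, pr_C, tolerance = 1e-12)
  }
})

test_that("gradient updates move q in the expected direction", {
  st <- ica_state(L = 3, p = 1, r_o = 4, Q0 = matrix(0.3, 3, 1), eta = 0.01)
  yh <- matrix(c(0, 0, 1), 1, 3)      # sampled event in the current bin
  up <- update_qtilde(st, x_k = c(1, 0, 1), y_hist = yh)
  dQ <- attr(up, "dQ")
  expect_gt(dQ[1, 1], 0)              # input spike + recent source -> LTP
  expect_lt(dQ[2, 1], 0)              # silent input + recent source -> LTD
  # no recent sampled events -> no update
  up0 <- update_qtilde(st, x_k = c(1, 0, 1), y_hist = matrix(0, 1, 3))
  expect_true(all(attr(up0, "dQ") == 0))
  # weights stay in [0, 1]
  st2 <- ica_state(L = 3, p = 1, r_o = 4, Q0 = matrix(0.999, 3, 1), eta = 10)
  up2 <- update_qtilde(st2, x_k = c(1, 1, 1), y_hist = yh)
  expect_true(all(up2$Q >= 0 & up2$Q <= 1))
})

test_that("the LTP/LTD curves have the STDP-like temporal and weight dependence", {
  st <- ica_state(L = 1, p = 1, dt_bin = 5, theta_t = 2)
  cur <- ltp_ltd_curve(st)
  # LTP peaks where the discretised kernel peaks (grid-evaluation oracle)
  for (q in unique(cur$q)) {
    sub <- cur[cur$q == q, ]
    expect_equal(sub$lag_bin[which.max(sub$ltp)],
                 which.max(st$phi) - 1)
  }
  ltd <- attr(cur, "ltd")
  # q = 0 limit: LTD total is -sum(phi)
  st0 <- ica_state(L = 1, p = 1)
  c0 <- ltp_ltd_curve(st0, q_values = c(1e-12, 0.1, 0.3, 0.5))
  expect_equal(unname(attr(c0, "ltd")[1]), -sum(st0$phi), tolerance = 1e-6)
  # |LTD| grows with the weight
  expect_true(all(diff(abs(attr(c0, "ltd"))) > 0))
})

test_that("the learner recovers the source structure and is deterministic", {
  # generate inputs from the generative model itself; enough input
  # neurons that single source events are detectable per bin
  set.seed(601)
  L <- 100; p <- 2; K <- 150e3          # 750 s of 5 ms bins
  qS <- 0.6
  st <- ica_state(L = L, p = p, r_o = 4, eta = 0.001)
  s <- matrix(rbinom(p * K, 1, st$r_s_dt), p, K)
  A <- t(vapply(1:p, function(mu) corrspike:::conv_events(s[mu, ], st$phi, K),
                numeric(K)))
  pA <- 1 - (1 - 4 * 5 / 1000) * (1 - qS * A[1, ])
  pB <- 1 - (1 - 4 * 5 / 1000) * (1 - qS * A[2, ])
  x <- rbind(matrix(rbinom(L / 2 * K, 1, rep(pA, each = L / 2)), L / 2),
             matrix(rbinom(L / 2 * K, 1, rep(pB, each = L / 2)), L / 2))
  Qtrue <- rbind(cbind(rep(qS, L / 2), 0), cbind(0, rep(qS, L / 2)))
  fit <- run_learning(st, x, mode = "sampled", seed = 602)
  m <- match_columns(fit$Q, Qtrue)
  st_init_err <- match_columns(st$Q, Qtrue)$max_abs_err
  expect_lt(m$max_abs_err, st_init_err)     # clear improvement
  expect_gt(m$mean_cosine, 0.9)             # column alignment with Q
  fit2 <- run_learning(st, x, mode = "sampled", seed = 602)
  expect_identical(fit$Q, fit2$Q)
  # the ideal observer's sampled sources track the truth at least as
  # well as the blind learner's
  fit_id <- run_learning(st, x, mode = "ideal", Q_true = Qtrue, seed = 603)
  cc_id <- as.numeric(cross_correlation(s, fit_id$Y))
  cc_sm <- as.numeric(cross_correlation(s, fit$Y))
  expect_gte(cc_id + 0.02, cc_sm)
})

test_that("with no sources in the input the estimate decays toward zero", {
  set.seed(80)
  L <- 10; K <- 40e3
  st <- ica_state(L = L, p = 1, r_o = 10, Q0 = matrix(0.5, L, 1), eta = 0.01)
  x <- matrix(rbinom(L * K, 1, 10 * 5 / 1000), L, K)   # pure baseline firing
  fit <- run_learning(st, x, mode = "sampled", seed = 81)
  expect_lt(mean(fit$Q), 0.3)
})
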