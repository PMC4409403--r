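test_that("log-STDP amplitudes match their closed forms", {
  expect_equal(log_stdp_fp(0), 1)                        # Cp = 1 at w = 0
  expect_equal(log_stdp_fp(2.5, w_o = 2.5, beta = 50), exp(-1 / 50))
  # LTD balance: Cd = Cp tau_p / tau_d = 0.5; f_d(w_o) = -Cd
  expect_equal(log_stdp_fd(2.5, w_o = 2.5, alpha = 20, Cd = 0.5), -0.5)
  expect_equal(log_stdp_fd(0), 0)
  w <- seq(0, 20, by = 0.5)
  expect_true(all(diff(log_stdp_fp(w)) < 0))             # monotone decreasing
  fd <- log_stdp_fd(w)
  expect_true(all(diff(fd) < 0))                         # |f_d| increasing
  expect_true(all(diff(diff(-fd)) < 0))                  # concave growth
})

test_that("the STDP window integral vanishes for the balanced lateral rule", {
  cfg <- stdp_config("hebbian", eta = 1, tau_p = 20, tau_d = 20, gamma = 1)
  expect_equal(stdp_window_integral(0, cfg), 0)
  # and for the correlation detector irrespective of gamma scaling of
  # one branch when gamma = 1
  cfg2 <- stdp_config("corr_detector", eta = 1, tau_p = 17, tau_d = 34,
                      gamma = 1)
  expect_equal(stdp_window_integral(0, cfg2), 0, tolerance = 1e-12)
})

test_that("single-pair updates follow the printed rule", {
  cfg <- stdp_config("log_stdp", eta = 0.125, w_o = 2.5)
  w <- 2.5
  # post exactly tau_p after pre
  r <- pair_update(pre = 10, post = 10 + cfg$tau_p, cfg, w)
  expect_equal(r$dw, cfg$eta * log_stdp_fp(w) * exp(-1), tolerance = 1e-12)
  # pre after post: LTD branch
  r2 <- pair_update(pre = 10 + cfg$tau_d, post = 10, cfg, w)
  expect_equal(r2$dw, cfg$eta * log_stdp_fd(w, Cd = cfg$Cd) * exp(-1),
               tolerance = 1e-12)
  # simultaneous at-synapse spikes tie-break as LTP
  r3 <- pair_update(pre = 10, post = 10, cfg, w)
  expect_equal(r3$dw, cfg$eta * log_stdp_fp(w), tolerance = 1e-12)
})

test_that("lateral rules match their printed branch values", {
  for (g in c(0.7, 1.4)) {
    heb <- stdp_config("hebbian", eta = 0.1, tau_p = 20, tau_d = 40, gamma = g)
    anti <- stdp_config("anti_hebbian", eta = 0.1, tau_p = 20, tau_d = 40,
                        gamma = g)
    # Hebbian LTP at dt = +tau_p
    expect_equal(pair_update(0, heb$tau_p, heb, 1)$dw, 0.1 * exp(-1))
    # anti-Hebbian: LTP branch is -eta exp(-dt/tau_d)
    expect_equal(pair_update(0, 10, anti, 1)$dw, -0.1 * exp(-10 / 40))
    # anti-Hebbian LTD branch: +eta gamma (tau_d / tau_p) exp(-|dt|/tau_p)
    expect_equal(pair_update(10, 0, anti, 1)$dw,
                 0.1 * g * (40 / 20) * exp(-10 / 20))
  }
  # correlation detector at dt -> 0+ gives eta (1 - tau_p / tau_d)
  cd <- stdp_config("corr_detector", eta = 0.1, tau_p = 17, tau_d = 34,
                    gamma = 1)
  expect_equal(pair_update(0, 1e-9, cd, 1)$dw, 0.1 * (1 - 17 / 34),
               tolerance = 1e-6)
  # anti-correlation detector is the sign flip
  acd <- stdp_config("anti_corr_detector", eta = 0.1, tau_p = 17, tau_d = 34,
                     gamma = 1)
  expect_equal(pair_update(3, 11, acd, 1)$dw, -pair_update(3, 11, cd, 1)$dw)
})

test_that("online traces equal brute-force all-pairs summation", {
  set.seed(42)
  for (rule in c("log_stdp", "hebbian", "anti_hebbian", "corr_detector")) {
    cfg <- stdp_config(rule, eta = 0.01, tau_p = 17, tau_d = 34,
                       gamma = 1.4, w_o = 2.5, w_max = 1e6)
    for (rep in 1:3) {
      pre <- sort(runif(80, 0, 2000))
      post <- sort(runif(80, 0, 2000))
      w0 <- 2.5
      online <- pair_update(pre, post, cfg, w0, sequential = FALSE)$dw
      brute <- brute_force_pairs(pre, post, cfg, w0)
      expect_equal(online, brute, tolerance = 1e-10)
    }
  }
})

test_that("weights stay inside their bounds and noise is zero-mean", {
  cfg <- stdp_config("log_stdp", eta = 5, w_o = 2.5, w_max = 10)
  set.seed(1)
  pre <- sort(runif(200, 0, 1000)); post <- sort(runif(200, 0, 1000))
  r <- pair_update(pre, post, cfg, 2.5)
  expect_true(r$w >= 0 && r$w <= 10)
  # multiplicative noise leaves the expected update unchanged
  cfg0 <- stdp_config("log_stdp", eta = 0.05, sigma_stdp = 0)
  cfgn <- stdp_config("log_stdp", eta = 0.05, sigma_stdp = 0.3)
  pre <- sort(runif(40, 0, 500)); post <- sort(runif(40, 0, 500))
  det <- pair_update(pre, post, cfg0, 2.5, sequential = FALSE)$dw
  noisy <- vapply(1:400, function(s)
    pair_update(pre, post, cfgn, 2.5, sequential = FALSE, seed = s)$dw,
    numeric(1))
  expect_equal(mean(noisy), det, tolerance = 4 * sd(noisy) / sqrt(400))
})

test_that("balanced Poisson pre/post trains drift at F-bar times the rate product", {
  # with independent pre/post Poisson trains the expected pairing drift
  # per unit time is F-bar(w) * rate_pre * rate_post
  cfg <- stdp_config("log_stdp", eta = 0.05, w_o = 2.5, w_max = 1e6)
  w0 <- 2.5
  rate <- 0.02            # per ms (20 Hz)
  T <- 60e3
  set.seed(9)
  drifts <- vapply(1:8, function(i) {
    pre <- cumsum(rexp(2 * rate * T, rate)); pre <- pre[pre < T]
    post <- cumsum(rexp(2 * rate * T, rate)); post <- post[post < T]
    pair_update(pre, post, cfg, w0, sequential = FALSE)$dw / T
  }, numeric(1))
  expected <- stdp_window_integral(w0, cfg) * rate^2
  expect_equal(mean(drifts), expected,
               tolerance = 4 * sd(drifts) / sqrt(length(drifts)) + 1e-8)
})
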