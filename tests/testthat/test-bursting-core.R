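test_that("sister chain stationary law is Binomial(2, p_on)", {
  # p_on = k_on_1p / (k_on_1p + k_off_1p); occupancy of {0,1,2} active copies
  cases <- list(c(1, 1), c(1, 3), c(0.25, 0.75), c(2.5, 0.5))
  for (cs in cases) {
    Q <- build_sister_chain(cs[1], cs[2])
    p_on <- cs[1] / sum(cs)
    expect_equal(unname(stationary_distribution(Q)),
                 dbinom(0:2, 2, p_on), tolerance = 1e-10)
  }
  expect_equal(unname(stationary_distribution(build_sister_chain(1, 1))),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(stationary_distribution(build_sister_chain(1, 3))[1]),
               9 / 16)
})

test_that("absorbing and degenerate generators are handled", {
  Q <- build_sister_chain(0, 2)   # OFF absorbing
  expect_equal(unname(Q[1, ]), c(0, 0, 0))
  expect_error(stationary_distribution(matrix(0, 3, 3)), "degenerate")
  expect_error(build_sister_chain(-1, 1), "k_on_1p")
})

test_that("symmetric chain has the uniform stationary law", {
  Q <- matrix(1, 3, 3); diag(Q) <- -2
  expect_equal(unname(stationary_distribution(Q)), rep(1 / 3, 3))
})

test_that("effective k_on sums the OFF-exit rates", {
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 0.8; Q[1, 3] <- 0.2; Q[2, 1] <- 1; Q[3, 2] <- 1
  diag(Q) <- -rowSums(Q)
  expect_equal(effective_kon(Q), 1.0)
  expect_equal(effective_kon(build_sister_chain(0.5, 1)), 1.0)
  expect_equal(effective_kon(build_sister_chain(0, 1)), 0)
})

test_that("effective k_off follows the OFF-occupancy formula", {
  expect_equal(effective_koff(1, 0.5), 1)
  expect_equal(effective_koff(1, 1 / 3), 0.5)
  expect_error(effective_koff(1, 0), "p_off")
  expect_error(effective_koff(1, 1), "p_off")
  # sister chain (1,1): k_on = 2, p_off = 1/4 -> k_off = 2/3
  Q <- build_sister_chain(1, 1)
  p <- stationary_distribution(Q)
  expect_equal(effective_koff(effective_kon(Q), p[["p_off"]]), 2 / 3)
})

test_that("two-state chain embedded in 3-state form returns its true k_off", {
  # q(1->2) = 0: aggregation must be exact, not approximate
  for (rates in list(c(0.7, 1.3), c(2, 0.4))) {
    Q <- matrix(0, 3, 3)
    Q[1, 2] <- rates[1]; Q[2, 1] <- rates[2]
    diag(Q) <- -rowSums(Q)
    Q[3, 3] <- -1e-3; Q[3, 2] <- 1e-3  # ON2 never entered, leaks back: pi3 = 0
    p <- stationary_distribution(Q)
    expect_equal(effective_koff(effective_kon(Q), p[["p_off"]]), rates[2],
                 tolerance = 1e-6)
  }
})

test_that("effective r is the occupancy-weighted ON-state mean", {
  expect_equal(effective_r(0.3, 0.6, 5, 5), 5)
  expect_equal(effective_r(0.5, 0, 4, 99), 4)
  expect_equal(effective_r(0.5, 0.25, 4, 8), 16 / 3)
  expect_error(effective_r(0, 0, 4, 8), "never ON")
})

test_that("mean initiation rate matches the two-state formula", {
  bp <- burst_params(1.5, 0.5, 10, 0.25, 0.5, 0.25)
  expect_equal(mean_initiation_rate(bp), 7.5)
  bp_on <- burst_params(1, 0, 10, 0, 0.5, 0.5)
  expect_equal(mean_initiation_rate(bp_on), 10)
})

test_that("Gillespie paths reproduce stationary occupancy and dwell times", {
  Q <- build_sister_chain(0.75, 0.5)
  path <- simulate_chain_path(Q, 1e4, seed = 11)
  brk <- c(0, path$jump_times, path$duration)
  dwell <- diff(brk)
  occ <- vapply(0:2, function(s) sum(dwell[path$states == s]), numeric(1)) /
    path$duration
  p <- stationary_distribution(Q)
  # binomial 3-s.e. bound on time-averaged occupancy
  se <- sqrt(p * (1 - p) / length(dwell))
  expect_true(all(abs(occ - p) < 3 * pmax(se, 0.01)))
  # OFF dwells are Exp(effective_kon)
  off_dwell <- dwell[path$states == 0 & seq_along(dwell) < length(dwell)]
  expect_equal(mean(off_dwell), 1 / effective_kon(Q),
               tolerance = 3 / sqrt(length(off_dwell)))
})

test_that("mean ON-excursion length matches 1/k_off for the sister chain", {
  Q <- build_sister_chain(1, 1)     # k_on = 2, p_off = 1/4 -> k_off = 2/3
  path <- simulate_chain_path(Q, 2e4, seed = 3)
  s <- path$states
  on <- s > 0
  runs <- rle(on)
  # interior ON excursions in chain time: measure their total duration
  brk <- c(0, path$jump_times, path$duration)
  dwell <- diff(brk)
  excursion_len <- numeric(0)
  i <- 1
  for (k in seq_along(runs$lengths)) {
    idx <- i:(i + runs$lengths[k] - 1)
    if (runs$values[k]) excursion_len <- c(excursion_len, sum(dwell[idx]))
    i <- i + runs$lengths[k]
  }
  excursion_len <- excursion_len[-c(1, length(excursion_len))]
  expect_equal(mean(excursion_len), 1.5,
               tolerance = 3 * sd(excursion_len) / sqrt(length(excursion_len)) / 1.5)
})

test_that("long-run rendered initiation matches mean_initiation_rate", {
  Q <- build_sister_chain(0.75, 0.5)
  r_vec <- c(0, 4, 8)
  bp <- aggregate_burst_params(Q, r_vec)
  model <- promoter_rate_model(Q, r_vec, sigma_noise = 0)
  path <- simulate_chain_path(Q, 5e3, seed = 5)
  occ <- msburst:::frame_occupancy(path, 20 / 60, floor(5e3 * 3))
  rho <- as.numeric(occ %*% r_vec)
  se <- sd(rho) / sqrt(length(rho) / 50)  # generous: dwell autocorrelation
  expect_equal(mean(rho), mean_initiation_rate(bp), tolerance = 3 * se / mean(rho))
})

test_that("rendered step response ramps to its plateau at t_elong", {
  model <- promoter_rate_model(build_sister_chain(1, 1), c(0, 6, 12),
                               t_elong = 140, dt_frame = 20, sigma_noise = 0)
  path <- state_path(1L, numeric(0), 10)   # ON1 from t = 0, never leaves
  tr <- render_trace(path, model)
  w <- 7
  plateau <- 6 * w * 20 / 60
  expect_equal(tr$fluo_au[1:7], 6 * (1:7) * 20 / 60)
  expect_equal(tr$time_s[min(which(abs(tr$fluo_au - plateau) < 1e-12))], 140)
  expect_true(all(abs(tr$fluo_au[7:nrow(tr)] - plateau) < 1e-12))
})

test_that("rendering is linear in r_vec and zero for silent paths", {
  q0 <- matrix(0, 3, 3)
  q0[3, 2] <- 1e-12; q0[2, 3] <- 1e-12; q0[1, 2] <- 1e-12; q0[2, 1] <- 1e-12
  diag(q0) <- -rowSums(q0)
  off_path <- state_path(0L, numeric(0), 10)
  m0 <- promoter_rate_model(q0, c(0, 5, 10), sigma_noise = 0)
  expect_true(all(render_trace(off_path, m0)$fluo_au == 0))
  on1 <- state_path(1L, numeric(0), 10)
  on2 <- state_path(2L, numeric(0), 10)
  m <- promoter_rate_model(q0, c(0, 5, 10), sigma_noise = 0)
  expect_equal(render_trace(on2, m)$fluo_au, 2 * render_trace(on1, m)$fluo_au)
})

test_that("stochastic operations are reproducible under a fixed seed", {
  Q <- build_sister_chain(1, 0.6)
  p1 <- simulate_chain_path(Q, 30, seed = 99)
  p2 <- simulate_chain_path(Q, 30, seed = 99)
  expect_identical(p1, p2)
  m <- promoter_rate_model(Q, c(0, 5, 10))
  expect_identical(render_trace(p1, m, seed = 7), render_trace(p2, m, seed = 7))
})

test_that("paths shorter than the trace window are rejected", {
  m <- promoter_rate_model(build_sister_chain(1, 1), c(0, 5, 10))
  p <- state_path(1L, numeric(0), 1)  # 1 min = 3 frames at 20 s
  expect_error(render_trace(p, m, n_frames = 10), "cover")
})
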