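test_that("compound state space enumerates histories with a shift successor map", {
  sp <- build_state_space(2, 2)
  expect_equal(sp$n_states, 4)
  expect_equal(dim(sp$succ), c(4, 2))
  sp3 <- build_state_space(3, 7)
  expect_equal(sp3$n_states, 2187)
  # successor of (a, b, c) under new symbol s is (s, a, b)
  for (s_idx in c(1, 500, 2187)) {
    for (j in 0:2) {
      succ_digits <- sp3$digits[sp3$succ[s_idx, j + 1], ]
      expect_equal(succ_digits, c(j, sp3$digits[s_idx, 1:6]))
    }
  }
  # each state has K predecessors
  expect_true(all(table(sp3$succ) == 3))
  expect_error(build_state_space(3, 8), "cap")
})

test_that("expected emission is the kernel-weighted dot product", {
  expect_equal(expected_emission(rep(0, 7), c(0, 6, 12), rep(1, 7)), 0)
  expect_equal(expected_emission(rep(1, 7), c(0, 6, 12), rep(1, 7), 20), 14)
  set.seed(8)
  st <- sample(0:2, 7, replace = TRUE)
  kap <- runif(7)
  r <- c(0, 4, 9)
  expect_equal(expected_emission(st, r, kap, 20),
               sum(kap * r[st + 1]) * 20 / 60)
})

test_that("forward-backward matches brute-force path enumeration", {
  set.seed(9)
  A <- matrix(c(0.85, 0.15, 0.4, 0.6), 2, byrow = TRUE)
  params <- cphmm_params(A, c(0.7, 0.3), c(0, 5), sigma = 1.1,
                         kernel = c(1, 1), dt_grid = 20)
  for (rep in 1:3) {
    f <- rnorm(5, sample(0:3, 5, replace = TRUE), 1)
    fb <- forward_backward(f, params, small_space_22)
    expect_equal(fb$loglik, brute_force_loglik(f, params, 2, 2),
                 tolerance = 1e-8)
    expect_equal(rowSums(fb$posterior), rep(1, 5), tolerance = 1e-10)
  }
})

test_that("with huge noise the posteriors approach the chain's prior marginals", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  params <- cphmm_params(A, c(0.5, 0.5), c(0, 5), sigma = 1e5,
                         kernel = c(1, 1), dt_grid = 20)
  f <- c(0, 3, 1, 2, 0, 4)
  fb <- forward_backward(f, params, small_space_22)
  # emission-free oracle: prior marginals under repeated application of A
  prior <- matrix(NA, 6, 2)
  p <- c(0.5, 0.5)
  for (t in 1:6) { prior[t, ] <- p; p <- as.numeric(p %*% A) }
  expect_equal(fb$posterior, prior, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("EM log-likelihood is non-decreasing and fits are reproducible", {
  tl <- simulate_bin(1.0, 0.5, 7.5, n_traces = 6, n_frames = 40,
                     t_elong = 60, seed = 21)
  sp <- build_state_space(3, 3)
  cfg <- cphmm_config(n_restarts = 2, max_iter = 40, tol = 1e-6, seed = 5)
  fit <- em_fit(tl, sp, cfg)
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik_trace[-1])))
  fit2 <- em_fit(tl, sp, cfg)
  expect_identical(fit$params, fit2$params)
})

test_that("noise-free constant-ON data recovers the plateau initiation rate", {
  # all frames at the full-window plateau of ON1 at rate r1
  r1 <- 6; w <- 3
  plateau <- r1 * w * 20 / 60
  sp <- build_state_space(2, w)
  tl <- lapply(1:3, function(i) rep(plateau, 30) + rnorm(30, 0, 1e-3))
  set.seed(1)
  fit <- em_fit(tl, sp, cphmm_config(n_restarts = 1, max_iter = 30, seed = 2))
  on_level <- max(fit$params$r_vec)
  expect_equal(on_level, r1, tolerance = 0.02)
})

test_that("decoding recovers true states when noise is tiny", {
  m <- model_from_burst_params(1, 0.5, 7.5, t_elong = 60, dt_frame = 20,
                               sigma_noise = 0.01)
  sp <- build_state_space(3, 3)
  path <- simulate_chain_path(m$Q, 25, seed = 31)
  tr <- render_trace(path, m, seed = 32)
  # decode with the true parameters
  dt_min <- 20 / 60
  A <- as.matrix(Matrix::expm(m$Q * dt_min))
  params <- cphmm_params(A, stationary_distribution(m$Q), m$r_vec,
                         sigma = 0.01, kernel = rep(1, 3), dt_grid = 20)
  dec <- decode_promoter_states(tr$fluo_au, params, sp)
  agree <- mean(dec == tr$true_state)
  expect_gte(agree, 0.95)
  vit <- decode_promoter_states(tr$fluo_au, params, sp, method = "viterbi")
  expect_gte(mean(vit == tr$true_state), 0.95)
  # all-zero traces decode to OFF everywhere
  dec0 <- decode_promoter_states(rep(0, 20), params, sp)
  expect_true(all(dec0 == 0))
  # table-level decoding annotates every frame
  df <- tibble::tibble(embryo_id = "e1", nucleus_id = "n1",
                       time_s = tr$time_s, fluo_au = tr$fluo_au)
  out <- decode_traces(df, params, sp)
  expect_equal(out$state_inferred, dec)
})

test_that("rate conversion round-trips an exactly exponentiated generator", {
  Q <- build_sister_chain(0.6, 0.9)
  dt_min <- 20 / 60
  A <- as.matrix(Matrix::expm(Q * dt_min))
  params <- cphmm_params(A, stationary_distribution(Q), c(0, 5, 10),
                         sigma = 1, kernel = rep(1, 3), dt_grid = 20)
  fake_fit <- structure(list(params = params), class = "cphmm_fit")
  bp <- to_burst_params(fake_fit)
  expect_equal(attr(bp, "rate_method"), "logm")
  truth <- aggregate_burst_params(Q, c(0, 5, 10))
  expect_equal(bp$k_on, truth$k_on, tolerance = 1e-6)
  expect_equal(bp$k_off, truth$k_off, tolerance = 1e-6)
  expect_equal(bp$r, truth$r, tolerance = 1e-6)
})

test_that("a no-switching fit is flagged as degenerate", {
  params <- cphmm_params(diag(3), c(1, 0, 0), c(0, 5, 10), sigma = 1,
                         kernel = rep(1, 3), dt_grid = 20)
  expect_error(to_burst_params(params), "degenerate")
})

test_that("compound posteriors marginalize consistently across frames", {
  # promoter-state marginal at frame t from the suffix symbol of frame t+1
  # compound posteriors must match the current-symbol marginal at frame t
  set.seed(10)
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  params <- cphmm_params(A, c(0.5, 0.5), c(0, 5), sigma = 1,
                         kernel = c(1, 1), dt_grid = 20)
  f <- rnorm(8, 2, 1.5)
  fb <- forward_backward(f, params, small_space_22)
  # digits[, 2] of the state at t+1 is the symbol at t
  prev_sym <- small_space_22$digits[, 2]
  for (t in 1:7) {
    marg_from_next <- rowsum(fb$gamma[, t + 1], prev_sym)[, 1]
    expect_equal(as.numeric(marg_from_next), fb$posterior[t, ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("fitting 3 states to effectively 2-state data empties ON2", {
  # one promoter permanently OFF: the locus never reaches ON2
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 1; Q[2, 1] <- 0.5
  diag(Q) <- -rowSums(Q)
  Q[3, 2] <- 1e-9; Q[3, 3] <- -1e-9
  m <- promoter_rate_model(Q, c(0, 6, 12), t_elong = 60, sigma_noise = 0.8)
  tl <- lapply(1:10, function(i) {
    p <- simulate_chain_path(Q, 21, initial = 0, seed = 40 + i)
    render_trace(p, m, n_frames = 60, seed = 140 + i)$fluo_au
  })
  sp <- build_state_space(3, 3)
  fit <- em_fit(tl, sp, cphmm_config(n_restarts = 2, max_iter = 60, seed = 3))
  p_stat <- msburst:::discrete_stationary(fit$params$A)
  # occupancy of the higher ON state collapses
  expect_lt(min(p_stat[2:3]), 0.05)
})
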