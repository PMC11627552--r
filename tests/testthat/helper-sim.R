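# Shared fixtures, all generated in code.

# one inference bin simulated at prescribed effective burst parameters
simulate_bin <- function(k_on, k_off, r, n_traces = 40, n_frames = 70,
                         t_elong = 140, dt_grid = 20, sigma_noise = 1.5,
                         seed = 1) {
  m <- model_from_burst_params(k_on, k_off, r, t_elong = t_elong,
                               dt_frame = dt_grid, sigma_noise = sigma_noise)
  lapply(seq_len(n_traces), function(i) {
    p <- simulate_chain_path(m$Q, (n_frames + 1) * dt_grid / 60,
                             seed = seed * 1000 + i)
    render_trace(p, m, n_frames = n_frames, seed = seed * 1000 + i + 500)$fluo_au
  })
}

# brute-force cpHMM log-likelihood by enumerating all K^T promoter paths
brute_force_loglik <- function(f, params, K, w) {
  T_len <- length(f)
  paths <- as.matrix(expand.grid(rep(list(0:(K - 1)), T_len)))
  rho <- params$r_vec * params$dt_grid / 60
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    x <- paths[i, ]
    pr <- params$pi0[x[1] + 1]
    if (T_len > 1) {
      for (t in 2:T_len) pr <- pr * params$A[x[t - 1] + 1, x[t] + 1]
    }
    for (t in seq_len(T_len)) {
      l <- min(t, w)
      mu <- sum(params$kernel[seq_len(l)] * rho[x[t:(t - l + 1)] + 1])
      pr <- pr * stats::dnorm(f[t], mu, params$sigma)
    }
    tot <- tot + pr
  }
  log(tot)
}

small_space_22 <- build_state_space(2, 2)
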