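#' Compound promoter-history state space
#'
#' Enumerates the K^w vectors of the last `w` promoter states (newest
#' first). Because MS2 fluorescence integrates initiation over the
#' elongation window, the emission at a frame depends on this whole
#' history, not just the current promoter state; the compound chain makes
#' that dependence Markovian again.
#'
#' @param K number of promoter states (default 3: OFF, ON1, ON2).
#' @param w window length in frames, typically `round(t_elong / dt_grid)`.
#' @param cap guard on the state-space size K^w.
#' @return An object of class `compound_state_space` with the digit matrix
#'   (`n_states` x `w`, symbols 0..K-1, column 1 = current frame), the
#'   current-symbol vector `cur` and the successor map `succ`
#'   (`n_states` x K, 1-based).
#' @export
build_state_space <- function(K = 3, w = 7, cap = 2187) {
  stopifnot(K >= 2, w >= 1)
  n <- K^w
  if (n > cap) {
    stop(sprintf("compound space K^w = %d exceeds cap %d; use a smaller w",
                 n, cap), call. = FALSE)
  }
  s0 <- 0:(n - 1L)
  digits <- vapply(seq_len(w),
                   function(i) (s0 %/% K^(i - 1L)) %% K,
                   numeric(n))
  digits <- matrix(as.integer(digits), nrow = n)
  cur <- digits[, 1L]
  # shifting in new symbol j: (j, d_1, ..., d_{w-1})
  base <- K * (s0 %% K^(w - 1L))
  succ <- vapply(0:(K - 1L), function(j) base + j + 1L, numeric(n))
  succ <- matrix(as.integer(succ), nrow = n)
  structure(list(K = as.integer(K), w = as.integer(w), n_states = n,
                 digits = digits, cur = cur, succ = succ),
            class = "compound_state_space")
}

#' Expected noise-free emission of one compound state
#'
#' `sum_i kappa_i r(state_i) dt/60`, where `state_1` is the current frame.
#'
#' @param compound_state integer vector of promoter symbols, newest first.
#' @param r_vec initiation rates per promoter state, AU/min.
#' @param kernel emission-kernel weights, same length as `compound_state`.
#' @param dt_grid frame interval, seconds.
#' @return expected fluorescence in AU.
#' @export
expected_emission <- function(compound_state, r_vec, kernel, dt_grid = 20) {
  stopifnot(length(kernel) == length(compound_state))
  sum(as.numeric(kernel) * r_vec[compound_state + 1L]) * dt_grid / SEC_PER_MIN
}

# kernel-weighted promoter-state occupancy of every compound state,
# for every truncation length l = 1..w (early frames see only l frames
# of real history)
compound_design <- function(space, kernel) {
  stopifnot(length(kernel) == space$w)
  D <- vector("list", space$w)
  acc <- matrix(0, space$n_states, space$K)
  for (l in seq_len(space$w)) {
    for (k in seq_len(space$K)) {
      acc[, k] <- acc[, k] + kernel[l] * (space$digits[, l] == k - 1L)
    }
    D[[l]] <- acc * 1  # copy
  }
  D
}

#' Discrete-time cpHMM parameters
#'
#' @param A K x K per-frame promoter transition probability matrix.
#' @param pi0 initial promoter-state distribution.
#' @param r_vec initiation rates (AU/min), `r_vec[1] = 0` for OFF.
#' @param sigma Gaussian emission s.d. (AU), > 0.
#' @param kernel an [emission_kernel()] (or plain weights of length w).
#' @param dt_grid frame interval, seconds.
#' @return An object of class `cphmm_params`.
#' @export
cphmm_params <- function(A, pi0, r_vec, sigma, kernel, dt_grid = 20) {
  A <- as.matrix(A)
  K <- nrow(A)
  stopifnot(ncol(A) == K, length(pi0) == K, length(r_vec) == K)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-8)) {
    stop("rows of `A` must be probability distributions", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(A = A, pi0 = as.numeric(pi0) / sum(pi0),
                 r_vec = as.numeric(r_vec), sigma = sigma,
                 kernel = as.numeric(kernel), dt_grid = dt_grid),
            class = "cphmm_params")
}

# per-frame emission log-likelihood matrix (n_states x T), truncated
# kernel on the first w-1 frames
emission_loglik <- function(fluo, params, space, design = NULL) {
  if (is.null(design)) design <- compound_design(space, params$kernel)
  rho <- params$r_vec * params$dt_grid / SEC_PER_MIN
  T_len <- length(fluo)
  out <- matrix(0, space$n_states, T_len)
  mu_full <- as.numeric(design[[space$w]] %*% rho)
  for (t in seq_len(T_len)) {
    l <- min(t, space$w)
    mu <- if (l == space$w) mu_full else as.numeric(design[[l]] %*% rho)
    out[, t] <- stats::dnorm(fluo[t], mu, params$sigma, log = TRUE)
  }
  out
}

compound_init <- function(params, space) {
  params$pi0[space$cur + 1L] / space$K^(space$w - 1L)
}

# column-rescaled likelihoods with a positive floor so that paths ruled
# out only by emission rounding cannot zero the forward recursion
scaled_lik <- function(logL) {
  off <- apply(logL, 2, max)
  L <- exp(pmax(sweep(logL, 2, off), -700))
  list(L = L, off = off)
}

#' Exact smoothing over the compound chain
#'
#' Scaled forward-backward with Gaussian emissions
#' `N(expected_emission, sigma^2)`. Promoter-state posteriors are the
#' compound posteriors marginalized over the current-frame symbol.
#'
#' @param fluo numeric fluorescence trace on the inference grid (AU).
#' @param params a [cphmm_params()] object.
#' @param space a [build_state_space()] object.
#' @return A list with `loglik`, `posterior` (T x K promoter-state
#'   posteriors), `xi` (expected promoter transition counts) and
#'   `gamma` (compound posteriors, n_states x T).
#' @export
forward_backward <- function(fluo, params, space) {
  stopifnot(inherits(params, "cphmm_params"),
            inherits(space, "compound_state_space"))
  sl <- scaled_lik(emission_loglik(fluo, params, space))
  res <- cpp_estep(sl$L, compound_init(params, space), params$A,
                   space$cur, space$succ)
  post <- t(rowsum(res$gamma, group = space$cur, reorder = TRUE))
  if (!all(is.finite(res$loglik))) {
    stop("non-finite log-likelihood in forward-backward", call. = FALSE)
  }
  list(loglik = res$loglik + sum(sl$off), posterior = post,
       xi = res$xi, gamma = res$gamma)
}

#' EM configuration for cpHMM fitting
#'
#' @param n_restarts random restarts; the best final log-likelihood wins.
#' @param max_iter maximum Baum-Welch iterations per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed optional integer seed for initialization draws.
#' @param min_points minimum pooled data points required (0 disables).
#' @return A list of class `cphmm_config`.
#' @export
cphmm_config <- function(n_restarts = 5, max_iter = 200, tol = 1e-5,
                         seed = NULL, min_points = 0) {
  structure(list(n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                 seed = seed, min_points = min_points),
            class = "cphmm_config")
}

init_params <- function(trace_list, space, kernel, dt_grid, jitter = FALSE) {
  K <- space$K
  f_all <- unlist(trace_list, use.names = FALSE)
  # Dirichlet rows biased to the diagonal: sticky chains to start from
  A <- t(vapply(seq_len(K), function(i) {
    a <- rep(1, K); a[i] <- 10
    g <- stats::rgamma(K, shape = a)
    g / sum(g)
  }, numeric(K)))
  scale_f <- sum(kernel) * dt_grid / SEC_PER_MIN
  q <- stats::quantile(f_all, c(0.5, 0.95), names = FALSE)
  r_init <- c(0, pmax(q, 1e-3) / scale_f)
  if (length(r_init) < K) r_init <- c(r_init, rep(r_init[length(r_init)], K - length(r_init)))
  r_init <- r_init[seq_len(K)]
  if (jitter) r_init[-1] <- r_init[-1] * stats::runif(K - 1, 0.7, 1.3)
  # high-pass residual scale: sd of first differences of a white process
  dif <- unlist(lapply(trace_list, diff), use.names = FALSE)
  sigma0 <- max(stats::sd(dif) / sqrt(2), 1e-3)
  cphmm_params(A, rep(1 / K, K), r_init, sigma0, kernel, dt_grid)
}

#' Fit the cpHMM by Baum-Welch EM
#'
#' E-steps run exactly over the compound chain; the M-step updates the
#' promoter transition matrix and initial distribution from expected
#' counts, and the initiation rates and noise s.d. by weighted least
#' squares of the observed fluorescence on the kernel-weighted state
#' occupancies (OFF-state rate pinned to 0).
#'
#' @param trace_list list of numeric fluorescence vectors on the
#'   inference grid (one per nucleus).
#' @param space a [build_state_space()] object.
#' @param config a [cphmm_config()].
#' @param kernel emission kernel weights of length `space$w`; default
#'   uniform.
#' @param dt_grid inference grid interval, seconds.
#' @return An object of class `cphmm_fit`: fitted `params`, `loglik_trace`
#'   per EM iteration of the winning restart, `converged`, `n_traces`,
#'   `n_points`, `restart_logliks` and the seed used.
#' @export
em_fit <- function(trace_list, space, config = cphmm_config(),
                   kernel = NULL, dt_grid = 20) {
  stopifnot(is.list(trace_list), length(trace_list) >= 1L)
  trace_list <- lapply(trace_list, as.numeric)
  n_points <- sum(lengths(trace_list))
  if (n_points < config$min_points) {
    stop(sprintf("pooled traces have %d points; %d required",
                 n_points, config$min_points), call. = FALSE)
  }
  if (is.null(kernel)) kernel <- rep(1, space$w)
  stopifnot(length(kernel) == space$w)
  design <- compound_design(space, kernel)

  with_local_seed(config$seed, {
    best <- NULL
    restart_ll <- numeric(config$n_restarts)
    for (rs in seq_len(config$n_restarts)) {
      params <- init_params(trace_list, space, kernel, dt_grid,
                            jitter = rs > 1L)
      run <- em_run(trace_list, space, params, design, config)
      restart_ll[rs] <- run$loglik
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    structure(list(params = best$params, loglik_trace = best$loglik_trace,
                   converged = best$converged, n_traces = length(trace_list),
                   n_points = n_points, restart_logliks = restart_ll,
                   seed = config$seed),
              class = "cphmm_fit")
  })
}

em_run <- function(trace_list, space, params, design, config) {
  K <- space$K
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  D_full <- design[[space$w]]
  for (iter in seq_len(config$max_iter)) {
    ll_tot <- 0
    xi_tot <- matrix(0, K, K)
    pi_counts <- numeric(K)
    X <- matrix(0, K, K)
    y <- numeric(K)
    sumf2 <- 0
    n_tot <- 0
    init <- compound_init(params, space)
    for (f in trace_list) {
      sl <- scaled_lik(emission_loglik(f, params, space, design))
      res <- cpp_estep(sl$L, init, params$A, space$cur, space$succ)
      ll_tot <- ll_tot + res$loglik + sum(sl$off)
      xi_tot <- xi_tot + res$xi
      g1 <- rowsum(res$gamma[, 1L], group = space$cur, reorder = TRUE)
      pi_counts <- pi_counts + as.numeric(g1)
      T_len <- length(f)
      for (l in seq_len(min(space$w, T_len))) {
        cols <- if (l < space$w) l else space$w:T_len
        if (l < space$w && T_len < l) next
        wsum <- if (length(cols) == 1L) res$gamma[, cols] else
          rowSums(res$gamma[, cols, drop = FALSE])
        wf <- if (length(cols) == 1L) res$gamma[, cols] * f[cols] else
          as.numeric(res$gamma[, cols, drop = FALSE] %*% f[cols])
        Dl <- design[[l]]
        X <- X + crossprod(Dl, wsum * Dl)
        y <- y + as.numeric(crossprod(Dl, wf))
      }
      sumf2 <- sumf2 + sum(f^2)
      n_tot <- n_tot + T_len
    }
    ll_trace <- c(ll_trace, ll_tot)

    # M-step
    A_new <- params$A
    rs_xi <- rowSums(xi_tot)
    for (i in seq_len(K)) {
      if (rs_xi[i] > 1e-12) A_new[i, ] <- xi_tot[i, ] / rs_xi[i]
    }
    pi_new <- pmax(pi_counts / sum(pi_counts), 1e-8)
    pi_new <- pi_new / sum(pi_new)
    dt_min <- params$dt_grid / SEC_PER_MIN
    rho <- params$r_vec * dt_min
    Xon <- X[-1, -1, drop = FALSE]
    if (rcond(Xon) > 1e-12) {
      rho_on <- solve(Xon, y[-1])
      rho <- c(0, pmax(rho_on, 0))
    }
    rss <- sumf2 - 2 * sum(rho * y) + as.numeric(t(rho) %*% X %*% rho)
    sigma_new <- sqrt(max(rss / n_tot, 1e-8))
    params <- cphmm_params(A_new, pi_new, rho / dt_min, sigma_new,
                           params$kernel, params$dt_grid)

    if (is.finite(ll_prev) &&
        abs(ll_tot - ll_prev) < config$tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll_tot
  }
  list(params = params, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, converged = converged)
}

#' Decode promoter states from a fitted cpHMM
#'
#' @param fluo numeric fluorescence trace on the inference grid.
#' @param params fitted [cphmm_params()].
#' @param space the matching [build_state_space()].
#' @param method `"marginal"` (posterior-mode promoter state per frame,
#'   default) or `"viterbi"` (most likely compound path).
#' @return Integer vector of promoter states (0 = OFF, 1 = ON1, 2 = ON2),
#'   one per frame.
#' @export
decode_promoter_states <- function(fluo, params, space,
                                   method = c("marginal", "viterbi")) {
  method <- match.arg(method)
  if (method == "marginal") {
    fb <- forward_backward(fluo, params, space)
    return(max.col(fb$posterior, ties.method = "first") - 1L)
  }
  logL <- emission_loglik(fluo, params, space)
  loginit <- log(compound_init(params, space))
  path <- cpp_viterbi(logL, loginit, log(params$A), space$cur, space$succ)
  space$cur[path]
}

#' Append cpHMM-decoded promoter states to a trace table
#'
#' Decodes every trace in a long tibble with one fitted parameter set
#' and adds a `state_inferred` column (0 = OFF, 1 = ON1, 2 = ON2).
#'
#' @param traces long tibble of interpolated traces.
#' @param params fitted [cphmm_params()].
#' @param space the matching [build_state_space()].
#' @param method decoding method, see [decode_promoter_states()].
#' @return The tibble with `state_inferred` added.
#' @export
decode_traces <- function(traces, params, space, method = "marginal") {
  stopifnot(is.data.frame(traces))
  key <- paste(traces$embryo_id, traces$nucleus_id)
  traces$state_inferred <- NA_integer_
  for (k in unique(key)) {
    sel <- key == k
    traces$state_inferred[sel] <-
      decode_promoter_states(traces$fluo_au[sel], params, space, method)
  }
  traces
}

# real matrix logarithm via eigendecomposition; NULL if not real
matrix_log <- function(A, tol = 1e-8) {
  e <- eigen(A)
  if (any(Mod(e$values) < 1e-12)) return(NULL)
  lv <- log(as.complex(e$values))
  Lm <- e$vectors %*% diag(lv, nrow = length(lv)) %*% solve(e$vectors)
  if (max(abs(Im(Lm))) > tol * max(1, max(abs(Re(Lm))))) return(NULL)
  Re(Lm)
}

discrete_stationary <- function(A) {
  K <- nrow(A)
  M <- rbind(t(A) - diag(K), rep(1, K))
  p <- qr.solve(M, c(rep(0, K), 1), tol = 1e-12)
  p <- pmax(unname(p), 0)
  p / sum(p)
}

#' Aggregate a fitted cpHMM to effective two-state burst parameters
#'
#' Converts the per-frame transition matrix to continuous-time rates via
#' the matrix logarithm Q = logm(A)/dt (negative off-diagonals clipped to
#' 0 and the diagonal rebalanced; first-order fallback (A - I)/dt when the
#' logarithm is not real), then applies the aggregation formulas:
#' k_on = q01 + q02, k_off = k_on p_off / (1 - p_off),
#' r = (p1 r1 + p2 r2) / (p1 + p2), with occupancies from the stationary
#' law of A.
#'
#' @param fit a `cphmm_fit` (or bare [cphmm_params()]).
#' @return A [burst_params()] with attribute `rate_method` recording
#'   whether the matrix logarithm or the first-order conversion was used.
#' @export
to_burst_params <- function(fit) {
  params <- if (inherits(fit, "cphmm_fit")) fit$params else fit
  stopifnot(inherits(params, "cphmm_params"))
  A <- params$A
  dt_min <- params$dt_grid / SEC_PER_MIN
  if (max(abs(A - diag(nrow(A)))) < 1e-10) {
    stop("degenerate fit: A = I implies no switching; burst parameters undefined",
         call. = FALSE)
  }
  Lm <- matrix_log(A)
  method <- if (is.null(Lm)) "first_order" else "logm"
  Qhat <- if (is.null(Lm)) (A - diag(nrow(A))) / dt_min else Lm / dt_min
  Qhat[Qhat < 0 & row(Qhat) != col(Qhat)] <- 0
  diag(Qhat) <- 0
  diag(Qhat) <- -rowSums(Qhat)
  p <- discrete_stationary(A)
  if (p[1] <= 0 || p[1] >= 1) {
    stop("stationary OFF occupancy outside (0,1); k_off undefined", call. = FALSE)
  }
  k_on <- unname(Qhat[1, 2] + Qhat[1, 3])
  k_off <- effective_koff(k_on, p[1])
  r <- effective_r(p[2], p[3], params$r_vec[2], params$r_vec[3])
  out <- burst_params(k_on, k_off, r, p[1], p[2], p[3])
  attr(out, "rate_method") <- method
  out
}
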