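#' Realized trajectory of the promoter chain
#'
#' A piecewise-constant path: `states[i]` holds on
#' `[jump_times[i-1], jump_times[i])` (with `jump_times[0] = 0`), the last
#' state holds until `duration`. States are 0 (OFF), 1 (ON1), 2 (ON2);
#' times are minutes.
#'
#' @param states integer states in \{0, 1, 2\}, length m.
#' @param jump_times strictly increasing jump times (min), length m - 1.
#' @param duration total duration (min), >= last jump time.
#' @return An object of class `state_path`.
#' @export
state_path <- function(states, jump_times, duration) {
  states <- as.integer(states)
  jump_times <- as.numeric(jump_times)
  if (length(states) != length(jump_times) + 1L) {
    stop("`states` must be one longer than `jump_times`", call. = FALSE)
  }
  if (any(!states %in% 0:2)) stop("states must be in {0, 1, 2}", call. = FALSE)
  if (length(jump_times) && any(diff(c(0, jump_times)) <= 0)) {
    stop("`jump_times` must be strictly increasing and positive", call. = FALSE)
  }
  if (length(states) > 1L && any(diff(states) == 0L)) {
    stop("consecutive states must differ", call. = FALSE)
  }
  if (duration < if (length(jump_times)) max(jump_times) else 0) {
    stop("`duration` must cover all jumps", call. = FALSE)
  }
  structure(list(states = states, jump_times = jump_times,
                 duration = as.numeric(duration)),
            class = "state_path")
}

#' Gillespie simulation of the promoter chain
#'
#' Exact continuous-time simulation of the 3-state generator.
#'
#' @param Q 3x3 generator matrix (min^-1).
#' @param duration_min duration in minutes.
#' @param initial `"stationary"` (default) to draw the initial state from
#'   the stationary law, or an integer state in \{0, 1, 2\}.
#' @param seed optional integer; if given, the simulation is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [state_path()].
#' @export
simulate_chain_path <- function(Q, duration_min, initial = "stationary",
                                seed = NULL) {
  Q <- validate_generator(Q)
  stop_if_not_scalar_num(duration_min, "duration_min", lo = 1e-12)
  with_local_seed(seed, {
    s <- if (identical(initial, "stationary")) {
      sample.int(3L, 1L, prob = stationary_distribution(Q)) - 1L
    } else {
      stopifnot(is.numeric(initial), initial %in% 0:2)
      as.integer(initial)
    }
    states <- s
    jumps <- numeric(0)
    t_now <- 0
    repeat {
      rate_out <- -Q[s + 1L, s + 1L]
      if (rate_out <= 0) break   # absorbing state
      t_now <- t_now + stats::rexp(1L, rate_out)
      if (t_now >= duration_min) break
      probs <- Q[s + 1L, ]
      probs[s + 1L] <- 0
      s <- sample.int(3L, 1L, prob = probs) - 1L
      states <- c(states, s)
      jumps <- c(jumps, t_now)
    }
    state_path(states, jumps, duration_min)
  })
}

#' MS2 emission kernel over the elongation window
#'
#' One weight per frame of the elongation window `w = round(t_elong /
#' dt_grid)`. The default is uniform (every loaded polymerase contributes
#' full fluorescence for exactly `t_elong`); `first_weight` < 1 optionally
#' down-weights the newest frame to emulate gradual transcription of the
#' MS2 loops.
#'
#' @param t_elong elongation time, seconds.
#' @param dt_grid frame interval, seconds.
#' @param first_weight weight of the newest frame, in (0, 1].
#' @return An object of class `emission_kernel` (numeric weights with a
#'   `dt_grid` attribute).
#' @export
emission_kernel <- function(t_elong = 140, dt_grid = 20, first_weight = 1) {
  stop_if_not_scalar_num(t_elong, "t_elong", lo = 1e-9)
  stop_if_not_scalar_num(dt_grid, "dt_grid", lo = 1e-9)
  stop_if_not_scalar_num(first_weight, "first_weight", lo = 1e-9, hi = 1)
  w <- max(1L, as.integer(round(t_elong / dt_grid)))
  kappa <- rep(1, w)
  kappa[1] <- first_weight
  structure(kappa, dt_grid = dt_grid, class = "emission_kernel")
}

# dwell fraction of each state within each frame interval ((j-1) dt, j dt]
frame_occupancy <- function(path, dt_min, n_frames) {
  occ <- matrix(0, n_frames, 3)
  brk <- c(0, path$jump_times, path$duration)
  for (i in seq_along(path$states)) {
    t0 <- brk[i]; t1 <- brk[i + 1L]
    if (t1 <= t0) next
    j0 <- max(1L, floor(t0 / dt_min) + 1L)
    j1 <- min(n_frames, ceiling(t1 / dt_min))
    if (j0 > j1) next
    js <- j0:j1
    overlap <- pmin(t1, js * dt_min) - pmax(t0, (js - 1) * dt_min)
    occ[js, path$states[i] + 1L] <- occ[js, path$states[i] + 1L] +
      pmax(overlap, 0) / dt_min
  }
  occ
}

#' Render an MS2 fluorescence trace from a promoter path
#'
#' Convolves the path's initiation activity with the elongation window:
#' frame j sits at time `j * dt` and the noise-free signal is
#' `F_j = sum_i kappa_i rho_(j-i) dt/60`, where `rho_j` is the dwell-
#' time-weighted mean initiation rate over the frame interval
#' `((j-1) dt, j dt]` and terms reaching before the start of the path are
#' dropped (truncated kernel). Gaussian noise of s.d. `sigma_noise` is
#' added; negative values are kept so the emission model stays symmetric.
#'
#' @param path a [state_path()].
#' @param model a [promoter_rate_model()].
#' @param kernel an [emission_kernel()]; defaults to the uniform kernel at
#'   the model's `t_elong` and `dt_frame`.
#' @param n_frames number of frames; defaults to all frames the path covers.
#' @param seed optional integer seed for the noise draw.
#' @return A tibble with columns `frame`, `time_s`, `fluo_au`, `true_state`
#'   (dominant promoter state in the frame interval).
#' @export
render_trace <- function(path, model, kernel = NULL, n_frames = NULL,
                         seed = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(model, "promoter_rate_model"))
  if (is.null(kernel)) {
    kernel <- emission_kernel(model$t_elong, model$dt_frame)
  }
  dt_s <- attr(kernel, "dt_grid")
  dt_min <- dt_s / SEC_PER_MIN
  max_frames <- floor(path$duration / dt_min + 1e-9)
  if (is.null(n_frames)) n_frames <- max_frames
  if (n_frames < 1L) stop("path too short for a single frame", call. = FALSE)
  if (n_frames > max_frames) {
    stop("path does not cover the requested trace window", call. = FALSE)
  }
  occ <- frame_occupancy(path, dt_min, n_frames)
  rho <- as.numeric(occ %*% model$r_vec)          # AU/min, per frame
  w <- length(kernel)
  f <- numeric(n_frames)
  for (i in seq_len(w)) {
    idx <- seq_len(n_frames) - (i - 1L)
    ok <- idx >= 1L
    f[ok] <- f[ok] + kernel[i] * rho[idx[ok]] * dt_min
  }
  noise <- if (model$sigma_noise > 0) {
    with_local_seed(seed, stats::rnorm(n_frames, 0, model$sigma_noise))
  } else {
    numeric(n_frames)
  }
  tibble::tibble(
    frame = seq_len(n_frames),
    time_s = seq_len(n_frames) * dt_s,
    fluo_au = f + noise,
    true_state = max.col(occ, ties.method = "first") - 1L
  )
}
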