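#' Continuous-time promoter rate model for a two-sister locus
#'
#' Bundles the 3-state generator over promoter states \{OFF = 0, ON1 = 1,
#' ON2 = 2\} (0, 1 or 2 sister promoters active) with the per-state
#' initiation rates, the elongation window and the imaging noise level.
#' Rates are per minute; `t_elong` and `dt_frame` are in seconds;
#' fluorescence is in arbitrary units (AU), with 1 AU defined as the
#' signal contributed by one (AU/min) x min of initiation.
#'
#' @param Q 3x3 generator matrix (rows sum to 0, off-diagonals >= 0),
#'   units min^-1.
#' @param r_vec initiation rates `(r0, r1, r2)` in AU/min; `r0` must be 0.
#' @param t_elong elongation time of the transcriptional unit, seconds.
#' @param dt_frame sampling interval of the rendered trace, seconds.
#' @param sigma_noise s.d. of i.i.d. Gaussian measurement noise, AU.
#' @return An object of class `promoter_rate_model`.
#' @seealso [build_sister_chain()], [render_trace()], [simulate_chain_path()]
#' @export
promoter_rate_model <- function(Q, r_vec, t_elong = 140, dt_frame = 20,
                                sigma_noise = 1.5) {
  Q <- validate_generator(Q)
  if (length(r_vec) != 3L || any(!is.finite(r_vec)) || any(r_vec < 0)) {
    stop("`r_vec` must be 3 finite non-negative rates (AU/min)", call. = FALSE)
  }
  if (r_vec[1] != 0) stop("`r_vec[1]` (OFF-state initiation) must be 0", call. = FALSE)
  stop_if_not_scalar_num(t_elong, "t_elong", lo = 1e-9)
  stop_if_not_scalar_num(dt_frame, "dt_frame", lo = 1e-9)
  stop_if_not_scalar_num(sigma_noise, "sigma_noise", lo = 0)
  structure(
    list(Q = Q, r_vec = as.numeric(r_vec), t_elong = t_elong,
         dt_frame = dt_frame, sigma_noise = sigma_noise),
    class = "promoter_rate_model"
  )
}

validate_generator <- function(Q) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(3L, 3L))) stop("`Q` must be 3x3", call. = FALSE)
  if (any(!is.finite(Q))) stop("`Q` must be finite", call. = FALSE)
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of `Q` must sum to 0", call. = FALSE)
  dimnames(Q) <- list(c("OFF", "ON1", "ON2"), c("OFF", "ON1", "ON2"))
  Q
}

#' Generator for two independent, identical sister promoters
#'
#' Builds the 3-state chain obtained by counting how many of two
#' independent telegraph promoters (each switching OFF->ON at
#' `k_on_1p` and ON->OFF at `k_off_1p`) are active:
#' q(0->1) = 2 k_on_1p, q(1->0) = k_off_1p, q(1->2) = k_on_1p,
#' q(2->1) = 2 k_off_1p, with no direct 0<->2 transitions.
#'
#' @param k_on_1p single-promoter activation rate, min^-1.
#' @param k_off_1p single-promoter deactivation rate, min^-1.
#' @return 3x3 generator matrix.
#' @export
build_sister_chain <- function(k_on_1p, k_off_1p) {
  stop_if_not_scalar_num(k_on_1p, "k_on_1p", lo = 0)
  stop_if_not_scalar_num(k_off_1p, "k_off_1p", lo = 0)
  Q <- matrix(0, 3, 3)
  Q[1, 2] <- 2 * k_on_1p
  Q[2, 1] <- k_off_1p
  Q[2, 3] <- k_on_1p
  Q[3, 2] <- 2 * k_off_1p
  diag(Q) <- -rowSums(Q)
  validate_generator(Q)
}

#' Stationary distribution of a 3-state generator
#'
#' Solves pi Q = 0, sum(pi) = 1. Errors if the chain does not have a
#' unique stationary law (reducible generator).
#'
#' @param Q 3x3 generator matrix.
#' @return Named numeric vector `(p_off, p1, p2)`.
#' @export
stationary_distribution <- function(Q) {
  Q <- validate_generator(Q)
  # unique stationary law needs rank(Q) = 2
  sv <- svd(Q)$d
  if (sum(sv > max(sv[1], 1) * 1e-10) < 2L) {
    stop("degenerate generator: no unique stationary distribution", call. = FALSE)
  }
  A <- rbind(t(Q), rep(1, 3))
  pi_hat <- qr.solve(A, c(0, 0, 0, 1), tol = 1e-12)
  if (any(pi_hat < -1e-8)) {
    stop("degenerate generator: stationary solve returned negative mass",
         call. = FALSE)
  }
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  stats::setNames(pi_hat, c("p_off", "p1", "p2"))
}

#' Effective burst frequency of the aggregated two-state model
#'
#' The locus-level k_on: total rate of leaving the OFF state,
#' q(0->1) + q(0->2).
#'
#' @param Q 3x3 generator matrix.
#' @return k_on in min^-1.
#' @export
effective_kon <- function(Q) {
  Q <- validate_generator(Q)
  Q[1, 2] + Q[1, 3]
}

#' Effective burst-termination rate from OFF occupancy
#'
#' Inverse mean burst duration of the aggregated ON state:
#' k_off^-1 = (1/p_off - 1) k_on^-1, i.e.
#' k_off = k_on p_off / (1 - p_off).
#'
#' @param k_on effective burst frequency, min^-1 (> 0).
#' @param p_off stationary OFF occupancy, in (0, 1).
#' @return k_off in min^-1.
#' @export
effective_koff <- function(k_on, p_off) {
  stop_if_not_scalar_num(k_on, "k_on", lo = 1e-12)
  stop_if_not_scalar_num(p_off, "p_off")
  if (p_off <= 0 || p_off >= 1) {
    stop("`p_off` must lie strictly in (0, 1): burst duration undefined",
         call. = FALSE)
  }
  k_on * p_off / (1 - p_off)
}

#' Effective burst amplitude of the aggregated ON state
#'
#' Occupancy-weighted mean initiation rate over the two ON states:
#' r = (p1 r1 + p2 r2) / (p1 + p2).
#'
#' @param p1,p2 stationary occupancies of ON1 and ON2 (p1 + p2 > 0).
#' @param r1,r2 initiation rates in ON1 and ON2, AU/min.
#' @return r in AU/min.
#' @export
effective_r <- function(p1, p2, r1, r2) {
  stop_if_not_scalar_num(p1, "p1", lo = 0)
  stop_if_not_scalar_num(p2, "p2", lo = 0)
  stop_if_not_scalar_num(r1, "r1", lo = 0)
  stop_if_not_scalar_num(r2, "r2", lo = 0)
  if (p1 + p2 <= 0) {
    stop("`p1 + p2` must be > 0: promoter is never ON", call. = FALSE)
  }
  (p1 * r1 + p2 * r2) / (p1 + p2)
}

#' Effective two-state burst parameters
#'
#' Container for the aggregated description of a locus: burst frequency
#' `k_on`, burst-termination rate `k_off` (burst duration is `1/k_off`),
#' burst amplitude `r`, and the stationary occupancies of the underlying
#' three states.
#'
#' @param k_on,k_off rates in min^-1.
#' @param r initiation rate in AU/min.
#' @param p_off,p1,p2 stationary occupancies (sum to 1).
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(k_on, k_off, r, p_off, p1, p2) {
  stop_if_not_scalar_num(k_on, "k_on", lo = 0)
  stop_if_not_scalar_num(k_off, "k_off", lo = 0)
  stop_if_not_scalar_num(r, "r", lo = 0)
  occ <- c(p_off, p1, p2)
  if (any(occ < -1e-9) || abs(sum(occ) - 1) > 1e-6) {
    stop("occupancies must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off, r = r,
                 p_off = p_off, p1 = p1, p2 = p2),
            class = "burst_params")
}

#' @export
print.burst_params <- function(x, ...) {
  cat(sprintf(
    "burst_params: k_on = %.3f /min, k_off = %.3f /min, r = %.3f AU/min\n",
    x$k_on, x$k_off, x$r))
  cat(sprintf("  occupancies: p_off = %.3f, p1 = %.3f, p2 = %.3f\n",
              x$p_off, x$p1, x$p2))
  invisible(x)
}

#' Aggregate a 3-state kinetic model to effective two-state parameters
#'
#' @param Q 3x3 generator matrix.
#' @param r_vec initiation rates `(r0, r1, r2)`, AU/min.
#' @return A [burst_params()] object.
#' @export
aggregate_burst_params <- function(Q, r_vec) {
  p <- stationary_distribution(Q)
  k_on <- effective_kon(Q)
  k_off <- effective_koff(k_on, p[["p_off"]])
  r <- effective_r(p[["p1"]], p[["p2"]], r_vec[2], r_vec[3])
  burst_params(k_on, k_off, r, p[["p_off"]], p[["p1"]], p[["p2"]])
}

#' Mean transcription-initiation rate of a bursting locus
#'
#' The time-averaged initiation rate r k_on / (k_on + k_off), which under
#' the two-state identification equals r (1 - p_off).
#'
#' @param bp a [burst_params()] object.
#' @return mean initiation rate in AU/min.
#' @export
mean_initiation_rate <- function(bp) {
  stopifnot(inherits(bp, "burst_params"))
  if (bp$k_on + bp$k_off <= 0) stop("k_on + k_off must be > 0", call. = FALSE)
  bp$r * bp$k_on / (bp$k_on + bp$k_off)
}

#' Sister-chain model with prescribed effective burst parameters
#'
#' Inverts the aggregation formulas: finds single-promoter rates and
#' ON-state initiation rates such that two independent identical sister
#' promoters have exactly the requested locus-level `k_on`, `k_off`
#' and `r` (with r2 = 2 r1).
#'
#' @param k_on,k_off effective rates, min^-1 (> 0).
#' @param r effective burst amplitude, AU/min.
#' @inheritParams promoter_rate_model
#' @return A [promoter_rate_model()].
#' @export
model_from_burst_params <- function(k_on, k_off, r, t_elong = 140,
                                    dt_frame = 20, sigma_noise = 1.5) {
  stop_if_not_scalar_num(k_on, "k_on", lo = 1e-9)
  stop_if_not_scalar_num(k_off, "k_off", lo = 1e-9)
  stop_if_not_scalar_num(r, "r", lo = 0)
  k_on_1p <- k_on / 2
  cc <- k_off / k_on          # target p_off / (1 - p_off)
  q <- sqrt(cc / (1 + cc))    # single-promoter OFF probability
  k_off_1p <- k_on_1p * q / (1 - q)
  Q <- build_sister_chain(k_on_1p, k_off_1p)
  p1 <- 2 * q * (1 - q)
  p2 <- (1 - q)^2
  r1 <- r * (p1 + p2) / (p1 + 2 * p2)
  promoter_rate_model(Q, c(0, r1, 2 * r1), t_elong = t_elong,
                      dt_frame = dt_frame, sigma_noise = sigma_noise)
}
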