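#' Bin traces by mean fluorescence within groups
#'
#' Within each group (stripe, or endogenous/ectopic class), traces are
#' sorted by mean fluorescence and distributed into
#' `floor(n / target_traces)` contiguous bins of as-equal-as-possible
#' size (~40 nuclei each, ~2500 points at 20 s). Groups with fewer than
#' `target_traces` traces yield 0 bins and are dropped; bins whose pooled
#' point count falls below `min_points` are kept but flagged.
#'
#' @param summaries per-trace tibble from [time_mean_fluo()] with an
#'   added `group` column.
#' @param target_traces nominal traces per bin.
#' @param min_points minimum pooled points per bin before flagging.
#' @return An object of class `fluor_bins`: `assignments` (one row per
#'   binned trace: group, bin, ids, mean_fluo, n_points), `summary` (one
#'   row per bin: group, bin, mean_fluo, n_traces, n_points, points_ok)
#'   and `dropped` (groups with 0 bins).
#' @export
make_bins <- function(summaries, target_traces = 40, min_points = 2500) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "mean_fluo", "n_points") %in% names(summaries)))
  parts <- split(summaries, summaries$group)
  assigns <- list()
  dropped <- character(0)
  for (g in names(parts)) {
    d <- parts[[g]][order(parts[[g]]$mean_fluo), ]
    n <- nrow(d)
    n_bins <- n %/% target_traces
    if (n_bins == 0L) {
      dropped <- c(dropped, g)
      next
    }
    sizes <- rep(n %/% n_bins, n_bins)
    extra <- n %% n_bins
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    d$bin <- rep(seq_len(n_bins), times = sizes)
    assigns[[g]] <- d
  }
  assignments <- dplyr::bind_rows(assigns)
  summary <- if (nrow(assignments)) {
    dplyr::summarise(
      dplyr::group_by(assignments, .data$group, .data$bin),
      mean_fluo = mean(.data$mean_fluo),
      n_traces = dplyr::n(),
      n_points = sum(.data$n_points),
      .groups = "drop")
  } else {
    tibble::tibble(group = character(), bin = integer(),
                   mean_fluo = numeric(), n_traces = integer(),
                   n_points = integer())
  }
  summary$points_ok <- summary$n_points >= min_points
  structure(list(assignments = assignments, summary = summary,
                 dropped = dropped, target_traces = target_traces,
                 min_points = min_points),
            class = "fluor_bins")
}

# pull the member fluorescence vectors of one bin out of the trace table
bin_trace_list <- function(bin_members, traces) {
  keys <- paste(traces$embryo_id, traces$nucleus_id)
  lapply(paste(bin_members$embryo_id, bin_members$nucleus_id), function(k) {
    traces$fluo_au[keys == k]
  })
}

#' Per-bin cpHMM inference along a fluorescence trend
#'
#' Fits the cpHMM to each bin and aggregates to effective two-state burst
#' parameters, giving one `(mean fluorescence, k_on, k_off, r)` point per
#' bin.
#'
#' @param bins a [make_bins()] object.
#' @param traces long tibble of interpolated traces.
#' @param space a [build_state_space()].
#' @param config a [cphmm_config()].
#' @param kernel optional emission kernel weights (length `space$w`).
#' @param dt_grid inference grid interval, seconds.
#' @param keep_fits if `TRUE`, the per-bin `cphmm_fit` objects are
#'   attached as attribute `"fits"`.
#' @return A `trend_curve` tibble sorted by mean fluorescence within each
#'   group: group, bin, mean_fluo, kon_per_min, koff_per_min,
#'   r_au_per_min, n_traces, n_points, converged, rate_method.
#' @export
infer_trend <- function(bins, traces, space, config = cphmm_config(),
                        kernel = NULL, dt_grid = 20, keep_fits = FALSE) {
  stopifnot(inherits(bins, "fluor_bins"))
  rows <- list()
  fits <- list()
  for (i in seq_len(nrow(bins$summary))) {
    b <- bins$summary[i, ]
    members <- bins$assignments[bins$assignments$group == b$group &
                                  bins$assignments$bin == b$bin, ]
    tl <- bin_trace_list(members, traces)
    cfg <- config
    cfg$seed <- if (is.null(config$seed)) NULL else config$seed + i
    fit <- em_fit(tl, space, cfg, kernel = kernel, dt_grid = dt_grid)
    if (keep_fits) fits[[paste(b$group, b$bin, sep = "_")]] <- fit
    bp <- to_burst_params(fit)
    rows[[i]] <- tibble::tibble(
      group = b$group, bin = b$bin, mean_fluo = b$mean_fluo,
      kon_per_min = bp$k_on, koff_per_min = bp$k_off,
      r_au_per_min = bp$r, n_traces = b$n_traces, n_points = b$n_points,
      converged = fit$converged,
      rate_method = attr(bp, "rate_method"))
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$group, .data$mean_fluo)
  class(out) <- c("trend_curve", class(out))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Serialize a cpHMM fit as JSON
#'
#' Writes the fitted transition matrix, initial distribution, initiation
#' rates, noise s.d., kernel, log-likelihood trajectory, seed and data
#' sizes.
#'
#' @param fit a `cphmm_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cphmm_fit"))
  p <- fit$params
  jsonlite::write_json(list(
    A = p$A, pi0 = p$pi0, r_vec = p$r_vec, sigma = p$sigma,
    kernel = p$kernel, dt_grid = p$dt_grid,
    loglik_trace = fit$loglik_trace, converged = fit$converged,
    n_traces = fit$n_traces, n_points = fit$n_points,
    restart_logliks = fit$restart_logliks, seed = fit$seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bootstrap uncertainty of one bin's burst parameters
#'
#' Resamples the bin's traces with replacement, refits the cpHMM, and
#' reports the standard deviation of each aggregated parameter across
#' replicates. Replicates whose fit fails to aggregate are excluded and
#' counted.
#'
#' @param trace_list list of fluorescence vectors (the bin's members).
#' @param space a [build_state_space()].
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param config a [cphmm_config()].
#' @param seed integer seed for the resampling.
#' @param kernel,dt_grid as in [infer_trend()].
#' @return List with `sigma_kon`, `sigma_koff`, `sigma_r`, `n_ok`,
#'   `n_failed` and the replicate table.
#' @export
bootstrap_uncertainty <- function(trace_list, space, n_boot = 10,
                                  config = cphmm_config(), seed = 1,
                                  kernel = NULL, dt_grid = 20) {
  stopifnot(n_boot >= 2)
  reps <- with_local_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(trace_list), replace = TRUE)
      cfg <- config
      cfg$seed <- stats::runif(1, 1, 2^30)
      tryCatch({
        fit <- em_fit(trace_list[idx], space, cfg, kernel = kernel,
                      dt_grid = dt_grid)
        bp <- to_burst_params(fit)
        tibble::tibble(replicate = b, kon = bp$k_on, koff = bp$k_off,
                       r = bp$r)
      }, error = function(e) NULL)
    })
  })
  tab <- dplyr::bind_rows(reps)
  n_ok <- nrow(tab)
  list(
    sigma_kon = if (n_ok >= 2) stats::sd(tab$kon) else NA_real_,
    sigma_koff = if (n_ok >= 2) stats::sd(tab$koff) else NA_real_,
    sigma_r = if (n_ok >= 2) stats::sd(tab$r) else NA_real_,
    n_ok = n_ok, n_failed = n_boot - n_ok, replicates = tab
  )
}

#' Compare bursting strategies between two trend curves
#'
#' For each parameter, reports the fold change across the fluorescence
#' range and the direction of the trend. Two curves follow the "same
#' strategy" when both show rising k_on and rising r while k_off stays
#' within a flatness band (max/min fold change below
#' `flatness_threshold`).
#'
#' @param curveA,curveB `trend_curve` tibbles with >= 2 points each.
#' @param flatness_threshold maximum k_off fold change still called flat.
#' @return List with per-curve summaries (`fold_kon`, `fold_r`,
#'   `fold_koff_band`, trend signs) and `same_strategy` /`verdict`.
#' @export
compare_strategies <- function(curveA, curveB, flatness_threshold = 1.5) {
  summarise_curve <- function(cv) {
    if (nrow(cv) < 2L) {
      stop("trend curves need >= 2 points to compare", call. = FALSE)
    }
    cv <- cv[order(cv$mean_fluo), ]
    first <- cv[1, ]; last <- cv[nrow(cv), ]
    list(
      fold_kon = last$kon_per_min / first$kon_per_min,
      fold_r = last$r_au_per_min / first$r_au_per_min,
      fold_koff_band = max(cv$koff_per_min) / min(cv$koff_per_min),
      kon_rising = last$kon_per_min > first$kon_per_min,
      r_rising = last$r_au_per_min > first$r_au_per_min
    )
  }
  a <- summarise_curve(curveA)
  b <- summarise_curve(curveB)
  same <- a$kon_rising && b$kon_rising && a$r_rising && b$r_rising &&
    a$fold_koff_band < flatness_threshold &&
    b$fold_koff_band < flatness_threshold
  list(curveA = a, curveB = b, same_strategy = same,
       verdict = if (same) "same strategy" else "different strategy",
       flatness_threshold = flatness_threshold)
}
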