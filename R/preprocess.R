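#' Interpolate traces onto the inference grid
#'
#' Linearly interpolates each nucleus's fluorescence (and AP position)
#' onto a regular grid of `grid_dt_s` seconds anchored at the trace's
#' first observed frame. No extrapolation: the grid stops at the last
#' observed frame. Native 16.8 or 19.5 s movies are brought onto the 20 s
#' grid the inference uses this way.
#'
#' @param traces long tibble with `embryo_id`, `nucleus_id`, `time_s`,
#'   `fluo_au` (and optionally `ap_frac`, other id columns).
#' @param grid_dt_s target grid interval, seconds.
#' @return Tibble of the same shape on the new grid, with a `grid_dt_s`
#'   marker column; `frame` is renumbered.
#' @export
interpolate_to_grid <- function(traces, grid_dt_s = 20) {
  stopifnot(is.data.frame(traces),
            all(c("nucleus_id", "time_s", "fluo_au") %in% names(traces)))
  stop_if_not_scalar_num(grid_dt_s, "grid_dt_s", lo = 1e-9)
  key <- paste(traces$embryo_id, traces$nucleus_id)
  parts <- split(seq_len(nrow(traces)), key)
  out <- lapply(parts, function(idx) {
    tr <- traces[idx, ]
    tr <- tr[order(tr$time_s), ]
    t0 <- tr$time_s[1]
    span <- tr$time_s[nrow(tr)] - t0
    if (nrow(tr) < 2L || span < grid_dt_s) {
      stop("trace too short to interpolate onto the grid (needs to span >= one grid step)",
           call. = FALSE)
    }
    grid <- t0 + grid_dt_s * 0:floor(span / grid_dt_s + 1e-9)
    new <- tr[rep(1L, length(grid)), , drop = FALSE]
    new$time_s <- grid
    new$frame <- seq_along(grid)
    new$fluo_au <- stats::approx(tr$time_s, tr$fluo_au, grid)$y
    if ("ap_frac" %in% names(tr)) {
      new$ap_frac <- stats::approx(tr$time_s, tr$ap_frac, grid)$y
    }
    if ("true_state" %in% names(tr)) {
      new$true_state <- tr$true_state[
        pmax(1L, findInterval(grid, tr$time_s))]
    }
    new
  })
  res <- dplyr::bind_rows(out)
  res$grid_dt_s <- grid_dt_s
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

#' Drop traces with too few grid points
#'
#' @param traces long tibble of (interpolated) traces.
#' @param min_points minimum frames per nucleus (>= 2).
#' @return The filtered tibble, original row order preserved.
#' @export
filter_traces <- function(traces, min_points = 10) {
  stopifnot(is.data.frame(traces))
  if (min_points < 2) stop("`min_points` must be >= 2", call. = FALSE)
  key <- paste(traces$embryo_id, traces$nucleus_id)
  n <- table(key)
  keep <- key %in% names(n)[n >= min_points]
  traces[keep, , drop = FALSE]
}

#' Per-nucleus mean fluorescence and trace length
#'
#' Arithmetic mean of a trace's fluorescence over its frames, the
#' quantity the binning for per-bin inference sorts on.
#'
#' @param traces long tibble of interpolated traces.
#' @return Tibble with one row per nucleus: ids, `mean_fluo`, `n_points`,
#'   mean `ap_frac` if present.
#' @export
time_mean_fluo <- function(traces) {
  stopifnot(is.data.frame(traces))
  gcols <- intersect(c("embryo_id", "nucleus_id", "genotype"), names(traces))
  out <- dplyr::summarise(
    dplyr::group_by(traces, dplyr::across(dplyr::all_of(gcols))),
    mean_fluo = mean(.data$fluo_au),
    n_points = dplyr::n(),
    ap_frac = if ("ap_frac" %in% names(traces)) mean(.data$ap_frac) else NA_real_,
    .groups = "drop"
  )
  out
}
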