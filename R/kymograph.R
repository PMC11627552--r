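#' Register embryos onto pseudo-stripes
#'
#' Cross-embryo alignment for kymographs: the pseudo-stripe center of
#' each label is the mean of that label's per-embryo centers (the mean AP
#' of its active nuclei); every nucleus is repositioned to the
#' pseudo-center plus its offset from its own embryo's stripe center, so
#' within-stripe geometry is preserved. Nuclei without a label (inactive
#' or unassigned) use the offset of the nearest labeled stripe in their
#' embryo.
#'
#' @param nuclei tibble with `embryo_id`, `nucleus_id`, `ap_frac` and
#'   `region` (NA or `"none"` when unassigned).
#' @return List with `nuclei` (input plus `ap_registered`),
#'   `pseudo_centers` (label -> AP) and `embryo_centers`. Labels present
#'   in no embryo are skipped with a warning.
#' @export
register_pseudo_stripes <- function(nuclei) {
  stopifnot(is.data.frame(nuclei),
            all(c("embryo_id", "ap_frac", "region") %in% names(nuclei)))
  lab <- nuclei$region
  lab[lab %in% "none"] <- NA
  labeled <- !is.na(lab)
  if (!any(labeled)) stop("no labeled nuclei to register on", call. = FALSE)
  emb_ctr <- dplyr::summarise(
    dplyr::group_by(nuclei[labeled, ], .data$embryo_id,
                    region = lab[labeled]),
    center = mean(.data$ap_frac), .groups = "drop")
  pseudo <- dplyr::summarise(dplyr::group_by(emb_ctr, .data$region),
                             center = mean(.data$center), .groups = "drop")
  pseudo_ctr <- stats::setNames(pseudo$center, pseudo$region)
  out <- nuclei
  out$ap_registered <- NA_real_
  for (e in unique(nuclei$embryo_id)) {
    sel_e <- nuclei$embryo_id == e
    ec <- emb_ctr[emb_ctr$embryo_id == e, ]
    if (!nrow(ec)) {
      warning(sprintf("embryo %s has no labeled stripes; left unregistered", e))
      out$ap_registered[sel_e] <- nuclei$ap_frac[sel_e]
      next
    }
    offsets <- stats::setNames(pseudo_ctr[ec$region] - ec$center, ec$region)
    for (i in which(sel_e)) {
      li <- lab[i]
      if (is.na(li) || !li %in% names(offsets)) {
        nearest <- ec$region[which.min(abs(nuclei$ap_frac[i] - ec$center))]
        li <- nearest
      }
      out$ap_registered[i] <- nuclei$ap_frac[i] + offsets[[li]]
    }
  }
  list(nuclei = out, pseudo_centers = pseudo_ctr, embryo_centers = emb_ctr)
}

#' Build a time x AP kymograph of mean fluorescence
#'
#' Rows are `dt_s` time bins anchored at t = 0 of nc14; columns are AP
#' bins of `x_bin` embryo length (half-open `[lo, hi)`). Each cell is the
#' mean fluorescence over all frames of all nuclei falling in it; cells
#' with no nuclei are `NA` (empty), distinct from cells of silent nuclei
#' (0).
#'
#' @param traces long tibble of interpolated traces with an AP position
#'   column (`ap_registered` if present, else `ap_frac`).
#' @param x_bin AP bin width, fraction of embryo length.
#' @param dt_s time bin, seconds.
#' @param ap_range optional AP range; defaults to the data's span.
#' @return An object of class `kymograph`: `mean` and `count` matrices,
#'   `time_s` row starts, `ap` column starts.
#' @export
build_kymograph <- function(traces, x_bin = 0.005, dt_s = 20,
                            ap_range = NULL) {
  stopifnot(is.data.frame(traces))
  ap <- if ("ap_registered" %in% names(traces)) traces$ap_registered
        else traces$ap_frac
  if (is.null(ap_range)) {
    ap_range <- c(floor(min(ap) / x_bin) * x_bin,
                  ceiling(max(ap) / x_bin + 1e-9) * x_bin)
  }
  col <- floor((ap - ap_range[1]) / x_bin) + 1L
  n_col <- ceiling((ap_range[2] - ap_range[1]) / x_bin - 1e-9)
  row <- floor(traces$time_s / dt_s) + 1L
  n_row <- max(row)
  keep <- col >= 1L & col <= n_col
  idx <- (col[keep] - 1L) * n_row + row[keep]
  sums <- numeric(n_row * n_col)
  cnts <- numeric(n_row * n_col)
  agg_s <- rowsum(traces$fluo_au[keep], idx)
  agg_n <- rowsum(rep(1, sum(keep)), idx)
  at <- as.integer(rownames(agg_s))
  sums[at] <- agg_s[, 1]
  cnts[at] <- agg_n[, 1]
  mean_mat <- matrix(ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
                     n_row, n_col)
  structure(list(
    mean = mean_mat,
    count = matrix(cnts, n_row, n_col),
    time_s = (seq_len(n_row) - 1L) * dt_s,
    ap = ap_range[1] + (seq_len(n_col) - 1L) * x_bin,
    x_bin = x_bin, dt_s = dt_s
  ), class = "kymograph")
}

#' Write a kymograph as a dense CSV matrix plus a JSON axis sidecar
#'
#' @param kymo a [build_kymograph()] object.
#' @param path CSV path; the sidecar gets the same path with
#'   `"_axes.json"` appended.
#' @return Invisibly, the two paths written.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  utils::write.table(kymo$mean, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  axes_path <- paste0(sub("\\.csv$", "", path), "_axes.json")
  jsonlite::write_json(list(time_s = kymo$time_s, ap = kymo$ap,
                            x_bin = kymo$x_bin, dt_s = kymo$dt_s),
                       axes_path, digits = NA)
  invisible(c(path, axes_path))
}

#' Plot a kymograph
#'
#' @param x a [build_kymograph()] object.
#' @param ... unused.
#' @return A ggplot object (requires ggplot2).
#' @export
plot.kymograph <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- expand.grid(time_min = x$time_s / SEC_PER_MIN, ap = x$ap)
  df$fluo <- as.vector(x$mean)
  ggplot2::ggplot(df, ggplot2::aes(.data$ap, .data$time_min,
                                   fill = .data$fluo)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "AP position (fraction EL)", y = "time into nc14 (min)",
                  fill = "mean MS2\nfluorescence (AU)")
}
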