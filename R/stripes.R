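#' Accumulated fluorescent output in five-minute windows
#'
#' Sums each nucleus's fluorescence within consecutive windows of
#' `window_min` minutes (window 1 covers `[0, window_min)` min, etc.),
#' the weights used to track nuclei during dynamic stripe assignment.
#'
#' @param traces long tibble of interpolated traces.
#' @param window_min window length in minutes.
#' @return Tibble with `embryo_id`, `nucleus_id`, `window`, `acc_fluo`,
#'   mean `ap_frac` in the window, and `n_frames`.
#' @export
accumulate_windows <- function(traces, window_min = 5) {
  stopifnot(is.data.frame(traces))
  stop_if_not_scalar_num(window_min, "window_min", lo = 1e-9)
  win <- floor(traces$time_s / (window_min * SEC_PER_MIN)) + 1L
  dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(traces, window = win),
      .data$embryo_id, .data$nucleus_id, .data$window),
    acc_fluo = sum(.data$fluo_au),
    ap_frac = mean(.data$ap_frac),
    n_frames = dplyr::n(),
    .groups = "drop"
  )
}

# weighted 1-D k-means (Lloyd with restarts); returns cluster per point
# ordered so that cluster 1 is the leftmost center
wkmeans1 <- function(x, wgt, k, n_restarts = 10) {
  n <- length(x)
  if (length(unique(x)) < k) {
    stop(sprintf("fewer distinct positions (%d) than clusters (%d)",
                 length(unique(x)), k), call. = FALSE)
  }
  wgt <- pmax(wgt, 1e-12)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    ctr <- sort(sample(unique(x), k))
    for (it in 1:100) {
      d <- abs(outer(x, ctr, "-"))
      assign <- max.col(-d, ties.method = "first")
      new_ctr <- vapply(seq_len(k), function(j) {
        sel <- assign == j
        if (!any(sel)) x[which.max(d[cbind(seq_len(n), assign)])]
        else sum(wgt[sel] * x[sel]) / sum(wgt[sel])
      }, numeric(1))
      if (max(abs(new_ctr - ctr)) < 1e-12) { ctr <- new_ctr; break }
      ctr <- new_ctr
    }
    d <- abs(outer(x, ctr, "-"))
    assign <- max.col(-d, ties.method = "first")
    inertia <- sum(wgt * (x - ctr[assign])^2)
    if (is.null(best) || inertia < best$inertia) {
      best <- list(ctr = ctr, assign = assign, inertia = inertia)
    }
  }
  ord <- order(best$ctr)
  rank <- match(seq_len(k), ord)
  list(cluster = rank[best$assign], centers = best$ctr[ord],
       inertia = best$inertia)
}

#' Dynamic stripe assignment by weighted k-means
#'
#' Per embryo and per five-minute window, runs 1-D k-means on nucleus AP
#' position weighted by the accumulated fluorescent output in that
#' window; clusters are relabeled left to right with the supplied stripe
#' labels. Nuclei active before `ref_time_min` (25 min) take their label
#' from the window containing that reference time; nuclei never seen
#' there keep the majority label over their active windows (ties to the
#' more anterior stripe).
#'
#' @param traces long tibble of interpolated traces of active nuclei.
#' @param k number of stripes expected for the genotype.
#' @param labels stripe labels left to right (length `k`); default
#'   `"S1".."Sk"`.
#' @param window_min window length in minutes.
#' @param ref_time_min reference time for early-active nuclei, minutes.
#' @param seed optional integer seed (k-means restarts draw initial
#'   centers).
#' @return Tibble with `embryo_id`, `nucleus_id`, `region`,
#'   `method = "kmeans"`.
#' @export
kmeans_assign <- function(traces, k, labels = NULL, window_min = 5,
                          ref_time_min = 25, seed = NULL) {
  stopifnot(k >= 1)
  if (is.null(labels)) labels <- paste0("S", seq_len(k))
  stopifnot(length(labels) == k)
  acc <- accumulate_windows(traces, window_min)
  ref_window <- floor(ref_time_min / window_min) + 1L
  with_local_seed(seed, {
    out <- lapply(split(acc, acc$embryo_id), function(a) {
      a$region <- NA_character_
      for (wi in sort(unique(a$window))) {
        sel <- a$window == wi
        if (sum(sel) < k) next
        km <- wkmeans1(a$ap_frac[sel], a$acc_fluo[sel], k)
        a$region[sel] <- labels[km$cluster]
      }
      # final label per nucleus
      per_nuc <- lapply(split(a, a$nucleus_id), function(d) {
        lab <- if (ref_window %in% d$window) {
          d$region[match(ref_window, d$window)]
        } else {
          tab <- table(factor(d$region, levels = labels))
          if (sum(tab) == 0) NA_character_ else names(tab)[which.max(tab)]
        }
        tibble::tibble(embryo_id = d$embryo_id[1],
                       nucleus_id = d$nucleus_id[1], region = lab)
      })
      dplyr::bind_rows(per_nuc)
    })
    res <- dplyr::bind_rows(out)
    res$method <- "kmeans"
    res
  })
}

#' Manual stripe assignment from AP boundary tables
#'
#' Labels each nucleus by the half-open interval `[lo, hi)` containing
#' its reference AP position (by default its position at the grid frame
#' nearest 45 min, when stripes have separated from the background).
#' Positions outside every interval get `"none"`.
#'
#' @param nuclei tibble with `nucleus_id` and `ap_frac` (one row per
#'   nucleus), or a long trace tibble from which the reference position
#'   is taken at `ref_time_min`.
#' @param boundaries tibble with `region`, `lo`, `hi` (sorted, fraction
#'   EL), e.g. `make_genotype_spec()$boundaries`.
#' @param ref_time_min reference time (min) when `nuclei` is a long
#'   trace table.
#' @return Tibble with `embryo_id` (if present), `nucleus_id`, `region`,
#'   `method = "manual"`.
#' @export
manual_assign <- function(nuclei, boundaries, ref_time_min = 45) {
  stopifnot(is.data.frame(nuclei),
            all(c("region", "lo", "hi") %in% names(boundaries)))
  if (any(diff(boundaries$lo) <= 0) ||
      any(boundaries$hi[-nrow(boundaries)] != boundaries$lo[-1])) {
    stop("`boundaries` must be sorted, contiguous half-open intervals",
         call. = FALSE)
  }
  if ("time_s" %in% names(nuclei)) {
    key <- paste(nuclei$embryo_id, nuclei$nucleus_id)
    nuclei <- dplyr::bind_rows(lapply(split(nuclei, key), function(tr) {
      i <- which.min(abs(tr$time_s - ref_time_min * SEC_PER_MIN))
      tr[i, intersect(c("embryo_id", "nucleus_id", "ap_frac"), names(tr))]
    }))
  }
  cuts <- c(boundaries$lo, boundaries$hi[nrow(boundaries)])
  idx <- findInterval(nuclei$ap_frac, cuts, rightmost.closed = FALSE)
  region <- ifelse(idx >= 1 & idx <= nrow(boundaries) &
                     nuclei$ap_frac < cuts[length(cuts)],
                   boundaries$region[pmin(pmax(idx, 1L), nrow(boundaries))],
                   "none")
  out <- nuclei[, intersect(c("embryo_id", "nucleus_id"), names(nuclei)),
                drop = FALSE]
  out$region <- region
  out$method <- "manual"
  tibble::as_tibble(out)
}

#' Label assigned regions as endogenous or ectopic
#'
#' Stripe 0 and the stripe 1-2 interstripe are ectopic; numbered stripes
#' S1-S5 are endogenous, including stripe 1 in genotypes with a disrupted
#' stripe 1 enhancer. Every region in wild-type embryos is endogenous.
#'
#' @param assignments tibble with a `region` column.
#' @param genotype genotype name.
#' @return The tibble with an added logical `ectopic` column (NA for
#'   `"none"`).
#' @export
flag_ectopic <- function(assignments, genotype) {
  stopifnot(is.data.frame(assignments), "region" %in% names(assignments))
  ect <- assignments$region %in% c("S0", "S1_2")
  if (identical(genotype, "wildtype")) ect <- rep(FALSE, nrow(assignments))
  ect[assignments$region %in% c("none", NA)] <- NA
  assignments$ectopic <- ect
  assignments
}
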