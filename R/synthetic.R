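GENOTYPES <- c("wildtype", "eveS1wt_eveS2Gt", "eveS1null_eveS2wt",
               "eveS1null_eveS2Gt")

# stripe centers in fraction of embryo length (anterior = 0)
STRIPE_CENTERS <- c(S0 = 0.20, S1 = 0.30, S1_2 = 0.34, S2 = 0.40,
                    S3 = 0.49, S4 = 0.58)

#' Genotype specification for the synthetic embryo generator
#'
#' Describes which expression regions a genotype carries, where they sit
#' along the anterior-posterior (AP) axis, whether each is endogenous or
#' ectopic, and its mean-output scale relative to an endogenous stripe.
#' Ectopic regions (stripe 0 and the stripe 1-2 interstripe) get a lower
#' mean output than endogenous stripes. A manual AP boundary table is
#' attached per genotype, with the stripe 1-2 / stripe 2 boundary at 36%
#' of embryo length.
#'
#' @param name one of `"wildtype"`, `"eveS1wt_eveS2Gt"`,
#'   `"eveS1null_eveS2wt"`, `"eveS1null_eveS2Gt"`.
#' @param ectopic_scale mean-output scale of ectopic regions (< 1).
#' @return An object of class `genotype_spec` with a `regions` tibble
#'   (label, center, half_width, endogenous, scale) and a `boundaries`
#'   tibble (region, lo, hi) of half-open `[lo, hi)` AP intervals.
#' @export
make_genotype_spec <- function(name, ectopic_scale = 0.6) {
  if (!name %in% GENOTYPES) {
    stop(sprintf("unknown genotype '%s'; expected one of: %s",
                 name, paste(GENOTYPES, collapse = ", ")), call. = FALSE)
  }
  stopifnot(ectopic_scale > 0, ectopic_scale < 1)
  labels <- switch(name,
    wildtype          = c("S1", "S2", "S3", "S4"),
    eveS1wt_eveS2Gt   = c("S1", "S1_2", "S2", "S3", "S4"),
    eveS1null_eveS2wt = c("S0", "S1", "S2", "S3", "S4"),
    eveS1null_eveS2Gt = c("S0", "S1", "S1_2", "S2", "S3", "S4"))
  endo <- !labels %in% c("S0", "S1_2")
  scale <- ifelse(endo, 1, ectopic_scale)
  # the Gt-site deletions strengthen stripe 2 relative to wild type
  if (name == "eveS1null_eveS2Gt") scale[labels == "S2"] <- 1.2
  regions <- tibble::tibble(
    label = labels,
    center = unname(STRIPE_CENTERS[labels]),
    half_width = ifelse(labels == "S1_2", 0.03, 0.02),
    endogenous = endo,
    scale = scale
  )
  boundaries <- stripe_boundaries(regions)
  structure(list(name = name, regions = regions, boundaries = boundaries),
            class = "genotype_spec")
}

# contiguous half-open AP intervals: midpoints between neighboring stripe
# centers, except the fixed S1_2/S2 boundary at 0.36 EL
stripe_boundaries <- function(regions) {
  ctr <- regions$center
  n <- nrow(regions)
  cuts <- c(ctr[1] - 0.04, (ctr[-n] + ctr[-1]) / 2, ctr[n] + 0.04)
  i12 <- which(regions$label == "S1_2")
  if (length(i12) && any(regions$label == "S2")) cuts[i12 + 1L] <- 0.36
  tibble::tibble(region = regions$label, lo = cuts[-(n + 1L)], hi = cuts[-1L])
}

#' Sample nuclei for one synthetic embryo
#'
#' Active nuclei are drawn around each region center from a normal
#' truncated to `[0, 1]` with s.d. half_width / 2; inactive nuclei are a
#' mix of extra within-region nuclei (so that `active_fraction` of
#' region nuclei are active) and background nuclei uniform over the
#' imaging window.
#'
#' @param spec a [make_genotype_spec()].
#' @param n_per_region active nuclei per region.
#' @param n_background inactive background nuclei.
#' @param active_fraction fraction of region nuclei that are active.
#' @param ap_window AP extent of the imaging window.
#' @param seed optional integer seed.
#' @return Tibble with `nucleus_id`, `ap_frac`, `region` (NA for
#'   background), `active`.
#' @export
sample_nuclei <- function(spec, n_per_region = 40, n_background = 60,
                          active_fraction = 0.8, ap_window = c(0.1, 0.7),
                          seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"),
            n_per_region > 0, n_background > 0,
            active_fraction > 0, active_fraction <= 1)
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(spec$regions)), function(i) {
      rg <- spec$regions[i, ]
      n_inact <- round(n_per_region * (1 - active_fraction) / active_fraction)
      n_tot <- n_per_region + n_inact
      tibble::tibble(
        ap_frac = rtruncnorm1(n_tot, rg$center, rg$half_width / 2),
        region = rg$label,
        active = rep(c(TRUE, FALSE), c(n_per_region, n_inact))
      )
    })
    bg <- tibble::tibble(
      ap_frac = stats::runif(n_background, ap_window[1], ap_window[2]),
      region = NA_character_,
      active = FALSE
    )
    out <- dplyr::bind_rows(c(rows, list(bg)))
    out$nucleus_id <- sprintf("n%03d", seq_len(nrow(out)))
    out[, c("nucleus_id", "ap_frac", "region", "active")]
  })
}

#' Kinetic model matching a target mean fluorescence
#'
#' Maps a nucleus's target mean MS2 fluorescence onto two-sister telegraph
#' parameters following the wild-type operating range: effective k_on
#' scales affinely from 0.5 to 1.5 per minute and r from 5 to 10 AU/min as
#' the target spans 2-15 AU, with k_off fixed at 0.5 per minute. The
#' initiation rates are then rescaled so that the model's steady-state
#' mean fluorescence hits the target exactly.
#'
#' @param target_meanF target time-averaged fluorescence, AU.
#' @param meanF_range admissible target range (AU).
#' @param kon_range,r_range,koff affine endpoints of the parameter map.
#' @inheritParams promoter_rate_model
#' @return A [promoter_rate_model()] with attribute `truth`, the implied
#'   effective [burst_params()], and attribute `meanF_target`.
#' @export
params_from_target <- function(target_meanF, meanF_range = c(2, 15),
                               kon_range = c(0.5, 1.5), r_range = c(5, 10),
                               koff = 0.5, t_elong = 140, dt_frame = 20,
                               sigma_noise = 1.5) {
  stop_if_not_scalar_num(target_meanF, "target_meanF",
                         lo = meanF_range[1], hi = meanF_range[2])
  u <- (target_meanF - meanF_range[1]) / diff(meanF_range)
  k_on <- kon_range[1] + u * diff(kon_range)
  r <- r_range[1] + u * diff(r_range)
  model <- model_from_burst_params(k_on, koff, r, t_elong = t_elong,
                                   dt_frame = dt_frame,
                                   sigma_noise = sigma_noise)
  kern <- emission_kernel(t_elong, dt_frame)
  bp <- aggregate_burst_params(model$Q, model$r_vec)
  implied <- mean_initiation_rate(bp) * sum(kern) * dt_frame / SEC_PER_MIN
  model$r_vec <- model$r_vec * target_meanF / implied
  truth <- aggregate_burst_params(model$Q, model$r_vec)
  attr(model, "truth") <- truth
  attr(model, "meanF_target") <- target_meanF
  model
}

#' Generate a synthetic multi-embryo MS2 dataset
#'
#' For each embryo, stripe centers are jittered (s.d. `jitter_sd`),
#' nuclei are sampled, and every active nucleus gets a target mean
#' fluorescence drawn per its region's output scale, a kinetic model from
#' [params_from_target()], a Gillespie promoter path and a rendered
#' noisy trace. Frame intervals of 16.8 or 19.5 s over up to 50 min of
#' nc14 emulate the imaging protocol.
#'
#' @param spec a [make_genotype_spec()] (or genotype name).
#' @param n_embryos number of embryos.
#' @param frame_dt_s frame interval in seconds (16.8, 19.5 or 20).
#' @param duration_min imaging duration in minutes (<= 50).
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param jitter_sd s.d. of per-embryo stripe-center jitter (EL).
#' @param meanF_range admissible range of target mean fluorescence (AU).
#' @param dir optional directory; if given, `traces.csv` and `truth.csv`
#'   are written there.
#' @inheritParams sample_nuclei
#' @inheritParams promoter_rate_model
#' @return An object of class `embryo_experiment`: the genotype spec and one
#'   `embryo_dataset` per embryo (nuclei, traces, truth, jittered
#'   centers). Use [collect_traces()] / [collect_truth()] to pool.
#' @export
generate_dataset <- function(spec, n_embryos = 1, frame_dt_s = 16.8,
                             duration_min = 40, n_per_region = 40,
                             n_background = 60, active_fraction = 0.8,
                             jitter_sd = 0.005, meanF_range = c(2, 15),
                             t_elong = 140, sigma_noise = 1.5, seed = 1,
                             dir = NULL) {
  if (is.character(spec)) spec <- make_genotype_spec(spec)
  stopifnot(inherits(spec, "genotype_spec"))
  if (!frame_dt_s %in% c(16.8, 19.5, 20)) {
    stop("`frame_dt_s` must be one of 16.8, 19.5, 20", call. = FALSE)
  }
  if (duration_min > 50) stop("`duration_min` must be <= 50", call. = FALSE)
  embryos <- with_local_seed(seed, {
    lapply(seq_len(n_embryos), function(e) {
      espec <- spec
      espec$regions$center <- pmin(pmax(
        spec$regions$center + stats::rnorm(nrow(spec$regions), 0, jitter_sd),
        0.02), 0.98)
      nuc <- sample_nuclei(espec, n_per_region, n_background, active_fraction)
      embryo_id <- sprintf("%s_e%02d", spec$name, e)
      act <- which(nuc$active)
      traces <- vector("list", length(act))
      truth <- vector("list", length(act))
      for (i in seq_along(act)) {
        row <- nuc[act[i], ]
        sc <- espec$regions$scale[espec$regions$label == row$region]
        base <- stats::runif(1, meanF_range[1], meanF_range[2])
        target <- min(max(sc * base, meanF_range[1]), meanF_range[2])
        model <- params_from_target(target, meanF_range = meanF_range,
                                    t_elong = t_elong,
                                    dt_frame = frame_dt_s,
                                    sigma_noise = sigma_noise)
        path <- simulate_chain_path(model$Q, duration_min)
        tr <- render_trace(path, model)
        tr$embryo_id <- embryo_id
        tr$nucleus_id <- row$nucleus_id
        tr$genotype <- spec$name
        tr$ap_frac <- row$ap_frac
        traces[[i]] <- tr
        bp <- attr(model, "truth")
        truth[[i]] <- tibble::tibble(
          embryo_id = embryo_id, nucleus_id = row$nucleus_id,
          region = row$region,
          k_on_true = bp$k_on, k_off_true = bp$k_off, r_true = bp$r,
          meanF_target = target)
      }
      traces <- dplyr::bind_rows(traces)
      traces <- traces[, c("embryo_id", "nucleus_id", "genotype", "frame",
                           "time_s", "ap_frac", "fluo_au", "true_state")]
      list(embryo_id = embryo_id, genotype = spec$name, nuclei = nuc,
           traces = traces, truth = dplyr::bind_rows(truth),
           centers = stats::setNames(espec$regions$center,
                                     espec$regions$label))
    })
  })
  out <- structure(list(spec = spec, embryos = embryos,
                        frame_dt_s = frame_dt_s,
                        duration_min = duration_min, seed = seed),
                   class = "embryo_experiment")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(collect_traces(out), file.path(dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(collect_truth(out), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  out
}

#' Pool traces across the embryos of an experiment
#' @param experiment an `embryo_experiment`.
#' @return Long tibble, one row per nucleus per frame.
#' @export
collect_traces <- function(experiment) {
  stopifnot(inherits(experiment, "embryo_experiment"))
  dplyr::bind_rows(lapply(experiment$embryos, `[[`, "traces"))
}

#' Pool ground-truth burst parameters across embryos
#' @param experiment an `embryo_experiment`.
#' @return Tibble, one row per active nucleus.
#' @export
collect_truth <- function(experiment) {
  stopifnot(inherits(experiment, "embryo_experiment"))
  dplyr::bind_rows(lapply(experiment$embryos, `[[`, "truth"))
}

#' Pool nucleus tables across embryos
#' @param experiment an `embryo_experiment`.
#' @return Tibble, one row per nucleus (active and inactive).
#' @export
collect_nuclei <- function(experiment) {
  stopifnot(inherits(experiment, "embryo_experiment"))
  dplyr::bind_rows(lapply(experiment$embryos, function(e) {
    out <- e$nuclei
    out$embryo_id <- e$embryo_id
    out$genotype <- e$genotype
    out
  }))
}
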