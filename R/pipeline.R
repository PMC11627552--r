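#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis (simulate ->
#' preprocess -> assign -> bin -> infer -> trends -> kymograph) with an
#' explicit seed for every stochastic stage. Round-trips through YAML
#' unchanged.
#'
#' @param genotype genotype name (see [make_genotype_spec()]).
#' @param seed master integer seed.
#' @param n_embryos embryos to simulate.
#' @param frame_dt_s native frame interval, seconds.
#' @param duration_min imaging duration, minutes.
#' @param n_per_region,n_background,active_fraction nucleus counts per
#'   embryo.
#' @param grid_dt_s inference grid, seconds.
#' @param t_elong elongation time, seconds.
#' @param sigma_noise imaging noise s.d., AU.
#' @param K promoter states.
#' @param n_restarts,max_iter,tol EM settings.
#' @param bin_target,bin_min_points binning rule (~40 traces, ~2500
#'   points).
#' @param min_trace_points minimum interpolated points per trace.
#' @param assign_method `"auto"` (manual boundaries for Gt-site mutant
#'   genotypes, k-means otherwise), `"kmeans"` or `"manual"`.
#' @param infer whether to run per-bin cpHMM inference.
#' @param n_boot bootstrap replicates per bin (0 disables).
#' @param out_dir artifact directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype = "wildtype", seed = 1, n_embryos = 3,
                            frame_dt_s = 16.8, duration_min = 40,
                            n_per_region = 40, n_background = 60,
                            active_fraction = 0.8, grid_dt_s = 20,
                            t_elong = 140, sigma_noise = 1.5, K = 3,
                            n_restarts = 3, max_iter = 100, tol = 1e-4,
                            bin_target = 40, bin_min_points = 2500,
                            min_trace_points = 10,
                            assign_method = c("auto", "kmeans", "manual"),
                            infer = TRUE, n_boot = 0,
                            out_dir = tempfile("msburst_run_")) {
  assign_method <- match.arg(assign_method)
  if (!genotype %in% GENOTYPES) {
    stop(sprintf("unknown genotype '%s'", genotype), call. = FALSE)
  }
  cfg <- list(genotype = genotype, seed = seed, n_embryos = n_embryos,
              frame_dt_s = frame_dt_s, duration_min = duration_min,
              n_per_region = n_per_region, n_background = n_background,
              active_fraction = active_fraction, grid_dt_s = grid_dt_s,
              t_elong = t_elong, sigma_noise = sigma_noise, K = K,
              w = as.integer(round(t_elong / grid_dt_s)),
              n_restarts = n_restarts, max_iter = max_iter, tol = tol,
              bin_target = bin_target, bin_min_points = bin_min_points,
              min_trace_points = min_trace_points,
              assign_method = assign_method, infer = infer, n_boot = n_boot,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals$w <- NULL  # derived
  yaml::write_yaml(vals, path)
  invisible(path)
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  attr(res, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
}

#' Run the full analysis pipeline
#'
#' Simulates a synthetic genotype dataset, interpolates to the inference
#' grid, assigns nuclei to stripes and endogenous/ectopic classes, bins
#' by mean fluorescence, optionally runs per-bin cpHMM inference for both
#' groupings, registers pseudo-stripes and builds the kymograph. All
#' artifacts (trace, truth, assignment, trend and kymograph CSVs plus a
#' manifest with the config hash and per-stage timings) are written to
#' `config$out_dir`. Deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the artifact paths and in-memory
#'   results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(name, expr) {
    res <- pipeline_stage(name, expr)
    timings[[name]] <<- attr(res, "elapsed_s")
    res
  }

  spec <- make_genotype_spec(config$genotype)
  experiment <- clock("simulate", generate_dataset(
    spec, n_embryos = config$n_embryos, frame_dt_s = config$frame_dt_s,
    duration_min = config$duration_min, n_per_region = config$n_per_region,
    n_background = config$n_background,
    active_fraction = config$active_fraction, t_elong = config$t_elong,
    sigma_noise = config$sigma_noise, seed = config$seed,
    dir = config$out_dir))

  traces <- clock("preprocess", {
    tr <- interpolate_to_grid(collect_traces(experiment), config$grid_dt_s)
    filter_traces(tr, config$min_trace_points)
  })

  assignments <- clock("assign", {
    method <- config$assign_method
    if (method == "auto") {
      method <- if (grepl("Gt$", config$genotype)) "manual" else "kmeans"
    }
    asg <- if (method == "manual") {
      manual_assign(traces, spec$boundaries)
    } else {
      kmeans_assign(traces, k = nrow(spec$regions),
                    labels = spec$regions$label,
                    seed = config$seed + 1L)
    }
    flag_ectopic(asg, config$genotype)
  })
  utils::write.csv(assignments, file.path(config$out_dir, "assignments.csv"),
                   row.names = FALSE)

  summaries <- dplyr::inner_join(
    time_mean_fluo(traces),
    assignments[, c("embryo_id", "nucleus_id", "region", "ectopic")],
    by = c("embryo_id", "nucleus_id"))

  space <- NULL
  trend_paths <- list()
  trends <- list()
  if (config$infer) {
    space <- build_state_space(config$K, config$w)
    emcfg <- cphmm_config(n_restarts = config$n_restarts,
                          max_iter = config$max_iter, tol = config$tol,
                          seed = config$seed + 2L)
    for (grouping in c("stripe", "ectopic")) {
      smm <- summaries
      smm$group <- if (grouping == "stripe") smm$region else
        ifelse(smm$ectopic, "ectopic", "endogenous")
      smm <- smm[!is.na(smm$group) & smm$group != "none", ]
      bins <- make_bins(smm, config$bin_target, config$bin_min_points)
      if (!nrow(bins$summary)) next
      curve <- clock(paste0("infer_", grouping),
                     infer_trend(bins, traces, space, emcfg,
                                 dt_grid = config$grid_dt_s,
                                 keep_fits = TRUE))
      fits <- attr(curve, "fits")
      for (nm in names(fits)) {
        write_fit_json(fits[[nm]], file.path(
          config$out_dir, sprintf("fit_%s_%s.json", grouping, nm)))
      }
      curve$sigma_kon <- NA_real_
      curve$sigma_koff <- NA_real_
      curve$sigma_r <- NA_real_
      if (config$n_boot >= 2) {
        for (i in seq_len(nrow(curve))) {
          members <- bins$assignments[
            bins$assignments$group == curve$group[i] &
              bins$assignments$bin == curve$bin[i], ]
          bs <- bootstrap_uncertainty(
            bin_trace_list(members, traces), space,
            n_boot = config$n_boot, config = emcfg,
            seed = config$seed + 10L + i, dt_grid = config$grid_dt_s)
          curve$sigma_kon[i] <- bs$sigma_kon
          curve$sigma_koff[i] <- bs$sigma_koff
          curve$sigma_r[i] <- bs$sigma_r
        }
      }
      trends[[grouping]] <- curve
      p <- file.path(config$out_dir, sprintf("trends_%s.csv", grouping))
      utils::write.csv(curve, p, row.names = FALSE)
      trend_paths[[grouping]] <- p
    }
  }

  kymo <- clock("kymograph", {
    nuclei <- collect_nuclei(experiment)
    nuclei$region[match(paste(assignments$embryo_id, assignments$nucleus_id),
                        paste(nuclei$embryo_id, nuclei$nucleus_id))] <-
      assignments$region
    reg <- register_pseudo_stripes(nuclei)
    key_tr <- paste(traces$embryo_id, traces$nucleus_id)
    key_nu <- paste(reg$nuclei$embryo_id, reg$nuclei$nucleus_id)
    tr <- traces
    tr$ap_registered <- reg$nuclei$ap_registered[match(key_tr, key_nu)]
    build_kymograph(tr, dt_s = config$grid_dt_s)
  })
  write_kymograph(kymo, file.path(config$out_dir, "kymograph.csv"))

  manifest <- list(
    package = "msburst",
    version = as.character(utils::packageVersion("msburst")),
    config = unclass(config),
    # hash the scientific settings only, not the artifact location
    config_hash = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    timings_s = timings,
    n_traces = length(unique(paste(traces$embryo_id, traces$nucleus_id))),
    created = "see config seed; outputs are a pure function of the config"
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = config$out_dir, traces = traces,
                 assignments = assignments, trends = trends,
                 kymograph = kymo, manifest = manifest))
}
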