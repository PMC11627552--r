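make_summaries <- function(n, group = "S2") {
  tibble::tibble(
    embryo_id = "e1",
    nucleus_id = sprintf("%s_n%03d", group, seq_len(n)),
    group = group,
    mean_fluo = seq(2, 15, length.out = n),
    n_points = 70L)
}

test_that("binning follows the ~40-trace rule with equal-as-possible sizes", {
  b120 <- make_bins(make_summaries(120), target_traces = 40)
  expect_equal(b120$summary$n_traces, rep(40L, 3))

  b39 <- make_bins(make_summaries(39), target_traces = 40)
  expect_equal(nrow(b39$summary), 0)
  expect_equal(b39$dropped, "S2")

  b100 <- make_bins(make_summaries(100), target_traces = 40)
  expect_equal(b100$summary$n_traces, c(50L, 50L))

  b85 <- make_bins(make_summaries(85), target_traces = 40)
  expect_equal(sort(b85$summary$n_traces), c(42L, 43L))
})

test_that("binning conserves traces and keeps bins ordered by fluorescence", {
  smm <- dplyr::bind_rows(make_summaries(97, "S1"), make_summaries(45, "S3"),
                          make_summaries(12, "S4"))
  b <- make_bins(smm, target_traces = 40)
  expect_equal(nrow(b$assignments), 97 + 45)   # S4 dropped
  expect_equal(anyDuplicated(b$assignments$nucleus_id), 0)
  expect_equal(b$dropped, "S4")
  for (g in unique(b$summary$group)) {
    s <- b$summary[b$summary$group == g, ]
    expect_true(all(diff(s$mean_fluo) > 0))
  }
  expect_equal(sum(b$summary$n_traces), nrow(b$assignments))
})

test_that("bin point-count flagging matches the 2500-point rule", {
  smm <- make_summaries(80)           # 2 bins x 40 traces x 70 pts = 2800
  b <- make_bins(smm, target_traces = 40, min_points = 2500)
  expect_true(all(b$summary$points_ok))
  smm$n_points <- 30L                  # 40 x 30 = 1200 < 2500
  b2 <- make_bins(smm, target_traces = 40, min_points = 2500)
  expect_false(any(b2$summary$points_ok))
})

test_that("per-bin inference recovers the generator's rising-k_on trend", {
  # traces simulated along the wild-type parameter map; 3 bins of 12
  set.seed(11)
  targets <- seq(2.5, 14.5, length.out = 36)
  traces <- list()
  smm <- list()
  for (i in seq_along(targets)) {
    m <- params_from_target(targets[i], t_elong = 60)
    p <- simulate_chain_path(m$Q, 21, seed = 200 + i)
    tr <- render_trace(p, m, n_frames = 60, seed = 300 + i)
    id <- sprintf("n%03d", i)
    traces[[i]] <- tibble::tibble(embryo_id = "e1", nucleus_id = id,
                                  time_s = tr$time_s, fluo_au = tr$fluo_au)
    smm[[i]] <- tibble::tibble(embryo_id = "e1", nucleus_id = id,
                               group = "S2", mean_fluo = mean(tr$fluo_au),
                               n_points = nrow(tr))
  }
  traces <- dplyr::bind_rows(traces)
  bins <- make_bins(dplyr::bind_rows(smm), target_traces = 12, min_points = 0)
  sp <- build_state_space(3, 3)
  curve <- infer_trend(bins, traces, sp,
                       cphmm_config(n_restarts = 2, max_iter = 60, seed = 17))
  expect_equal(nrow(curve), 3)
  expect_true(all(diff(curve$kon_per_min) > 0))
  # k_off has no trend by construction; 12-trace bins scatter more than
  # the ~40-trace bins of the full analysis, so only a loose band here
  expect_lt(max(curve$koff_per_min) / min(curve$koff_per_min), 2.2)
  expect_true(all(diff(curve$mean_fluo) > 0))
})

test_that("bootstrap uncertainties are reproducible and scale sanely", {
  tl <- simulate_bin(1, 0.5, 7.5, n_traces = 10, n_frames = 40,
                     t_elong = 60, seed = 23)
  sp <- build_state_space(3, 3)
  cfg <- cphmm_config(n_restarts = 1, max_iter = 30, seed = 1)
  bs1 <- bootstrap_uncertainty(tl, sp, n_boot = 3, config = cfg, seed = 5)
  bs2 <- bootstrap_uncertainty(tl, sp, n_boot = 3, config = cfg, seed = 5)
  expect_equal(bs1$replicates, bs2$replicates)
  expect_true(all(c(bs1$sigma_kon, bs1$sigma_koff, bs1$sigma_r) >= 0))
  expect_equal(bs1$n_ok + bs1$n_failed, 3)
})

test_that("fits serialize to JSON with their full parameter set", {
  tl <- simulate_bin(1, 0.5, 7.5, n_traces = 4, n_frames = 30,
                     t_elong = 60, seed = 41)
  sp <- build_state_space(3, 3)
  fit <- em_fit(tl, sp, cphmm_config(n_restarts = 1, max_iter = 15, seed = 2))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(dim(js$A), c(3, 3))
  expect_equal(js$r_vec, fit$params$r_vec)
  expect_equal(length(js$loglik_trace), length(fit$loglik_trace))
  unlink(path)
})

test_that("strategy comparison classifies matched and mismatched curves", {
  rising <- tibble::tibble(mean_fluo = c(3, 6, 9, 12),
                           kon_per_min = c(0.5, 0.8, 1.1, 1.5),
                           koff_per_min = c(0.5, 0.55, 0.48, 0.5),
                           r_au_per_min = c(5, 6.5, 8, 10))
  rising2 <- dplyr::mutate(rising, kon_per_min = kon_per_min * 1.05)
  cmp <- compare_strategies(rising, rising2)
  expect_true(cmp$same_strategy)
  expect_equal(cmp$verdict, "same strategy")
  expect_equal(cmp$curveA$fold_kon, 3)
  expect_equal(cmp$curveA$fold_r, 2)

  # burst-duration-modulating counterexample: k_off drives the trend
  duration_mod <- tibble::tibble(mean_fluo = c(3, 6, 9, 12),
                                 kon_per_min = rep(0.8, 4),
                                 koff_per_min = c(1.5, 0.9, 0.55, 0.3),
                                 r_au_per_min = c(7, 7, 7, 7))
  cmp2 <- compare_strategies(rising, duration_mod)
  expect_false(cmp2$same_strategy)
  expect_error(compare_strategies(rising, rising[1, ]), ">= 2 points")
})
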