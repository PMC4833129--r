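test_that("the experiment enumerates the full condition grid", {
  cfg <- experiment_config(protocols = "p12345", snr_levels = Inf,
                           n_orientations = 5L, n_trials = 1L)
  res <- run_experiment(cfg)
  expect_equal(nrow(res), 4 * 5 * 5 * 1)   # icvf x kappa x orientations x trials
  expect_true(all(res$icvf_est >= 0 & res$icvf_est <= 1))
  expect_true(all(res$odi_est > 0 & res$odi_est <= 1))
  expect_true(all(res$fiso_est >= 0 & res$fiso_est <= 1))
  # noise-free estimates sit on the truth
  expect_lt(max(abs(res$icvf_est - res$icvf_true)), 0.02)
})

test_that("runs are deterministic under a fixed master seed", {
  cfg <- experiment_config(protocols = "NODDI-p14", snr_levels = 20,
                           icvf_grid = 0.6, kappa_grid = 4,
                           n_orientations = 2L, n_trials = 2L,
                           master_seed = 13L)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1, r2)
  r3 <- run_experiment(experiment_config(
    protocols = "NODDI-p14", snr_levels = 20, icvf_grid = 0.6,
    kappa_grid = 4, n_orientations = 2L, n_trials = 2L, master_seed = 14L))
  expect_false(identical(r1$icvf_est, r3$icvf_est))
})

test_that("aggregation pools exactly as the grouping asks", {
  res <- synthetic_results()
  agg <- aggregate_results(res, group_by = "icvf_true")
  expect_equal(nrow(agg), 2 * 2)  # protocols x icvf levels
  one <- res %>% dplyr::filter(protocol == "A", icvf_true == 0.5)
  got <- agg %>% dplyr::filter(protocol == "A", icvf_true == 0.5)
  expect_equal(got$icvf_est_mean, mean(one$icvf_est))
  expect_equal(got$icvf_est_sd, sd(one$icvf_est))
  expect_equal(got$n, nrow(one))

  # grouping by all keys leaves variation over trials only
  all_keys <- c("icvf_true", "kappa_true", "orientation_id")
  agg2 <- aggregate_results(res, group_by = all_keys)
  expect_true(all(agg2$n == 3))

  # single record: mean = value, sd = 0
  agg3 <- aggregate_results(res[1, ], group_by = all_keys)
  expect_equal(agg3$icvf_est_mean, res$icvf_est[1])
  expect_equal(agg3$icvf_est_sd, 0)

  expect_error(aggregate_results(res, group_by = "nope"), "unknown grouping")
  expect_error(aggregate_results(res[0, ]), "empty")
})

test_that("scheme comparison is an honest paired test", {
  res <- synthetic_results(shift = 0)
  self <- compare_schemes(res, "A", "B", metric = "icvf_est", snr = 20)
  expect_equal(self$mean_diff, 0)
  expect_equal(self$p_value, 1)

  shifted <- synthetic_results(shift = 0.1)
  cmp <- compare_schemes(shifted, "A", "B", metric = "icvf_est", snr = 20)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$mean_diff, -0.1, tolerance = 1e-12)

  # oracle: a noisy shift detected identically by stats::t.test
  noisy_shift <- synthetic_results(shift = 0.1)
  noisy_shift$icvf_est <- noisy_shift$icvf_est +
    rep(c(0, 0.01), each = nrow(noisy_shift) / 2) *
      rep(c(-1, 1), length.out = nrow(noisy_shift))
  a <- noisy_shift[noisy_shift$protocol == "A", ]
  b <- noisy_shift[noisy_shift$protocol == "B", ]
  keys <- c("icvf_true", "kappa_true", "orientation_id", "trial")
  m <- merge(a, b, by = keys)
  ref <- stats::t.test(m$icvf_est.x - m$icvf_est.y)
  got <- compare_schemes(noisy_shift, "A", "B", metric = "icvf_est", snr = 20)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  wil <- compare_schemes(shifted, "A", "B", metric = "icvf_est", snr = 20,
                         method = "wilcoxon")
  expect_lt(wil$p_value, 0.001)

  expect_error(compare_schemes(res, "A", "C", metric = "icvf_est", snr = 20),
               "present")
  expect_error(
    compare_schemes(dplyr::bind_rows(res, res[1, ]), "A", "B",
                    metric = "icvf_est", snr = 20), "1:1")
})

test_that("the packaged white-matter reference table matches the source", {
  tab <- load_roi_reference()
  expect_equal(nrow(tab), 48)
  expect_equal(ncol(tab), 17)   # roi + 8 metrics x (mean, std)
  expect_equal(load_roi_reference("GCC")$icvf_mean, 0.722)
  expect_equal(load_roi_reference("SCC")$odi_mean, 0.122)
  expect_equal(load_roi_reference("ACR-L")$da_mean, 840)
  expect_equal(load_roi_reference("Fx")$fiso_mean, 0.622)
  expect_equal(load_roi_reference("UNC-R")$fa_std, 0.055)
  expect_error(load_roi_reference("NOPE"), "Valid labels")
})

test_that("summary figures render one file per SNR, deterministically", {
  res <- dplyr::bind_rows(synthetic_results(snr = 20),
                          synthetic_results(snr = 30))
  dir <- file.path(tempdir(), "figs_test")
  files <- render_summary_figures(res, dir)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  files2 <- render_summary_figures(res, dir)
  expect_identical(files, files2)
  expect_error(render_summary_figures(res[0, ], dir), "protocol")
  p <- plot_recovery_summary(res, 20)
  expect_s3_class(p, "ggplot")
})

test_that("aggregated means are robust to rotating the orientation design", {
  cfg <- experiment_config(protocols = "NODDI-p14", snr_levels = 20,
                           icvf_grid = 0.7, kappa_grid = 4,
                           n_orientations = 6L, n_trials = 2L,
                           master_seed = 5L)
  r1 <- run_experiment(cfg)
  # same run with a different orientation design (different master seed only
  # affects orientations and noise draws)
  cfg2 <- cfg
  cfg2$master_seed <- 6L
  r2 <- run_experiment(cfg2)
  expect_lt(abs(mean(r1$icvf_est) - mean(r2$icvf_est)), 0.1)
})
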