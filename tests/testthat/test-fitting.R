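test_that("the initial guess recovers direction and flags degeneracies", {
  mu <- unit3(c(0.3, -0.5, 0.81))
  sig <- synthesize_signal(build_protocol("p12345"),
                           tissue_params(1, 1e8, 0, mu = mu))
  guess <- initial_guess(sig)
  angle <- acos(min(abs(sum(guess$mu * mu)), 1)) * 180 / pi
  expect_lt(angle, 3)

  # pure free water: the coarse grid picks its largest f_iso level
  sigw <- synthesize_signal(build_protocol("p12345"),
                            tissue_params(0.5, 1, 1))
  gw <- initial_guess(sigw)
  expect_equal(gw$f_iso, 0.9)

  # the grid argmin never loses to an evaluated grid point
  sig2 <- synthesize_signal(build_protocol("NODDI-p14"),
                            tissue_params(0.6, 4, 0.1, mu = mu))
  g2 <- initial_guess(sig2)
  obj0 <- noddi_objective(sig2, tissue_params(g2$f_ic, g2$kappa, g2$f_iso,
                                              mu = g2$mu))
  for (pt in list(c(0.1, 0.25, 0.2), c(0.85, 16, 0.01), c(0.35, 1, 0.5))) {
    obj <- noddi_objective(sig2, tissue_params(pt[1], pt[2], pt[3],
                                               mu = g2$mu))
    expect_lte(obj0, obj + 1e-6)
  }

  # degenerate inputs
  b0only <- tibble::tibble(shell = 0L, b = c(0, 0), gx = 0, gy = 0, gz = 0,
                           signal = 1)
  expect_error(initial_guess(b0only), "distinct b-values")
  few <- synthesize_signal(build_protocol("p12"), tissue_params(0.5, 1))[1:6, ]
  expect_error(initial_guess(few), "7 measurements")
})

test_that("noise-free fits reach the ground truth on both protocol families", {
  mu <- unit3(c(0.2, 0.6, 0.77))
  for (proto in c("p12345", "NODDI-p14")) {
    sig <- synthesize_signal(build_protocol(proto),
                             tissue_params(0.8, 4, 0, mu = mu))
    fit <- fit_noddi(sig)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$f_ic - 0.8), 0.01)
    expect_lt(abs(fit$params$f_iso), 0.01)
    expect_equal(fit$odi, odi_from_kappa(fit$params$kappa))
    # no worse-than-truth optimum on noise-free input
    obj_truth <- noddi_objective(sig, tissue_params(0.8, 4, 0, mu = mu))
    expect_gte(obj_truth, fit$objective_value - 1e-9)
  }
})

test_that("pure free water fits to FISO ~ 1", {
  sig <- synthesize_signal(build_protocol("p12345"), tissue_params(0.5, 1, 1))
  fit <- fit_noddi(sig)
  expect_gte(fit$params$f_iso, 0.99)
})

test_that("the objective is antipodally symmetric in the fiber direction", {
  sig <- synthesize_signal(build_protocol("p123"),
                           tissue_params(0.6, 2, 0.1, mu = unit3(c(1, 2, 3))))
  fit <- fit_noddi(sig)
  p <- fit$params
  o1 <- noddi_objective(sig, tissue_params(p$f_ic, p$kappa, p$f_iso, mu = p$mu))
  o2 <- noddi_objective(sig, tissue_params(p$f_ic, p$kappa, p$f_iso, mu = -p$mu))
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("refitting a fit's own synthesized signal is a fixed point", {
  sig <- synthesize_signal(build_protocol("p1234"),
                           tissue_params(0.55, 3, 0.05, mu = unit3(c(1, -1, 2))))
  noisy <- add_rician_noise(sig, 30, seed = 21)
  fit1 <- fit_noddi(noisy)
  resynth <- synthesize_signal(build_protocol("p1234"), fit1$params)
  fit2 <- fit_noddi(resynth)
  expect_lt(abs(fit2$params$f_ic - fit1$params$f_ic), 1e-3)
  expect_lt(abs(fit2$params$f_iso - fit1$params$f_iso), 1e-3)
  expect_lt(abs(fit2$odi - fit1$odi), 1e-3)
})

test_that("the Rician likelihood objective fits noisy data", {
  mu <- unit3(c(0.5, 0.5, 0.7))
  sig <- synthesize_signal(build_protocol("p12345"),
                           tissue_params(0.7, 4, 0, mu = mu))
  noisy <- add_rician_noise(sig, 25, seed = 77)
  fit <- fit_noddi(noisy, fit_options(objective = "rician-likelihood",
                                      snr_b0 = 25))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$f_ic - 0.7), 0.15)
  expect_error(fit_options(objective = "rician-likelihood"), "snr_b0")
})

test_that("tidy and glance expose the fit in broom form", {
  sig <- synthesize_signal(build_protocol("p12"), tissue_params(0.6, 4))
  fit <- fit_noddi(sig)
  td <- tidy(fit)
  expect_equal(td$term[1:4], c("icvf", "kappa", "odi", "fiso"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_gt(gl$n_evals, 0)
})
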