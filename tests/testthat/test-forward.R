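test_that("limit cases of the three-compartment signal are exact", {
  sch <- hydi_shells()
  # b = 0 always gives 1
  sig <- synthesize_signal(sch, tissue_params(0.5, 2, 0.3, mu = c(0, 0, 1)))
  expect_equal(sig$signal[sig$b == 0], 1)
  expect_true(all(sig$signal > 0 & sig$signal <= 1))

  # pure free water: closed-form mono-exponential
  sig <- synthesize_signal(sch, tissue_params(0.5, 2, 1))
  expect_equal(sig$signal[sig$b == 3375][1], exp(-3375 * 3.0e-3),
               tolerance = 1e-12)

  # delta-dispersion stick: perpendicular gradient leaves the signal at 1
  mu <- c(0, 0, 1)
  g <- c(1, 0, 0)
  sch2 <- tibble::tibble(shell = c(0L, 1L, 1L), b = c(0, 3375, 3375),
                         gx = c(0, g[1], mu[1]), gy = c(0, g[2], mu[2]),
                         gz = c(0, g[3], mu[3]))
  sig <- synthesize_signal(sch2, tissue_params(1, 1e8, 0, mu = mu))
  expect_equal(sig$signal[2], 1, tolerance = 1e-4)
  expect_equal(sig$signal[3], exp(-3375 * 1.7e-3), tolerance = 1e-4)
})

test_that("rotating fibers and gradients together leaves signals unchanged", {
  set.seed(11)
  sch <- build_protocol("p1234")
  for (i in 1:3) {
    R <- random_rotation()
    mu <- random_unit()
    tis <- tissue_params(0.6, 3, 0.1, mu = mu)
    tis_rot <- tissue_params(0.6, 3, 0.1, mu = as.vector(R %*% mu))
    s1 <- synthesize_signal(sch, tis)$signal
    s2 <- synthesize_signal(rotate_scheme(sch, R), tis_rot)$signal
    expect_equal(s1, s2, tolerance = 1e-10)
  }
})

test_that("signal decays with b and is a convex combination of compartments", {
  set.seed(12)
  mu <- random_unit()
  g <- random_unit()
  bs <- c(0, 375, 1500, 3375, 6000, 9375)
  sch <- tibble::tibble(shell = seq_along(bs) - 1L, b = bs,
                        gx = ifelse(bs == 0, 0, g[1]),
                        gy = ifelse(bs == 0, 0, g[2]),
                        gz = ifelse(bs == 0, 0, g[3]))
  tis <- tissue_params(0.4, 2, 0.2, mu = mu)
  E <- synthesize_signal(sch, tis)$signal
  expect_true(all(diff(E) <= 1e-12))

  # compartment bounds: E_iso, E_ic (f_ic = 1), E_ec (tortuosity of f_ic)
  E_iso <- exp(-bs * 3.0e-3)
  E_ic <- synthesize_signal(sch, tissue_params(1, 2, 0, mu = mu))$signal
  tau1 <- watson_tau1(2)
  d_par <- 1.7e-3
  d_perp <- d_par * (1 - 0.4)
  c2 <- sum(g * mu)^2
  gDg <- d_perp + (d_par - d_perp) * ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * c2)
  E_ec <- exp(-bs * gDg)
  E_ec[bs == 0] <- 1
  lo <- pmin(E_iso, E_ic, E_ec)
  hi <- pmax(E_iso, E_ic, E_ec)
  expect_true(all(E >= lo - 1e-10 & E <= hi + 1e-10))
})

test_that("kappa = 0 gives an isotropic orientation average", {
  set.seed(13)
  sch <- build_protocol("p123")
  s1 <- synthesize_signal(sch, tissue_params(0.7, 0, 0, mu = random_unit()))
  s2 <- synthesize_signal(sch, tissue_params(0.7, 0, 0, mu = random_unit()))
  expect_equal(s1$signal, s2$signal, tolerance = 1e-10)
  # matches the closed-form isotropic stick average sqrt(pi/(4 tau)) erf(sqrt(tau))
  b <- 1500
  tau <- b * 1.7e-3
  E_ic <- sqrt(pi / (4 * tau)) * pracma::erf(sqrt(tau))
  md <- (1.7e-3 + 2 * 1.7e-3 * 0.3) / 3   # mean diffusivity, tortuosity d_perp
  expected <- 0.7 * E_ic + 0.3 * exp(-b * md)
  expect_equal(s1$signal[s1$b == 1500][1], expected, tolerance = 1e-8)
})

test_that("fast signal agrees with the quadrature oracle on random cases", {
  set.seed(14)
  for (i in 1:25) {
    tis <- tissue_params(runif(1), runif(1, 0, 20), runif(1, 0, 0.5),
                         mu = random_unit())
    b <- sample(c(375, 1500, 3375, 6000, 9375), 1)
    g <- random_unit()
    sch <- tibble::tibble(shell = 1L, b = b, gx = g[1], gy = g[2], gz = g[3])
    fast <- synthesize_signal(sch, tis)$signal
    slow <- quadrature_signal_oracle(tis, b, g, grid_order = 150)
    expect_equal(fast, slow, tolerance = 1e-6)
  }
})

test_that("invalid tissue parameters are rejected", {
  expect_error(tissue_params(1.2, 1), "f_ic")
  expect_error(tissue_params(0.5, -1), "kappa")
  expect_error(tissue_params(0.5, 1, 2), "f_iso")
  expect_error(tissue_params(0.5, 1, 0, mu = c(0, 0, 0)), "mu")
})

test_that("signal CSV round trip preserves the table", {
  sig <- synthesize_signal(build_protocol("p12"), tissue_params(0.6, 4))
  path <- file.path(tempdir(), "sig.csv")
  write_signal_csv(sig, path)
  back <- read_signal_csv(path)
  expect_equal(back$signal, sig$signal, tolerance = 1e-12)
  expect_equal(back$b, sig$b)
})
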