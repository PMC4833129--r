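# NODDI parameter estimation.
#
# The scalar parameters are optimized on an unconstrained scale --
# logit(f_ic), logit(kappa / kappa_max), logit(f_iso) -- so the box bounds
# hold by construction, and the fiber direction through spherical angles
# (theta, phi).  Gaussian least squares runs through Levenberg-Marquardt
# (minpack.lm); the Rician likelihood objective through BFGS.
# d_par and d_iso stay fixed at their defaults throughout.

#' Fitting options
#'
#' @param objective `"least-squares"` (default) or `"rician-likelihood"`.
#'   The least-squares objective is the sum of squared signal residuals; the
#'   Rician objective is the negative log-likelihood of the observed
#'   magnitudes and requires `snr_b0`.
#' @param n_starts Multi-start count: the deterministic initial guess plus
#'   `n_starts - 1` seeded perturbations of it.
#' @param max_iter Iteration budget per start.
#' @param kappa_max Upper bound on kappa (default 64, i.e. ODI about 0.01;
#'   generously beyond the dispersion range of white matter).
#' @param snr_b0 b0-referenced SNR fixing the Rician noise level; only used
#'   by the Rician objective.
#' @param seed Integer seed for the restart perturbations.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(objective = c("least-squares", "rician-likelihood"),
                        n_starts = 2L, max_iter = 100L, kappa_max = 64,
                        snr_b0 = NULL, seed = 1L) {
  objective <- arg_match(objective)
  if (objective == "rician-likelihood" &&
      (is.null(snr_b0) || !is.finite(snr_b0) || snr_b0 <= 0)) {
    abort("the Rician objective needs a finite positive `snr_b0`.")
  }
  structure(list(objective = objective, n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), kappa_max = kappa_max,
                 snr_b0 = snr_b0, seed = as.integer(seed)),
            class = "fit_options")
}

# parameter transform helpers -------------------------------------------------

mu_from_angles <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

pack_params <- function(f_ic, kappa, f_iso, mu, kappa_max) {
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  c(qlogis(clamp(f_ic)), qlogis(clamp(kappa / kappa_max)),
    qlogis(clamp(f_iso)), acos(pmin(pmax(mu[3], -1), 1)),
    atan2(mu[2], mu[1]))
}

unpack_params <- function(p, kappa_max) {
  list(f_ic = plogis(p[1]), kappa = kappa_max * plogis(p[2]),
       f_iso = plogis(p[3]), mu = mu_from_angles(p[4], p[5]))
}

# Per-fit precomputation: stick kernels per unique b, row indices, and a
# small cache.  The optimizer's numerical Jacobian perturbs one parameter
# at a time, so the kappa-dependent Watson coefficients and the
# direction-dependent Legendre table are memoized on their inputs and
# reused across most objective evaluations.  The fitting path truncates
# the series at .LMAX_FIT (tail < 3e-8 over the schemes' b range).
fit_context <- function(b, G) {
  ub <- sort(unique(b[b > 0]))
  ctx <- new.env(parent = emptyenv())
  ctx$b <- b
  ctx$G <- G
  ctx$ub <- ub
  ctx$idx <- lapply(ub, function(bb) which(b == bb))
  ctx$KL <- vapply(ub, function(bb) {
    stick_legendre_coefs(bb * 1.7e-3)[1:(.LMAX_FIT + 1)]
  }, numeric(.LMAX_FIT + 1))
  ctx$ell <- 0:.LMAX_FIT
  ctx$kappa_key <- NA_real_
  ctx$mu_key <- c(NA_real_, NA_real_)
  ctx
}

ctx_watson <- function(ctx, kappa) {
  if (!identical(kappa, ctx$kappa_key)) {
    ctx$wl <- watson_legendre_coefs(kappa)[1:(.LMAX_FIT + 1)]
    ctx$tau1 <- watson_tau1(kappa)
    ctx$kappa_key <- kappa
  }
}

ctx_direction <- function(ctx, theta, phi) {
  key <- c(theta, phi)
  if (!identical(key, ctx$mu_key)) {
    mu <- mu_from_angles(theta, phi)
    cb <- as.vector(ctx$G %*% mu)
    ctx$P <- legendre_table(cb, .LMAX_FIT)
    ctx$cb <- cb
    ctx$mu_key <- key
  }
}

# model prediction for unconstrained params within a context (kappa > 0
# guaranteed by the transform, so the generic series path applies)
predict_signal_ctx <- function(p, ctx, kappa_max, d_par = 1.7e-3,
                               d_iso = 3.0e-3) {
  th <- unpack_params(p, kappa_max)
  ctx_watson(ctx, th$kappa)
  ctx_direction(ctx, p[4], p[5])
  tau1 <- ctx$tau1
  d_perp <- d_par * (1 - th$f_ic)
  E <- rep(1, length(ctx$b))
  for (k in seq_along(ctx$ub)) {
    bb <- ctx$ub[k]
    id <- ctx$idx[[k]]
    cb <- ctx$cb[id]
    coef <- (2 * ctx$ell + 1) / (4 * pi) * ctx$KL[, k] * ctx$wl
    E_ic <- as.vector(ctx$P[id, , drop = FALSE] %*% coef)
    gDg <- d_perp +
      (d_par - d_perp) * ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * cb^2)
    E[id] <- (1 - th$f_iso) * (th$f_ic * E_ic + (1 - th$f_ic) * exp(-bb * gDg)) +
      th$f_iso * exp(-bb * d_iso)
  }
  E
}

# Rician negative log-likelihood of observed magnitudes y given model E
rician_nll <- function(E, y, sigma) {
  z <- y * E / sigma^2
  logI0 <- log(besselI(z, 0, expon.scaled = TRUE)) + z
  -sum(log(pmax(y, 1e-12) / sigma^2) - (y^2 + E^2) / (2 * sigma^2) + logI0)
}

#' Evaluate the data-fit objective at given tissue parameters
#'
#' Computes the objective that [fit_noddi()] minimizes -- the residual sum
#' of squares, or the Rician negative log-likelihood -- at an arbitrary
#' tissue state.  Useful for auditing fits (e.g. checking that the optimum
#' is no worse than the ground truth on noise-free data).
#'
#' @param signal A signal tibble with columns `b`, `gx`, `gy`, `gz`,
#'   `signal`.
#' @param tissue A [tissue_params()] object.
#' @param options A [fit_options()] object selecting the objective.
#' @return A single number (lower is better for both objectives).
#' @export
noddi_objective <- function(signal, tissue, options = fit_options()) {
  validate_scheme(signal)
  E <- signal_values(signal$b, cbind(signal$gx, signal$gy, signal$gz),
                     f_ic = tissue$f_ic, kappa = tissue$kappa,
                     f_iso = tissue$f_iso, mu = tissue$mu,
                     d_par = tissue$d_par, d_iso = tissue$d_iso)
  if (options$objective == "least-squares") {
    sum((E - signal$signal)^2)
  } else {
    rician_nll(E, signal$signal, 1 / options$snr_b0)
  }
}

#' Deterministic starting point for the NODDI fit
#'
#' The fiber direction comes from the principal eigenvector of a log-linear
#' diffusion tensor fit restricted to b <= 1600 s/mm^2 (all b > 0 rows are
#' used if that subset is too small); the scalar parameters from a coarse
#' grid over (f_ic, kappa, f_iso), 4 levels each, minimizing the chosen
#' objective with the direction held fixed.
#'
#' @inheritParams noddi_objective
#' @return A [tissue_params()] object.
#' @export
initial_guess <- function(signal, options = fit_options()) {
  validate_scheme(signal, require_b0 = TRUE)
  if (length(unique(signal$b)) < 2) {
    abort("scheme must contain at least 2 distinct b-values including b = 0.")
  }
  if (sum(signal$b > 0) < 7) {
    abort("tensor initialization needs at least 7 measurements with b > 0.")
  }
  sub <- signal[signal$b > 0 & signal$b <= 1600, , drop = FALSE]
  if (nrow(sub) < 7) sub <- signal[signal$b > 0, , drop = FALSE]
  y <- log(pmax(sub$signal, 1e-6))
  X <- with(sub, cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
                       -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz))
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  mu0 <- eigen(D, symmetric = TRUE)$vectors[, 1]

  ctx <- fit_context(signal$b, cbind(signal$gx, signal$gy, signal$gz))
  # kappa slowest so the context cache is reused within each kappa block
  grid <- tidyr::expand_grid(kappa = c(0.25, 1, 4, 16),
                             f_ic = c(0.1, 0.35, 0.6, 0.85),
                             f_iso = c(0.01, 0.2, 0.5, 0.9))
  sigma <- if (is.null(options$snr_b0)) NULL else 1 / options$snr_b0
  vals <- purrr::pmap_dbl(grid, function(f_ic, kappa, f_iso) {
    p <- pack_params(f_ic, kappa, f_iso, mu0, options$kappa_max)
    E <- predict_signal_ctx(p, ctx, options$kappa_max)
    if (options$objective == "least-squares") {
      sum((E - signal$signal)^2)
    } else {
      rician_nll(E, signal$signal, sigma)
    }
  })
  best <- grid[which.min(vals), ]
  tissue_params(best$f_ic, best$kappa, best$f_iso, mu = mu0)
}

#' Fit the NODDI model to a signal set
#'
#' Bounded nonlinear minimization of the chosen objective over
#' (f_ic, kappa, f_iso, theta, phi), starting from [initial_guess()] plus
#' `n_starts - 1` seeded perturbed restarts; the lowest objective wins, ties
#' broken by earliest start.  d_par and d_iso are held fixed.  If every
#' start fails the result carries `converged = FALSE` rather than an error.
#'
#' @inheritParams noddi_objective
#' @return An object of class `noddi_fit`: estimated [tissue_params()]
#'   (`params`), the derived `odi`, `objective_value`, `converged`,
#'   `n_evals` and bookkeeping fields.  See [tidy.noddi_fit()] and
#'   [glance.noddi_fit()].
#' @examples
#' sig <- synthesize_signal(build_protocol("p12"),
#'                          tissue_params(0.6, 4, mu = c(1, 0, 0)))
#' fit <- fit_noddi(sig)
#' tidy(fit)
#' @export
fit_noddi <- function(signal, options = fit_options()) {
  start_tissue <- initial_guess(signal, options)
  ctx <- fit_context(signal$b, cbind(signal$gx, signal$gy, signal$gz))
  kmax <- options$kappa_max
  sigma <- if (is.null(options$snr_b0)) NULL else 1 / options$snr_b0
  y <- signal$signal
  evals <- new.env(parent = emptyenv())
  evals$n <- 0L

  resid_fn <- function(p) {
    evals$n <- evals$n + 1L
    predict_signal_ctx(p, ctx, kmax) - y
  }
  nll_fn <- function(p) {
    evals$n <- evals$n + 1L
    rician_nll(predict_signal_ctx(p, ctx, kmax), y, sigma)
  }

  p0 <- pack_params(start_tissue$f_ic, start_tissue$kappa,
                    start_tissue$f_iso, start_tissue$mu, kmax)
  starts <- list(p0)
  if (options$n_starts > 1) {
    perturb <- with_local_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1), function(i) {
        p0 + c(rnorm(3, sd = 0.75), rnorm(2, sd = 0.4))
      })
    })
    starts <- c(starts, perturb)
  }

  ls_stage <- function(p) {
    fit <- minpack.lm::nls.lm(
      p, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iter, ftol = 1e-10, ptol = 1e-10))
    list(par = fit$par, value = sum(fit$fvec^2), ok = fit$info %in% 1:4)
  }

  best <- NULL
  for (s in seq_along(starts)) {
    res <- tryCatch({
      if (options$objective == "least-squares") {
        ls_stage(starts[[s]])
      } else {
        # warm start: the cheap least-squares optimum is close to the
        # Rician MLE, so BFGS only has to polish it
        warm <- tryCatch(ls_stage(starts[[s]])$par,
                         error = function(e) starts[[s]])
        fit <- optim(warm, nll_fn, method = "BFGS",
                     control = list(maxit = options$max_iter))
        list(par = fit$par, value = fit$value, ok = fit$convergence == 0)
      }
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }

  if (is.null(best)) {
    best <- list(par = p0, value = NA_real_, ok = FALSE)
  }
  th <- unpack_params(best$par, kmax)
  params <- tissue_params(th$f_ic, th$kappa, th$f_iso, mu = th$mu)
  structure(
    list(params = params, odi = odi_from_kappa(params$kappa),
         objective_value = best$value, converged = isTRUE(best$ok),
         n_evals = evals$n, objective = options$objective,
         n_starts = options$n_starts,
         scheme_name = attr(signal, "scheme_name")),
    class = "noddi_fit")
}

#' @export
print.noddi_fit <- function(x, ...) {
  cat("NODDI fit (", x$objective, ")\n", sep = "")
  cat(sprintf("  ICVF = %.4f  ODI = %.4f  FISO = %.4f\n",
              x$params$f_ic, x$odi, x$params$f_iso))
  cat(sprintf("  mu = (%.3f, %.3f, %.3f)  kappa = %.3f\n",
              x$params$mu[1], x$params$mu[2], x$params$mu[3],
              x$params$kappa))
  cat(sprintf("  objective = %.6g  converged = %s  evals = %d\n",
              x$objective_value, x$converged, x$n_evals))
  invisible(x)
}

#' Tidy a NODDI fit
#'
#' `tidy()` returns one row per estimated quantity; `glance()` a one-row
#' summary of the optimization.
#'
#' @param x A `noddi_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy noddi_fit
#' @export
tidy.noddi_fit <- function(x, ...) {
  tibble(
    term = c("icvf", "kappa", "odi", "fiso", "mu_x", "mu_y", "mu_z"),
    estimate = c(x$params$f_ic, x$params$kappa, x$odi, x$params$f_iso,
                 x$params$mu))
}

#' @rdname tidy.noddi_fit
#' @method glance noddi_fit
#' @export
glance.noddi_fit <- function(x, ...) {
  tibble(objective = x$objective, objective_value = x$objective_value,
         converged = x$converged, n_evals = x$n_evals,
         n_starts = x$n_starts)
}
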