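# Three-compartment NODDI signal model.
#
# Normalized signal for a measurement (b, g):
#   E = (1 - f_iso) * [ f_ic * E_ic + (1 - f_ic) * E_ec ] + f_iso * e^{-b d_iso}
# with
#   E_ic = int W(n; mu, kappa) exp(-b d_par (g.n)^2) dn     (dispersed stick)
#   E_ec = exp(-b g' <D> g),  <D> = (d_par - d_perp) <nn'>_W + d_perp I,
#          d_perp = d_par (1 - f_ic)                         (tortuosity)
# and <nn'>_W has eigenvalue tau1 along mu, (1 - tau1)/2 perpendicular.
#
# E_ic is evaluated by a Funk-Hecke Legendre series: with w_l the Legendre
# coefficients of the Watson density about mu and khat_l those of the stick
# kernel exp(-tau t^2), tau = b d_par,
#   E_ic(g) = sum_{l even} (2l+1)/(4pi) * khat_l * w_l * P_l(g.mu).
# The truncation (l <= 60) is uniformly accurate because khat_l decays
# super-algebraically for every b in range; accuracy is asserted against a
# brute-force spherical quadrature oracle in the validation module.

#' Tissue parameters of the NODDI model
#'
#' Bundles the ground-truth or fitted parameter set: intracellular volume
#' fraction `f_ic` (ICVF, within the non-free-water tissue), Watson
#' concentration `kappa`, free-water fraction `f_iso` (FISO), fiber
#' direction `mu`, and the fixed diffusivities `d_par` (intrinsic axial,
#' default 1.7e-3 mm^2/s) and `d_iso` (free water, default 3.0e-3 mm^2/s).
#'
#' @param f_ic Intracellular volume fraction in \eqn{[0, 1]}.
#' @param kappa Watson concentration, \eqn{\ge 0}.
#' @param f_iso Free-water volume fraction in \eqn{[0, 1]}.
#' @param mu Unit 3-vector fiber direction.
#' @param d_par Intrinsic axial diffusivity, mm^2/s.
#' @param d_iso Isotropic (free-water) diffusivity, mm^2/s.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(f_ic = 0.7, kappa = 4, f_iso = 0.1)
#' @export
tissue_params <- function(f_ic, kappa, f_iso = 0, mu = c(0, 0, 1),
                          d_par = 1.7e-3, d_iso = 3.0e-3) {
  stopifnot(length(f_ic) == 1, length(kappa) == 1, length(f_iso) == 1,
            length(mu) == 3)
  if (!is.finite(f_ic) || f_ic < 0 || f_ic > 1) {
    abort("`f_ic` must lie in [0, 1].")
  }
  if (!is.finite(f_iso) || f_iso < 0 || f_iso > 1) {
    abort("`f_iso` must lie in [0, 1].")
  }
  check_kappa(kappa)
  nrm <- sqrt(sum(mu^2))
  if (abs(nrm - 1) > 1e-10) {
    if (nrm == 0) abort("`mu` must be a nonzero vector.")
    mu <- mu / nrm
  }
  structure(
    list(f_ic = f_ic, kappa = kappa, f_iso = f_iso, mu = as.numeric(mu),
         d_par = d_par, d_iso = d_iso),
    class = "tissue_params"
  )
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "NODDI tissue: ICVF=%.3f kappa=%.3g (ODI=%.3f) FISO=%.3f mu=(%.3f, %.3f, %.3f)\n",
    x$f_ic, x$kappa, odi_from_kappa(x$kappa), x$f_iso,
    x$mu[1], x$mu[2], x$mu[3]))
  invisible(x)
}

# E_ic for one tau over a vector of cos(angles to mu), given precomputed
# Watson coefficients.  Special-cased kappa = 0 uses the closed form
# int_0^1 e^{-tau t^2} dt = sqrt(pi/(4 tau)) erf(sqrt(tau)).
eic_values <- function(wl, tau, cos_beta, kappa0 = FALSE) {
  if (kappa0) {
    if (tau == 0) return(rep(1, length(cos_beta)))
    return(rep(sqrt(pi / (4 * tau)) * pracma::erf(sqrt(tau)),
               length(cos_beta)))
  }
  kl <- stick_legendre_coefs(tau)
  l <- 0:.LMAX
  coef <- (2 * l + 1) / (4 * pi) * kl * wl
  as.vector(legendre_table(cos_beta, .LMAX) %*% coef)
}

#' Synthesize noise-free NODDI signals for a scheme
#'
#' Evaluates the three-compartment model signal for every measurement of
#' `scheme` at the tissue state `tissue`.  Signals are normalized so the
#' b = 0 signal is exactly 1.
#'
#' @param scheme A scheme tibble (see [hydi_shells()], [build_protocol()]).
#' @param tissue A [tissue_params()] object.
#' @return The scheme tibble with an added `signal` column in \eqn{(0, 1]}.
#' @examples
#' sig <- synthesize_signal(build_protocol("p12"), tissue_params(0.7, 4))
#' head(sig)
#' @export
synthesize_signal <- function(scheme, tissue) {
  validate_scheme(scheme)
  if (!inherits(tissue, "tissue_params")) {
    abort("`tissue` must be a tissue_params object.")
  }
  out <- as_tibble(scheme)
  out$signal <- signal_values(
    b = scheme$b, G = cbind(scheme$gx, scheme$gy, scheme$gz),
    f_ic = tissue$f_ic, kappa = tissue$kappa, f_iso = tissue$f_iso,
    mu = tissue$mu, d_par = tissue$d_par, d_iso = tissue$d_iso)
  out
}

# vectorized core: b, G (n x 3) -> signal vector.  Exact special cases:
# b = 0 -> 1; kappa = 0 -> isotropic-dispersion closed forms; f_ic in {0,1}
# skip the absent compartment.
signal_values <- function(b, G, f_ic, kappa, f_iso, mu,
                          d_par = 1.7e-3, d_iso = 3.0e-3) {
  n <- length(b)
  E <- rep(1, n)
  dwi <- which(b > 0)
  if (!length(dwi)) return(E)
  kappa0 <- kappa == 0
  wl <- if (kappa0) NULL else watson_legendre_coefs(kappa)
  tau1 <- if (kappa0) 1 / 3 else watson_tau1(kappa)
  d_perp <- d_par * (1 - f_ic)
  cos_beta <- as.vector(G %*% mu)
  for (bb in unique(b[dwi])) {
    idx <- which(b == bb)
    cb <- cos_beta[idx]
    E_tissue <- 0
    if (f_iso < 1) {
      E_ic <- if (f_ic > 0) {
        eic_values(wl, bb * d_par, cb, kappa0 = kappa0)
      } else 0
      E_ec <- if (f_ic < 1) {
        gDg <- d_perp +
          (d_par - d_perp) * ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * cb^2)
        exp(-bb * gDg)
      } else 0
      E_tissue <- f_ic * E_ic + (1 - f_ic) * E_ec
    }
    E[idx] <- (1 - f_iso) * E_tissue + f_iso * exp(-bb * d_iso)
  }
  E
}

#' Write or read a signal set as CSV
#'
#' Serializes a signal tibble (scheme columns plus `signal`) to a plain CSV
#' with columns `measurement, b, gx, gy, gz, signal`.
#'
#' @param signal A signal tibble from [synthesize_signal()] or
#'   [add_rician_noise()].
#' @param path CSV file path.
#' @return `write_signal_csv()` returns `path` invisibly;
#'   `read_signal_csv()` returns a signal tibble.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot("signal" %in% names(signal))
  validate_scheme(signal)
  cols <- intersect(c("measurement", "shell", "b", "gx", "gy", "gz", "signal"),
                    names(signal))
  utils::write.csv(signal[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  validate_scheme(df)
  df
}
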