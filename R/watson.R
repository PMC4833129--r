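# Watson distribution machinery.
#
# The axially symmetric Watson density on the sphere,
#   W(n; mu, kappa) = exp(kappa * (mu.n)^2) / (4*pi*Z(kappa)),
# models fiber orientation dispersion.  All of its moments reduce to 1-D
# integrals of exp(kappa*t^2) over t in [0,1].  Two quadrature regimes are
# used: plain Gauss-Legendre for kappa <= 100, and a Laplace-type
# substitution u = kappa*(1 - t^2) evaluated with Gauss-Laguerre nodes for
# larger kappa, where the integrand concentrates at t = 1.

.KAPPA_GL_MAX <- 100      # switch point between quadrature regimes
.LMAX <- 60               # Legendre truncation order for signal synthesis
.LMAX_FIT <- 36           # reduced order for the fitting hot path (series
                          # tail < 3e-8 for every b in the schemes)
.N_GL <- 301              # Gauss-Legendre nodes on [0, 1]
.N_LAG <- 128             # Gauss-Laguerre nodes for the large-kappa regime

# Legendre polynomials P_0..P_lmax evaluated at x (vector) via the
# three-term recurrence; returns length(x) x (lmax + 1).
legendre_table <- function(x, lmax) {
  P <- matrix(0, length(x), lmax + 1)
  P[, 1] <- 1
  if (lmax >= 1) P[, 2] <- x
  if (lmax >= 2) {
    for (l in 1:(lmax - 1)) {
      P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
    }
  }
  P
}

# memoized quadrature tables
quad_tables <- function() {
  if (is.null(.noddisim_cache$quad)) {
    gl <- pracma::gaussLegendre(.N_GL, 0, 1)
    lag <- pracma::gaussLaguerre(.N_LAG)
    .noddisim_cache$quad <- list(
      x = gl$x, w = gl$w,
      P = legendre_table(gl$x, .LMAX),
      lag_x = lag$x, lag_w = lag$w
    )
  }
  .noddisim_cache$quad
}

check_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    abort("`kappa` must be finite and >= 0.")
  }
}

#' Watson normalization constant
#'
#' Spherical mean of the unnormalized Watson density,
#' \eqn{Z(\kappa) = \frac{1}{4\pi}\int_{S^2} e^{\kappa (\mu\cdot n)^2}\,dn
#' = \int_0^1 e^{\kappa t^2}\,dt}, so that
#' \eqn{W(n) = e^{\kappa(\mu\cdot n)^2} / (4\pi Z)} integrates to one.
#'
#' @param kappa Watson concentration parameter(s), \eqn{\kappa \ge 0}.
#'   Values above ~709 overflow the double range and return `Inf`.
#' @return Numeric vector of \eqn{Z(\kappa)}, same length as `kappa`.
#' @examples
#' watson_normalization(0)   # 1: uniform density
#' watson_normalization(4)
#' @export
watson_normalization <- function(kappa) {
  check_kappa(kappa)
  q <- quad_tables()
  vapply(kappa, function(k) {
    if (k <= .KAPPA_GL_MAX) {
      sum(exp(k * q$x^2) * q$w)
    } else {
      # Z = e^k * int_0^k e^{-u} / (2k sqrt(1 - u/k)) du
      keep <- q$lag_x < k * (1 - 1e-12)
      t <- sqrt(1 - q$lag_x[keep] / k)
      exp(k) * sum(q$lag_w[keep] / (2 * k * t))
    }
  }, numeric(1))
}

#' Mean-squared alignment of the Watson distribution
#'
#' \eqn{\tau_1(\kappa) = \int (\mu\cdot n)^2\, W(n;\mu,\kappa)\, dn}, the
#' second moment of the orientation distribution along its mean axis.
#' Equals 1/3 for the uniform distribution (\eqn{\kappa = 0}) and tends to 1
#' as dispersion vanishes; strictly increasing in \eqn{\kappa}.  It sets the
#' eigenvalues of the dispersed extracellular diffusion tensor.
#'
#' @inheritParams watson_normalization
#' @return Numeric vector in \eqn{[1/3, 1)}.
#' @examples
#' watson_tau1(0)    # 1/3
#' watson_tau1(16)
#' @export
watson_tau1 <- function(kappa) {
  check_kappa(kappa)
  q <- quad_tables()
  vapply(kappa, function(k) {
    if (k <= .KAPPA_GL_MAX) {
      f <- exp(k * (q$x^2 - 1)) * q$w
      sum(q$x^2 * f) / sum(f)
    } else {
      # substitution u = kappa (1 - t^2):
      # tau1 = int e^{-u} t du / int e^{-u} / t du
      keep <- q$lag_x < k * (1 - 1e-12)
      t <- sqrt(1 - q$lag_x[keep] / k)
      sum(q$lag_w[keep] * t) / sum(q$lag_w[keep] / t)
    }
  }, numeric(1))
}

#' Orientation dispersion index from the Watson concentration
#'
#' The standard monotone reparameterization
#' \eqn{\mathrm{ODI} = (2/\pi)\arctan(1/\kappa)}: 0 means perfectly parallel
#' fibers, 1 (the \eqn{\kappa = 0} limit) isotropic dispersion.
#'
#' @inheritParams watson_normalization
#' @return ODI values in \eqn{(0, 1]}.
#' @seealso [kappa_from_odi()] for the inverse map.
#' @examples
#' odi_from_kappa(1)   # 0.5
#' odi_from_kappa(0)   # 1, by the limit convention
#' @export
odi_from_kappa <- function(kappa) {
  check_kappa(kappa)
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' @rdname odi_from_kappa
#' @param odi Orientation dispersion index values in \eqn{(0, 1]}.
#' @export
kappa_from_odi <- function(odi) {
  if (any(!is.finite(odi)) || any(odi <= 0) || any(odi > 1)) {
    abort("`odi` must lie in (0, 1].")
  }
  ifelse(odi == 1, 0, 1 / tan(pi * odi / 2))
}

# Legendre coefficients of the normalized Watson density:
#   w_l = int W(n) P_l(mu.n) dn
#       = int_{-1}^{1} e^{kappa t^2} P_l(t) dt / int_{-1}^{1} e^{kappa t^2} dt,
# even l only (odd vanish by antipodal symmetry).  Vector of length .LMAX+1
# with zeros at odd l.  Valid for all kappa >= 0 (Laguerre regime above
# .KAPPA_GL_MAX).
watson_legendre_coefs <- function(kappa) {
  q <- quad_tables()
  if (kappa <= .KAPPA_GL_MAX) {
    f <- exp(kappa * (q$x^2 - 1)) * q$w
    raw <- as.vector(crossprod(q$P, f))
  } else {
    keep <- q$lag_x < kappa * (1 - 1e-12)
    t <- sqrt(1 - q$lag_x[keep] / kappa)
    wt <- q$lag_w[keep] / t
    raw <- as.vector(crossprod(legendre_table(t, .LMAX), wt))
  }
  out <- raw / raw[1]
  out[seq(2, .LMAX + 1, by = 2)] <- 0
  out
}

# Funk-Hecke coefficients of the stick kernel K(t) = exp(-tau t^2):
#   khat_l = 2*pi*int_{-1}^{1} e^{-tau t^2} P_l(t) dt, even l only.
stick_legendre_coefs <- function(tau) {
  q <- quad_tables()
  f <- exp(-tau * q$x^2) * q$w
  out <- 4 * pi * as.vector(crossprod(q$P, f))
  out[seq(2, .LMAX + 1, by = 2)] <- 0
  out
}
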