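# Rician noise at a b0-referenced SNR.
#
# Magnitude MRI noise: a complex Gaussian perturbation of the true signal,
# reported as magnitude.  With S0 normalized to 1, the channel noise level
# is sigma = 1 / SNR_b0.

#' Add Rician noise to a signal set
#'
#' Each noise-free value \eqn{S} is replaced by
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}} with \eqn{n_1, n_2} independent
#' zero-mean Gaussian draws of standard deviation \eqn{\sigma = 1 /
#' \mathrm{SNR}_{b0}}.  The b = 0 measurement is noised like any other.
#' `snr_b0 = Inf` returns the input unchanged.  Deterministic given `seed`.
#'
#' @param signal A signal tibble (scheme columns plus `signal`).
#' @param snr_b0 Signal-to-noise ratio defined at b = 0 (positive, possibly
#'   `Inf`).
#' @param seed Integer seed for the noise draws.
#' @return The tibble with `signal` replaced by its noisy magnitude.
#' @examples
#' sig <- synthesize_signal(build_protocol("p12"), tissue_params(0.7, 4))
#' noisy <- add_rician_noise(sig, snr_b0 = 20, seed = 1)
#' @export
add_rician_noise <- function(signal, snr_b0, seed = 1L) {
  stopifnot("signal" %in% names(signal))
  if (!is.numeric(snr_b0) || length(snr_b0) != 1 || is.na(snr_b0) ||
      snr_b0 <= 0) {
    abort("`snr_b0` must be a single positive number (possibly Inf).")
  }
  if (any(signal$signal < 0)) abort("signal values must be >= 0.")
  if (is.infinite(snr_b0)) return(signal)
  sigma <- 1 / snr_b0
  n <- nrow(signal)
  noise <- with_local_seed(seed, {
    matrix(rnorm(2L * n, sd = sigma), ncol = 2)
  })
  out <- signal
  out$signal <- sqrt((signal$signal + noise[, 1])^2 + noise[, 2]^2)
  out
}

#' Effective per-shell SNR of a protocol
#'
#' The per-direction SNR of a diffusion-weighted measurement is its
#' noise-free signal divided by the channel noise level
#' \eqn{\sigma = 1/\mathrm{SNR}_{b0}}.  For each shell of `scheme` this
#' reports the mean and standard deviation of that ratio pooled with equal
#' weight over all directions in the shell, all rows of the ground-truth
#' `grid`, and all fiber `orientations` — the attenuated-shell counterpart
#' of the nominal b0 SNR.
#'
#' @param scheme A scheme tibble.
#' @param snr_b0 SNR at b = 0 (finite, positive).
#' @param grid Tibble of tissue conditions with columns `f_ic`, `kappa` and
#'   optionally `f_iso` (default 0); defaults to [default_tissue_grid()].
#' @param orientations Matrix/tibble of unit fiber directions (columns
#'   `gx`,`gy`,`gz` or a 3-column matrix), or a single count passed to
#'   [uniform_sphere_directions()] (default 250).
#' @param orientation_seed Seed used when `orientations` is a count.
#' @return A tibble with one row per shell: `shell`, `b`, `n_dir`,
#'   `snr_mean`, `snr_sd`.
#' @examples
#' shell_snr_report(build_protocol("p12"), snr_b0 = 20,
#'                  grid = default_tissue_grid(), orientations = 20)
#' @export
shell_snr_report <- function(scheme, snr_b0, grid = default_tissue_grid(),
                             orientations = 250, orientation_seed = 101L) {
  validate_scheme(scheme)
  if (!is.numeric(snr_b0) || length(snr_b0) != 1 || !is.finite(snr_b0) ||
      snr_b0 <= 0) {
    abort("`snr_b0` must be a single finite positive number.")
  }
  if (is.null(grid) || nrow(grid) == 0) abort("`grid` must be nonempty.")
  if (!"f_iso" %in% names(grid)) grid$f_iso <- 0
  if (length(orientations) == 1 && is.numeric(orientations)) {
    orientations <- uniform_sphere_directions(orientations,
                                              seed = orientation_seed)
  }
  MU <- as.matrix(as.data.frame(orientations))
  storage.mode(MU) <- "double"
  sigma <- 1 / snr_b0
  b <- scheme$b
  G <- cbind(scheme$gx, scheme$gy, scheme$gz)

  per_condition <- purrr::pmap(grid, function(f_ic, kappa, f_iso, ...) {
    vapply(seq_len(nrow(MU)), function(j) {
      signal_values(b, G, f_ic = f_ic, kappa = kappa, f_iso = f_iso,
                    mu = MU[j, ])
    }, numeric(length(b)))   # length(b) x n_orient
  })
  # pool: per shell, over directions x conditions x orientations
  shells <- sort(unique(scheme$shell))
  purrr::map_dfr(shells, function(s) {
    idx <- which(scheme$shell == s)
    vals <- unlist(lapply(per_condition, function(M) M[idx, , drop = FALSE]))
    snr <- vals / sigma
    tibble(shell = s, b = b[idx][1], n_dir = length(idx),
           snr_mean = mean(snr), snr_sd = stats::sd(snr))
  })
}

#' Ground-truth tissue grid of the simulation design
#'
#' The factorial grid used throughout the simulation study:
#' ICVF in \{0.2, 0.4, 0.5, 0.8\}, kappa in \{0, 0.25, 1, 4, 16\}, and
#' FISO = 0, values representative of the white-matter reference table
#' shipped with the package.
#'
#' @param icvf,kappa,f_iso Grid levels; defaults are the study design.
#' @return A tibble with columns `f_ic`, `kappa`, `f_iso`, one row per
#'   combination.
#' @examples
#' default_tissue_grid()   # 20 conditions
#' @export
default_tissue_grid <- function(icvf = c(0.2, 0.4, 0.5, 0.8),
                                kappa = c(0, 0.25, 1, 4, 16),
                                f_iso = 0) {
  tidyr::expand_grid(f_ic = icvf, kappa = kappa, f_iso = f_iso)
}
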