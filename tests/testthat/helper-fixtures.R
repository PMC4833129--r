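# shared helpers for the test suite

unit3 <- function(v) v / sqrt(sum(v^2))

# seeded random unit vector
random_unit <- function() unit3(rnorm(3))

# seeded random rotation matrix (QR of a random Gaussian matrix, det +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rotate the gradient table of a scheme tibble
rotate_scheme <- function(scheme, R) {
  G <- as.matrix(scheme[, c("gx", "gy", "gz")]) %*% t(R)
  scheme$gx <- G[, 1]
  scheme$gy <- G[, 2]
  scheme$gz <- G[, 3]
  scheme
}

# small hand-built results table for aggregation / comparison tests:
# two protocols, identical estimates except an optional shift on protocol b
synthetic_results <- function(shift = 0, n_orient = 4, n_trial = 3,
                              snr = 20, seed = 42) {
  base <- tidyr::expand_grid(
    icvf_true = c(0.5, 0.8), kappa_true = c(1, 4),
    orientation_id = seq_len(n_orient), trial = seq_len(n_trial))
  set.seed(seed)
  base$est <- 0.6 + 0.05 * rnorm(nrow(base))
  dplyr::bind_rows(
    dplyr::mutate(base, protocol = "A"),
    dplyr::mutate(base, protocol = "B", est = est + shift)
  ) %>%
    dplyr::mutate(snr = snr, odi_true = odi_from_kappa(kappa_true),
                  icvf_est = est, odi_est = est / 2, fiso_est = 0.05,
                  converged = TRUE) %>%
    dplyr::select(-est)
}
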