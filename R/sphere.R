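# Quasi-uniform point sets on the unit sphere.

# run expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Quasi-uniformly distributed unit vectors
#'
#' Generates `n` unit 3-vectors spread quasi-uniformly over the sphere by
#' electrostatic-repulsion optimization: starting from a seeded random
#' configuration, projected gradient descent minimizes the antipodally
#' symmetric Coulomb energy \eqn{\sum_{i<j} 1/(1 - (v_i\cdot v_j)^2)}, which
#' penalizes close pairs and close antipodal pairs alike.  Used both for
#' per-shell gradient direction tables and for fiber-orientation designs.
#'
#' @param n Number of directions, \eqn{\ge 1}.
#' @param seed Integer seed; the result is deterministic given `(n, seed)`.
#' @param n_iter Gradient-descent iterations (default 400 is ample for
#'   \eqn{n \le 250}).
#' @return A tibble with columns `gx`, `gy`, `gz`; each row a unit vector.
#' @examples
#' v <- uniform_sphere_directions(50, seed = 7)
#' range(sqrt(v$gx^2 + v$gy^2 + v$gz^2))
#' @export
uniform_sphere_directions <- function(n, seed = 1L, n_iter = 400L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  n <- as.integer(n)
  V <- with_local_seed(seed, {
    matrix(rnorm(3L * n), ncol = 3)
  })
  V <- V / sqrt(rowSums(V^2))
  if (n > 1) V <- repel_on_sphere(V, n_iter)
  tibble(gx = V[, 1], gy = V[, 2], gz = V[, 3])
}

# projected gradient descent on E = sum_{i<j} 1/(1 - c_ij^2), c = V V^T,
# with backtracking step control; deterministic.
repel_on_sphere <- function(V, n_iter) {
  n <- nrow(V)
  energy <- function(V) {
    C <- tcrossprod(V)
    diag(C) <- 0
    sum(1 / (1 - C^2)) / 2 - n / 2
  }
  step <- 0.1 / n
  e <- energy(V)
  for (it in seq_len(n_iter)) {
    C <- tcrossprod(V)
    diag(C) <- 0
    W <- 2 * C / (1 - C^2)^2     # dE/dc per pair
    G <- W %*% V                 # gradient wrt rows of V
    # project out radial component, descend, renormalize
    G <- G - V * rowSums(G * V)
    V2 <- V - step * G
    V2 <- V2 / sqrt(rowSums(V2^2))
    e2 <- energy(V2)
    if (e2 < e) {
      V <- V2
      e <- e2
      step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-14) break
    }
  }
  V
}

# minimum pairwise angle (radians) of a direction set, +/-v distinct
min_pairwise_angle <- function(V) {
  V <- as.matrix(V)
  C <- tcrossprod(V)
  diag(C) <- -Inf
  acos(min(max(C), 1))
}
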