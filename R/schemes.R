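# Multi-shell diffusion acquisition schemes.
#
# A scheme is a tibble with one row per measurement: columns `measurement`
# (index), `shell` (integer label, 0 for b = 0), `b` (diffusion weighting,
# s/mm^2) and `gx`, `gy`, `gz` (unit gradient direction; zero where b = 0).
# b-values are carried in s/mm^2 and diffusivities in mm^2/s so products
# b * d are dimensionless.

# shell table of the 5-shell HYDI acquisition: Ne directions per b-value
.HYDI_SHELLS <- data.frame(
  shell = 0:5,
  n_dir = c(1L, 6L, 21L, 24L, 24L, 50L),
  b     = c(0, 375, 1500, 3375, 6000, 9375)
)

.PROTOCOLS <- c("NODDI-p14", "p12", "p123", "p1234", "p12345")

new_scheme <- function(df, name) {
  df <- as_tibble(df)
  df$measurement <- seq_len(nrow(df))
  df <- df[, c("measurement", "shell", "b", "gx", "gy", "gz")]
  attr(df, "scheme_name") <- name
  class(df) <- c("noddi_scheme", class(df))
  df
}

#' @export
print.noddi_scheme <- function(x, ...) {
  nm <- attr(x, "scheme_name")
  if (!is.null(nm)) cat("<acquisition scheme: ", nm, ">\n", sep = "")
  NextMethod()
}

#' Validate an acquisition scheme table
#'
#' Checks the scheme invariants: required columns, `b >= 0`, unit gradient
#' norm wherever `b > 0`, and constant b within each shell.
#'
#' @param scheme A data frame with columns `b`, `gx`, `gy`, `gz` (and
#'   optionally `shell`, `measurement`).
#' @param require_b0 Require at least one `b = 0` measurement (needed by any
#'   protocol used for fitting).
#' @return The scheme, invisibly, or an error.
#' @export
validate_scheme <- function(scheme, require_b0 = FALSE) {
  need <- c("b", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(scheme))
  if (length(missing_cols)) {
    abort(paste0("scheme is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(scheme$b < 0)) abort("b-values must be >= 0.")
  dwi <- scheme$b > 0
  if (any(dwi)) {
    nrm <- sqrt(scheme$gx[dwi]^2 + scheme$gy[dwi]^2 + scheme$gz[dwi]^2)
    if (any(abs(nrm - 1) > 1e-10)) {
      abort("gradient directions must be unit vectors where b > 0.")
    }
  }
  if (require_b0 && !any(scheme$b == 0)) {
    abort("scheme must contain at least one b = 0 measurement.")
  }
  if ("shell" %in% names(scheme)) {
    nb <- tapply(scheme$b, scheme$shell, function(v) length(unique(v)))
    if (any(nb != 1)) abort("b-values within a shell must be identical.")
  }
  invisible(scheme)
}

#' The full five-shell HYDI acquisition scheme
#'
#' One b = 0 measurement plus shells of 6, 21, 24, 24 and 50 directions at
#' b = 375, 1500, 3375, 6000 and 9375 s/mm^2 (126 measurements in total).
#' Each shell receives its own quasi-uniform direction set from
#' [uniform_sphere_directions()], seeded per shell so the scheme is
#' deterministic.
#'
#' @param seed Base integer seed for the per-shell direction sets.
#' @return A scheme tibble (see [validate_scheme()] for the column contract).
#' @examples
#' sch <- hydi_shells()
#' nrow(sch)                 # 126
#' table(sch$b)
#' @export
hydi_shells <- function(seed = 20L) {
  rows <- purrr::pmap(.HYDI_SHELLS, function(shell, n_dir, b) {
    if (b == 0) {
      tibble(shell = shell, b = b, gx = 0, gy = 0, gz = 0)
    } else {
      dirs <- uniform_sphere_directions(n_dir, seed = seed + shell)
      tibble(shell = shell, b = b, gx = dirs$gx, gy = dirs$gy, gz = dirs$gz)
    }
  })
  new_scheme(bind_rows(rows), "p12345")
}

#' Build a named diffusion encoding protocol
#'
#' The HYDI shell-combination protocols `p12`, `p123`, `p1234`, `p12345`
#' are nested subsets of the five-shell scheme (always keeping the b = 0
#' measurement).  `NODDI-p14` is the originally proposed two-shell NODDI
#' protocol: one b = 0, 30 directions at b = 711 and 60 directions at
#' b = 2855 s/mm^2.
#'
#' @param name One of `"NODDI-p14"`, `"p12"`, `"p123"`, `"p1234"`,
#'   `"p12345"`.
#' @param seed Base seed passed to the direction generator.
#' @return A scheme tibble.
#' @examples
#' build_protocol("p12")        # 28 measurements, max b = 1500
#' build_protocol("NODDI-p14")  # 91 measurements
#' @export
build_protocol <- function(name, seed = 20L) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .PROTOCOLS)) {
    abort(paste0("unknown protocol ", deparse(name), "; valid protocols: ",
                 paste(.PROTOCOLS, collapse = ", ")))
  }
  if (name == "NODDI-p14") {
    d1 <- uniform_sphere_directions(30, seed = seed + 11L)
    d2 <- uniform_sphere_directions(60, seed = seed + 12L)
    df <- bind_rows(
      tibble(shell = 0L, b = 0, gx = 0, gy = 0, gz = 0),
      tibble(shell = 1L, b = 711, gx = d1$gx, gy = d1$gy, gz = d1$gz),
      tibble(shell = 2L, b = 2855, gx = d2$gx, gy = d2$gy, gz = d2$gz)
    )
    return(new_scheme(df, name))
  }
  n_shells <- nchar(name) - 1L   # "p12" -> shells 1..2
  full <- hydi_shells(seed = seed)
  sub <- full[full$shell <= n_shells, , drop = FALSE]
  new_scheme(sub, name)
}

#' Read and write FSL-style gradient tables
#'
#' `write_bval_bvec()` writes a scheme as plain-text `.bval` (one line of
#' b-values) and `.bvec` (three lines: x, y, z components) files with
#' measurements in column order; `read_bval_bvec()` reads the pair back into
#' a scheme tibble, inferring shell labels by grouping identical b-values.
#' The round trip is lossless to 6 significant digits.
#'
#' @param scheme A scheme tibble.
#' @param prefix Path prefix; files `<prefix>.bval` and `<prefix>.bvec` are
#'   written/read.
#' @return `write_bval_bvec()` returns the two file paths invisibly;
#'   `read_bval_bvec()` returns a scheme tibble.
#' @examples
#' pre <- file.path(tempdir(), "demo")
#' write_bval_bvec(build_protocol("p12"), pre)
#' sch <- read_bval_bvec(pre)
#' @export
write_bval_bvec <- function(scheme, prefix) {
  validate_scheme(scheme)
  fmt <- function(v) paste(formatC(v, digits = 6, format = "g"), collapse = " ")
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(fmt(scheme$b), bval)
  writeLines(c(fmt(scheme$gx), fmt(scheme$gy), fmt(scheme$gz)), bvec)
  invisible(c(bval = bval, bvec = bvec))
}

#' @rdname write_bval_bvec
#' @export
read_bval_bvec <- function(prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  if (!file.exists(bval) || !file.exists(bvec)) {
    abort(paste0("missing ", bval, " or ", bvec))
  }
  b <- scan(bval, quiet = TRUE)
  g <- do.call(rbind, lapply(readLines(bvec)[1:3],
                             function(l) scan(text = l, quiet = TRUE)))
  if (ncol(g) != length(b)) abort(".bval and .bvec disagree in length.")
  shell <- match(b, sort(unique(b))) - 1L
  # renormalize against text-precision loss
  nrm <- sqrt(colSums(g^2))
  scale <- ifelse(b > 0 & nrm > 0, nrm, 1)
  g <- sweep(g, 2, scale, "/")
  df <- tibble(shell = shell, b = b, gx = g[1, ], gy = g[2, ], gz = g[3, ])
  out <- new_scheme(df, basename(prefix))
  validate_scheme(out)
  out
}
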