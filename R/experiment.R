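# Full simulation pipeline: synthesize -> noise -> fit across protocols,
# SNR levels and the ground-truth grid; aggregate; compare schemes.

#' Configuration of a simulation run
#'
#' Defaults are the full study design: protocols NODDI-p14 and the four
#' HYDI shell combinations; SNR_b0 in \{20, 30, 40, 50, Inf\}; ICVF grid
#' \{0.2, 0.4, 0.5, 0.8\}; kappa grid \{0, 0.25, 1, 4, 16\}; FISO = 0;
#' 250 fiber orientations; 30 trials.  `preset = "desk"` is a scaled-down
#' design for interactive work and continuous testing: ICVF \{0.5, 0.8\},
#' kappa \{1, 4\}, 50 orientations, 5 trials, SNR \{20, 30\}, protocols
#' NODDI-p14 and p12345.
#'
#' @param protocols Character subset of
#'   `"NODDI-p14"`, `"p12"`, `"p123"`, `"p1234"`, `"p12345"`.
#' @param snr_levels Numeric SNR_b0 levels (may include `Inf`).
#' @param icvf_grid,kappa_grid Ground-truth levels.
#' @param fiso_true Ground-truth free-water fraction.
#' @param n_orientations Number of fiber orientations (one shared seeded
#'   design per run).
#' @param n_trials Noise realizations per condition.
#' @param master_seed Integer; every random draw in the run derives from it.
#' @param fit FitOptions used for every fit (see [fit_options()]).
#' @param preset `"full"` (use the arguments as given) or `"desk"`.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(protocols = c("NODDI-p14", "p12", "p123",
                                            "p1234", "p12345"),
                              snr_levels = c(20, 30, 40, 50, Inf),
                              icvf_grid = c(0.2, 0.4, 0.5, 0.8),
                              kappa_grid = c(0, 0.25, 1, 4, 16),
                              fiso_true = 0,
                              n_orientations = 250L,
                              n_trials = 30L,
                              master_seed = 7L,
                              fit = fit_options(),
                              preset = c("full", "desk")) {
  preset <- arg_match(preset)
  if (preset == "desk") {
    protocols <- c("NODDI-p14", "p12345")
    snr_levels <- c(20, 30)
    icvf_grid <- c(0.5, 0.8)
    kappa_grid <- c(1, 4)
    n_orientations <- 50L
    n_trials <- 5L
  }
  bad <- setdiff(protocols, .PROTOCOLS)
  if (length(bad)) {
    abort(paste0("unknown protocol(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(protocols = protocols, snr_levels = snr_levels,
                 icvf_grid = icvf_grid, kappa_grid = kappa_grid,
                 fiso_true = fiso_true,
                 n_orientations = as.integer(n_orientations),
                 n_trials = as.integer(n_trials),
                 master_seed = as.integer(master_seed), fit = fit),
            class = "experiment_config")
}

# stable 31-bit hash of the master seed and a condition tuple, so each
# record's noise seed is independent of execution order
stable_seed <- function(master, ...) {
  s <- paste(master, ..., sep = "|")
  h <- 2166136261 %% 2147483647
  for (v in utf8ToInt(s)) {
    h <- (h * 33 + v) %% 2147483647
  }
  as.integer(h)
}

#' Run the simulation experiment
#'
#' For every tuple (protocol, SNR, ICVF, kappa, orientation, trial):
#' synthesize the noise-free signal, add Rician noise with a seed derived
#' deterministically from the master seed and the tuple, fit the model, and
#' record the estimates.  Output is identical regardless of execution order;
#' fit failures are recorded with `converged = FALSE` and the run continues.
#'
#' @param config An [experiment_config()].
#' @param progress Print a line per protocol/condition block.
#' @return A results tibble with one row per tuple: `protocol`, `snr`,
#'   `icvf_true`, `kappa_true`, `odi_true`, `orientation_id`, `trial`,
#'   `icvf_est`, `odi_est`, `fiso_est`, `converged`.
#' @examples
#' cfg <- experiment_config(protocols = "p12345", snr_levels = Inf,
#'                          n_orientations = 2L, n_trials = 1L)
#' res <- run_experiment(cfg)
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  orient <- uniform_sphere_directions(
    config$n_orientations, seed = stable_seed(config$master_seed, "orient"))
  MU <- as.matrix(orient)
  truth <- tidyr::expand_grid(icvf_true = config$icvf_grid,
                              kappa_true = config$kappa_grid)

  purrr::map_dfr(config$protocols, function(proto) {
    scheme <- build_protocol(proto)
    purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      fi <- truth$icvf_true[i]
      kp <- truth$kappa_true[i]
      if (progress) {
        message(sprintf("%s: ICVF=%.2f kappa=%.2f", proto, fi, kp))
      }
      tissue <- tissue_params(fi, kp, config$fiso_true)
      purrr::map_dfr(seq_len(nrow(MU)), function(o) {
        tis <- tissue
        tis$mu <- MU[o, ]
        clean <- synthesize_signal(scheme, tis)
        purrr::map_dfr(config$snr_levels, function(snr) {
          # the Rician likelihood needs the record's own noise level; at
          # SNR = Inf it degenerates, so fall back to least squares there
          fo <- config$fit
          if (fo$objective == "rician-likelihood") {
            if (is.finite(snr)) {
              fo$snr_b0 <- snr
            } else {
              fo$objective <- "least-squares"
            }
          }
          purrr::map_dfr(seq_len(config$n_trials), function(trial) {
            seed <- stable_seed(config$master_seed, proto, snr, fi, kp,
                                o, trial)
            noisy <- add_rician_noise(clean, snr_b0 = snr, seed = seed)
            fit <- tryCatch(fit_noddi(noisy, fo),
                            error = function(e) NULL)
            if (is.null(fit)) {
              tibble(protocol = proto, snr = snr, icvf_true = fi,
                     kappa_true = kp, odi_true = odi_from_kappa(kp),
                     orientation_id = o, trial = trial,
                     icvf_est = NA_real_, odi_est = NA_real_,
                     fiso_est = NA_real_, converged = FALSE)
            } else {
              tibble(protocol = proto, snr = snr, icvf_true = fi,
                     kappa_true = kp, odi_true = odi_from_kappa(kp),
                     orientation_id = o, trial = trial,
                     icvf_est = fit$params$f_ic, odi_est = fit$odi,
                     fiso_est = fit$params$f_iso,
                     converged = fit$converged)
            }
          })
        })
      })
    })
  })
}

#' Aggregate simulation results
#'
#' Mean and standard deviation of each estimate per (protocol, SNR, grouped
#' truth level), pooling across trials, orientations, and the truth
#' parameters not named in `group_by` -- the summary behind the per-SNR
#' recovery figures.
#'
#' @param results A results tibble from [run_experiment()].
#' @param group_by Character vector of grouping keys beyond `protocol` and
#'   `snr` (e.g. `"icvf_true"`); must name columns of `results`.
#' @return A tibble of means and standard deviations of `icvf_est`,
#'   `odi_est`, `fiso_est` per group.
#' @export
aggregate_results <- function(results, group_by = "icvf_true") {
  if (nrow(results) == 0) abort("`results` is empty.")
  bad <- setdiff(group_by, names(results))
  if (length(bad)) {
    abort(paste0("unknown grouping key(s): ", paste(bad, collapse = ", ")))
  }
  results %>%
    group_by(across(all_of(unique(c("protocol", "snr", group_by))))) %>%
    summarise(
      n = dplyr::n(),
      across(all_of(c("icvf_est", "odi_est", "fiso_est")),
             list(mean = ~ mean(.x, na.rm = TRUE),
                  sd = ~ if (sum(!is.na(.x)) < 2) 0
                         else stats::sd(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' Paired comparison of two acquisition schemes
#'
#' Pairs the estimates of protocols `a` and `b` by (truth condition,
#' orientation, trial) at one SNR level and applies a two-sided paired test
#' to the chosen estimate: Student's t by default, Wilcoxon signed-rank as
#' an alternative.
#'
#' @param results A results tibble containing both protocols at `snr`.
#' @param a,b Protocol names.
#' @param metric One of `"icvf_est"`, `"odi_est"`, `"fiso_est"`.
#' @param snr SNR level at which to compare.
#' @param method `"t-test"` or `"wilcoxon"`.
#' @return A one-row tibble: `metric`, `snr`, `n_pairs`, `mean_diff`,
#'   `statistic`, `p_value`, `method`.
#' @export
compare_schemes <- function(results, a, b,
                            metric = c("icvf_est", "odi_est", "fiso_est"),
                            snr, method = c("t-test", "wilcoxon")) {
  metric <- arg_match(metric)
  method <- arg_match(method)
  keys <- c("icvf_true", "kappa_true", "orientation_id", "trial")
  xa <- results %>% filter(.data$protocol == a, .data$snr == !!snr)
  xb <- results %>% filter(.data$protocol == b, .data$snr == !!snr)
  if (nrow(xa) == 0 || nrow(xb) == 0) {
    abort("both protocols must be present at the given `snr`.")
  }
  paired <- inner_join(xa[, c(keys, metric)], xb[, c(keys, metric)],
                       by = keys, suffix = c("_a", "_b"))
  if (nrow(paired) != nrow(xa) || nrow(paired) != nrow(xb)) {
    abort("condition tuples of the two protocols do not match 1:1.")
  }
  d <- paired[[paste0(metric, "_a")]] - paired[[paste0(metric, "_b")]]
  d <- d[!is.na(d)]
  if (stats::sd(d) == 0) {
    # degenerate: identical pairs give p = 1, a constant nonzero shift p = 0
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else if (method == "t-test") {
    ht <- t.test(d)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ht <- wilcox.test(d, exact = FALSE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble(metric = metric, snr = snr, n_pairs = length(d),
         mean_diff = mean(d), statistic = stat, p_value = p,
         method = method)
}

#' White-matter ROI reference table
#'
#' Means and standard deviations of eight diffusion metrics (DTI axial,
#' radial and mean diffusivity, FA, the q-space zero-displacement
#' probability Po, and the NODDI ODI, ICVF and FISO) in 48 white-matter
#' regions of the JHU ICBM-DTI-81 atlas, averaged across 52 healthy adults.
#' These values motivate the "realistic" simulation settings (high ICVF,
#' low ODI in coherent white matter).  Diffusivities are in 1e-6 mm^2/s.
#'
#' @param roi Optional character vector of ROI labels to select; unknown
#'   labels raise an error listing the valid ones.
#' @return A tibble of 48 rows (or the selected subset) with `roi` plus
#'   `<metric>_mean` / `<metric>_std` columns.
#' @examples
#' load_roi_reference("GCC")$icvf_mean
#' @export
load_roi_reference <- function(roi = NULL) {
  path <- system.file("extdata", "jhu_wm_roi_reference.csv",
                      package = "noddisim", mustWork = TRUE)
  tab <- as_tibble(read.csv(path, check.names = FALSE))
  if (!is.null(roi)) {
    bad <- setdiff(roi, tab$roi)
    if (length(bad)) {
      abort(paste0("unknown ROI label(s): ", paste(bad, collapse = ", "),
                   ". Valid labels: ", paste(tab$roi, collapse = ", ")))
    }
    tab <- tab[match(roi, tab$roi), , drop = FALSE]
  }
  tab
}
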