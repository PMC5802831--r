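#' Configuration of a full recovery experiment
#'
#' Bundles every knob of the scheme-generation, simulation, inversion and
#' analysis pipeline, with an explicit seed for every random stage (derived
#' deterministically from the master `seed`).  Round-trips losslessly
#' through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param n_points acquisition points in the pseudo-random scheme.
#' @param snr signal-to-noise ratio of the simulated data.
#' @param n_boot bootstrap replicates (the full-scale experiments used
#'   1000; 100 is a desk-scale default).
#' @param seed master seed; all stage seeds derive from it.
#' @param weights phantom compartment fractions (lc, intra, extra).
#' @param scheme_limits an [acq_limits()] box.
#' @param biases the four scheme bias fractions.
#' @param b_min b-value floor of the resampling rule, s/m^2.
#' @param inversion an [inversion_config()].
#' @param regions named list of [subvolume()] boxes.
#' @param tolerance pass/fail tolerance on sub-volume means, log10 units
#'   (a region passes when the estimate is within
#'   `max(tolerance, 1 bootstrap SD)` of truth).
#' @return A `"run_config"` list.
#' @export
run_config <- function(n_points = 1500, snr = 120, n_boot = 100, seed = 1,
                       weights = c(lc = 1/3, intra = 1/3, extra = 1/3),
                       scheme_limits = acq_limits(),
                       biases = c(linear = 0.30, spherical = 0.15,
                                  planar = 0.10, stability = 0.05),
                       b_min = 6.06e8,
                       inversion = inversion_config(),
                       regions = default_regions(),
                       tolerance = 0.3) {
  structure(list(n_points = as.integer(n_points), snr = snr,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 weights = weights, scheme_limits = scheme_limits,
                 biases = biases, b_min = b_min, inversion = inversion,
                 regions = regions, tolerance = tolerance),
            class = "run_config")
}

# Ground-truth sub-volume statistics implied by a phantom spec: weighted
# means of the true components falling inside each region.
region_truth <- function(spec, regions) {
  tab <- phantom_log_table(spec)
  do.call(rbind, lapply(names(regions), function(rn) {
    inside <- in_region(tab, regions[[rn]])
    if (!any(inside)) {
      return(data.frame(region = rn, truth_Pvol = 0,
                        truth_E_logR1 = NA_real_, truth_E_logR2 = NA_real_,
                        truth_E_logDiso = NA_real_,
                        truth_E_logratio = NA_real_))
    }
    w <- tab$weight[inside] / sum(tab$weight[inside])
    data.frame(region = rn, truth_Pvol = sum(tab$weight[inside]),
               truth_E_logR1 = sum(w * tab$logR1[inside]),
               truth_E_logR2 = sum(w * tab$logR2[inside]),
               truth_E_logDiso = sum(w * tab$logDiso[inside]),
               truth_E_logratio = sum(w * tab$logratio[inside]))
  }))
}

#' Run a full simulated recovery experiment
#'
#' Pipeline: generate the pseudo-random scheme, synthesize the
#' yeast/liquid-crystal phantom signal, add Gaussian noise, run the
#' bootstrap Monte Carlo NNLS inversion, and compare per-region bootstrap
#' statistics against the known ground truth.  Fully deterministic given
#' the config (same config twice gives a byte-identical report).
#'
#' @param cfg a [run_config()].
#' @param keep_ensemble keep the solution ensemble in the returned object
#'   (default TRUE; set FALSE to shrink the report).
#' @return A `"recovery_report"`: list with `table` (per region: bootstrap
#'   mean and SD of `Pvol` and the four log-coordinate means, ground
#'   truth, and a pass flag at `max(tolerance, 1 SD)`),
#'   `median_recovery_error` (see [recovery_error()]), stage seeds,
#'   config, and optionally the ensemble.
#' @export
run_recovery_experiment <- function(cfg = run_config(),
                                    keep_ensemble = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- child_seeds(cfg$seed, 3)
  scheme <- generate_scheme(cfg$n_points, limits = cfg$scheme_limits,
                            biases = cfg$biases, b_min = cfg$b_min,
                            seed = seeds[1])
  spec <- yeast_lc_phantom(cfg$weights)
  ds <- simulate_experiment(spec, scheme, snr = cfg$snr, seed = seeds[2])
  ens <- bootstrap_invert(ds, cfg$inversion, n_boot = cfg$n_boot,
                          seed = seeds[3])
  stats <- subvolume_stats(ens, cfg$regions)
  truth <- region_truth(spec, cfg$regions)
  tab <- merge(stats$summary, truth, by = "region", sort = FALSE)
  for (v in c("E_logR1", "E_logR2", "E_logDiso", "E_logratio")) {
    est <- tab[[paste0(v, "_mean")]]
    tru <- tab[[paste0("truth_", v)]]
    tol <- pmax(cfg$tolerance, tab[[paste0(v, "_sd")]])
    tab[[paste0(v, "_pass")]] <- ifelse(is.na(tru), NA, abs(est - tru) <= tol)
  }
  err <- recovery_error(ens, phantom_log_table(spec)$logDiso)
  structure(list(table = tab,
                 median_recovery_error = median(err),
                 recovery_errors = err,
                 stats = stats,
                 ensemble = if (keep_ensemble) ens else NULL,
                 seeds = seeds,
                 config = cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<recovery_report> %d points, SNR %g, %d bootstrap replicates\n",
    cfg$n_points, cfg$snr, cfg$n_boot))
  cat(sprintf("  median recovery error (log10 Diso): %.4g\n",
              x$median_recovery_error))
  cols <- c("region", "Pvol_mean", "Pvol_sd", "E_logDiso_mean",
            "E_logDiso_sd", "truth_E_logDiso", "E_logDiso_pass")
  print(x$table[cols], digits = 3)
  invisible(x)
}

#' Sweep recovery experiments over sampling density and SNR
#'
#' Runs [run_recovery_experiment()] for every `(n_points, snr)` cell of the
#' grid, with deterministic per-cell seeds derived from the base config
#' seed.  Scheme-parameter overrides (e.g. a reduced or extended `b_delta`
#' range to probe the oblate artefact) apply to all cells.
#'
#' @param cfg base [run_config()].
#' @param n_points vector of sampling densities.
#' @param snr vector of signal-to-noise ratios.
#' @param scheme_overrides optional named list replacing fields of the base
#'   config (e.g. `list(scheme_limits = ..., b_min = ...)`).
#' @return Data frame with one row per cell, in row-major
#'   `(n_points x snr)` order: the cell coordinates, the median recovery
#'   error, and the per-region `E_logDiso` estimates.
#' @export
sweep_recovery <- function(cfg = run_config(), n_points = c(500, 1500, 5000),
                           snr = c(60, 120, 400),
                           scheme_overrides = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(scheme_overrides)) {
    cfg[names(scheme_overrides)] <- scheme_overrides
  }
  cells <- expand.grid(snr = snr, n_points = n_points)[, 2:1]
  seeds <- child_seeds(cfg$seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ci <- cfg
    ci$n_points <- as.integer(cells$n_points[i])
    ci$snr <- cells$snr[i]
    ci$seed <- seeds[i]
    rep_i <- run_recovery_experiment(ci, keep_ensemble = FALSE)
    out <- data.frame(n_points = ci$n_points, snr = ci$snr,
                      median_recovery_error = rep_i$median_recovery_error)
    for (rn in rep_i$table$region) {
      out[[paste0("E_logDiso_", rn)]] <-
        rep_i$table$E_logDiso_mean[rep_i$table$region == rn]
    }
    out
  })
  do.call(rbind, rows)
}

#' Read and write run configurations
#'
#' JSON serialization; numeric fields round-trip exactly.
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the `"run_config"`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  obj <- unclass(cfg)
  obj$scheme_limits <- unclass(obj$scheme_limits)
  inv <- unclass(obj$inversion)
  inv$limits <- unclass(inv$limits)
  obj$inversion <- inv
  obj$regions <- lapply(obj$regions, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  run_config(
    n_points = obj$n_points, snr = num(obj$snr), n_boot = obj$n_boot,
    seed = obj$seed, weights = num(obj$weights),
    scheme_limits = do.call(acq_limits, lapply(obj$scheme_limits, num)),
    biases = setNames(num(obj$biases), names(obj$biases)),
    b_min = num(obj$b_min),
    inversion = inversion_config(
      limits = do.call(analysis_limits, lapply(obj$inversion$limits, num)),
      n_candidates = obj$inversion$n_candidates,
      n_prolif = obj$inversion$n_prolif,
      n_mutate = obj$inversion$n_mutate,
      mutation_scale = num(obj$inversion$mutation_scale),
      max_components = obj$inversion$max_components,
      shape_constraint = obj$inversion$shape_constraint,
      polish_sweeps = obj$inversion$polish_sweeps,
      polish_maxit = obj$inversion$polish_maxit,
      polish_rtol = num(obj$inversion$polish_rtol),
      polish_prune = num(obj$inversion$polish_prune)),
    regions = lapply(obj$regions, function(r) {
      subvolume(r$name, logR1 = num(r$logR1), logR2 = num(r$logR2),
                logDiso = num(r$logDiso), logratio = num(r$logratio))
    }),
    tolerance = num(obj$tolerance))
}
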