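#' Analysis-space limits for the inversion
#'
#' The box of allowed component parameters.  Rates and diffusivity are
#' bounded in log10; anisotropy is linear in `Ddelta`; orientations are
#' always uniform over the sphere (area-uniform in `cos(theta)`).  The
#' defaults bracket the yeast/liquid-crystal phantom with margin on every
#' axis.
#'
#' @param logR1,logR2,logDiso length-2 log10 ranges (1/s, 1/s, m^2/s).
#' @param Ddelta length-2 range within `[-0.5, 1]`.
#' @return Named list of ranges, class `"analysis_limits"`.
#' @export
analysis_limits <- function(logR1 = c(-1, 1), logR2 = c(0, 3),
                            logDiso = c(-12, -8), Ddelta = c(-0.5, 1)) {
  lim <- list(logR1 = logR1, logR2 = logR2, logDiso = logDiso,
              Ddelta = Ddelta)
  for (nm in names(lim)) {
    v <- lim[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] >= v[2]) {
      stop(sprintf("limit `%s` must be an ordered length-2 range", nm),
           call. = FALSE)
    }
  }
  if (lim$Ddelta[1] < -0.5 || lim$Ddelta[2] > 1) {
    stop("Ddelta limits must stay within [-0.5, 1]", call. = FALSE)
  }
  structure(lim, class = "analysis_limits")
}

#' Configuration of the Monte Carlo NNLS inversion
#'
#' The inversion is a stochastic search over discrete component sets:
#' random candidate components are scored by non-negative least squares,
#' survivors are kept, and the set is iteratively refreshed
#' ("proliferation") and locally perturbed ("mutation").  Candidate counts
#' and round numbers trade accuracy against run time and are deliberately
#' exposed here; the defaults are desk-scale.
#'
#' @param limits an [analysis_limits()] box.
#' @param n_candidates components per NNLS pass (fresh draws top the
#'   retained set back up to this count each proliferation round).
#' @param n_prolif number of proliferation rounds.
#' @param n_mutate number of mutation rounds.
#' @param mutation_scale standard deviation of the Gaussian perturbation,
#'   in log10 units for rates/diffusivity, linear for `Ddelta`, radians
#'   for angles.
#' @param max_components maximum components retained in the final solution
#'   (largest weights win; ties break by draw order).
#' @param shape_constraint `"none"` (default) or `"iso_prolate"`, which
#'   restricts candidates to isotropic or prolate shapes
#'   (`Ddelta in {0} union (0, 1]`) — a remedy for the oblate artefact
#'   caused by shape undersampling at low b.
#' @param polish_sweeps maximum number of deterministic refinement sweeps
#'   after the stochastic search (0, the default, disables polishing).
#'   Each sweep runs a Nelder-Mead optimization of every retained
#'   component's six nonlinear parameters in turn, with the weights
#'   re-solved by NNLS at every step (variable projection).  Useful for
#'   precision benchmarks on noise-free data; unnecessary for bootstrap
#'   ensembles, where the tolerance is set by the noise.
#' @param polish_maxit Nelder-Mead iteration cap per component and sweep.
#' @param polish_rtol relative residual improvement below which polishing
#'   stops early.
#' @param polish_prune weight fraction (of the total) below which a
#'   component is dropped between polish sweeps.
#' @return A list of class `"inversion_config"`.
#' @export
inversion_config <- function(limits = analysis_limits(),
                             n_candidates = 200,
                             n_prolif = 20,
                             n_mutate = 20,
                             mutation_scale = 0.1,
                             max_components = 50,
                             shape_constraint = c("none", "iso_prolate"),
                             polish_sweeps = 0,
                             polish_maxit = 150,
                             polish_rtol = 0.01,
                             polish_prune = 0.005) {
  stopifnot(n_candidates >= 1, n_prolif >= 0, n_mutate >= 0,
            mutation_scale > 0, max_components >= 1, polish_sweeps >= 0,
            polish_maxit >= 1, polish_rtol >= 0, polish_prune >= 0)
  structure(list(limits = limits,
                 n_candidates = as.integer(n_candidates),
                 n_prolif = as.integer(n_prolif),
                 n_mutate = as.integer(n_mutate),
                 mutation_scale = mutation_scale,
                 max_components = as.integer(max_components),
                 shape_constraint = match.arg(shape_constraint),
                 polish_sweeps = as.integer(polish_sweeps),
                 polish_maxit = as.integer(polish_maxit),
                 polish_rtol = polish_rtol,
                 polish_prune = polish_prune),
            class = "inversion_config")
}

# Draw k candidate components uniformly in the transformed analysis space.
draw_candidates <- function(k, cfg) {
  lim <- cfg$limits
  Ddelta <- if (cfg$shape_constraint == "iso_prolate") {
    # Atom at the sphere plus a uniform prolate branch.
    ifelse(runif(k) < 0.5, 0, runif(k, 0, max(0, lim$Ddelta[2])))
  } else {
    runif(k, lim$Ddelta[1], lim$Ddelta[2])
  }
  data.frame(
    weight = 0,
    R1 = 10^runif(k, lim$logR1[1], lim$logR1[2]),
    R2 = 10^runif(k, lim$logR2[1], lim$logR2[2]),
    Diso = 10^runif(k, lim$logDiso[1], lim$logDiso[2]),
    Ddelta = Ddelta,
    theta = acos(runif(k, -1, 1)),
    phi = runif(k, 0, 2 * pi))
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Reflect values back into a range.  Used for mutation proposals: clamping
# would make the box edges absorbing and pile mass there (visible as
# spurious Ddelta = 1 atoms with divergent D_par/D_perp); reflection keeps
# the proposal density smooth across the boundary.
reflect <- function(x, range) {
  w <- range[2] - range[1]
  y <- (x - range[1]) %% (2 * w)
  range[1] + pmin(y, 2 * w - y)
}

# Gaussian perturbation of retained components in transformed coordinates,
# reflected at the analysis box; angles jitter on the sphere with
# wrap/reflect.
mutate_components <- function(comps, cfg) {
  k <- nrow(comps)
  s <- cfg$mutation_scale
  lim <- cfg$limits
  out <- comps
  out$R1 <- 10^reflect(log10(comps$R1) + rnorm(k, 0, s), lim$logR1)
  out$R2 <- 10^reflect(log10(comps$R2) + rnorm(k, 0, s), lim$logR2)
  out$Diso <- 10^reflect(log10(comps$Diso) + rnorm(k, 0, s), lim$logDiso)
  dd_range <- if (cfg$shape_constraint == "iso_prolate") {
    c(0, max(0, lim$Ddelta[2]))
  } else {
    lim$Ddelta
  }
  out$Ddelta <- reflect(comps$Ddelta + rnorm(k, 0, s), dd_range)
  theta <- comps$theta + rnorm(k, 0, s)
  phi <- comps$phi + rnorm(k, 0, s)
  flip <- theta < 0 | theta > pi
  theta <- ifelse(theta < 0, -theta, theta)
  theta <- ifelse(theta > pi, 2 * pi - theta, theta)
  out$theta <- theta
  out$phi <- (phi + ifelse(flip, pi, 0)) %% (2 * pi)
  out
}

#' Non-negative least squares
#'
#' Solves `min ||K w - s||_2` subject to `w >= 0` with the Lawson-Hanson
#' active-set algorithm (compiled).  All-zero columns (components the
#' scheme cannot see at all) are removed with a warning and receive zero
#' weight.
#'
#' @param K design matrix (acquisition points by candidate components,
#'   entries in `[0, 1]` for signal kernels).
#' @param s signal vector, one entry per row of `K`.
#' @return List with `weights` (length `ncol(K)`, non-negative) and
#'   `rnorm` (the residual 2-norm).
#' @export
nnls_solve <- function(K, s) {
  K <- as.matrix(K)
  zero_cols <- which(colSums(abs(K)) == 0)
  if (length(zero_cols)) {
    warning(sprintf("removed %d all-zero column(s) from the design",
                    length(zero_cols)))
    keep <- setdiff(seq_len(ncol(K)), zero_cols)
    fit <- nnls_cpp(K[, keep, drop = FALSE], s)
    w <- numeric(ncol(K))
    w[keep] <- drop(fit$x)
    return(list(weights = w, rnorm = fit$rnorm))
  }
  fit <- nnls_cpp(K, s)
  list(weights = drop(fit$x), rnorm = fit$rnorm)
}

new_solution <- function(components, rnorm, noise, residual_trace, n_points,
                         S0) {
  structure(list(components = components, residual_norm = rnorm,
                 noise = noise, residual_trace = residual_trace,
                 n_points = n_points, S0 = S0),
            class = "dtd_solution")
}

#' @export
print.dtd_solution <- function(x, ...) {
  cat(sprintf(
    "<dtd_solution> %d components, total weight %.4g, residual %.4g, noise %.4g\n",
    nrow(x$components), sum(x$components$weight), x$residual_norm, x$noise))
  invisible(x)
}

# Deterministic block-coordinate refinement (variable projection): each
# retained component's six nonlinear parameters are optimized by
# Nelder-Mead with the weights re-solved by NNLS at every objective
# evaluation.  Negligible-weight components are pruned between sweeps.
polish_components <- function(scheme, s, comps, cfg) {
  lim <- cfg$limits
  dd_range <- if (cfg$shape_constraint == "iso_prolate") {
    c(0, max(0, lim$Ddelta[2]))
  } else {
    lim$Ddelta
  }
  unpack1 <- function(p) {
    data.frame(weight = 0,
               R1 = 10^clamp(p[1], lim$logR1),
               R2 = 10^clamp(p[2], lim$logR2),
               Diso = 10^clamp(p[3], lim$logDiso),
               Ddelta = clamp(p[4], dd_range),
               theta = p[5], phi = p[6])
  }
  prev <- Inf
  fit <- NULL
  for (sw in seq_len(cfg$polish_sweeps)) {
    K <- kernel_matrix_impl(scheme, comps)
    for (j in order(-comps$weight)) {
      others <- K[, -j, drop = FALSE]
      p0 <- c(log10(comps$R1[j]), log10(comps$R2[j]), log10(comps$Diso[j]),
              comps$Ddelta[j], comps$theta[j], comps$phi[j])
      obj <- function(p) {
        nnls_cpp(cbind(others, kernel_matrix_impl(scheme, unpack1(p))),
                 s)$rnorm
      }
      opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = cfg$polish_maxit))
      comps[j, ] <- unpack1(opt$par)[1, ]
      K[, j] <- kernel_matrix_impl(scheme, comps[j, , drop = FALSE])
    }
    fit <- nnls_cpp(K, s)
    w <- drop(fit$x)
    keep <- w > cfg$polish_prune * sum(w)
    if (!any(keep)) keep <- w > 0
    comps <- comps[keep, , drop = FALSE]
    comps$weight <- w[keep]
    if (prev - fit$rnorm < cfg$polish_rtol * prev && all(keep)) break
    prev <- fit$rnorm
  }
  comps
}

# Core search; consumes the current RNG stream (seeding is the caller's
# concern so bootstrap replicates can share one child seed for resampling
# and inversion).
invert_core <- function(scheme, signal, S0, cfg) {
  s <- signal / S0
  comps <- draw_candidates(cfg$n_candidates, cfg)
  K <- kernel_matrix_impl(scheme, comps)
  fit <- nnls_cpp(K, s)
  keep <- fit$x > 0
  comps <- comps[keep, , drop = FALSE]
  K <- K[, keep, drop = FALSE]
  w <- fit$x[keep]
  trace <- fit$rnorm

  # Proliferation: survivors compete against fresh random candidates.
  for (i in seq_len(cfg$n_prolif)) {
    n_fresh <- cfg$n_candidates - nrow(comps)
    if (n_fresh <= 0) n_fresh <- 1L
    fresh <- draw_candidates(n_fresh, cfg)
    K2 <- cbind(K, kernel_matrix_impl(scheme, fresh))
    pool <- rbind(comps, fresh)
    fit <- nnls_cpp(K2, s)
    keep <- fit$x > 0
    comps <- pool[keep, , drop = FALSE]
    K <- K2[, keep, drop = FALSE]
    w <- fit$x[keep]
    trace <- c(trace, fit$rnorm)
  }

  # Mutation: survivors compete against jittered copies of themselves.
  # The candidate union contains the incumbents, so the residual cannot
  # increase.
  for (i in seq_len(cfg$n_mutate)) {
    if (nrow(comps) == 0) break
    mut <- mutate_components(comps, cfg)
    K2 <- cbind(K, kernel_matrix_impl(scheme, mut))
    pool <- rbind(comps, mut)
    fit <- nnls_cpp(K2, s)
    keep <- fit$x > 0
    comps <- pool[keep, , drop = FALSE]
    K <- K2[, keep, drop = FALSE]
    w <- fit$x[keep]
    trace <- c(trace, fit$rnorm)
  }

  if (nrow(comps) == 0) {
    empty <- draw_candidates(0, cfg)
    return(new_solution(empty, rnorm = sqrt(sum(s^2)) * S0, noise = NA_real_,
                        residual_trace = trace * S0,
                        n_points = nrow(scheme), S0 = S0))
  }

  # Prune to the largest weights (draw order breaks ties) and refit.
  if (nrow(comps) > cfg$max_components) {
    ord <- order(-w)[seq_len(cfg$max_components)]
    ord <- sort(ord)
    comps <- comps[ord, , drop = FALSE]
    K <- K[, ord, drop = FALSE]
  }
  fit <- nnls_cpp(K, s)
  keep <- drop(fit$x) > 0
  comps <- comps[keep, , drop = FALSE]
  comps$weight <- drop(fit$x)[keep]
  trace <- c(trace, fit$rnorm)

  # Optional deterministic refinement.
  if (cfg$polish_sweeps > 0 && nrow(comps) > 0) {
    comps <- polish_components(scheme, s, comps, cfg)
  }
  K <- kernel_matrix_impl(scheme, comps)
  fit <- nnls_cpp(K, s)
  keep <- drop(fit$x) > 0
  comps <- comps[keep, , drop = FALSE]
  K <- K[, keep, drop = FALSE]
  comps$weight <- drop(fit$x)[keep]

  resid <- S0 * (s - drop(K %*% comps$weight))
  rownames(comps) <- NULL
  new_solution(comps, rnorm = fit$rnorm * S0, noise = mad(resid),
               residual_trace = trace * S0, n_points = nrow(scheme), S0 = S0)
}

#' Model-free inversion of a relaxation-diffusion dataset
#'
#' Estimates a discrete 6D distribution `P(R1, R2, Diso, Ddelta, theta,
#' phi)` by Monte Carlo sampled non-negative least squares: (i) draw
#' `n_candidates` components uniformly in the transformed analysis space;
#' (ii) fit by NNLS and keep the components with positive weight; (iii)
#' repeat for `n_prolif` rounds, each time topping the retained set back up
#' with fresh draws; (iv) run `n_mutate` rounds in which retained
#' components compete against Gaussian-perturbed copies of themselves;
#' (v) prune to `max_components` and refit; (vi) optionally refine the
#' surviving components deterministically (`polish_sweeps > 0`; see
#' [inversion_config()]).  Because every NNLS pass of the stochastic stage
#' includes the incumbent components, the residual norm is non-increasing
#' across rounds (recorded in `residual_trace`; the polish stage reports
#' its final residual in `residual_norm`).  The only constraints are
#' non-negativity and the analysis-range box — no smoothness
#' regularization.
#'
#' @param ds a `"signal_dataset"`.
#' @param cfg an [inversion_config()].
#' @param seed integer seed; the solution is deterministic given it.
#' @return A `"dtd_solution"`: component table (strictly positive weights,
#'   in units of the signal fraction of `S0`), residual norm, robust noise
#'   estimate, and the residual trace.
#' @export
invert <- function(ds, cfg = inversion_config(), seed = NULL) {
  stopifnot(inherits(ds, "signal_dataset"))
  with_seed(seed, invert_core(ds$scheme, ds$signal, ds$S0, cfg))
}

#' Bootstrap ensemble of inversions
#'
#' Runs [invert()] on `n_boot` datasets obtained by resampling the
#' acquisition points (rows) with replacement, each with an independent
#' child seed.  The spread of the resulting solution ensemble quantifies
#' the variability intrinsic to this ill-posed inversion; downstream
#' reportables are averages over the ensemble.
#'
#' @param ds a `"signal_dataset"`.
#' @param cfg an [inversion_config()].
#' @param n_boot number of bootstrap replicates.
#' @param seed master seed; child seeds (and hence the whole ensemble) are
#'   deterministic given it.
#' @return A `"dtd_ensemble"`: list with `solutions` (length `n_boot`;
#'   failed replicates are recorded as error conditions, not dropped),
#'   `config`, `seed` and provenance.
#' @export
bootstrap_invert <- function(ds, cfg = inversion_config(), n_boot = 100,
                             seed = NULL) {
  stopifnot(inherits(ds, "signal_dataset"), n_boot >= 1)
  seeds <- child_seeds(seed, n_boot)
  n <- length(ds$signal)
  solutions <- vector("list", n_boot)
  for (i in seq_len(n_boot)) {
    solutions[[i]] <- tryCatch(
      with_seed(if (is.null(seed)) NULL else seeds[i], {
        idx <- sample.int(n, n, replace = TRUE)
        scheme_b <- new_scheme(as.data.frame(ds$scheme)[idx, , drop = FALSE],
                               attr(ds$scheme, "provenance"))
        invert_core(scheme_b, ds$signal[idx], ds$S0, cfg)
      }),
      error = function(e) e)
  }
  failed <- vapply(solutions, inherits, logical(1), "error")
  if (any(failed)) {
    warning(sprintf("%d of %d bootstrap replicates failed", sum(failed),
                    n_boot))
  }
  structure(list(solutions = solutions, config = cfg, seed = seed,
                 n_boot = n_boot,
                 data_hash = content_hash(ds$signal)),
            class = "dtd_ensemble")
}

#' @export
print.dtd_ensemble <- function(x, ...) {
  ok <- !vapply(x$solutions, inherits, logical(1), "error")
  ncomp <- vapply(x$solutions[ok], function(s) nrow(s$components), integer(1))
  cat(sprintf("<dtd_ensemble> %d replicates (%d ok), %.1f components/solution\n",
              x$n_boot, sum(ok), mean(ncomp)))
  invisible(x)
}

#' Robust noise estimate from fit residuals
#'
#' Median absolute deviation (scaled by 1.4826 for Gaussian consistency) of
#' the residuals of a solution against a dataset.
#'
#' @param solution a `"dtd_solution"`.
#' @param ds the `"signal_dataset"` it was fit to.
#' @return Scalar noise level, in signal units.
#' @export
estimate_noise <- function(solution, ds) {
  stopifnot(inherits(solution, "dtd_solution"),
            inherits(ds, "signal_dataset"))
  if (nrow(solution$components) == 0) {
    return(mad(ds$signal, center = 0))
  }
  K <- kernel_matrix_impl(ds$scheme, solution$components)
  resid <- ds$signal - ds$S0 * drop(K %*% solution$components$weight)
  mad(resid)
}

#' Serialize solution ensembles
#'
#' Ensembles are stored as JSON: one record per solution with its component
#' table, residual norm and noise estimate, plus configuration and seeds —
#' sufficient to reproduce any downstream statistic.
#'
#' @param ens a `"dtd_ensemble"`.
#' @param path JSON file path.
#' @return `read_ensemble` returns the `"dtd_ensemble"`; `write_ensemble`
#'   returns `path` invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "dtd_ensemble"))
  sols <- lapply(ens$solutions, function(s) {
    if (inherits(s, "error")) {
      list(failed = TRUE, message = conditionMessage(s))
    } else {
      list(components = s$components, residual_norm = s$residual_norm,
           noise = s$noise, n_points = s$n_points, S0 = s$S0)
    }
  })
  cfg <- ens$config
  cfg$limits <- unclass(cfg$limits)
  jsonlite::write_json(
    list(solutions = sols, config = unclass(cfg), seed = ens$seed,
         n_boot = ens$n_boot, data_hash = ens$data_hash),
    path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- obj$config
  cfg <- inversion_config(
    limits = do.call(analysis_limits, lapply(cfg$limits, as.numeric)),
    n_candidates = cfg$n_candidates, n_prolif = cfg$n_prolif,
    n_mutate = cfg$n_mutate, mutation_scale = cfg$mutation_scale,
    max_components = cfg$max_components,
    shape_constraint = cfg$shape_constraint,
    polish_sweeps = cfg$polish_sweeps, polish_maxit = cfg$polish_maxit,
    polish_rtol = cfg$polish_rtol, polish_prune = cfg$polish_prune)
  sols <- lapply(obj$solutions, function(s) {
    if (isTRUE(s$failed)) {
      simpleError(s$message)
    } else {
      comps <- as.data.frame(
        lapply(component_columns, function(nm) {
          vapply(s$components, function(row) as.numeric(row[[nm]]), 0)
        }), col.names = component_columns)
      new_solution(comps, s$residual_norm, s$noise,
                   residual_trace = numeric(0), n_points = s$n_points,
                   S0 = s$S0)
    }
  })
  structure(list(solutions = sols, config = cfg, seed = obj$seed,
                 n_boot = obj$n_boot, data_hash = obj$data_hash),
            class = "dtd_ensemble")
}
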