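#' Three-compartment yeast plus liquid-crystal phantom
#'
#' Ground truth for the synthetic validation voxel: a reverse-hexagonal
#' liquid crystal whose water diffuses along aligned cylindrical channels,
#' plus the intra- and extracellular water pools of a packed yeast cell
#' suspension.  On a log10 basis the three components sit at
#' \describe{
#'   \item{lc}{`(log R1, log R2, log Diso, log D_par/D_perp) = (0, 1.5, -9, 2)`,
#'     symmetry axis along +z (the crystallites align with the main
#'     magnetic field); `Ddelta = 99/102` so that `D_par/D_perp = 100`.}
#'   \item{intra}{isotropic, `(0, 2, -11, 0)` — slow, restricted
#'     intracellular water.}
#'   \item{extra}{isotropic, `(0, 2, -9, 0)` — free extracellular water.}
#' }
#' The compartments' signal fractions are not constrained by the phantom
#' design; they default to equal thirds and are configurable.
#'
#' @param weights three signal fractions summing to 1, ordered
#'   (liquid crystal, intracellular, extracellular).
#' @param lc_dispersion optional small-angle orientation dispersion of the
#'   liquid-crystal axis (standard deviation in radians of a Gaussian
#'   polar jitter); 0 (default) keeps a delta function at theta = 0.
#'   Intended for robustness experiments only.
#' @return A `"phantom_spec"`: list with the component table and the
#'   dispersion parameter.
#' @examples
#' spec <- yeast_lc_phantom()
#' spec$components
#' @export
yeast_lc_phantom <- function(weights = c(lc = 1/3, intra = 1/3, extra = 1/3),
                             lc_dispersion = 0) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be three non-negative fractions summing to 1",
         call. = FALSE)
  }
  comps <- data.frame(
    name = c("lc", "intra", "extra"),
    weight = as.numeric(weights),
    R1 = c(1, 1, 1),
    R2 = c(10^1.5, 100, 100),
    Diso = c(1e-9, 1e-11, 1e-9),
    Ddelta = c(delta_from_ratio(100), 0, 0),
    theta = c(0, 0, 0),
    phi = c(0, 0, 0),
    stringsAsFactors = FALSE)
  structure(list(components = comps, lc_dispersion = lc_dispersion),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  print(phantom_log_table(x))
  invisible(x)
}

#' Ground-truth table in log10 analysis coordinates
#'
#' @param spec a `"phantom_spec"`.
#' @return Data frame with one row per component: `name, weight, logR1,
#'   logR2, logDiso, logratio` (all rates in 1/s, diffusivity in m^2/s,
#'   ratio dimensionless).
#' @export
phantom_log_table <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  c0 <- spec$components
  data.frame(name = c0$name, weight = c0$weight,
             logR1 = log10(c0$R1), logR2 = log10(c0$R2),
             logDiso = log10(c0$Diso),
             logratio = log10(ratio_from_delta(c0$Ddelta)),
             stringsAsFactors = FALSE)
}

#' Simulate a phantom acquisition
#'
#' Composes [synthesize()] and [add_noise()] for a phantom specification:
#' noise-free forward synthesis of the three-compartment signal over the
#' scheme, then Gaussian noise of amplitude `S0/snr`.  When the phantom has
#' a nonzero `lc_dispersion`, the liquid-crystal weight is split over
#' `n_dispersion` sub-components with polar angles drawn from a half-normal
#' jitter around +z.
#'
#' @param spec a `"phantom_spec"`.
#' @param scheme an `"acq_scheme"`.
#' @param snr signal-to-noise ratio; `Inf` for noise-free data.
#' @param seed integer seed driving both the dispersion draw (if any) and
#'   the noise.
#' @param S0 unattenuated amplitude (default 1).
#' @param n_dispersion number of orientation sub-components when
#'   `lc_dispersion > 0`.
#' @return A `"signal_dataset"`.
#' @export
simulate_experiment <- function(spec, scheme, snr = Inf, seed = NULL,
                                S0 = 1, n_dispersion = 32) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_scheme(scheme)
  seeds <- child_seeds(seed, 2)
  comps <- spec$components[component_columns]
  if (spec$lc_dispersion > 0) {
    lc <- comps[1, ]
    jit <- with_seed(if (is.null(seed)) NULL else seeds[1], {
      data.frame(theta = abs(rnorm(n_dispersion, 0, spec$lc_dispersion)),
                 phi = runif(n_dispersion, 0, 2 * pi))
    })
    lc_split <- lc[rep(1, n_dispersion), ]
    lc_split$weight <- lc$weight / n_dispersion
    lc_split$theta <- pmin(jit$theta, pi)
    lc_split$phi <- jit$phi
    comps <- rbind(lc_split, comps[-1, ])
  }
  ds <- synthesize(comps, scheme, S0 = S0)
  ds <- add_noise(ds, snr, seed = if (is.null(seed)) NULL else seeds[2])
  ds$seed <- seed
  ds
}

#' Read and write phantom specifications
#'
#' @param spec a `"phantom_spec"`.
#' @param path JSON file path.
#' @return `read_phantom` returns the `"phantom_spec"`; `write_phantom`
#'   returns `path` invisibly.
#' @export
write_phantom <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(
    list(components = spec$components, lc_dispersion = spec$lc_dispersion),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- as.data.frame(obj$components, stringsAsFactors = FALSE)
  validate_components(comps)
  structure(list(components = comps[c("name", component_columns)],
                 lc_dispersion = obj$lc_dispersion),
            class = "phantom_spec")
}
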