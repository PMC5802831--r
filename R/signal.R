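#' Component tables: discrete atoms of the 6D distribution
#'
#' A heterogeneous voxel is modelled as a collection of non-exchanging
#' Gaussian micro-domains, each carrying a signal fraction `weight`, the
#' relaxation rates `R1` and `R2` (1/s), and an axisymmetric diffusion
#' tensor given by `Diso` (m^2/s), normalized anisotropy `Ddelta`, and the
#' symmetry-axis angles `theta, phi` (radians).  Component sets are stored
#' as plain data frames with these seven columns.
#'
#' @param weight signal fraction at full relaxation, non-negative.
#' @param R1,R2 longitudinal/transverse relaxation rates, 1/s, positive.
#' @param Diso isotropic diffusivity, m^2/s, non-negative.
#' @param Ddelta normalized diffusion anisotropy in `[-0.5, 1]`.
#' @param theta,phi symmetry-axis polar/azimuthal angles, radians.
#' @return A one-row (or, for vector input, multi-row) component data frame.
#' @export
component <- function(weight, R1, R2, Diso, Ddelta = 0, theta = 0, phi = 0) {
  df <- data.frame(weight = weight, R1 = R1, R2 = R2, Diso = Diso,
                   Ddelta = Ddelta, theta = theta, phi = phi)
  validate_components(df)
}

component_columns <- c("weight", "R1", "R2", "Diso", "Ddelta", "theta", "phi")

validate_components <- function(df) {
  missing_cols <- setdiff(component_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("component table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  with(df, {
    if (any(weight < 0)) stop("component weights must be >= 0", call. = FALSE)
    if (any(R1 <= 0) || any(R2 <= 0)) {
      stop("relaxation rates must be positive", call. = FALSE)
    }
    if (any(Diso < 0)) stop("Diso must be non-negative", call. = FALSE)
    if (any(Ddelta < -0.5) || any(Ddelta > 1)) {
      stop("Ddelta must lie in [-0.5, 1]", call. = FALSE)
    }
  })
  df[component_columns]
}

# Point-by-component kernel matrix: K[i, k] in [0, 1] couples acquisition
# point i to component k.
kernel_matrix_impl <- function(scheme, comps) {
  cos_beta <- outer(cos(scheme$Theta), cos(comps$theta)) +
    cos(outer(scheme$Phi, comps$phi, "-")) *
      outer(sin(scheme$Theta), sin(comps$theta))
  bD <- outer(scheme$b, comps$Diso) *
    (1 + 2 * outer(scheme$b_delta, comps$Ddelta) * p2(cos_beta))
  r1w <- 1 - exp(-outer(scheme$tau_R, comps$R1))
  r2w <- exp(-outer(scheme$tau_e, comps$R2))
  r1w * r2w * exp(-bD)
}

#' Relaxation-diffusion signal kernel
#'
#' The per-point, per-component signal weighting
#' `K = [1 - exp(-tau_R * R1)] * exp(-tau_e * R2) * exp(-b:D)`,
#' the product of longitudinal recovery, transverse relaxation and Gaussian
#' diffusion attenuation.  The diffusion exponent `b:D` is the generalized
#' scalar product of the acquisition point's b-tensor and the component's
#' diffusion tensor (see [contract()]).  `kernel_value` evaluates one
#' (point, component) pair; `kernel_matrix` evaluates all pairs of a scheme
#' and a component table.
#'
#' @param point one acquisition point: a list or one-row data frame with
#'   fields `tau_R, tau_e, b, b_delta, Theta, Phi`.
#' @param comp one component: a list or one-row data frame with fields
#'   `R1, R2, Diso, Ddelta, theta, phi`.
#' @return `kernel_value`: a scalar in `[0, 1]`.
#' @export
kernel_value <- function(point, comp) {
  point <- as.list(point)
  comp <- as.list(comp)
  (1 - exp(-point$tau_R * comp$R1)) * exp(-point$tau_e * comp$R2) *
    exp(-bd_exponent(point$b, point$b_delta, point$Theta, point$Phi,
                     comp$Diso, comp$Ddelta, comp$theta, comp$phi))
}

#' @rdname kernel_value
#' @param scheme an `"acq_scheme"`.
#' @param comps a component data frame (see [component()]).
#' @return `kernel_matrix`: an `nrow(scheme) x nrow(comps)` matrix with
#'   entries in `[0, 1]`.
#' @export
kernel_matrix <- function(scheme, comps) {
  validate_scheme(scheme)
  comps <- validate_components(comps)
  kernel_matrix_impl(scheme, comps)
}

new_signal_dataset <- function(scheme, signal, S0, snr = NULL, seed = NULL) {
  stopifnot(length(signal) == nrow(scheme))
  structure(list(scheme = scheme, signal = as.numeric(signal), S0 = S0,
                 snr = snr, seed = seed),
            class = "signal_dataset")
}

#' Synthesize a noise-free multi-component signal
#'
#' Discrete forward model: `signal_i = S0 * sum_k weight_k * K(p_i, c_k)`.
#' The model is linear in the component weights and additive over
#' components.
#'
#' @param comps component data frame with at least one row.
#' @param scheme an `"acq_scheme"`.
#' @param S0 unattenuated signal amplitude (default 1).
#' @return A `"signal_dataset"`: list with fields `scheme`, `signal`, `S0`,
#'   `snr` (NULL for noise-free), `seed`.
#' @export
synthesize <- function(comps, scheme, S0 = 1) {
  comps <- validate_components(comps)
  if (nrow(comps) == 0) stop("need at least one component", call. = FALSE)
  K <- kernel_matrix_impl(scheme, comps)
  new_signal_dataset(scheme, S0 * drop(K %*% comps$weight), S0 = S0)
}

#' Add Gaussian measurement noise
#'
#' Adds iid zero-mean Gaussian noise of standard deviation `S0 / snr` to
#' every point, the noise model used for the simulation studies (real-valued
#' spectroscopic integrals, not Rician magnitude noise).
#'
#' @param ds a `"signal_dataset"`.
#' @param snr nominal signal-to-noise ratio (noise amplitude `S0/snr`);
#'   `Inf` returns the dataset unchanged.
#' @param seed integer seed for reproducible noise.
#' @return A `"signal_dataset"` with noisy `signal` and recorded `snr`/`seed`.
#' @export
add_noise <- function(ds, snr, seed = NULL) {
  stopifnot(inherits(ds, "signal_dataset"))
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  if (is.infinite(snr)) return(ds)
  noise <- with_seed(seed, rnorm(length(ds$signal), 0, ds$S0 / snr))
  new_signal_dataset(ds$scheme, ds$signal + noise, ds$S0, snr = snr,
                     seed = seed)
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d points, S0 = %g, snr = %s\n",
              length(x$signal), x$S0,
              if (is.null(x$snr)) "noise-free" else format(x$snr)))
  invisible(x)
}

#' Read and write signal datasets
#'
#' The signal is stored as CSV (`index, signal`) with a JSON metadata
#' sidecar `<path>.json` recording `S0`, `snr`, `seed` and the scheme
#' provenance.  The acquisition scheme itself travels in its own file (see
#' [write_scheme()]); `read_signal` re-attaches it.
#'
#' @param ds a `"signal_dataset"`.
#' @param path CSV file path for the signal column.
#' @param scheme the matching `"acq_scheme"` (for `read_signal`).
#' @return `read_signal` returns the `"signal_dataset"`; `write_signal`
#'   returns `path` invisibly.
#' @export
write_signal <- function(ds, path) {
  stopifnot(inherits(ds, "signal_dataset"))
  df <- data.frame(index = seq_along(ds$signal), signal = fmt_num(ds$signal))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(S0 = ds$S0, snr = ds$snr, seed = ds$seed,
               n = length(ds$signal),
               scheme_provenance = attr(ds$scheme, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path, scheme) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "signal") %in% names(df))) {
    stop(sprintf("signal file '%s' must have columns index, signal", path),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(S0 = 1, snr = NULL, seed = NULL)
  }
  if (nrow(df) != nrow(scheme)) {
    stop("signal length does not match the scheme", call. = FALSE)
  }
  snr <- meta$snr
  if (!is.null(snr) && !is.numeric(snr)) snr <- as.numeric(snr)
  new_signal_dataset(scheme, df$signal[order(df$index)],
                     S0 = if (is.null(meta$S0)) 1 else meta$S0,
                     snr = snr, seed = meta$seed)
}
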