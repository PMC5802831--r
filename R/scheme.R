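#' Default acquisition-space limits
#'
#' The 6D acquisition coordinate is `(tau_R, tau_e, b, b_delta, Theta, Phi)`:
#' repetition delay and echo time in seconds, b-value in s/m^2, b-tensor
#' anisotropy, and b-tensor axis angles in radians.  Random sampling is
#' uniform in the transformed coordinates
#' `(tau_R, log(tau_e), log(b), b_delta, cos(Theta), Phi)`.
#'
#' @param tau_R,tau_e,b,b_delta,cos_Theta,Phi length-2 numeric ranges.
#' @return A named list of ranges, class `"acq_limits"`.
#' @export
acq_limits <- function(tau_R = c(0.1, 5),
                       tau_e = c(1e-3, 0.1),
                       b = c(6.06e8, 1e11),
                       b_delta = c(-0.5, 1),
                       cos_Theta = c(-1, 1),
                       Phi = c(0, 2 * pi)) {
  lim <- list(tau_R = tau_R, tau_e = tau_e, b = b, b_delta = b_delta,
              cos_Theta = cos_Theta, Phi = Phi)
  for (nm in names(lim)) {
    v <- lim[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2]) {
      stop(sprintf("limit `%s` must be an ordered length-2 numeric range", nm),
           call. = FALSE)
    }
  }
  if (b_delta[1] < -0.5 || b_delta[2] > 1) {
    stop("b_delta limits must stay within [-0.5, 1]", call. = FALSE)
  }
  structure(lim, class = "acq_limits")
}

new_scheme <- function(df, provenance) {
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("acq_scheme", "data.frame"))
}

#' Generate a pseudo-random 6D acquisition scheme
#'
#' Sampling proceeds in three steps.  (1) Each point is drawn uniformly in
#' the transformed acquisition coordinates `(tau_R, log tau_e, log b,
#' b_delta, cos Theta, Phi)` within `limits`.  (2) The b-tensor anisotropy
#' is resampled as `b_delta <- b_delta * (b - b_min) / b`, shrinking the
#' accessible shape range at low b (the experimental motivation is gradient
#' spoiling at small b-values); this produces the characteristic funnel in
#' the `(b, b_delta)` plane.  (3) Four disjoint subsets of sizes
#' `round(biases * n)` are biased, in order, onto the linear shape line
#' `b_delta = (b - b_min)/b`, the spherical line `b_delta = 0`, the planar
#' line `b_delta = -0.5 (b - b_min)/b`, and a constant stability point
#' `(tau_R, tau_e, b)` at maximal signal.  The three shape lines hold the
#' points most sensitive to diffusion anisotropy; the stability points probe
#' instrument drift.  Stability points also get `b_delta = 0` (the step-2
#' rule applied at `b = b_min`), keeping the funnel constraint valid for the
#' whole scheme; their `(Theta, Phi)` keep their random draws.
#'
#' @param n number of acquisition points.
#' @param limits an [acq_limits()] object.
#' @param biases four fractions (of the total `n`) for the linear,
#'   spherical, planar and stability subsets, in that order; must sum to
#'   at most 1.
#' @param b_min b-value floor used by the resampling rule, s/m^2.
#' @param seed integer seed; the whole scheme is reproducible from it.
#' @return An `"acq_scheme"` data frame with columns `tau_R, tau_e, b,
#'   b_delta, Theta, Phi, bias` and a provenance attribute recording
#'   `seed, n, biases, limits, b_min`.
#' @examples
#' s <- generate_scheme(100, seed = 1)
#' table(s$bias)
#' @export
generate_scheme <- function(n,
                            limits = acq_limits(),
                            biases = c(linear = 0.30, spherical = 0.15,
                                       planar = 0.10, stability = 0.05),
                            b_min = 6.06e8,
                            seed = NULL) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (length(biases) != 4L || any(biases < 0)) {
    stop("`biases` must be four non-negative fractions", call. = FALSE)
  }
  if (sum(biases) > 1 + 1e-12) {
    stop("`biases` must sum to at most 1", call. = FALSE)
  }
  if (is.null(names(biases))) {
    names(biases) <- c("linear", "spherical", "planar", "stability")
  }
  sizes <- round(biases * n)
  if (n < sum(sizes)) stop("`n` too small for the requested biases", call. = FALSE)
  if (n < sum(biases > 0)) {
    stop("`n` smaller than the number of nonzero bias subsets", call. = FALSE)
  }

  df <- with_seed(seed, {
    tau_R <- runif(n, limits$tau_R[1], limits$tau_R[2])
    tau_e <- exp(runif(n, log(limits$tau_e[1]), log(limits$tau_e[2])))
    b <- exp(runif(n, log(limits$b[1]), log(limits$b[2])))
    b_delta <- runif(n, limits$b_delta[1], limits$b_delta[2])
    cos_Theta <- runif(n, limits$cos_Theta[1], limits$cos_Theta[2])
    Phi <- runif(n, limits$Phi[1], limits$Phi[2])

    # Step 2: anisotropy resampling towards zero at low b.
    b_delta <- b_delta * (b - b_min) / b

    # Step 3: consecutive biases on disjoint subsets of the total.
    bias <- rep("none", n)
    avail <- seq_len(n)
    pick <- function(k) {
      idx <- avail[sample.int(length(avail), k)]
      avail <<- setdiff(avail, idx)
      idx
    }
    i1 <- pick(sizes[1])
    b_delta[i1] <- (b[i1] - b_min) / b[i1]
    bias[i1] <- "linear"
    i2 <- pick(sizes[2])
    b_delta[i2] <- 0
    bias[i2] <- "spherical"
    i3 <- pick(sizes[3])
    b_delta[i3] <- -0.5 * (b[i3] - b_min) / b[i3]
    bias[i3] <- "planar"
    i4 <- pick(sizes[4])
    tau_R[i4] <- limits$tau_R[2]
    tau_e[i4] <- limits$tau_e[1]
    b[i4] <- b_min
    b_delta[i4] <- 0
    bias[i4] <- "stability"

    data.frame(tau_R = tau_R, tau_e = tau_e, b = b, b_delta = b_delta,
               Theta = acos(cos_Theta), Phi = Phi, bias = bias,
               stringsAsFactors = FALSE)
  })

  new_scheme(df, provenance = list(
    kind = "pseudo-random", seed = seed, n = n, biases = as.list(biases),
    limits = unclass(limits), b_min = b_min))
}

#' Generate a rectangular-grid acquisition scheme
#'
#' Traditional multidimensional Laplace sampling: the full Cartesian product
#' over per-dimension grids in the same transformed coordinates as
#' [generate_scheme()] (linear `tau_R`, logarithmic `tau_e` and `b`, linear
#' `b_delta`, `cos Theta` and `Phi`).  A dimension with a single level sits
#' at the midpoint of its transformed range; the periodic `Phi` grid omits
#' the duplicate endpoint.  No anisotropy resampling or bias is applied.
#'
#' @param n_per_dim integer vector of six grid sizes, ordered
#'   `(tau_R, tau_e, b, b_delta, cos_Theta, Phi)`.
#' @param limits an [acq_limits()] object.
#' @param cap maximum allowed total number of points.
#' @return An `"acq_scheme"` of `prod(n_per_dim)` points.
#' @export
generate_grid_scheme <- function(n_per_dim, limits = acq_limits(),
                                 cap = 1e5) {
  if (length(n_per_dim) != 6L || any(n_per_dim < 1)) {
    stop("`n_per_dim` must be six positive counts", call. = FALSE)
  }
  n_per_dim <- as.integer(n_per_dim)
  if (prod(n_per_dim) > cap) {
    stop(sprintf("grid of %d points exceeds cap %d",
                 prod(n_per_dim), as.integer(cap)), call. = FALSE)
  }
  phi_grid <- if (n_per_dim[6] == 1) {
    mean(limits$Phi)
  } else {
    seq(limits$Phi[1], limits$Phi[2], length.out = n_per_dim[6] + 1)[seq_len(n_per_dim[6])]
  }
  g <- expand.grid(
    tau_R = lin_seq(limits$tau_R, n_per_dim[1]),
    tau_e = exp(lin_seq(log(limits$tau_e), n_per_dim[2])),
    b = exp(lin_seq(log(limits$b), n_per_dim[3])),
    b_delta = lin_seq(limits$b_delta, n_per_dim[4]),
    cos_Theta = lin_seq(limits$cos_Theta, n_per_dim[5]),
    Phi = phi_grid,
    KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(tau_R = g$tau_R, tau_e = g$tau_e, b = g$b,
                   b_delta = g$b_delta, Theta = acos(g$cos_Theta),
                   Phi = g$Phi, bias = "none", stringsAsFactors = FALSE)
  new_scheme(df, provenance = list(
    kind = "grid", n_per_dim = n_per_dim, limits = unclass(limits)))
}

#' @export
print.acq_scheme <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<acq_scheme> %d points (%s)\n", nrow(x),
              if (is.null(pv$kind)) "unknown origin" else pv$kind))
  cat(sprintf("  bias subsets: %s\n",
              paste(sprintf("%s=%d", names(table(x$bias)), table(x$bias)),
                    collapse = ", ")))
  invisible(x)
}

scheme_columns <- c("tau_R", "tau_e", "b", "b_delta", "Theta", "Phi")

validate_scheme <- function(df, where = "scheme") {
  missing_cols <- setdiff(scheme_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing required column(s): %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  checks <- list(
    tau_R = function(v) v > 0,
    tau_e = function(v) v > 0,
    b = function(v) v > 0,
    b_delta = function(v) v >= -0.5 & v <= 1,
    Theta = function(v) v >= 0 & v <= pi,
    Phi = function(v) v >= 0 & v < 2 * pi)
  for (nm in names(checks)) {
    bad <- which(!checks[[nm]](df[[nm]]))
    if (length(bad)) {
      stop(sprintf("%s: column `%s` out of range at row %d (value %g)",
                   where, nm, bad[1], df[[nm]][bad[1]]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read and write acquisition schemes
#'
#' Schemes are stored as plain CSV with columns
#' `tau_R, tau_e, b, b_delta, Theta, Phi` (SI units, radians, '.' decimal)
#' plus an optional `bias` label column, alongside a JSON provenance sidecar
#' `<path>.json` holding the seed, size, bias fractions and range limits.
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces the scheme exactly.
#'
#' @param scheme an `"acq_scheme"`.
#' @param path CSV file path.
#' @return `read_scheme` returns the validated `"acq_scheme"`;
#'   `write_scheme` returns `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme, "scheme")
  df <- as.data.frame(scheme)
  out <- df
  for (nm in scheme_columns) out[[nm]] <- fmt_num(df[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  pv <- attr(scheme, "provenance")
  if (!is.null(pv)) {
    jsonlite::write_json(pv, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_scheme(df, where = sprintf("scheme file '%s'", path))
  if (is.null(df$bias)) df$bias <- "none"
  df <- df[c(scheme_columns, "bias")]
  sidecar <- paste0(path, ".json")
  pv <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(kind = "file", source = path)
  }
  new_scheme(df, provenance = pv)
}
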