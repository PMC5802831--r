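#' Axisymmetric second-order tensor
#'
#' Parameterizes a symmetric, axially symmetric 3x3 tensor by its isotropic
#' average `iso` (one third of the trace), normalized anisotropy `delta`
#' (dimensionless, in `[-0.5, 1]`), and the polar/azimuthal angles
#' `(theta, phi)` of its symmetry axis in the laboratory frame.  The axial
#' and radial eigenvalues are `iso * (1 + 2 * delta)` and
#' `iso * (1 - delta)`; positive semidefiniteness of the reconstructed
#' tensor is exactly the `delta` range above.
#'
#' The same parameterization serves both the diffusion tensor `D`
#' (`iso = Diso` in m^2/s) and the diffusion-encoding b-tensor
#' (`iso = b/3` in s/m^2, `delta = b_delta`).  Angles are stored in
#' radians; the main magnetic field defines the laboratory +z axis.
#'
#' @param iso isotropic average (trace/3), non-negative.
#' @param delta normalized anisotropy in `[-0.5, 1]`.
#' @param theta polar angle of the symmetry axis, radians in `[0, pi]`.
#' @param phi azimuthal angle, radians (wrapped into `[0, 2*pi)`).
#' @return An object of class `"axisym_tensor"`.
#' @examples
#' D <- axisym_tensor(1e-9, 0.5, theta = pi / 3, phi = pi / 4)
#' eigen(to_matrix(D))$values
#' @export
axisym_tensor <- function(iso, delta, theta = 0, phi = 0) {
  stopifnot_scalar(iso, "iso")
  stopifnot_scalar(delta, "delta")
  stopifnot_scalar(theta, "theta")
  stopifnot_scalar(phi, "phi")
  if (iso < 0) stop("`iso` must be non-negative", call. = FALSE)
  if (delta < -0.5 || delta > 1) {
    stop("`delta` must lie in [-0.5, 1] (positive semidefiniteness)",
         call. = FALSE)
  }
  if (theta < 0 || theta > pi) stop("`theta` must lie in [0, pi]", call. = FALSE)
  structure(list(iso = iso, delta = delta, theta = theta,
                 phi = phi %% (2 * pi)),
            class = "axisym_tensor")
}

#' @export
print.axisym_tensor <- function(x, ...) {
  cat(sprintf(
    "<axisym_tensor> iso = %.6g, delta = %.4g, theta = %.4g rad, phi = %.4g rad\n",
    x$iso, x$delta, x$theta, x$phi))
  invisible(x)
}

#' Build a b-tensor from its trace
#'
#' Convenience constructor using the trace parameterization common for
#' diffusion encoding: the returned tensor has `iso = b / 3` so that its
#' trace equals the b-value.
#'
#' @param b b-value (trace of the b-tensor), s/m^2.
#' @param b_delta b-tensor anisotropy in `[-0.5, 1]` (1 linear, 0 spherical,
#'   -0.5 planar).
#' @param Theta,Phi orientation angles of the b-tensor symmetry axis, radians.
#' @return An `"axisym_tensor"`.
#' @export
b_tensor <- function(b, b_delta, Theta = 0, Phi = 0) {
  axisym_tensor(b / 3, b_delta, Theta, Phi)
}

#' Reconstruct the explicit 3x3 matrix of an axisymmetric tensor
#'
#' @param t an [axisym_tensor()].
#' @return A symmetric positive semidefinite 3x3 matrix with trace
#'   `3 * iso`, eigenvalues `{iso*(1+2*delta), iso*(1-delta), iso*(1-delta)}`,
#'   and the eigenvector of the axial eigenvalue along
#'   `(cos(phi)*sin(theta), sin(phi)*sin(theta), cos(theta))`.
#' @export
to_matrix <- function(t) {
  stopifnot(inherits(t, "axisym_tensor"))
  l <- c(cos(t$phi) * sin(t$theta), sin(t$phi) * sin(t$theta), cos(t$theta))
  t$iso * (diag(3) + t$delta * (3 * tcrossprod(l) - diag(3)))
}

#' Convert axial/radial eigenvalues to (iso, delta)
#'
#' @param lambda_par axial eigenvalue, non-negative.
#' @param lambda_perp radial (doubly degenerate) eigenvalue, non-negative.
#' @return A named numeric vector `c(iso =, delta =)` with
#'   `iso = (lambda_par + 2*lambda_perp)/3` and
#'   `delta = (lambda_par - lambda_perp)/(3*iso)`.
#' @export
eigenvalues_to_iso_delta <- function(lambda_par, lambda_perp) {
  stopifnot_scalar(lambda_par, "lambda_par")
  stopifnot_scalar(lambda_perp, "lambda_perp")
  if (lambda_par < 0 || lambda_perp < 0) {
    stop("eigenvalues must be non-negative", call. = FALSE)
  }
  iso <- (lambda_par + 2 * lambda_perp) / 3
  if (iso == 0) {
    stop("degenerate input: both eigenvalues are zero, delta is undefined",
         call. = FALSE)
  }
  c(iso = iso, delta = (lambda_par - lambda_perp) / (3 * iso))
}

#' Second Legendre polynomial
#'
#' `P2(x) = (3 x^2 - 1) / 2`.  Governs the coupling between b- and D-tensor
#' shapes and their relative orientation.
#'
#' @param x numeric vector.
#' @return `(3 * x^2 - 1) / 2`, vectorized.
#' @export
p2 <- function(x) (3 * x^2 - 1) / 2

# Vectorized generalized scalar product b:D in closed form, used by the
# signal kernel.  `b` is the b-value (trace), all angles in radians.
bd_exponent <- function(b, b_delta, Theta, Phi, Diso, Ddelta, theta, phi) {
  cos_beta <- cos(Theta) * cos(theta) +
    cos(Phi - phi) * sin(Theta) * sin(theta)
  b * Diso * (1 + 2 * b_delta * Ddelta * p2(cos_beta))
}

#' Generalized scalar product of a b-tensor and a diffusion tensor
#'
#' Computes `b:D = sum_ij b_ij D_ij` in closed form for two axisymmetric
#' tensors: `b * Diso * (1 + 2 * b_delta * D_delta * P2(cos beta))`, where
#' `beta` is the arc angle between the two symmetry axes.  This is the
#' dimensionless diffusion attenuation exponent of the signal kernel.
#'
#' @param b an [axisym_tensor()] in the trace parameterization
#'   (`iso = b_value / 3`), e.g. from [b_tensor()].
#' @param D an [axisym_tensor()] for the diffusion tensor.
#' @return Scalar `b:D`, identical (to numerical precision) to
#'   `sum(to_matrix(b) * to_matrix(D))`.
#' @export
contract <- function(b, D) {
  stopifnot(inherits(b, "axisym_tensor"), inherits(D, "axisym_tensor"))
  bd_exponent(3 * b$iso, b$delta, b$theta, b$phi,
              D$iso, D$delta, D$theta, D$phi)
}

#' b-tensor anisotropy from the gradient-cone angle, and back
#'
#' Three gradient directions equally distributed on a cone of half-opening
#' `zeta` produce a b-tensor of anisotropy `b_delta = P2(cos(zeta))`:
#' linear encoding at `zeta = 0`, spherical (shape-insensitive) encoding at
#' the magic angle `acos(1/sqrt(3)) ~ 54.74` degrees, planar at 90 degrees.
#'
#' @param zeta cone half-angle in radians, in `[0, pi/2]`.
#' @return `bdelta_from_zeta`: the b-tensor anisotropy in `[-0.5, 1]`.
#' @export
bdelta_from_zeta <- function(zeta) {
  if (any(zeta < 0 | zeta > pi / 2)) {
    stop("`zeta` must lie in [0, pi/2]", call. = FALSE)
  }
  p2(cos(zeta))
}

#' @rdname bdelta_from_zeta
#' @param b_delta b-tensor anisotropy in `[-0.5, 1]`.
#' @return `zeta_from_bdelta`: the unique cone angle in `[0, pi/2]`
#'   (radians) with `P2(cos(zeta)) = b_delta`; monotone decreasing in
#'   `b_delta`.
#' @export
zeta_from_bdelta <- function(b_delta) {
  if (any(b_delta < -0.5 | b_delta > 1)) {
    stop("`b_delta` must lie in [-0.5, 1]", call. = FALSE)
  }
  acos(sqrt((2 * b_delta + 1) / 3))
}

#' Axial/radial diffusivity ratio from normalized anisotropy, and back
#'
#' `D_par / D_perp = (1 + 2 * Ddelta) / (1 - Ddelta)`.  The ratio is
#' positive for every tensor shape and is therefore the log-scalable
#' anisotropy coordinate used in projections and sub-volume statistics.
#'
#' @param Ddelta normalized anisotropy in `[-0.5, 1]`; the prolate limit
#'   `Ddelta = 1` yields an infinite ratio (returned as `Inf` with a
#'   warning).
#' @return `ratio_from_delta`: the eigenvalue ratio `D_par / D_perp >= 0`.
#' @export
ratio_from_delta <- function(Ddelta) {
  if (any(Ddelta < -0.5 | Ddelta > 1)) {
    stop("`Ddelta` must lie in [-0.5, 1]", call. = FALSE)
  }
  if (any(Ddelta == 1)) {
    warning("Ddelta = 1: D_par/D_perp is infinite (stick limit)")
  }
  (1 + 2 * Ddelta) / (1 - Ddelta)
}

#' @rdname ratio_from_delta
#' @param r eigenvalue ratio `D_par / D_perp`, non-negative; `Inf` (or any
#'   ratio mapping above `1 - eps`) clamps to `1 - eps` so log-scale grids
#'   can include the prolate limit.
#' @param eps clamp distance from the prolate limit (default `1e-9`).
#' @return `delta_from_ratio`: the normalized anisotropy `(r - 1) / (r + 2)`.
#' @export
delta_from_ratio <- function(r, eps = 1e-9) {
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  d <- ifelse(is.infinite(r), 1, (r - 1) / (r + 2))
  pmin(d, 1 - eps)
}

# Canonicalize a symmetry-axis orientation under antipodal symmetry:
# fold theta into [0, pi/2] (D is invariant under axis inversion).
canonical_axis <- function(theta, phi) {
  flip <- theta > pi / 2
  list(theta = ifelse(flip, pi - theta, theta),
       phi = ifelse(flip, (phi + pi) %% (2 * pi), phi %% (2 * pi)))
}
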