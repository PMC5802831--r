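# Shared fixtures: everything is generated in code at test time.

# Small pseudo-random scheme for forward-model tests.
tiny_scheme <- function(n = 40, seed = 101) {
  generate_scheme(n, seed = seed)
}

# Fast inversion configuration for module-level tests (the defaults are
# exercised by the acceptance suite).
tiny_config <- function(...) {
  inversion_config(n_candidates = 60, n_prolif = 6, n_mutate = 6, ...)
}

# Random component table within the default analysis box.
random_components <- function(k, seed = NULL) {
  with_seed_test(seed, {
    data.frame(weight = runif(k, 0.1, 1),
               R1 = 10^runif(k, -1, 1),
               R2 = 10^runif(k, 0, 3),
               Diso = 10^runif(k, -12, -8),
               Ddelta = runif(k, -0.5, 1),
               theta = acos(runif(k, -1, 1)),
               phi = runif(k, 0, 2 * pi))
  })
}

with_seed_test <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Build a solution ensemble directly from component tables (bypassing the
# inversion) for analysis-module tests.
make_ensemble <- function(comp_tables) {
  sols <- lapply(comp_tables, function(cc) {
    rdtd:::new_solution(cc, rnorm = 0, noise = 0,
                        residual_trace = numeric(0),
                        n_points = 0L, S0 = 1)
  })
  structure(list(solutions = sols, config = inversion_config(),
                 seed = NULL, n_boot = length(sols), data_hash = ""),
            class = "dtd_ensemble")
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Spherical angles of a unit vector.
vec_to_angles <- function(u) {
  list(theta = acos(pmin(pmax(u[3], -1), 1)),
       phi = atan2(u[2], u[1]) %% (2 * pi))
}

# Exhaustive disjoint partition of the clipped analysis box, used by the
# conservation checks.
partition_regions <- function() {
  full_r1 <- c(-1, 1); full_r2 <- c(0, 3)
  list(
    subvolume("slow", logR1 = full_r1, logR2 = full_r2,
              logDiso = c(-12, -10), logratio = c(-1, 3.2)),
    subvolume("fast_lowani", logR1 = full_r1, logR2 = full_r2,
              logDiso = c(-10, -8), logratio = c(-1, 0)),
    subvolume("fast_highani", logR1 = full_r1, logR2 = full_r2,
              logDiso = c(-10, -8), logratio = c(0, 3.2)))
}
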