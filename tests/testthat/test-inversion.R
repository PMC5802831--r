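# Monte Carlo NNLS inversion.

test_that("nnls recovers a known sparse non-negative combination", {
  s <- tiny_scheme(60, seed = 31)
  comps <- random_components(6, seed = 32)
  K <- kernel_matrix(s, comps)
  signal <- drop(K[, c(2, 5)] %*% c(0.3, 0.7))
  fit <- nnls_solve(K, signal)
  expect_true(all(fit$weights >= 0))
  expect_true(all(which(fit$weights > 1e-8) %in% c(2, 5)))
  expect_equal(fit$weights[2], 0.3, tolerance = 1e-6)
  expect_equal(fit$weights[5], 0.7, tolerance = 1e-6)
  expect_lt(fit$rnorm, 1e-8)
})

test_that("nnls handles degenerate inputs", {
  K <- matrix(c(1, 2, 3, 0, 0, 0), ncol = 2)
  expect_warning(fit <- nnls_solve(K, c(1, 2, 3)), "all-zero")
  expect_equal(fit$weights, c(1, 0))
  # Zero signal -> zero weights.
  s <- tiny_scheme(20)
  K2 <- kernel_matrix(s, random_components(4, seed = 1))
  fit0 <- nnls_solve(K2, rep(0, 20))
  expect_equal(fit0$weights, rep(0, 4))
  # Single column: clipped least-squares projection.
  a <- c(1, 2, 2)
  expect_equal(nnls_solve(cbind(a), 0.4 * a + c(0.01, -0.01, 0))$weights,
               sum(a * (0.4 * a + c(0.01, -0.01, 0))) / sum(a^2),
               tolerance = 1e-12)
  expect_equal(nnls_solve(cbind(a), -a)$weights, 0)
})

test_that("nnls solution is optimal among non-negative candidates", {
  with_seed_test(44, {
    K <- matrix(runif(300), 60, 5)
    signal <- runif(60)
    fit <- nnls_solve(K, signal)
    r0 <- sum((signal - drop(K %*% fit$weights))^2)
    for (i in 1:100) {
      w_alt <- pmax(fit$weights + rnorm(5, 0, 0.05), 0)
      r_alt <- sum((signal - drop(K %*% w_alt))^2)
      expect_gte(r_alt, r0 - 1e-12)
    }
    expect_equal(fit$rnorm, sqrt(r0), tolerance = 1e-10)
  })
})

test_that("noise-free single-component data is recovered accurately", {
  truth <- component(1, R1 = 10^0.3, R2 = 10^1.2, Diso = 10^-9.5,
                     Ddelta = 0.4, theta = 0.8, phi = 2.5)
  s <- generate_scheme(400, seed = 51)
  ds <- synthesize(truth, s)
  sol <- invert(ds, tiny_config(), seed = 52)
  cc <- sol$components
  expect_gt(sum(cc$weight), 0.98)
  # Loose absolute tolerances: this is a smoke test with the fast config;
  # the acceptance suite checks 0.05 log units with the default config.
  wm <- function(v) sum(cc$weight * v) / sum(cc$weight)
  expect_lt(abs(wm(log10(cc$R1)) - 0.3), 0.15)
  expect_lt(abs(wm(log10(cc$R2)) - 1.2), 0.15)
  expect_lt(abs(wm(log10(cc$Diso)) - (-9.5)), 0.15)
  expect_lt(abs(wm(cc$Ddelta) - 0.4), 0.15)
})

test_that("residual trace is monotone non-increasing", {
  spec <- yeast_lc_phantom()
  s <- generate_scheme(300, seed = 61)
  ds <- simulate_experiment(spec, s, snr = 120, seed = 62)
  sol <- invert(ds, tiny_config(), seed = 63)
  expect_true(all(diff(sol$residual_trace) <= 1e-10))
  expect_equal(sol$residual_norm, tail(sol$residual_trace, 1))
})

test_that("pure-noise data yields a near-empty solution", {
  s <- generate_scheme(300, seed = 71)
  noise_sd <- 0.01
  ds <- rdtd:::new_signal_dataset(
    s, with_seed_test(72, rnorm(300, 0, noise_sd)), S0 = 1, snr = NULL)
  sol <- invert(ds, tiny_config(), seed = 73)
  data_norm <- sqrt(sum(ds$signal^2))
  expect_gt(sol$residual_norm, 0.85 * data_norm)
  expect_lt(sum(sol$components$weight), 5 * noise_sd)
})

test_that("inversion is deterministic given its seed and weights are positive", {
  spec <- yeast_lc_phantom()
  s <- generate_scheme(250, seed = 81)
  ds <- simulate_experiment(spec, s, snr = 120, seed = 82)
  a <- invert(ds, tiny_config(), seed = 83)
  b <- invert(ds, tiny_config(), seed = 83)
  expect_identical(a$components, b$components)
  expect_true(all(a$components$weight > 0))
  expect_lte(nrow(a$components), tiny_config()$max_components)
})

test_that("total weight respects the sanity bound at the operating scale", {
  # The bound S0 * (1 + 3/snr) holds for a converged fit in expectation;
  # single realizations fluctuate around 1 by a few parts in a hundred, so
  # the property is checked on the mean over independent inversions.
  spec <- yeast_lc_phantom()
  s <- generate_scheme(1500, seed = 84)
  ds <- simulate_experiment(spec, s, snr = 120, seed = 85)
  tot <- sapply(86:90, function(sd_) {
    sum(invert(ds, inversion_config(), seed = sd_)$components$weight)
  })
  # The non-negative fit inflates the total weight by ~2-3% at SNR 120
  # (noise rectification); bound the inflation at twice the noise margin.
  expect_lte(mean(tot), 1 * (1 + 6 / 120))
  # And no realization strays far from the true total weight of 1.
  expect_true(all(abs(tot - 1) < 0.1))
})

test_that("noise estimate matches the injected noise level", {
  spec <- yeast_lc_phantom()
  s <- generate_scheme(1500, seed = 91)
  ds0 <- synthesize(spec$components[rdtd:::component_columns], s)
  ds <- add_noise(ds0, snr = 120, seed = 92)
  # Oracle solution: the true components themselves.
  sol_true <- rdtd:::new_solution(
    spec$components[rdtd:::component_columns], rnorm = 0, noise = NA,
    residual_trace = numeric(0), n_points = 1500, S0 = 1)
  est <- estimate_noise(sol_true, ds)
  expect_equal(est, 1 / 120, tolerance = 0.1)
  # Exact fit -> zero noise.
  expect_lt(estimate_noise(sol_true, ds0), 1e-12)
  # Scale equivariance.
  ds_scaled <- rdtd:::new_signal_dataset(ds$scheme, 3 * ds$signal, S0 = 3)
  expect_equal(estimate_noise(sol_true, ds_scaled), 3 * est,
               tolerance = 1e-10)
})

test_that("bootstrap ensembles are deterministic and well-formed", {
  spec <- yeast_lc_phantom()
  s <- generate_scheme(200, seed = 101)
  ds <- simulate_experiment(spec, s, snr = 120, seed = 102)
  cfg <- tiny_config()
  e1 <- bootstrap_invert(ds, cfg, n_boot = 3, seed = 103)
  e2 <- bootstrap_invert(ds, cfg, n_boot = 3, seed = 103)
  expect_equal(length(e1$solutions), 3)
  expect_identical(lapply(e1$solutions, `[[`, "components"),
                   lapply(e2$solutions, `[[`, "components"))
  # Replicates differ from each other (resampling + fresh candidate draws).
  expect_false(identical(e1$solutions[[1]]$components,
                         e1$solutions[[2]]$components))
  # n_boot = 1 is a single inversion of a resampled dataset.
  e3 <- bootstrap_invert(ds, cfg, n_boot = 1, seed = 104)
  expect_s3_class(e3$solutions[[1]], "dtd_solution")
  expect_equal(e3$solutions[[1]]$n_points, 200)
})

test_that("ensembles round-trip through JSON", {
  spec <- yeast_lc_phantom()
  s <- generate_scheme(150, seed = 111)
  ds <- simulate_experiment(spec, s, snr = 120, seed = 112)
  ens <- bootstrap_invert(ds, tiny_config(), n_boot = 2, seed = 113)
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$n_boot, 2)
  expect_equal(back$solutions[[1]]$components,
               ens$solutions[[1]]$components)
  expect_equal(back$config$n_candidates, ens$config$n_candidates)
})

test_that("shape-constrained mode draws only isotropic or prolate candidates", {
  cfg <- tiny_config(shape_constraint = "iso_prolate")
  cands <- with_seed_test(121, rdtd:::draw_candidates(500, cfg))
  expect_true(all(cands$Ddelta >= 0))
  expect_gt(mean(cands$Ddelta == 0), 0.3)
})
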