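# Projections, ODF, sub-volume statistics.

test_that("a delta component puts all mass in one bin before smoothing", {
  cc <- component(0.8, R1 = 1, R2 = 10^1.5, Diso = 1e-10, Ddelta = 0.5)
  ens <- make_ensemble(list(cc))
  m <- project_2d(ens, c("logDiso", "logratio"), grid = 32)
  expect_equal(sum(m$density > 0), 1)
  expect_equal(sum(m$density), 1)  # solution-normalized mass
  expect_equal(length(m$levels), 12)
  expect_equal(m$levels[1], 0.075 * max(m$density))
  expect_equal(m$levels[12], 0.90 * max(m$density))
})

test_that("1D marginals equal axis-sums of the 2D projection", {
  tables <- lapply(1:5, function(i) random_components(20, seed = 200 + i))
  ens <- make_ensemble(tables)
  for (axes in list(c("logDiso", "logratio"), c("logR1", "logR2"),
                    c("logDiso", "logR2"))) {
    m2 <- project_2d(ens, axes, grid = 48)
    m1x <- project_1d(ens, axes[1], grid = 48)
    m1y <- project_1d(ens, axes[2], grid = 48)
    expect_equal(rowSums(m2$density), m1x$density, tolerance = 1e-12)
    expect_equal(colSums(m2$density), m1y$density, tolerance = 1e-12)
  }
})

test_that("projection mass is conserved, also under display smoothing", {
  ens <- make_ensemble(lapply(1:3, function(i) random_components(15, seed = i)))
  m_raw <- project_2d(ens, grid = 64)
  expect_equal(sum(m_raw$density), 1, tolerance = 1e-12)
  m_smooth <- project_2d(ens, grid = 64, smoothing = 1)
  expect_equal(sum(m_smooth$density), 1, tolerance = 1e-10)
  expect_error(project_2d(ens, c("logDiso", "logDiso")), "distinct")
  expect_error(project_2d(ens, grid = 4), "at least 8")
})

test_that("ODF concentrates aligned prolate mass at the poles", {
  # Prolate components along +z and its antipode.
  cc1 <- component(c(0.5, 0.5), R1 = 1, R2 = 30, Diso = 1e-9,
                   Ddelta = 0.95, theta = c(0, pi), phi = c(0, 1))
  o <- odf(make_ensemble(list(cc1)), ratio_threshold = 10)
  expect_false(o$empty)
  expect_equal(o$total_mass, 1)
  top <- which.max(o$weights)
  expect_gt(abs(o$vertices[top, 3]), 0.999)
  expect_equal(sum(o$weights), 1)
  expect_equal(nrow(o$vertices), 642)  # icosahedron subdivided 3 times
})

test_that("isotropic-only ensembles yield a flagged empty ODF", {
  cc <- component(1, R1 = 1, R2 = 100, Diso = 1e-9, Ddelta = 0)
  o <- odf(make_ensemble(list(cc)))
  expect_true(o$empty)
  expect_equal(o$total_mass, 0)
})

test_that("ODF mass equals the supra-threshold weight", {
  cc <- rbind(
    component(0.25, R1 = 1, R2 = 30, Diso = 1e-9, Ddelta = 0.95,
              theta = 0.3, phi = 1),
    component(0.75, R1 = 1, R2 = 100, Diso = 1e-10, Ddelta = 0))
  o <- odf(make_ensemble(list(cc)), ratio_threshold = 10)
  expect_equal(o$total_mass, 0.25)
  expect_error(odf(make_ensemble(list(cc)), ratio_threshold = 0), "positive")
})

test_that("a region covering the whole space carries unit weight", {
  ens <- make_ensemble(lapply(1:4, function(i) random_components(10, seed = i)))
  whole <- list(all = subvolume("all"))
  st <- subvolume_stats(ens, whole)
  expect_equal(st$per_replicate$Pvol, rep(1, 4), tolerance = 1e-12)
})

test_that("single-component statistics are exact", {
  cc <- component(0.6, R1 = 10^0.4, R2 = 10^1.7, Diso = 10^-9.3,
                  Ddelta = 0.4)
  st <- subvolume_stats(make_ensemble(list(cc)),
                        list(box = subvolume("box")))
  expect_equal(st$per_replicate$E_logDiso, -9.3)
  expect_equal(st$per_replicate$E_logR1, 0.4)
  expect_equal(st$per_replicate$E_logR2, 1.7)
  expect_equal(st$per_replicate$E_logratio,
               log10(ratio_from_delta(0.4)))
  expect_equal(st$per_replicate$Pvol, 1)
})

test_that("region weights over an exhaustive partition sum to one", {
  ens <- make_ensemble(lapply(1:6, function(i) random_components(25, seed = 300 + i)))
  st <- subvolume_stats(ens, partition_regions())
  per <- st$per_replicate
  for (i in unique(per$replicate)) {
    expect_equal(sum(per$Pvol[per$replicate == i]), 1, tolerance = 1e-12)
  }
})

test_that("empty regions record missing means, overlap is warned", {
  cc <- component(1, R1 = 1, R2 = 100, Diso = 1e-9, Ddelta = 0)
  empty_reg <- subvolume("nowhere", logDiso = c(-12, -11.5))
  st <- subvolume_stats(make_ensemble(list(cc)), list(nowhere = empty_reg))
  expect_equal(st$per_replicate$Pvol, 0)
  expect_true(is.na(st$per_replicate$E_logDiso))
  overlapping <- list(
    a = subvolume("a", logDiso = c(-10, -8)),
    b = subvolume("b", logDiso = c(-9, -8.5)))
  expect_warning(subvolume_stats(make_ensemble(list(cc)), overlapping),
                 "overlap")
})

test_that("recovery error is zero for exact reconstructions and positive otherwise", {
  truth <- c(-9, -11)
  exact <- rbind(
    component(0.5, R1 = 1, R2 = 30, Diso = 1e-9),
    component(0.5, R1 = 1, R2 = 100, Diso = 1e-11))
  expect_equal(recovery_error(make_ensemble(list(exact)), truth), 0)
  off <- component(1, R1 = 1, R2 = 30, Diso = 10^-9.5)
  expect_equal(recovery_error(make_ensemble(list(off)), truth), 0.5)
})

test_that("projection maps export to CSV", {
  ens <- make_ensemble(list(random_components(10, seed = 7)))
  m <- project_2d(ens, grid = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_projection(m, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 256)
  expect_equal(sum(df$density), sum(m$density), tolerance = 1e-12)
})
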