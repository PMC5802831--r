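# Analysis axes are the four log10 coordinates of the non-orientation
# sub-space.  Anisotropy uses log10(D_par/D_perp) because, unlike Ddelta,
# the eigenvalue ratio is positive for every shape and log-scalable;
# values are clipped into the axis range (the oblate end maps to -Inf).

analysis_axes <- c("logR1", "logR2", "logDiso", "logratio")

default_axis_limits <- function(limits = analysis_limits()) {
  list(logR1 = limits$logR1, logR2 = limits$logR2,
       logDiso = limits$logDiso, logratio = c(-1, 3.2))
}

ok_solutions <- function(ens) {
  stopifnot(inherits(ens, "dtd_ensemble"))
  sols <- Filter(function(s) !inherits(s, "error"), ens$solutions)
  if (length(sols) == 0) stop("ensemble has no successful solutions", call. = FALSE)
  sols
}

# Pool components across solutions with per-solution weight normalization;
# each solution contributes total mass 1/n_solutions (empty solutions
# contribute nothing).
pooled_components <- function(ens, axis_limits = default_axis_limits()) {
  sols <- ok_solutions(ens)
  n_sol <- length(sols)
  rows <- lapply(seq_len(n_sol), function(i) {
    cc <- sols[[i]]$components
    if (nrow(cc) == 0) return(NULL)
    tot <- sum(cc$weight)
    data.frame(replicate = i, weight = cc$weight / tot / n_sol,
               logR1 = log10(cc$R1), logR2 = log10(cc$R2),
               logDiso = log10(cc$Diso),
               logratio = clamp(
                 suppressWarnings(log10(ratio_from_delta(cc$Ddelta))),
                 axis_limits$logratio),
               theta = cc$theta, phi = cc$phi)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

bin_index <- function(x, edges) {
  # Clip into the grid so no mass is lost at the box boundary.
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

# Separable Gaussian blur with a truncated, renormalized kernel
# (mass-conserving on the grid).  Display helper only.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    # Full convolution, then fold the overhanging tails back into the edge
    # bins so the total mass is conserved exactly.
    full <- numeric(n + 2L * half)
    for (j in seq_along(k)) {
      idx <- seq_len(n) + (j - 1L)
      full[idx] <- full[idx] + k[j] * v
    }
    out <- full[half + seq_len(n)]
    out[1] <- out[1] + sum(full[seq_len(half)])
    out[n] <- out[n] + sum(full[n + half + seq_len(half)])
    out
  }
  mat <- apply(mat, 2, smooth_1d)
  t(apply(mat, 1, smooth_1d))
}

#' 2D projection of a solution ensemble
#'
#' Pools all components across the bootstrap solutions (solution-normalized
#' weights, so each replicate contributes equal mass), deposits them on a
#' regular grid over two of the log10 analysis axes, and computes contour
#' levels linearly spaced from 7.5% to 90% of the map maximum.  Smoothing
#' is for display only; quantitative checks should use the raw map.
#'
#' @param ens a `"dtd_ensemble"`.
#' @param axes two distinct axis names among
#'   `"logR1", "logR2", "logDiso", "logratio"`.
#' @param grid number of bins per axis (>= 8).
#' @param smoothing isotropic Gaussian smoothing sigma in bins (0 = raw).
#' @param axis_limits named list of axis ranges (defaults span the
#'   analysis-space box).
#' @param n_levels number of contour levels.
#' @return A `"projection_map"`: axes, bin edges, density matrix
#'   (`grid x grid`, rows = first axis), and contour levels.
#' @export
project_2d <- function(ens, axes = c("logDiso", "logratio"), grid = 64,
                       smoothing = 0, axis_limits = default_axis_limits(),
                       n_levels = 12) {
  axes <- match.arg(axes, analysis_axes, several.ok = TRUE)
  if (length(axes) != 2L || axes[1] == axes[2]) {
    stop("`axes` must be two distinct axis names", call. = FALSE)
  }
  if (grid < 8) stop("`grid` must be at least 8", call. = FALSE)
  pc <- pooled_components(ens, axis_limits)
  xe <- seq(axis_limits[[axes[1]]][1], axis_limits[[axes[1]]][2],
            length.out = grid + 1)
  ye <- seq(axis_limits[[axes[2]]][1], axis_limits[[axes[2]]][2],
            length.out = grid + 1)
  dens <- matrix(0, grid, grid)
  ix <- bin_index(pc[[axes[1]]], xe)
  iy <- bin_index(pc[[axes[2]]], ye)
  for (r in seq_len(nrow(pc))) {
    dens[ix[r], iy[r]] <- dens[ix[r], iy[r]] + pc$weight[r]
  }
  dens <- gaussian_blur(dens, smoothing)
  levels <- seq(0.075, 0.90, length.out = n_levels) * max(dens)
  structure(list(axes = axes, x_edges = xe, y_edges = ye, density = dens,
                 levels = levels, smoothing = smoothing),
            class = "projection_map")
}

#' 1D marginal of a solution ensemble
#'
#' Same pooling and binning as [project_2d()]; the marginal over `axis`
#' equals the corresponding axis-sum of any 2D projection sharing that axis
#' and grid.
#'
#' @inheritParams project_2d
#' @param axis one axis name.
#' @return List with `axis`, `edges` and `density` (length `grid`).
#' @export
project_1d <- function(ens, axis = "logDiso", grid = 64,
                       axis_limits = default_axis_limits()) {
  axis <- match.arg(axis, analysis_axes)
  pc <- pooled_components(ens, axis_limits)
  edges <- seq(axis_limits[[axis]][1], axis_limits[[axis]][2],
               length.out = grid + 1)
  dens <- numeric(grid)
  ib <- bin_index(pc[[axis]], edges)
  for (r in seq_len(nrow(pc))) dens[ib[r]] <- dens[ib[r]] + pc$weight[r]
  list(axis = axis, edges = edges, density = dens)
}

# Geodesic sphere: subdivided icosahedron, vertices on the unit sphere.
icosphere <- function(subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- verts[i, ] + verts[j, ]
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    new_f <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      new_f[(4 * k - 3):(4 * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- new_f
  }
  list(vertices = v, faces = f)
}

#' Orientation distribution function of anisotropic components
#'
#' Deposits the (solution-normalized) weights of all components whose
#' eigenvalue ratio `D_par/D_perp` exceeds `ratio_threshold` onto the
#' nearest vertex of a geodesic spherical mesh, with antipodal
#' symmetrization (a symmetry axis is a line, not a direction).  Vertex
#' colors follow the `[|x|, |y|, |z|]` direction-encoding convention.
#'
#' @param ens a `"dtd_ensemble"`.
#' @param ratio_threshold minimum `D_par/D_perp` (default 10).
#' @param subdivisions icosahedron subdivision level (3 gives 642
#'   vertices).
#' @return A `"dtd_odf"`: `vertices` (unit vectors), `faces`, `weights`
#'   per vertex, `colors` (`n x 3` in `[0,1]`), `total_mass`, and `empty`
#'   (TRUE when no component passes the threshold — e.g. for a purely
#'   isotropic sample, where any recovered ODF is numerical noise).
#' @export
odf <- function(ens, ratio_threshold = 10, subdivisions = 3) {
  if (ratio_threshold <= 0) stop("`ratio_threshold` must be positive", call. = FALSE)
  mesh <- icosphere(subdivisions)
  pc <- pooled_components(ens)
  sel <- pc$logratio > log10(ratio_threshold)
  weights <- numeric(nrow(mesh$vertices))
  if (any(sel)) {
    pcs <- pc[sel, ]
    ax <- canonical_axis(pcs$theta, pcs$phi)
    u <- cbind(cos(ax$phi) * sin(ax$theta), sin(ax$phi) * sin(ax$theta),
               cos(ax$theta))
    # Antipodally symmetric nearest-vertex assignment.
    dots <- abs(u %*% t(mesh$vertices))
    nearest <- max.col(dots, ties.method = "first")
    for (r in seq_len(nrow(pcs))) {
      weights[nearest[r]] <- weights[nearest[r]] + pcs$weight[r]
    }
  }
  structure(list(vertices = mesh$vertices, faces = mesh$faces,
                 weights = weights,
                 colors = abs(mesh$vertices),
                 total_mass = sum(weights),
                 ratio_threshold = ratio_threshold,
                 empty = !any(sel)),
            class = "dtd_odf")
}

#' @export
print.dtd_odf <- function(x, ...) {
  cat(sprintf("<dtd_odf> %d vertices, total mass %.4g%s\n",
              nrow(x$vertices), x$total_mass,
              if (x$empty) " [EMPTY: no component above threshold]" else ""))
  invisible(x)
}

#' Axis-aligned sub-volume of the analysis space
#'
#' A box in the four non-orientation log10 coordinates; orientations are
#' unrestricted.
#'
#' @param name region label.
#' @param logR1,logR2,logDiso,logratio length-2 ranges.
#' @return A `"subvolume"` list.
#' @export
subvolume <- function(name, logR1 = c(-Inf, Inf), logR2 = c(-Inf, Inf),
                      logDiso = c(-Inf, Inf), logratio = c(-Inf, Inf)) {
  structure(list(name = name, logR1 = logR1, logR2 = logR2,
                 logDiso = logDiso, logratio = logratio),
            class = "subvolume")
}

#' Default sub-volumes of the yeast/liquid-crystal analysis space
#'
#' Four boxes matching the four populations seen in the phantom
#' reconstructions: (1) the prolate liquid crystal (`D_par/D_perp > 10`),
#' (2) fast isotropic (extracellular) water, (3) slow isotropic
#' (intracellular) water, and (4) the oblate low-b shape-undersampling
#' artefact.  The exact bounds are package choices; the boxes are disjoint.
#'
#' @return Named list of [subvolume()] objects.
#' @export
default_regions <- function() {
  list(
    anisotropic = subvolume("anisotropic", logR1 = c(-1, 1),
                            logR2 = c(0, 3), logDiso = c(-10, -8),
                            logratio = c(1, 3.2)),
    fast_isotropic = subvolume("fast_isotropic", logR1 = c(-1, 1),
                               logR2 = c(0, 3), logDiso = c(-10, -8),
                               logratio = c(-0.3, 1)),
    slow_isotropic = subvolume("slow_isotropic", logR1 = c(-1, 1),
                               logR2 = c(0, 3), logDiso = c(-12, -10),
                               logratio = c(-1, 3.2)),
    oblate_artefact = subvolume("oblate_artefact", logR1 = c(-1, 1),
                                logR2 = c(0, 3), logDiso = c(-10, -8),
                                logratio = c(-1, -0.3)))
}

in_region <- function(pc, region) {
  pc$logR1 >= region$logR1[1] & pc$logR1 <= region$logR1[2] &
    pc$logR2 >= region$logR2[1] & pc$logR2 <= region$logR2[2] &
    pc$logDiso >= region$logDiso[1] & pc$logDiso <= region$logDiso[2] &
    pc$logratio >= region$logratio[1] & pc$logratio <= region$logratio[2]
}

regions_overlap <- function(a, b) {
  all(vapply(analysis_axes, function(ax) {
    max(a[[ax]][1], b[[ax]][1]) < min(a[[ax]][2], b[[ax]][2])
  }, logical(1)))
}

#' Per-bootstrap sub-volume statistics
#'
#' For every bootstrap solution and every region: the solution-normalized
#' weight inside the region (`Pvol`) and the weight-weighted means of the
#' four log10 coordinates (`E_logR1`, `E_logR2`, `E_logDiso`,
#' `E_logratio`).  Means are recorded as missing when a replicate puts no
#' weight in the region.  A summary table reports the across-replicate mean
#' and standard deviation of each statistic.
#'
#' @param ens a `"dtd_ensemble"`.
#' @param regions named list of [subvolume()] boxes (default
#'   [default_regions()]); overlapping regions are permitted but warned
#'   about.
#' @return A `"subvolume_stats"`: list with `per_replicate` (long data
#'   frame), `summary` (one row per region) and the regions used.
#' @export
subvolume_stats <- function(ens, regions = default_regions()) {
  if (is.null(names(regions))) {
    names(regions) <- vapply(regions, `[[`, "", "name")
  }
  if (length(regions) > 1) {
    for (i in seq_len(length(regions) - 1)) {
      for (j in seq((i + 1), length(regions))) {
        if (regions_overlap(regions[[i]], regions[[j]])) {
          warning(sprintf("regions '%s' and '%s' overlap",
                          names(regions)[i], names(regions)[j]))
        }
      }
    }
  }
  pc <- pooled_components(ens)
  n_rep <- length(unique(pc$replicate))
  # Undo the 1/n_sol pooling factor: per-replicate weights are normalized
  # within each solution.
  rows <- list()
  for (rn in names(regions)) {
    reg <- regions[[rn]]
    for (i in sort(unique(pc$replicate))) {
      sub <- pc[pc$replicate == i, ]
      w <- sub$weight / sum(sub$weight)
      inside <- in_region(sub, reg)
      pvol <- sum(w[inside])
      if (pvol > 0) {
        wm <- function(v) sum(w[inside] * v[inside]) / pvol
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, replicate = i, Pvol = pvol,
          E_logR1 = wm(sub$logR1), E_logR2 = wm(sub$logR2),
          E_logDiso = wm(sub$logDiso), E_logratio = wm(sub$logratio))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rn, replicate = i, Pvol = 0,
          E_logR1 = NA_real_, E_logR2 = NA_real_,
          E_logDiso = NA_real_, E_logratio = NA_real_)
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(regions), function(rn) {
    sub <- per_rep[per_rep$region == rn, ]
    stat_cols <- c("Pvol", "E_logR1", "E_logR2", "E_logDiso", "E_logratio")
    means <- vapply(stat_cols, function(cl) mean(sub[[cl]], na.rm = TRUE), 0)
    sds <- vapply(stat_cols, function(cl) sd(sub[[cl]], na.rm = TRUE), 0)
    out <- data.frame(region = rn, n_defined = sum(!is.na(sub$E_logDiso)))
    for (cl in stat_cols) {
      out[[paste0(cl, "_mean")]] <- means[[cl]]
      out[[paste0(cl, "_sd")]] <- sds[[cl]]
    }
    out
  }))
  structure(list(per_replicate = per_rep, summary = summ,
                 regions = regions, n_replicates = n_rep),
            class = "subvolume_stats")
}

#' @export
print.subvolume_stats <- function(x, ...) {
  cat(sprintf("<subvolume_stats> %d regions x %d replicates\n",
              length(x$regions), x$n_replicates))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Weight-transport recovery error in log10 Diso
#'
#' Per bootstrap replicate, the normalized-weight-weighted mean distance of
#' every recovered component to the nearest ground-truth `log10 Diso`
#' value.  A scalar figure of merit for recovery quality: zero for a
#' perfect reconstruction, larger when components land between or away from
#' the true populations.
#'
#' @param ens a `"dtd_ensemble"`.
#' @param truth_logDiso numeric vector of ground-truth `log10 Diso` values.
#' @return Numeric vector, one error per successful replicate.
#' @export
recovery_error <- function(ens, truth_logDiso) {
  pc <- pooled_components(ens)
  err <- vapply(sort(unique(pc$replicate)), function(i) {
    sub <- pc[pc$replicate == i, ]
    w <- sub$weight / sum(sub$weight)
    d <- vapply(sub$logDiso,
                function(x) min(abs(x - truth_logDiso)), 0)
    sum(w * d)
  }, 0)
  err
}

#' Export a projection map as CSV
#'
#' Long-format grid export: one row per bin with the two bin centers and
#' the density value.
#'
#' @param map a `"projection_map"`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(map, path) {
  stopifnot(inherits(map, "projection_map"))
  xc <- (head(map$x_edges, -1) + map$x_edges[-1]) / 2
  yc <- (head(map$y_edges, -1) + map$y_edges[-1]) / 2
  g <- expand.grid(x = seq_along(xc), y = seq_along(yc))
  df <- data.frame(g$x, g$y, xc[g$x], yc[g$y],
                   map$density[cbind(g$x, g$y)])
  names(df) <- c("ix", "iy", map$axes[1], map$axes[2], "density")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
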