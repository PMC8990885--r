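# Observables and QA: depth/lateral profiles, Bragg-peak finding,
# spread-out-Bragg-peak weight optimisation and gamma-index comparison.

#' One-dimensional dose profile
#'
#' @param x Strictly increasing coordinate grid in cm (bin centres).
#' @param value Non-negative profile values.
#' @param axis Axis label.
#' @param integration Description of the reduction that produced it.
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(x, value, axis = "z", integration = "") {
  if (any(diff(x) <= 0)) {
    stop(cionmc_error("profile grid must be strictly increasing", "geometry"))
  }
  if (any(value < 0)) {
    stop(cionmc_error("profile values must be non-negative", "geometry"))
  }
  structure(list(x = x, value = value, axis = axis,
                 integration = integration), class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %s: %d bins over [%g, %g] cm, max %.3g\n",
              x$axis, length(x$x), min(x$x), max(x$x), max(x$value)))
  invisible(x)
}

#' @export
plot.profile1d <- function(x, ...) {
  graphics::plot(x$x, x$value, type = "l",
                 xlab = sprintf("%s [cm]", x$axis),
                 ylab = x$integration, ...)
  invisible(x)
}

#' Depth-dose profile
#'
#' Transverse-integrated dose versus depth along the beam axis:
#' `P(z) = sum_xy D(x, y, z) dx dy`, so that the profile integrated over
#' depth equals the dose-volume integral of the grid.
#'
#' @param dose A `dose_grid`.
#' @param axis Beam axis (1, 2 or 3; default 3 = z).
#' @return A [profile1d()] in Gy cm^2 per primary.
#' @export
depth_dose <- function(dose, axis = 3) {
  if (!axis %in% 1:3) {
    stop(cionmc_error("beam axis must be 1, 2 or 3", "configuration"))
  }
  tr <- setdiff(1:3, axis)
  val <- apply(dose$dose, axis, sum) * prod(dose$voxel[tr])
  z <- dose$origin[axis] + (seq_len(dose$dims[axis]) - 0.5) * dose$voxel[axis]
  profile1d(z, val, axis = c("x", "y", "z")[axis],
            integration = "transverse-integrated dose [Gy cm^2 / primary]")
}

#' Lateral dose profile at a given depth
#'
#' One-dimensional transverse profile at the depth slice nearest to
#' `depth`, integrated over the remaining transverse axis; its integral
#' equals the depth-dose value of that slice.
#'
#' @param dose A `dose_grid`.
#' @param depth Depth in cm along the beam axis.
#' @param axis Transverse axis to resolve (default 1 = x).
#' @param beam_axis Beam axis (default 3 = z).
#' @return A [profile1d()] in Gy cm per primary.
#' @export
lateral_profile <- function(dose, depth, axis = 1, beam_axis = 3) {
  zmin <- dose$origin[beam_axis]
  zmax <- zmin + dose$dims[beam_axis] * dose$voxel[beam_axis]
  if (depth < zmin || depth > zmax) {
    stop(cionmc_error("depth outside the grid", "range"))
  }
  k <- min(max(1L, 1L + floor((depth - zmin) / dose$voxel[beam_axis])),
           dose$dims[beam_axis])
  other <- setdiff(1:3, c(axis, beam_axis))
  sl <- switch(beam_axis,
               dose$dose[k, , ], dose$dose[, k, ], dose$dose[, , k])
  # sl is now 2D over the two non-beam axes in ascending axis order
  ax2 <- sort(setdiff(1:3, beam_axis))
  margin <- match(axis, ax2)
  val <- apply(sl, margin, sum) * dose$voxel[other]
  x <- dose$origin[axis] + (seq_len(dose$dims[axis]) - 0.5) * dose$voxel[axis]
  profile1d(x, val, axis = c("x", "y", "z")[axis],
            integration = "line-integrated dose [Gy cm / primary]")
}

#' Locate the Bragg peak of a depth-dose profile
#'
#' Returns the coordinate of the global maximum with parabolic
#' refinement over the three bins around it.  Flat profiles and
#' profiles whose maximum sits on the boundary (monotone profiles) are
#' rejected as ambiguous.
#'
#' @param profile A [profile1d()].
#' @return Peak coordinate in cm.
#' @export
find_bragg_peak <- function(profile) {
  y <- profile$value
  if (length(y) < 3 || diff(range(y)) == 0) {
    stop(cionmc_error("profile has no unambiguous maximum", "ambiguity"))
  }
  m <- which.max(y)
  if (m == 1 || m == length(y)) {
    stop(cionmc_error("profile maximum on the boundary (monotone profile?)",
                      "ambiguity"))
  }
  h <- profile$x[m + 1] - profile$x[m]
  denom <- y[m - 1] - 2 * y[m] + y[m + 1]
  off <- if (denom < 0) 0.5 * h * (y[m - 1] - y[m + 1]) / denom else 0
  profile$x[m] + off
}

#' Optimise spread-out Bragg peak layer weights
#'
#' Solves a non-negative least-squares problem for the per-layer
#' primary weights so that the weighted sum of the mono-energetic
#' depth-dose kernels is flat at the prescribed dose over the target
#' depth interval.
#'
#' @param kernels Matrix (depth bins x layers) of per-primary depth-dose
#'   kernels, or a list of [profile1d()] on a common grid.
#' @param energies Layer energies in MeV/u, strictly increasing.
#' @param z Depth grid in cm (taken from the profiles if `kernels` is a
#'   list).
#' @param target Depth interval `c(z1, z2)` in cm.
#' @param dose Prescribed dose in Gy at the plateau.
#' @return An object of class `sobp_plan`: energies, weights (primaries
#'   per layer), the predicted summed profile and the achieved plateau
#'   flatness (max relative deviation over the target interval).
#' @export
build_sobp <- function(kernels, energies, z = NULL, target, dose) {
  if (is.list(kernels) && !is.matrix(kernels)) {
    z <- kernels[[1]]$x
    kernels <- vapply(kernels, function(p) p$value, numeric(length(z)))
  }
  if (is.null(z)) stop(cionmc_error("depth grid z is required", "configuration"))
  if (length(energies) != ncol(kernels)) {
    stop(cionmc_error("one energy per kernel column required", "configuration"))
  }
  if (length(energies) > 1 && any(diff(energies) <= 0)) {
    stop(cionmc_error("energies must be strictly increasing", "configuration"))
  }
  # feasibility: the deepest layer must reach the distal target edge
  deepest <- which.max(energies)
  peak_deep <- z[which.max(kernels[, deepest])]
  if (peak_deep < target[2] - 2 * (z[2] - z[1])) {
    stop(cionmc_error("target extends beyond the range of the deepest layer",
                      "infeasibility"))
  }
  rows <- which(z >= target[1] & z <= target[2])
  if (length(rows) == 0) {
    stop(cionmc_error("no depth bins inside the target interval",
                      "configuration"))
  }
  A <- kernels[rows, , drop = FALSE]
  b <- rep(dose, length(rows))
  w <- if (ncol(A) == 1) {
    max(0, sum(A * b) / sum(A * A))
  } else {
    pracma::lsqnonneg(A, b)$x
  }
  pred <- as.numeric(kernels %*% w)
  flat <- max(abs(pred[rows] - dose)) / dose
  structure(list(energies = energies, weights = w, z = z,
                 profile = profile1d(z, pred, "z", "SOBP depth dose [Gy]"),
                 target = target, dose = dose, flatness = flat),
            class = "sobp_plan")
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf("<sobp_plan> %d layers %g-%g MeV/u; plateau %g-%g cm @ %g Gy\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$target[1], x$target[2], x$dose))
  cat(sprintf("  plateau flatness: %.2f%%\n", 100 * x$flatness))
  invisible(x)
}

# integer-shifted copy of a 3D array, NA outside
shift_array <- function(a, s) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    if (s[i] >= 0) {
      if (s[i] >= d[i]) return(out)
      src[[i]] <- (1 + s[i]):d[i]
      dst[[i]] <- 1:(d[i] - s[i])
    } else {
      if (-s[i] >= d[i]) return(out)
      src[[i]] <- 1:(d[i] + s[i])
      dst[[i]] <- (1 - s[i]):d[i]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Gamma-index dose comparison
#'
#' Standard gamma evaluation: for every reference voxel the minimum of
#' `sqrt((dose difference / (dd% of ref max))^2 + (distance / dta)^2)`
#' over a search sphere of radius `search_factor * dta` around the
#' voxel, with sub-voxel trilinear interpolation of the evaluated
#' distribution on a lattice refined by `subdivision` per axis.  The
#' dose-difference criterion is global (normalized to the reference
#' maximum); voxels below the low-dose cutoff are excluded from the
#' pass-rate.
#'
#' @param ref,eval Two `dose_grid`s on identical geometry.
#' @param dta Distance-to-agreement criterion in mm.
#' @param dd Dose-difference criterion in percent of the reference
#'   maximum.
#' @param cutoff Low-dose cutoff in percent of the reference maximum.
#' @param subdivision Sub-voxel refinement factor per axis (1 = voxel
#'   centres only).
#' @param search_factor Search radius in units of `dta`.
#' @return An object of class `gamma_result`: the per-voxel gamma
#'   array, pass rate (%), mean and max gamma over evaluated voxels and
#'   the parameters.
#' @examples
#' ph <- make_water_phantom(c(2, 2, 2), 5)
#' d <- dose_grid(ph, array(1, ph$dims))
#' gamma_index(d, d)$pass_rate  # 100
#' @export
gamma_index <- function(ref, eval, dta = 2, dd = 3, cutoff = 5,
                        subdivision = 3, search_factor = 3) {
  if (!all(ref$dims == eval$dims) || !all(abs(ref$voxel - eval$voxel) < 1e-9) ||
      !all(abs(ref$origin - eval$origin) < 1e-9)) {
    stop(cionmc_error("reference and evaluated grids do not overlap",
                      "geometry"))
  }
  dmax <- max(ref$dose)
  if (dmax <= 0) stop(cionmc_error("reference dose is empty", "geometry"))
  denom <- dd / 100 * dmax
  vox_mm <- ref$voxel * 10
  delta <- vox_mm / subdivision
  rad <- search_factor * dta
  ks <- lapply(1:3, function(i) {
    k <- floor(rad / delta[i])
    (-k):k
  })
  offs <- expand.grid(kx = ks[[1]], ky = ks[[2]], kz = ks[[3]])
  r2 <- (offs$kx * delta[1])^2 + (offs$ky * delta[2])^2 +
    (offs$kz * delta[3])^2
  keep <- r2 <= rad^2
  offs <- offs[keep, ]
  r2 <- r2[keep]
  ord <- order(r2)
  offs <- offs[ord, ]
  r2 <- r2[ord]

  g2 <- array(Inf, ref$dims)
  for (q in seq_len(nrow(offs))) {
    spatial <- r2[q] / dta^2
    if (all(g2 <= spatial)) break   # no voxel can still improve
    k <- c(offs$kx[q], offs$ky[q], offs$kz[q])
    b <- floor(k / subdivision)
    f <- k / subdivision - b
    shifted <- 0
    wsum <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
      if (w == 0) next
      shifted <- shifted + w * shift_array(eval$dose, b + c(cx, cy, cz))
      wsum <- wsum + w
    }
    cand <- ((shifted - ref$dose) / denom)^2 + spatial
    g2 <- pmin(g2, cand, na.rm = TRUE)
  }
  gam <- sqrt(g2)
  mask <- ref$dose >= cutoff / 100 * dmax
  structure(list(
    gamma = gam,
    pass_rate = 100 * mean(gam[mask] <= 1),
    mean_gamma = mean(gam[mask]),
    max_gamma = max(gam[mask]),
    params = c(dta = dta, dd = dd, cutoff = cutoff,
               subdivision = subdivision),
    n_evaluated = sum(mask)
  ), class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("<gamma_result> %gmm/%g%% (cutoff %g%%): pass %.2f%%, mean %.3f, max %.3f (%d voxels)\n",
              p[["dta"]], p[["dd"]], p[["cutoff"]], x$pass_rate,
              x$mean_gamma, x$max_gamma, x$n_evaluated))
  invisible(x)
}
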