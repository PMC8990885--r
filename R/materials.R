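#' Define a material from its elemental mass fractions
#'
#' A material carries everything the transport and nuclear models need:
#' mass fractions `w_i`, mass numbers `A_i`, atomic numbers `Z_i` and the
#' relative number fractions `n_i` (occurrences per formula unit, up to a
#' constant) used to weight per-element nuclear cross-sections.  The
#' electronic quantities `Z/A` and mean excitation energy `I` and the
#' radiation length `X0` are derived from the composition.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (> 0).
#' @param composition Data frame with columns `element` (symbol) and `w`
#'   (mass fraction); mass fractions must sum to 1 within 1e-6.
#' @param I_eV Mean excitation energy in eV.  Default `NULL` applies the
#'   Bragg additivity rule on the elemental values.
#' @return An object of class `material`.
#' @examples
#' water_material()
#' material("PMMA-ish", 1.19,
#'          data.frame(element = c("H", "C", "O"), w = c(0.081, 0.600, 0.319)))
#' @export
material <- function(name, density, composition, I_eV = NULL) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0) {
    stop(cionmc_error("material density must be a single positive number",
                      "configuration"))
  }
  if (!is.data.frame(composition) || nrow(composition) < 1 ||
      !all(c("element", "w") %in% names(composition))) {
    stop(cionmc_error("composition needs columns 'element' and 'w'",
                      "configuration"))
  }
  i <- match(composition$element, .elements$symbol)
  if (anyNA(i)) {
    stop(cionmc_error(sprintf("unknown element(s): %s",
                              paste(composition$element[is.na(i)], collapse = ", ")),
                      "configuration"))
  }
  w <- composition$w
  if (abs(sum(w) - 1) > 1e-6) {
    stop(cionmc_error("mass fractions must sum to 1 within 1e-6", "configuration"))
  }
  comp <- data.frame(
    element = composition$element,
    w = w,
    A = .elements$A[i],
    Z = .elements$Z[i],
    stringsAsFactors = FALSE
  )
  # number fractions proportional to w/A, normalized to sum 1
  n <- comp$w / comp$A
  comp$n <- n / sum(n)
  z_over_a <- sum(comp$w * comp$Z / comp$A)
  if (is.null(I_eV)) {
    # Bragg additivity on ln(I), weighted by electron density contributions
    I_eV <- exp(sum(comp$w * comp$Z / comp$A * log(.elements$I_eV[i])) / z_over_a)
  }
  # radiation length via the compact Dahl form, combined by mass fraction
  x0_el <- 716.4 * comp$A / (comp$Z * (comp$Z + 1) * log(287 / sqrt(comp$Z)))
  x0 <- 1 / sum(comp$w / x0_el)   # g/cm^2
  structure(
    list(name = name, density = density, composition = comp,
         z_over_a = z_over_a, I_eV = I_eV, X0 = x0),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %g g/cm^3, Z/A = %.4f, I = %.1f eV)\n",
              x$name, x$density, x$z_over_a, x$I_eV))
  print(x$composition, row.names = FALSE)
  invisible(x)
}

#' Liquid water
#'
#' Water with 2:1 H:O stoichiometry (mass fractions 0.1119/0.8881),
#' density 1 g/cm^3 and mean excitation energy 78 eV.
#'
#' @return A `material` object.
#' @export
water_material <- function() {
  material("water", 1.0,
           data.frame(element = c("H", "O"), w = c(0.1119, 0.8881)),
           I_eV = 78)
}

#' Construct a voxel grid
#'
#' Coordinates are right-handed with the beam default along +z and the
#' world origin at the centre of the phantom entrance face, so the grid
#' corner sits at `(-Lx/2, -Ly/2, 0)`.  Voxels are half-open intervals
#' `[edge, next edge)`; R-side indices are 1-based.
#'
#' @param dims_n Integer triple of voxel counts.
#' @param voxel_cm Numeric triple of voxel sizes in cm (> 0).
#' @param density Numeric array of per-voxel densities in g/cm^3, or a
#'   scalar for a uniform grid.
#' @param materials List of `material` objects (usually length 1).
#' @param material_index Optional integer array mapping voxels to
#'   `materials`; `NULL` means every voxel is `materials[[1]]`.
#' @param origin Grid corner in cm; default centres the entrance face.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims_n, voxel_cm, density, materials,
                       material_index = NULL, origin = NULL) {
  dims_n <- as.integer(dims_n)
  if (length(dims_n) != 3 || any(dims_n < 1)) {
    stop(cionmc_error("dims_n must be three positive integers", "geometry"))
  }
  if (length(voxel_cm) != 3 || any(voxel_cm <= 0)) {
    stop(cionmc_error("voxel sizes must be positive", "geometry"))
  }
  if (length(density) == 1) density <- array(density, dim = dims_n)
  if (!all(dim(density) == dims_n)) {
    stop(cionmc_error("density array does not match grid dimensions", "geometry"))
  }
  if (any(density < 0)) {
    stop(cionmc_error("densities must be non-negative", "geometry"))
  }
  if (is.null(origin)) {
    origin <- c(-dims_n[1] * voxel_cm[1] / 2, -dims_n[2] * voxel_cm[2] / 2, 0)
  }
  structure(
    list(origin = origin, voxel = as.numeric(voxel_cm), dims = dims_n,
         density = density, materials = materials,
         material_index = material_index),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %g x %g x %g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              10 * x$voxel[1], 10 * x$voxel[2], 10 * x$voxel[3]))
  cat(sprintf("  extent: %g x %g x %g cm, origin (%g, %g, %g) cm\n",
              x$dims[1] * x$voxel[1], x$dims[2] * x$voxel[2],
              x$dims[3] * x$voxel[3], x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  material: %s, density %g..%g g/cm^3\n",
              x$materials[[1]]$name, min(x$density), max(x$density)))
  invisible(x)
}

#' Build a uniform water phantom
#'
#' @param dims Phantom extent in cm (x, y, z triple).
#' @param voxel Voxel size in mm (triple or scalar).
#' @return A `voxel_grid` filled with water.
#' @examples
#' ph <- make_water_phantom(c(4, 4, 10), 2)
#' @export
make_water_phantom <- function(dims = c(10, 10, 40), voxel = c(0.5, 0.5, 0.5)) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  if (any(dims <= 0) || any(voxel <= 0)) {
    stop(cionmc_error("phantom dimensions and voxel sizes must be positive",
                      "geometry"))
  }
  voxel_cm <- voxel / 10
  n <- dims / voxel_cm
  if (any(abs(n - round(n)) > 1e-6)) {
    stop(cionmc_error("phantom dimensions must be divisible by the voxel size",
                      "geometry"))
  }
  voxel_grid(round(n), voxel_cm, 1.0, list(water_material()))
}

#' World coordinates of voxel centres
#'
#' @param grid A `voxel_grid`.
#' @param index Integer matrix (n x 3) or triple of 1-based voxel indices.
#' @return Matrix of centre coordinates in cm.
#' @export
voxel_center <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index - 0.5, 2, grid$voxel, "*"), 2, grid$origin, "+")
}

#' Voxel index containing a world coordinate
#'
#' Inverse of [voxel_center()] for points inside the grid; voxels are
#' half-open `[edge, next edge)`.
#'
#' @param grid A `voxel_grid`.
#' @param xyz Numeric matrix (n x 3) or triple of world coordinates in cm.
#' @return Integer matrix of 1-based indices; rows outside the grid are NA.
#' @export
voxel_index <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  idx <- floor(sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$voxel, "/")) + 1
  bad <- rowSums(idx < 1 | sweep(idx, 2, grid$dims, ">")) > 0
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

#' CT-number to density calibration
#'
#' Piecewise-linear calibration knots mapping Hounsfield units to mass
#' density.  The default two-knot curve maps air (-1000 HU) to
#' 0.00121 g/cm^3 and water (0 HU) to 1 g/cm^3.
#'
#' @param hu Strictly increasing HU knots.
#' @param density Non-negative, non-decreasing densities in g/cm^3.
#' @return An object of class `density_calibration`.
#' @export
density_calibration <- function(hu = c(-1000, 0), density = c(0.00121, 1.0)) {
  if (length(hu) < 2 || length(hu) != length(density)) {
    stop(cionmc_error("calibration needs at least 2 (HU, density) knots",
                      "configuration"))
  }
  if (any(diff(hu) <= 0)) {
    stop(cionmc_error("HU knots must be strictly increasing", "configuration"))
  }
  if (any(density < 0) || any(diff(density) < 0)) {
    stop(cionmc_error("densities must be non-negative and non-decreasing",
                      "configuration"))
  }
  structure(list(hu = hu, density = density), class = "density_calibration")
}

#' Convert Hounsfield units to mass density
#'
#' Piecewise-linear interpolation between the calibration knots, clamped
#' at the end knots.
#'
#' @param calib A [density_calibration()].
#' @param hu Numeric vector of HU values.
#' @return Densities in g/cm^3.
#' @export
hu_to_density <- function(calib, hu) {
  if (!inherits(calib, "density_calibration")) {
    stop(cionmc_error("calib must be a density_calibration", "configuration"))
  }
  approx(calib$hu, calib$density, xout = hu, rule = 2)$y
}
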