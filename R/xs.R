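# Nuclear cross-sections: fitted carbon-carbon non-elastic channel,
# Kox-ratio scaling to other targets, the hydrogen-target data table,
# and the per-material mass attenuation coefficient.

#' Carbon-carbon non-elastic cross-section fit parameters
#'
#' Parameters of the fitted energy dependence
#' `sigma(E) = (1 - exp(-E/E_c)) * (p0 + p1*E + exp(p2 - p3*E))`
#' with `E` the *total* projectile kinetic energy in MeV.
#'
#' @param E_c Threshold-shaping energy in MeV.
#' @param p0 Constant term in mb.
#' @param p1 Linear slope in mb/MeV.
#' @param p2 Dimensionless exponent offset.
#' @param p3 Exponential slope in 1/MeV.
#' @return An object of class `cc_fit_params`.
#' @export
cc_fit_params <- function(E_c = 30, p0 = 762, p1 = 14.0e-4, p2 = 6.7,
                          p3 = 13.4e-3) {
  v <- c(E_c = E_c, p0 = p0, p1 = p1, p2 = p2, p3 = p3)
  if (any(v <= 0)) {
    stop(cionmc_error("all cross-section fit parameters must be positive",
                      "configuration"))
  }
  structure(as.list(v), class = "cc_fit_params")
}

#' Carbon-carbon non-elastic cross-section
#'
#' @param E_total Total projectile kinetic energy in MeV (>= 0); for a
#'   carbon ion this is 12x the energy per nucleon.
#' @param params A [cc_fit_params()].
#' @return Cross-section in mb.
#' @examples
#' sigma_cc(95 * 12)
#' @export
sigma_cc <- function(E_total, params = cc_fit_params()) {
  if (any(E_total < 0)) {
    stop(cionmc_error("energy must be non-negative", "invalid_energy"))
  }
  (1 - exp(-E_total / params$E_c)) *
    (params$p0 + params$p1 * E_total + exp(params$p2 - params$p3 * E_total))
}

# Energy-dependent transparency parameter of the Kox parameterization,
# as published: c = 2 - 10/x^5 for x = log10(E/A) >= 1.5, with a cubic
# ramp from zero below.
kox_transparency <- function(E_u) {
  x <- log10(pmax(E_u, 1e-6))
  chigh <- 2 - 10 / x^5
  clow <- (2 - 10 / 1.5^5) * (x / 1.5)^3
  ifelse(x >= 1.5, chigh, clow)
}

# All Kox constants in one place: r0 and rC in fm, surface strength a.
.kox_const <- list(r0 = 1.1, a = 1.85, rC = 1.3)

#' Kox reaction cross-section
#'
#' Published geometric + surface + Coulomb parameterization of the total
#' nucleus-nucleus reaction cross-section.  Used by the engine only as a
#' ratio to the carbon-carbon value (see [scaling_K()]), which suppresses
#' sensitivity to its absolute normalization.
#'
#' @param proj,targ Element symbols or species names.
#' @param E Projectile kinetic energy per nucleon in MeV/u.
#' @return Cross-section in mb.
#' @examples
#' kox_sigma("12C", "O", 95)
#' @export
kox_sigma <- function(proj, targ, E) {
  p <- resolve_nuclide(proj)
  t <- resolve_nuclide(targ)
  ap <- p$A^(1 / 3)
  at <- t$A^(1 / 3)
  D <- .kox_const$a * ap * at / (ap + at)
  Bc <- p$Z * t$Z * .const$e2_fm / (.kox_const$rC * (ap + at))
  Ecm <- E * p$A * t$A / (p$A + t$A)   # non-relativistic CoM kinetic energy
  s <- pi * .kox_const$r0^2 * (ap + at + D - kox_transparency(E))^2 *
    (1 - Bc / Ecm) * 10   # fm^2 -> mb
  pmax(s, 0)
}

#' Kox scaling ratio to carbon-carbon
#'
#' `K(proj, targ, E) = sigma_K(proj, targ, E) / sigma_K(12C, 12C, E)`;
#' identically 1 for carbon on carbon.
#'
#' @inheritParams kox_sigma
#' @return Dimensionless scaling factor.
#' @export
scaling_K <- function(proj, targ, E) {
  ref <- kox_sigma("12C", "12C", E)
  # below the Coulomb barrier both cross-sections vanish and the ratio
  # is undefined; return 1 there (the affected ions have sub-micron
  # residual range, so the absolute value is immaterial)
  ifelse(ref > 0, kox_sigma(proj, targ, E) / ref, 1)
}

# Packaged hydrogen-target cross-section knots (synthetic digitization;
# see inst/extdata/xs_carbon_on_hydrogen_synthetic.tsv).
c_on_h_table <- function() {
  tab <- .cionmc_cache[["xs_c_on_h"]]
  if (is.null(tab)) {
    path <- system.file("extdata", "xs_carbon_on_hydrogen_synthetic.tsv",
                        package = "cionmc")
    tab <- read.delim(path, comment.char = "#")
    .cionmc_cache[["xs_c_on_h"]] <- tab
  }
  tab
}

#' Carbon-on-hydrogen non-elastic cross-section
#'
#' Interpolated from the packaged fit table (nearly constant above
#' 250 MeV/u).  Energies outside the 10-450 MeV/u grid are clamped with
#' a warning.
#'
#' @param E Kinetic energy per nucleon in MeV/u.
#' @return Cross-section in mb.
#' @export
sigma_c_on_h <- function(E) {
  tab <- c_on_h_table()
  if (any(E < tab$E[1] | E > tab$E[nrow(tab)])) {
    warning("energy outside the hydrogen-target table; clamping to grid ends")
    E <- pmin(pmax(E, tab$E[1]), tab$E[nrow(tab)])
  }
  approx(tab$E, tab$sigma, xout = E)$y
}

# Per-element non-elastic cross-section for a carbon projectile [mb]:
# data-fit channels for H and C, Kox-scaled carbon-carbon fit otherwise.
sigma_nonelastic_element <- function(element, E_u, params = cc_fit_params()) {
  if (element == "H") return(sigma_c_on_h(E_u))
  if (element == "C") return(sigma_cc(12 * E_u, params))
  scaling_K("12C", element, E_u) * sigma_cc(12 * E_u, params)
}

# Elastic channel, carbon on hydrogen only, as a configurable fraction of
# the hydrogen-target data cross-section.
sigma_elastic_element <- function(element, E_u, elastic_fraction = 0.25) {
  if (element != "H") return(rep(0, length(E_u)))
  elastic_fraction * sigma_c_on_h(E_u)
}

#' Mass attenuation coefficient for nuclear interactions
#'
#' `mu/rho = sum_i N_A w_i sigma_i / A_i` over the elements of the
#' material, with `sigma_i` the total (elastic + non-elastic) per-nucleus
#' cross-section; the mb to cm^2 conversion is applied once here.
#'
#' @param material A [material()].
#' @param proj Projectile species (the packaged channels are for `"12C"`;
#'   other species use the Kox cross-section for every element).
#' @param E Kinetic energy per nucleon in MeV/u.
#' @param elastic_fraction Elastic fraction of the hydrogen-target
#'   cross-section (carbon projectiles only).
#' @param params A [cc_fit_params()].
#' @return mu/rho in cm^2/g.
#' @examples
#' 1 / mass_attenuation(water_material(), "12C", 95)  # mean free path, cm
#' @export
mass_attenuation <- function(material, proj = "12C", E,
                             elastic_fraction = 0.25,
                             params = cc_fit_params()) {
  comp <- material$composition
  if (is.null(comp) || nrow(comp) == 0) {
    stop(cionmc_error("material has an empty composition", "configuration"))
  }
  out <- numeric(length(E))
  for (i in seq_len(nrow(comp))) {
    if (identical(proj, "12C")) {
      s <- sigma_nonelastic_element(comp$element[i], E, params) +
        sigma_elastic_element(comp$element[i], E, elastic_fraction)
    } else {
      s <- kox_sigma(proj, comp$element[i], E)
    }
    out <- out + .const$N_A * comp$w[i] * s * .const$mb_to_cm2 / comp$A[i]
  }
  out
}

#' Tabulate assembled cross-sections
#'
#' @param proj Projectile species.
#' @param targ Target element symbol.
#' @param energies Energy grid in MeV/u.
#' @return Data frame with columns `proj`, `targ`, `E` and `sigma` (mb).
#' @export
xs_table <- function(proj, targ, energies = .table_grid(200, 10, 450)) {
  s <- if (identical(proj, "12C")) {
    sigma_nonelastic_element(targ, energies)
  } else {
    kox_sigma(proj, targ, energies)
  }
  data.frame(proj = proj, targ = targ, E = energies, sigma = s)
}
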