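# Multiple Coulomb scattering (Highland) and Bohr energy-loss straggling.

#' EM transport configuration
#'
#' Settings for the continuous processes.  `f_mcs` is the empirical
#' multiplicative correction to Highland's Gaussian multiple-scattering
#' width for ions; published tunings for light ions span 1.29 (alphas)
#' to 1.43 (oxygen), and the packaged default for Z >= 2 ions is the
#' midpoint 1.37, with no correction (1.0) for singly charged particles.
#'
#' @param f_mcs Named numeric vector of per-species scaling factors,
#'   each in \[1, 2\].  Species not listed fall back on `f_mcs_default`
#'   (Z >= 2) or 1 (Z = 1).
#' @param f_mcs_default Fallback scaling factor for ions, in \[1, 2\].
#' @param max_frac_eloss Maximum fractional kinetic-energy loss per
#'   step, in (0, 0.25].
#' @param straggling Logical, sample Gaussian energy-loss straggling.
#' @param e_cutoff Kinetic energy (MeV/u) below which charged particles
#'   deposit their remaining energy locally.
#' @return An object of class `em_config`.
#' @export
em_config <- function(f_mcs = NULL, f_mcs_default = 1.37,
                      max_frac_eloss = 0.02, straggling = TRUE,
                      e_cutoff = 0.5) {
  if (f_mcs_default < 1 || f_mcs_default > 2) {
    stop(cionmc_error("f_mcs must lie in [1, 2]", "configuration"))
  }
  if (!is.null(f_mcs)) {
    if (is.null(names(f_mcs)) || any(f_mcs < 1) || any(f_mcs > 2)) {
      stop(cionmc_error("f_mcs must be a named vector with values in [1, 2]",
                        "configuration"))
    }
  }
  if (max_frac_eloss <= 0 || max_frac_eloss > 0.25) {
    stop(cionmc_error("max_frac_eloss must lie in (0, 0.25]", "configuration"))
  }
  structure(list(f_mcs = f_mcs, f_mcs_default = f_mcs_default,
                 max_frac_eloss = max_frac_eloss,
                 straggling = isTRUE(straggling), e_cutoff = e_cutoff),
            class = "em_config")
}

# f_mcs for one species under a given config
f_mcs_for <- function(species, cfg) {
  if (!is.null(cfg$f_mcs) && species %in% names(cfg$f_mcs)) {
    return(unname(cfg$f_mcs[[species]]))
  }
  sp <- species_info(species)
  if (sp$Z <= 1) 1.0 else cfg$f_mcs_default
}

#' Multiple-Coulomb-scattering angular sigma
#'
#' Highland's single-Gaussian width for a step of length `step`,
#' multiplied by the configured `f_mcs` scaling factor.
#'
#' @param species Species name.
#' @param E Kinetic energy in MeV/u.
#' @param step Step length in cm (0 returns 0).
#' @param material A [material()]; default water.
#' @param cfg An [em_config()].
#' @return Projected angular sigma in radians.
#' @examples
#' mcs_sigma("12C", 200, 0.05)
#' @export
mcs_sigma <- function(species, E, step, material = water_material(),
                      cfg = em_config()) {
  if (any(step < 0)) stop(cionmc_error("step must be >= 0", "geometry"))
  sp <- species_info(species)
  k <- beta_gamma(E)
  pc <- sp$A * sqrt(E^2 + 2 * E * .const$m_u)   # total momentum * c [MeV]
  t <- step * material$density / material$X0    # step in radiation lengths
  bracket <- pmax(1 + 0.038 * log(t), 0.1)
  s <- .const$highland_e / (pc * k$beta) * sp$Z * sqrt(t) * bracket
  s[step == 0] <- 0
  s * f_mcs_for(species, cfg)
}

#' Energy-loss straggling sigma
#'
#' Bohr Gaussian energy-loss spread over one step; the variance is
#' proportional to the traversed areal density, hence additive over
#' sub-steps.
#'
#' @inheritParams mcs_sigma
#' @return Sigma of the energy loss over the step, in MeV (total, not
#'   per nucleon).
#' @export
straggling_sigma <- function(species, E, step, material = water_material()) {
  sp <- species_info(species)
  k <- beta_gamma(E)
  zeff <- effective_charge(sp$Z, k$beta)
  sqrt(.const$bohr_k * zeff^2 * material$z_over_a * material$density * step)
}
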