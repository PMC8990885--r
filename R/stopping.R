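# Continuous energy loss: Bethe stopping power with Barkas effective
# charge at low energy, tabulated on a log-energy grid and interpolated.

# relativistic kinematics per nucleon
beta_gamma <- function(E_u) {
  g <- 1 + E_u / .const$m_u
  b2 <- 1 - 1 / g^2
  list(gamma = g, beta2 = b2, beta = sqrt(b2))
}

# Barkas-style effective charge of a partially stripped ion
effective_charge <- function(z, beta) {
  if (z <= 1) return(rep(z, length(beta)))
  z * (1 - exp(-125 * beta / z^(2 / 3)))
}

# Mass stopping power [MeV cm^2/g] of an ion with charge z at E_u [MeV/u]
bethe_mass_stopping <- function(E_u, z, z_over_a, I_eV) {
  k <- beta_gamma(E_u)
  zeff <- effective_charge(z, k$beta)
  L <- log(2 * .const$m_e * 1e6 * k$beta2 * k$gamma^2 / I_eV) - k$beta2
  L <- pmax(L, 1e-3)  # guard the (never reached at E > 0.025 MeV/u) turnover
  .const$K_bethe * z_over_a * zeff^2 / k$beta2 * L
}

# Grid shared by all pre-computed tables (log-uniform, 0.025-460 MeV/u).
# The transport clamps below the grid; the top covers therapeutic beams.
.table_grid <- function(n = 700, emin = 0.025, emax = 460) {
  exp(seq(log(emin), log(emax), length.out = n))
}

#' Pre-computed stopping-power and range table
#'
#' Builds (and caches) the look-up table used by the transport kernel:
#' kinetic energy per nucleon, mass stopping power and CSDA range
#' (continuous-slowing-down integral of the inverse stopping power).
#'
#' @param species Species name (e.g. `"12C"`, `"1H"`, `"4He"`).
#' @param material A [material()]; default water.
#' @return Data frame with columns `E` (MeV/u), `S` (MeV cm^2/g) and
#'   `range` (g/cm^2).
#' @examples
#' tab <- stopping_table("12C")
#' @export
stopping_table <- function(species, material = water_material()) {
  key <- paste0("stop:", species, ":", material$name, ":",
                signif(material$z_over_a, 8), ":", signif(material$I_eV, 8))
  tab <- .cionmc_cache[[key]]
  if (!is.null(tab)) return(tab)
  sp <- species_info(species)
  E <- .table_grid()
  S <- bethe_mass_stopping(E, sp$Z, material$z_over_a, material$I_eV)
  # cumulative trapezoid of A dE / S from the grid bottom; the residual
  # range below 0.025 MeV/u is sub-micron and set to zero
  inv <- sp$A / S
  rng <- c(0, cumsum(diff(E) * (inv[-1] + inv[-length(E)]) / 2))
  tab <- data.frame(E = E, S = S, range = rng)
  .cionmc_cache[[key]] <- tab
  tab
}

#' Mass stopping power
#'
#' Interpolated from the pre-computed table on a log-energy grid.
#'
#' @param species Species name.
#' @param E Kinetic energy per nucleon in MeV/u (> 0).
#' @param material A [material()]; default water.
#' @return Mass stopping power in MeV cm^2/g.
#' @examples
#' stopping_power("12C", 200) / stopping_power("1H", 200)  # ~ z^2 = 36
#' @export
stopping_power <- function(species, E, material = water_material()) {
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop(cionmc_error("kinetic energy must be positive", "invalid_energy"))
  }
  tab <- stopping_table(species, material)
  Ec <- pmin(pmax(E, tab$E[1]), tab$E[nrow(tab)])
  exp(approx(log(tab$E), log(tab$S), xout = log(Ec))$y)
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation path length, the integral of the
#' inverse stopping power from (numerically) zero up to `E`.
#'
#' @inheritParams stopping_power
#' @return Range in g/cm^2 (equals cm in unit-density water).
#' @examples
#' csda_range("12C", 200)  # ~ 8.7 cm in water
#' @export
csda_range <- function(species, E, material = water_material()) {
  tab <- stopping_table(species, material)
  if (any(E > tab$E[nrow(tab)])) {
    stop(cionmc_error("energy above the tabulated grid", "extrapolation"))
  }
  out <- numeric(length(E))
  hi <- E >= tab$E[1]
  if (any(hi)) {
    out[hi] <- exp(approx(log(tab$E), log(pmax(tab$range, 1e-12)),
                          xout = log(E[hi]))$y)
  }
  # below the grid the range vanishes ~ E^1.8; continue that power law to 0
  if (any(!hi)) {
    r0 <- tab$range[2]
    out[!hi] <- r0 * (E[!hi] / tab$E[2])^1.8
  }
  out
}

#' Export a stopping table as delimited text
#'
#' @param tab A table from [stopping_table()].
#' @param path Output file path (tab-separated, with header).
#' @export
write_stopping_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stopping table from delimited text
#'
#' @param path File written by [write_stopping_table()].
#' @return Data frame with columns `E`, `S`, `range`.
#' @export
read_stopping_table <- function(path) {
  read.delim(path)
}
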