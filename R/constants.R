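# Physical constants (MeV, cm, g units unless noted)
.const <- list(
  m_u       = 931.49410242,   # atomic mass unit [MeV]
  m_e       = 0.51099895,     # electron mass [MeV]
  K_bethe   = 0.307075,       # 4 pi NA re^2 me c^2 [MeV cm^2 / mol]
  bohr_k    = 0.1569,         # Bohr straggling constant [MeV^2 cm^2 / g]
  N_A       = 6.02214076e23,  # Avogadro number [1/mol]
  mb_to_cm2 = 1e-27,          # millibarn -> cm^2
  mev_to_j  = 1.602176634e-13,
  highland_e = 13.6,          # Highland constant [MeV]
  e2_fm     = 1.44,           # e^2/(4 pi eps0) [MeV fm]
  calib_energy = 95           # reference beam energy of the emission tables [MeV/u]
)

# Elements the engine knows about: atomic number, standard atomic weight,
# mean excitation energy [eV] (ICRU-37 style values).
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Al", "P", "Ca", "Ti"),
  Z      = c(1, 6, 7, 8, 13, 15, 20, 22),
  A      = c(1.008, 12.011, 14.007, 15.999, 26.982, 30.974, 40.078, 47.867),
  I_eV   = c(19.2, 78, 82, 95, 166, 173, 191, 233),
  stringsAsFactors = FALSE
)

#' Fragment species table
#'
#' The fixed set of nuclides the fragmentation model can emit: neutrons
#' plus the charged isotopes with non-negligible production cross-section
#' in 95 MeV/u carbon fragmentation on light targets.
#'
#' @return A data frame with columns `name`, `Z` (charge number),
#'   `A` (mass number) and `charged`.
#' @examples
#' fragment_species()
#' @export
fragment_species <- function() {
  data.frame(
    name = c("n", "1H", "2H", "3H", "3He", "4He", "6He", "6Li", "7Li",
             "7Be", "9Be", "10Be", "8B", "10B", "11B", "10C", "11C", "12C"),
    Z = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 6L, 6L, 6L),
    A = c(1L, 1L, 2L, 3L, 3L, 4L, 6L, 6L, 7L, 7L, 9L, 10L, 8L, 10L, 11L, 10L, 11L, 12L),
    charged = c(FALSE, rep(TRUE, 17)),
    stringsAsFactors = FALSE
  )
}

# Resolve a species name (with a few aliases) to one row of the species table.
species_info <- function(name) {
  sp <- fragment_species()
  alias <- c("C12" = "12C", "carbon" = "12C", "p" = "1H", "proton" = "1H",
             "d" = "2H", "t" = "3H", "alpha" = "4He", "He4" = "4He")
  if (name %in% names(alias)) name <- alias[[name]]
  i <- match(name, sp$name)
  if (is.na(i)) {
    stop(cionmc_error(sprintf("unknown species '%s'", name), "configuration"))
  }
  sp[i, ]
}

# Resolve either an element symbol or a species name to (A, Z) for
# cross-section formulas.
resolve_nuclide <- function(x) {
  if (x %in% .elements$symbol) {
    i <- match(x, .elements$symbol)
    return(list(A = .elements$A[i], Z = .elements$Z[i], name = x))
  }
  sp <- tryCatch(species_info(x), error = function(e) NULL)
  if (is.null(sp)) {
    stop(cionmc_error(sprintf("unknown nuclide '%s'", x), "configuration"))
  }
  list(A = as.numeric(sp$A), Z = as.numeric(sp$Z), name = sp$name)
}

# Classed error constructor so callers can condition on failure modes.
cionmc_error <- function(msg, subclass) {
  errorCondition(msg, class = c(paste0("cionmc_", subclass, "_error"),
                                "cionmc_error", "error", "condition"))
}
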