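# Loaders for the packaged fragmentation tables (delimited text under
# inst/extdata), with lazy caching and target-element mapping.

# Targets with packaged tables are H, C and O; any other element maps to
# the nearest packaged table by mass number (N -> O, Ca -> O, ...).
# Hydrogen is never a fallback: it is qualitatively different (the
# struck nucleus is a single proton).
map_table_target <- function(element) {
  vapply(element, function(el) {
    if (el %in% c("H", "C", "O")) return(el)
    A <- .elements$A[match(el, .elements$symbol)]
    if (is.na(A)) {
      stop(cionmc_error(sprintf("unknown target element '%s'", el),
                        "configuration"))
    }
    if (abs(A - 12.011) < abs(A - 15.999)) "C" else "O"
  }, character(1), USE.NAMES = FALSE)
}

#' Fragment production table for one target element
#'
#' The packaged per-draw species probabilities and their normalized
#' cumulative distribution.  Entries are tagged `measured` where the
#' thin-target experiment constrained them and `fluka-filled` where a
#' general-purpose MC filled the acceptance gaps (neutrons everywhere,
#' species heavier than 7Be on hydrogen).
#'
#' @param target Target element symbol; elements without a packaged
#'   table map to the nearest packaged one by mass number.
#' @return Data frame with columns `species`, `Z`, `A`, `charged`,
#'   `prob` (normalized to sum 1), `cum` and `source`.
#' @examples
#' production_table("H")
#' @export
production_table <- function(target) {
  target <- map_table_target(target)
  key <- paste0("prod:", target)
  tab <- .cionmc_cache[[key]]
  if (!is.null(tab)) return(tab)
  path <- system.file("extdata", "production_probabilities.tsv",
                      package = "cionmc")
  raw <- read.delim(path, comment.char = "#")
  raw <- raw[raw$target == target, ]
  sp <- fragment_species()
  i <- match(sp$name, raw$species)  # enforce canonical species order
  if (anyNA(i)) {
    stop(cionmc_error("production table is missing species rows",
                      "configuration"))
  }
  p <- raw$probability[i]
  tab <- data.frame(species = sp$name, Z = sp$Z, A = sp$A,
                    charged = sp$charged, prob = p / sum(p),
                    cum = cumsum(p / sum(p)), source = raw$source[i],
                    stringsAsFactors = FALSE)
  tab$cum[nrow(tab)] <- 1  # exact endpoint
  .cionmc_cache[[key]] <- tab
  tab
}

#' Emission-distribution parameters
#'
#' Parameters of the two-component (exponential + Gaussian) energy-angle
#' emission distribution at the 95 MeV/u calibration energy, per
#' (target element, fragment species).
#'
#' @param target Target element symbol (mapped as in
#'   [production_table()]).
#' @param species Optional species name; `NULL` returns all rows.
#' @return Data frame with columns `species`, `A1`, `A2`, `E_mean`,
#'   `E_sigma`, `theta_mean`, `theta_sigma` (MeV/u and degrees) and
#'   `alpha_E`, `alpha_theta` (their inverse-scale counterparts).
#' @export
emission_params <- function(target, species = NULL) {
  target <- map_table_target(target)
  key <- paste0("emis:", target)
  tab <- .cionmc_cache[[key]]
  if (is.null(tab)) {
    path <- system.file("extdata", "emission_parameters.tsv",
                        package = "cionmc")
    raw <- read.delim(path, comment.char = "#")
    tab <- raw[raw$target == target, -1]
    rownames(tab) <- NULL
    .cionmc_cache[[key]] <- tab
  }
  if (is.null(species)) return(tab)
  row <- tab[tab$species == species, ]
  if (nrow(row) != 1) {
    stop(cionmc_error(sprintf("no emission parameters for %s on %s",
                              species, target), "configuration"))
  }
  row
}
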