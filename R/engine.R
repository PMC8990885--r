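# The Monte Carlo trunk: primary generation, kernel dispatch, nuclear
# interaction handling, secondary queueing and dose scoring.

#' Pencil-beam specification
#'
#' @param species Beam species (default `"12C"`).
#' @param energy Nominal kinetic energy in MeV/u.
#' @param n Number of primaries (>= 1).
#' @param position Beam spot centre in cm; default the centre of the
#'   phantom entrance face, `c(0, 0, 0)`.
#' @param direction Unit beam direction; default `+z`.
#' @param spot_sigma Transverse Gaussian spot sigma in mm (>= 0).
#' @param energy_spread Fractional Gaussian energy spread (>= 0).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(species = "12C", energy, n, position = c(0, 0, 0),
                      direction = c(0, 0, 1), spot_sigma = 0,
                      energy_spread = 0) {
  if (n < 1) stop(cionmc_error("primary count must be >= 1", "configuration"))
  if (spot_sigma < 0 || energy_spread < 0) {
    stop(cionmc_error("spot sigma and energy spread must be >= 0",
                      "configuration"))
  }
  if (energy <= 0) stop(cionmc_error("energy must be positive",
                                     "invalid_energy"))
  direction <- direction / sqrt(sum(direction^2))
  structure(list(species = species, energy = energy, n = as.integer(n),
                 position = position, direction = direction,
                 spot_sigma = spot_sigma, energy_spread = energy_spread),
            class = "beam_spec")
}

#' Engine configuration
#'
#' Physics toggles and parameters of a run.
#'
#' @param nuclear Enable nuclear interactions of the primary beam.
#' @param mcs Enable multiple Coulomb scattering.
#' @param secondary_fragmentation Attenuation-only removal of secondary
#'   fragments by their own nuclear reactions (default off: secondaries
#'   are transported electromagnetically only).
#' @param elastic_fraction Elastic fraction of the hydrogen-target
#'   cross-section (carbon on hydrogen only).
#' @param c_corr Fragment energy correlation factor.
#' @param em An [em_config()] for the continuous processes.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(nuclear = TRUE, mcs = TRUE,
                      secondary_fragmentation = FALSE,
                      elastic_fraction = 0.25, c_corr = 0.4,
                      em = em_config()) {
  structure(list(nuclear = isTRUE(nuclear), mcs = isTRUE(mcs),
                 secondary_fragmentation = isTRUE(secondary_fragmentation),
                 elastic_fraction = elastic_fraction, c_corr = c_corr,
                 em = em), class = "mc_config")
}

#' Sample nuclear free paths
#'
#' Exponential path lengths with mean `1/(mu/rho * rho)`; infinite when
#' the attenuation vanishes.
#'
#' @param mu_rho Mass attenuation coefficient in cm^2/g.
#' @param rho Density in g/cm^3.
#' @param n Number of draws.
#' @return Path lengths in cm.
#' @export
sample_free_path <- function(mu_rho, rho, n = 1) {
  rate <- mu_rho * rho
  if (rate <= 0) return(rep(Inf, n))
  rexp(n, rate = rate)
}

# Rotate parent directions (n x 3) by polar angle theta (rad) with
# azimuth phi (rad) about each parent axis.
rotate_direction <- function(dir, theta, phi) {
  dir <- matrix(dir, ncol = 3)
  n <- nrow(dir)
  near_z <- abs(dir[, 3]) >= 0.99
  b1 <- cbind(-dir[, 2], dir[, 1], 0)
  if (any(near_z)) {
    d <- dir[near_z, 1]
    b1[near_z, ] <- cbind(1 - d * dir[near_z, 1], -d * dir[near_z, 2],
                          -d * dir[near_z, 3])
  }
  b1 <- b1 / sqrt(rowSums(b1^2))
  b2 <- cbind(dir[, 2] * b1[, 3] - dir[, 3] * b1[, 2],
              dir[, 3] * b1[, 1] - dir[, 1] * b1[, 3],
              dir[, 1] * b1[, 2] - dir[, 2] * b1[, 1])
  out <- cos(theta) * dir +
    sin(theta) * (cos(phi) * b1 + sin(phi) * b2)
  out / sqrt(rowSums(out^2))
}

# Vectorized struck-element + channel choice for interacting primaries.
# Returns the element per track and, where the element is hydrogen, a
# logical elastic flag drawn from the elastic/non-elastic ratio.
choose_channel <- function(material, E, elastic_fraction) {
  comp <- material$composition
  nel <- nrow(comp)
  w <- matrix(0, length(E), nel)
  for (i in seq_len(nel)) {
    # interaction energies can fall below the hydrogen table grid near
    # the end of range; the clamped plateau value is the intended one
    s <- suppressWarnings(
      sigma_nonelastic_element(comp$element[i], E) +
        sigma_elastic_element(comp$element[i], E, elastic_fraction))
    w[, i] <- comp$n[i] * s
  }
  cw <- t(apply(w, 1, cumsum))
  u <- runif(length(E)) * cw[, nel]
  pick <- rowSums(u > cw) + 1L
  element <- comp$element[pick]
  elastic <- rep(FALSE, length(E))
  ish <- element == "H"
  if (any(ish)) {
    sne <- suppressWarnings(sigma_c_on_h(E[ish]))
    sel <- elastic_fraction * sne
    elastic[ish] <- runif(sum(ish)) < sel / (sel + sne)
  }
  list(element = element, elastic = elastic)
}

# Assemble the per-species physics tables handed to the C++ kernel.
build_kernel_tables <- function(material, cfg) {
  sp <- fragment_species()
  E <- .table_grid()
  nsp <- nrow(sp)
  stop_tab <- matrix(1e-6, nsp, length(E))
  for (i in seq_len(nsp)) {
    if (sp$Z[i] == 0) next
    stop_tab[i, ] <- stopping_table(sp$name[i], material)$S
  }
  fm <- vapply(sp$name, f_mcs_for, numeric(1), cfg = cfg$em)
  fm[sp$Z == 0] <- 1
  murho_row <- rep(-1L, nsp)
  murho <- NULL
  if (cfg$nuclear) {
    rows <- list(suppressWarnings(
      mass_attenuation(material, "12C", E, cfg$elastic_fraction)))
    murho_row[sp$name == "12C"] <- 0L
    if (cfg$secondary_fragmentation) {
      for (i in which(sp$Z > 0 & sp$name != "12C")) {
        rows[[length(rows) + 1]] <- suppressWarnings(
          mass_attenuation(material, sp$name[i], E))
        murho_row[i] <- length(rows) - 1L
      }
    }
    murho <- do.call(rbind, rows)
  } else {
    murho <- matrix(0, 0, length(E))
  }
  list(species = sp, Egrid = E, loge0 = log(E[1]),
       dloge = diff(log(E[1:2])), stop_tab = stop_tab, f_mcs = fm,
       murho = murho, murho_row = murho_row)
}

#' Run a Monte Carlo simulation
#'
#' Transports the primary beam and all charged secondaries through the
#' voxel grid, scoring absorbed dose per primary.  Primaries undergo
#' continuous energy loss, straggling and multiple scattering plus
#' nuclear interactions (elastic on hydrogen, non-elastic fragmentation
#' elsewhere); charged fragments are queued and transported; neutrons
#' are bookkept but not transported.  The run is deterministic for a
#' fixed `set.seed()`.
#'
#' @param beam A [beam_spec()].
#' @param grid A [voxel_grid()].
#' @param config An [mc_config()].
#' @param verbose Print per-generation progress.
#' @return An object of class `mc_run` with elements `dose` (a
#'   `dose_grid`: Gy per primary), `ledger` (energy bookkeeping in MeV),
#'   `counts` (interaction statistics) plus the inputs.
#' @examples
#' \donttest{
#' set.seed(1)
#' ph <- make_water_phantom(c(4, 4, 12), c(2, 2, 1))
#' run <- run_mc(beam_spec(energy = 150, n = 200), ph)
#' summary(run)
#' }
#' @export
run_mc <- function(beam, grid, config = mc_config(), verbose = FALSE) {
  material <- grid$materials[[1]]
  tabs <- build_kernel_tables(material, config)
  sp <- tabs$species
  spid <- function(name) match(name, sp$name)

  nvox <- prod(grid$dims)
  dose <- numeric(nvox)
  dose_sq <- numeric(nvox)

  # primaries
  n <- beam$n
  E0 <- beam$energy * (1 + beam$energy_spread * rnorm(n))
  pos <- matrix(rep(beam$position, each = n), ncol = 3)
  if (beam$spot_sigma > 0) {
    off <- cbind(rnorm(n, 0, beam$spot_sigma / 10),
                 rnorm(n, 0, beam$spot_sigma / 10))
    b1 <- rotate_direction(matrix(beam$direction, 1), pi / 2, 0)
    b2 <- rotate_direction(matrix(beam$direction, 1), pi / 2, pi / 2)
    pos <- pos + off[, 1] %*% b1 + off[, 2] %*% b2
  }
  dirm <- matrix(rep(beam$direction, each = n), ncol = 3)
  beam_sp <- species_info(beam$species)$name

  state <- cbind(pos, dirm, E0)
  spec_id <- rep(spid(beam_sp), n)
  is_primary <- rep(TRUE, n)

  ledger <- c(injected = sum(E0) * sp$A[spid(beam_sp)], deposited = 0,
              escaped = 0, neutrons = 0, nuclear_deficit = 0,
              secondary_absorbed = 0)
  counts <- c(primaries = n, elastic = 0, nonelastic = 0,
              charged_fragments = 0)
  mult_sum <- 0

  gen <- 0
  while (nrow(state) > 0) {
    gen <- gen + 1
    if (verbose) {
      message(sprintf("generation %d: %d tracks", gen, nrow(state)))
    }
    res <- transport_kernel(
      state, spec_id - 1L, sp$Z, sp$A, tabs$f_mcs,
      is_primary | config$secondary_fragmentation,
      dose, dose_sq, as.numeric(grid$density), grid$dims, grid$voxel,
      grid$origin, tabs$loge0, tabs$dloge, tabs$stop_tab, tabs$murho,
      tabs$murho_row, material$z_over_a, material$X0,
      config$em$e_cutoff, config$em$max_frac_eloss,
      config$em$straggling, config$mcs)
    ledger["deposited"] <- ledger["deposited"] + res$edep
    ledger["escaped"] <- ledger["escaped"] + res$escaped

    hit <- which(res$fate == 2L)
    if (length(hit) == 0) break
    st <- res$state[hit, , drop = FALSE]
    prim <- is_primary[hit]

    # non-primary interactions: attenuation-only removal
    if (any(!prim)) {
      i <- hit[!prim]
      ledger["secondary_absorbed"] <- ledger["secondary_absorbed"] +
        sum(res$state[i, 7] * sp$A[spec_id[i]])
    }

    ip <- which(prim)
    new_state <- NULL; new_spec <- NULL; new_prim <- NULL
    if (length(ip) > 0) {
      sti <- st[ip, , drop = FALSE]
      Eint <- sti[, 7]
      ch <- choose_channel(material, Eint, config$elastic_fraction)

      # elastic scattering on hydrogen: carbon survives, proton recoils
      iel <- which(ch$elastic)
      if (length(iel) > 0) {
        counts["elastic"] <- counts["elastic"] + length(iel)
        A <- sp$A[spec_id[hit[ip[1]]]]
        el <- sample_elastic(length(iel), Eint[iel] * A, A)
        psi <- runif(length(iel), 0, 2 * pi)
        dcar <- rotate_direction(sti[iel, 4:6, drop = FALSE],
                                 el$theta_l, psi)
        dpro <- rotate_direction(sti[iel, 4:6, drop = FALSE],
                                 el$phi_l, psi + pi)
        new_state <- rbind(
          cbind(sti[iel, 1:3, drop = FALSE], dcar, el$E_l_prime / A),
          cbind(sti[iel, 1:3, drop = FALSE], dpro, el$E_l_p))
        new_spec <- c(rep(spid(beam_sp), length(iel)),
                      rep(spid("1H"), length(iel)))
        new_prim <- c(rep(TRUE, length(iel)), rep(FALSE, length(iel)))
      }

      # non-elastic: fragmentation event, primary removed
      ine <- which(!ch$elastic)
      if (length(ine) > 0) {
        counts["nonelastic"] <- counts["nonelastic"] + length(ine)
        ev <- generate_events(ch$element[ine], Eint[ine], length(ine),
                              c_corr = config$c_corr)
        mult_sum <- mult_sum + sum(ev$events$n_charged)
        ledger["nuclear_deficit"] <- ledger["nuclear_deficit"] +
          sum(12 * Eint[ine] - ev$events$E_fragments)
        fr <- ev$fragments
        neut <- fr$Z == 0
        ledger["neutrons"] <- ledger["neutrons"] +
          sum(fr$E[neut] * fr$A[neut])
        fr <- fr[!neut, ]
        counts["charged_fragments"] <- counts["charged_fragments"] + nrow(fr)
        if (nrow(fr) > 0) {
          pdir <- sti[ine, 4:6, drop = FALSE][fr$event, , drop = FALSE]
          fdir <- rotate_direction(pdir, fr$theta * pi / 180, fr$phi)
          fpos <- sti[ine, 1:3, drop = FALSE][fr$event, , drop = FALSE]
          low <- fr$E <= config$em$e_cutoff
          if (any(low)) {   # sub-cutoff fragments deposit at the vertex
            vi <- voxel_index(grid, fpos[low, , drop = FALSE])
            flat <- vi[, 1] + grid$dims[1] *
              ((vi[, 2] - 1) + grid$dims[2] * (vi[, 3] - 1))
            dep <- fr$E[low] * fr$A[low]
            ok <- !is.na(flat)
            for (q in which(ok)) {
              dose[flat[q]] <- dose[flat[q]] + dep[q]
              dose_sq[flat[q]] <- dose_sq[flat[q]] + dep[q]^2
            }
            ledger["deposited"] <- ledger["deposited"] + sum(dep[ok])
            ledger["escaped"] <- ledger["escaped"] + sum(dep[!ok])
          }
          if (any(!low)) {
            new_state <- rbind(new_state,
                               cbind(fpos[!low, , drop = FALSE],
                                     fdir[!low, , drop = FALSE],
                                     fr$E[!low]))
            new_spec <- c(new_spec, match(fr$species[!low], sp$name))
            new_prim <- c(new_prim, rep(FALSE, sum(!low)))
          }
        }
      }
    }

    if (is.null(new_state) || nrow(new_state) == 0) break
    state <- new_state
    spec_id <- new_spec
    is_primary <- new_prim
  }

  vol <- prod(grid$voxel)
  mass_g <- as.numeric(grid$density) * vol
  dgy <- numeric(nvox)
  nz <- mass_g > 0
  dgy[nz] <- dose[nz] * .const$mev_to_j / (mass_g[nz] * 1e-3) / n
  dg <- dose_grid(grid, array(dgy, grid$dims),
                  dose_sq = array(dose_sq, grid$dims),
                  edep = array(dose, grid$dims), n_primaries = n)

  structure(list(dose = dg, ledger = ledger, counts = counts,
                 mean_multiplicity = if (counts["nonelastic"] > 0)
                   mult_sum / counts["nonelastic"] else NA_real_,
                 beam = beam, config = config), class = "mc_run")
}

#' Dose grid container
#'
#' Couples a voxel grid geometry with per-voxel absorbed dose (Gy per
#' primary).  Used both for simulation output and for synthetic fields
#' in QA analysis.
#'
#' @param grid A [voxel_grid()] (geometry and densities).
#' @param dose Dose array in Gy per primary, matching the grid dims.
#' @param dose_sq Optional per-deposit squared-sum array (MeV^2).
#' @param edep Optional deposited-energy array (MeV).
#' @param n_primaries Number of simulated primaries.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose, dose_sq = NULL, edep = NULL,
                      n_primaries = NA_integer_) {
  if (!all(dim(dose) == grid$dims)) {
    stop(cionmc_error("dose array does not match the grid", "geometry"))
  }
  if (any(dose < 0)) {
    stop(cionmc_error("dose must be non-negative", "geometry"))
  }
  structure(list(origin = grid$origin, voxel = grid$voxel,
                 dims = grid$dims, density = grid$density, dose = dose,
                 dose_sq = dose_sq, edep = edep,
                 n_primaries = n_primaries), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels; max %.3g Gy/primary\n",
              x$dims[1], x$dims[2], x$dims[3], max(x$dose)))
  invisible(x)
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %s @ %g MeV/u, %d primaries\n",
              x$beam$species, x$beam$energy, x$counts[["primaries"]]))
  cat(sprintf("  nonelastic events: %d, elastic: %d, charged fragments: %d\n",
              x$counts[["nonelastic"]], x$counts[["elastic"]],
              x$counts[["charged_fragments"]]))
  invisible(x)
}

#' @export
summary.mc_run <- function(object, ...) {
  l <- object$ledger
  closure <- (l[["deposited"]] + l[["escaped"]] + l[["neutrons"]] +
                l[["nuclear_deficit"]] + l[["secondary_absorbed"]]) /
    l[["injected"]]
  cat(sprintf("Run: %s @ %g MeV/u, %d primaries\n", object$beam$species,
              object$beam$energy, object$counts[["primaries"]]))
  cat("Energy ledger (MeV):\n")
  for (nm in names(l)) cat(sprintf("  %-18s %.4g\n", nm, l[[nm]]))
  cat(sprintf("  ledger closure: %.6f (should be 1)\n", closure))
  cat(sprintf("Events: %d nonelastic, %d elastic; mean charged multiplicity %.2f\n",
              object$counts[["nonelastic"]], object$counts[["elastic"]],
              if (is.na(object$mean_multiplicity)) 0 else
                object$mean_multiplicity))
  invisible(list(ledger = l, closure = closure, counts = object$counts))
}

#' Single transport step (reference implementation)
#'
#' A pure-R reference of one continuous-transport step: adaptive step
#' choice (voxel crossing vs. maximum fractional energy loss), midpoint
#' energy loss, optional straggling and multiple scattering.  The fast
#' C++ kernel implements the same physics; this function exists for
#' transparent, inspectable stepping and for equivalence tests.
#'
#' @param track List with `position` (cm), `direction` (unit),
#'   `E` (MeV/u), `species`.
#' @param grid A [voxel_grid()].
#' @param cfg An [em_config()].
#' @return List with the updated `track`, the energy `deposit` (MeV),
#'   the flat voxel index of the deposit (NA outside the grid) and
#'   `alive`.
#' @export
step_track <- function(track, grid, cfg = em_config()) {
  sp <- species_info(track$species)
  material <- grid$materials[[1]]
  vi <- voxel_index(grid, track$position)
  if (anyNA(vi)) {
    return(list(track = track, deposit = 0, voxel = NA_integer_,
                alive = FALSE, escaped = TRUE))
  }
  rho <- grid$density[vi[1], vi[2], vi[3]]
  # distance to the voxel boundary
  lo <- grid$origin + (vi - 1) * grid$voxel
  hi <- lo + grid$voxel
  u <- track$direction
  tb <- ifelse(u > 0, (hi - track$position) / u,
               ifelse(u < 0, (lo - track$position) / u, Inf))
  step <- max(min(tb), 0) + 1e-6
  if (rho < 1e-9) {
    track$position <- track$position + u * step
    return(list(track = track, deposit = 0, voxel = NA_integer_,
                alive = TRUE, escaped = FALSE))
  }
  S <- stopping_power(track$species, track$E, material) * rho
  step <- min(step, cfg$max_frac_eloss * track$E * sp$A / S)
  dE <- S * step
  Emid <- max(track$E - 0.5 * dE / sp$A, 0.025)
  dE <- stopping_power(track$species, Emid, material) * rho * step
  if (cfg$straggling) {
    dE <- dE + rnorm(1) * straggling_sigma(track$species, Emid, step, material)
  }
  dE <- min(max(dE, 0), track$E * sp$A)
  track$E <- track$E - dE / sp$A
  track$position <- track$position + u * step
  alive <- TRUE
  if (track$E <= cfg$e_cutoff) {
    dE <- dE + track$E * sp$A
    track$E <- 0
    alive <- FALSE
  } else {
    s0 <- mcs_sigma(track$species, track$E, step, material, cfg)
    # two independent projected Gaussians = Rayleigh polar deflection
    track$direction <- as.numeric(
      rotate_direction(matrix(u, 1), sqrt(rnorm(1)^2 + rnorm(1)^2) * s0,
                       runif(1, 0, 2 * pi)))
  }
  flat <- vi[1] + grid$dims[1] * ((vi[2] - 1) + grid$dims[2] * (vi[3] - 1))
  list(track = track, deposit = dE, voxel = flat, alive = alive,
       escaped = FALSE)
}
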