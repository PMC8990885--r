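# Non-elastic event generation: target-nucleus choice, fragment-set
# sampling with conservation enforcement, energy-angle sampling at the
# 95 MeV/u calibration energy, and rescaling to the beam energy.

#' Sample the struck target nucleus
#'
#' Draws the element on which a non-elastic interaction occurs, with
#' probabilities proportional to the number fraction times the
#' per-element cross-section (`P_i = n_i sigma_i / sigma_tot`).  For
#' hydrogen and carbon targets the data-fit cross-sections are used,
#' for all other elements the Kox cross-section scaled carbon-carbon
#' fit.
#'
#' @param material A [material()].
#' @param E Projectile kinetic energy in MeV/u.
#' @param n Number of draws.
#' @param include_elastic Add the elastic hydrogen channel to the
#'   hydrogen weight (used by the engine, where the elastic/non-elastic
#'   branch is decided after the element).
#' @param elastic_fraction Elastic fraction of the hydrogen-target
#'   cross-section.
#' @return Character vector of element symbols.
#' @examples
#' set.seed(1)
#' table(sample_target_nucleus(water_material(), 200, 1000))
#' @export
sample_target_nucleus <- function(material, E, n = 1,
                                  include_elastic = FALSE,
                                  elastic_fraction = 0.25) {
  comp <- material$composition
  w <- vapply(seq_len(nrow(comp)), function(i) {
    s <- sigma_nonelastic_element(comp$element[i], E)
    if (include_elastic) {
      s <- s + sigma_elastic_element(comp$element[i], E, elastic_fraction)
    }
    comp$n[i] * s
  }, numeric(1))
  if (all(w <= 0)) {
    stop(cionmc_error("all per-element cross-sections are zero",
                      "invalid_material"))
  }
  comp$element[sample.int(nrow(comp), n, replace = TRUE, prob = w)]
}

#' Draw fragment species from a production table
#'
#' Direct inverse-CDF draws from the normalized cumulative
#' production-probability distribution of one target.
#'
#' @param target Target element symbol.
#' @param n Number of draws.
#' @return Character vector of species names.
#' @examples
#' set.seed(1)
#' mean(sample_species("H", 1e4) == "4He")  # ~ 0.26
#' @export
sample_species <- function(target, n) {
  tab <- production_table(target)
  tab$species[findInterval(runif(n), c(0, tab$cum), rightmost.closed = TRUE)]
}

# Vectorized fragment-set sampling for n events on one (mapped) target.
#
# Projectile side: species are drawn sequentially from the cumulative
# table; draws that would push the running sums past A = 12 or Z = 6 are
# rejected and redrawn; the set closes when sum(A) reaches 12 exactly.
# Target side: one fragment per event from the same table, capped by the
# target's A and Z (the remainder of the struck nucleus is an untracked
# residual).
#
# Returns a data.frame(event, species_idx, origin, pos) where pos is the
# draw order on the projectile side.
sample_fragment_sets <- function(target, n, max_rounds = 10000) {
  tab <- production_table(target)
  tgt <- resolve_nuclide(map_table_target(target))
  spA <- tab$A
  spZ <- tab$Z
  cum <- c(0, tab$cum)

  ev_out <- vector("list", 64)
  sp_out <- vector("list", 64)
  pos_out <- vector("list", 64)
  nout <- 0

  active <- seq_len(n)
  sA <- integer(n)
  sZ <- integer(n)
  npos <- integer(n)
  round <- 0
  while (length(active) > 0) {
    round <- round + 1
    if (round > max_rounds) {
      stop(cionmc_error("projectile fragment sampling failed to close",
                        "sampling_failure"))
    }
    k <- findInterval(runif(length(active)), cum, rightmost.closed = TRUE)
    ok <- sA[active] + spA[k] <= 12L & sZ[active] + spZ[k] <= 6L
    if (any(ok)) {
      ev <- active[ok]
      sA[ev] <- sA[ev] + spA[k[ok]]
      sZ[ev] <- sZ[ev] + spZ[k[ok]]
      npos[ev] <- npos[ev] + 1L
      nout <- nout + 1
      ev_out[[nout]] <- ev
      sp_out[[nout]] <- k[ok]
      pos_out[[nout]] <- npos[ev]
    }
    active <- active[sA[active] < 12L]
  }
  proj <- data.frame(event = unlist(ev_out[seq_len(nout)]),
                     species_idx = unlist(sp_out[seq_len(nout)]),
                     origin = "projectile",
                     pos = unlist(pos_out[seq_len(nout)]))

  # target side: one fragment fitting inside the struck nucleus
  fits <- which(spA <= tgt$A & spZ <= tgt$Z)
  pfit <- tab$prob[fits] / sum(tab$prob[fits])
  tk <- fits[sample.int(length(fits), n, replace = TRUE, prob = pfit)]
  targ <- data.frame(event = seq_len(n), species_idx = tk,
                     origin = "target", pos = 1L)

  out <- rbind(proj, targ)
  out[order(out$event, out$origin, out$pos), ]
}

# Integrated weights of the exponential and Gaussian components of the
# emission distribution over the sampling support E > 0, 0 <= theta <= 180.
component_weights <- function(par) {
  w_exp <- par$A1 / par$alpha_E *
    (1 - exp(-par$alpha_theta * 180)) / par$alpha_theta
  w_gau <- par$A2 * (2 * pi * par$E_sigma * par$theta_sigma) *
    pnorm(par$E_mean / par$E_sigma) *
    (pnorm(180 / par$theta_sigma) - 0.5)
  c(exponential = w_exp, gaussian = w_gau)
}

# Draw from the Gaussian (projectile) component: truncated normal in E
# (> 0) and half-normal in theta (<= 180 deg).
sample_gaussian_component <- function(par, n) {
  E <- rnorm(n, par$E_mean, par$E_sigma)
  while (any(bad <- E <= 0)) E[bad] <- rnorm(sum(bad), par$E_mean, par$E_sigma)
  th <- abs(rnorm(n, par$theta_mean, par$theta_sigma))
  while (any(bad <- th > 180)) {
    th[bad] <- abs(rnorm(sum(bad), par$theta_mean, par$theta_sigma))
  }
  data.frame(E95 = E, theta95 = th)
}

# Draw from the exponential (target) component: E ~ Exp(alpha_E),
# theta from the truncated exponential on [0, 180] deg.
sample_exponential_component <- function(par, n) {
  E <- rexp(n, rate = par$alpha_E)
  u <- runif(n)
  th <- -log(1 - u * (1 - exp(-par$alpha_theta * 180))) / par$alpha_theta
  data.frame(E95 = E, theta95 = th)
}

#' Sample fragment energy and angle at the calibration energy
#'
#' Draws `(E, theta)` pairs from the packaged two-component emission
#' distribution of a 95 MeV/u carbon beam.  Hydrogen isotopes and
#' neutrons are sampled from the full exponential + Gaussian mixture
#' regardless of origin (the two components overlap and cannot be
#' separated for them); every other species uses the Gaussian component
#' for projectile fragments and the exponential component for target
#' fragments.  Angles cover the full \[0, 180\] degree range.
#'
#' @param species Species name.
#' @param target Target element symbol.
#' @param origin `"projectile"` or `"target"`.
#' @param n Number of draws.
#' @return Data frame with columns `E95` (MeV/u) and `theta95` (deg).
#' @examples
#' set.seed(1)
#' colMeans(sample_energy_angle("4He", "C", "projectile", 1e4))
#' @export
sample_energy_angle <- function(species, target, origin, n = 1) {
  origin <- match.arg(origin, c("projectile", "target"))
  par <- emission_params(target, species)
  if (species %in% c("n", "1H", "2H", "3H")) {
    w <- component_weights(par)
    from_gau <- runif(n) < w[["gaussian"]] / sum(w)
    out <- data.frame(E95 = numeric(n), theta95 = numeric(n))
    if (any(from_gau)) {
      out[from_gau, ] <- sample_gaussian_component(par, sum(from_gau))
    }
    if (any(!from_gau)) {
      out[!from_gau, ] <- sample_exponential_component(par, sum(!from_gau))
    }
    return(out)
  }
  if (origin == "projectile") {
    sample_gaussian_component(par, n)
  } else {
    sample_exponential_component(par, n)
  }
}

#' Rescale a fragment energy from the calibration to the beam energy
#'
#' Projectile fragments scale as
#' `E_i = E95 * (E_proj / 95) * (1 - k)` with `k = c * (1 - R)`, where
#' `R` is the A-weighted mean energy per nucleon of the previously drawn
#' fragments of the same event divided by the projectile energy per
#' nucleon; for the first fragment `R = 1` (no correction), which keeps
#' the mean fragment energy per nucleon equal to the projectile's.
#' Target fragments scale by the plain `E_proj / 95` factor with no
#' correlation term.
#'
#' @param E95 Energy drawn at the calibration energy, MeV/u.
#' @param E_proj Projectile kinetic energy, MeV/u (> 0).
#' @param prev_E,prev_A Energies (MeV/u) and mass numbers of the
#'   previously drawn fragments in the event (projectile origin only).
#' @param origin `"projectile"` or `"target"`.
#' @param c_corr Correlation factor `c` (default 0.4).
#' @return Scaled energy in MeV/u (clamped at 0 with a warning).
#' @examples
#' scale_energy(83, 200)            # first fragment: 83 * 200/95
#' scale_energy(83, 95)             # identity at the calibration energy
#' @export
scale_energy <- function(E95, E_proj, prev_E = NULL, prev_A = NULL,
                         origin = "projectile", c_corr = 0.4) {
  if (any(E_proj <= 0)) {
    stop(cionmc_error("E_proj must be positive", "invalid_energy"))
  }
  if (origin == "target") {
    return(E95 * E_proj / .const$calib_energy)
  }
  R <- if (is.null(prev_E) || length(prev_E) == 0) {
    1
  } else {
    sum(prev_E * prev_A) / sum(prev_A) / E_proj
  }
  k <- c_corr * (1 - R)
  out <- E95 * (E_proj / .const$calib_energy) * (1 - k)
  if (any(out < 0)) {
    warning("negative scaled energy clamped to 0")
    out <- pmax(out, 0)
  }
  out
}

#' Rescale a fragment emission angle to the beam energy
#'
#' `theta_i = theta95 * sqrt(95 / E_proj)`, reflecting the
#' energy-independent transverse momentum of projectile fragments.
#' Protons and neutrons are left unscaled (their emission angle is
#' nearly energy-independent at therapeutic energies); all other
#' species are scaled, target fragments included.
#'
#' @param theta95 Angle drawn at the calibration energy, degrees.
#' @param E_proj Projectile kinetic energy, MeV/u (> 0).
#' @param species Species name (vector allowed).
#' @return Scaled angle in degrees, capped at 180.
#' @export
scale_angle <- function(theta95, E_proj, species) {
  if (any(E_proj <= 0)) {
    stop(cionmc_error("E_proj must be positive", "invalid_energy"))
  }
  fac <- ifelse(species %in% c("1H", "n"), 1,
                sqrt(.const$calib_energy / E_proj))
  pmin(theta95 * fac, 180)
}

#' Generate nuclear fragmentation events
#'
#' The full event pipeline: struck-nucleus choice (for a compound
#' material), sequential fragment-set sampling with charge/mass budget
#' enforcement, energy-angle draws at the calibration energy, rescaling
#' to the beam energy with the inter-fragment energy correlation, and
#' event-level energy-conservation enforcement (an event whose fragments
#' carry more kinetic energy than the projectile is discarded and
#' redrawn).  Azimuths are uniform.  Neutrons are generated for the
#' conservation bookkeeping but are flagged `charged = FALSE` and are
#' not transported by the engine.
#'
#' @param target A [material()], or a character vector of element
#'   symbols (length 1 or `n`) fixing the struck nucleus.
#' @param E_proj Projectile kinetic energy in MeV/u (scalar or length
#'   `n`).
#' @param n Number of events.
#' @param c_corr Energy correlation factor (default 0.4).
#' @param max_resample Resampling attempts per event before a
#'   sampling-failure error is raised.
#' @return An object of class `frag_events`: a list with `fragments`
#'   (data frame: `event`, `species`, `Z`, `A`, `origin`, `E` in MeV/u,
#'   `theta` in degrees, `phi` in radians) and `events` (data frame:
#'   `event`, `element`, `E_proj`, `n_charged`, `E_fragments` total MeV,
#'   `resamples`).
#' @examples
#' set.seed(1)
#' ev <- generate_events(water_material(), 200, 100)
#' mean(ev$events$n_charged)
#' @export
generate_events <- function(target, E_proj, n, c_corr = 0.4,
                            max_resample = 1000) {
  E_proj <- rep_len(E_proj, n)
  if (inherits(target, "material")) {
    elements <- character(n)
    for (e in unique(E_proj)) {
      i <- which(E_proj == e)
      elements[i] <- sample_target_nucleus(target, e, length(i))
    }
  } else {
    elements <- rep_len(as.character(target), n)
  }
  tab_target <- map_table_target(elements)

  sp <- fragment_species()
  frag_acc <- vector("list", 0)
  resamples <- integer(n)
  pending <- seq_len(n)
  attempt <- 0
  while (length(pending) > 0) {
    attempt <- attempt + 1
    if (attempt > max_resample) {
      stop(cionmc_error(
        "energy conservation could not be satisfied within max_resample",
        "sampling_failure"))
    }
    frags <- draw_scaled_fragments(tab_target[pending], E_proj[pending],
                                   c_corr)
    frags$event <- pending[frags$event]
    Etot <- rowsum(frags$E * sp$A[frags$species_idx], frags$event)
    ok_ev <- as.integer(rownames(Etot))[Etot[, 1] <= 12 * E_proj[as.integer(rownames(Etot))]]
    frag_acc[[length(frag_acc) + 1]] <- frags[frags$event %in% ok_ev, ]
    pending <- setdiff(pending, ok_ev)
    resamples[pending] <- resamples[pending] + 1L
  }
  frags <- do.call(rbind, frag_acc)
  frags <- frags[order(frags$event, frags$origin == "target", frags$pos), ]
  fragments <- data.frame(
    event = frags$event,
    species = sp$name[frags$species_idx],
    Z = sp$Z[frags$species_idx],
    A = sp$A[frags$species_idx],
    origin = frags$origin,
    E = frags$E,
    theta = frags$theta,
    phi = runif(nrow(frags), 0, 2 * pi),
    stringsAsFactors = FALSE
  )
  n_charged <- tabulate_by_event(fragments$event[fragments$Z > 0], n)
  E_frag <- numeric(n)
  etot <- rowsum(fragments$E * fragments$A, fragments$event)
  E_frag[as.integer(rownames(etot))] <- etot[, 1]
  structure(list(
    fragments = fragments,
    events = data.frame(event = seq_len(n), element = elements,
                        E_proj = E_proj, n_charged = n_charged,
                        E_fragments = E_frag, resamples = resamples)
  ), class = "frag_events")
}

# counts per event id over 1..n (events with no rows get 0)
tabulate_by_event <- function(ev, n) {
  tabulate(ev, nbins = n)
}

# One sampling attempt for a batch of events: draw the sets, the
# calibration-energy (E, theta) pairs, and apply both scalings.
draw_scaled_fragments <- function(tab_target, E_proj, c_corr) {
  n <- length(tab_target)
  sp <- fragment_species()
  parts <- lapply(unique(tab_target), function(tt) {
    i <- which(tab_target == tt)
    sets <- sample_fragment_sets(tt, length(i))
    sets$event <- i[sets$event]
    sets$tab_target <- tt
    sets
  })
  frags <- do.call(rbind, parts)

  # calibration-energy draws, grouped by (table target, species, component)
  frags$E95 <- NA_real_
  frags$theta95 <- NA_real_
  grp <- interaction(frags$tab_target, frags$species_idx, frags$origin,
                     drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    ea <- sample_energy_angle(sp$name[frags$species_idx[i[1]]],
                              frags$tab_target[i[1]],
                              frags$origin[i[1]], length(i))
    frags$E95[i] <- ea$E95
    frags$theta95[i] <- ea$theta95
  }

  # energy scaling: projectile side sequentially in draw order, with the
  # correlation term built from the previously scaled fragments
  frags$E <- NA_real_
  Ep <- E_proj  # indexed by local event id
  cumE <- numeric(n)
  cumA <- numeric(n)
  is_proj <- frags$origin == "projectile"
  maxpos <- if (any(is_proj)) max(frags$pos[is_proj]) else 0
  for (j in seq_len(maxpos)) {
    i <- which(is_proj & frags$pos == j)
    if (length(i) == 0) next
    ev <- frags$event[i]
    R <- if (j == 1) 1 else (cumE[ev] / pmax(cumA[ev], 1e-300)) / Ep[ev]
    k <- c_corr * (1 - R)
    Ei <- pmax(frags$E95[i] * (Ep[ev] / .const$calib_energy) * (1 - k), 0)
    frags$E[i] <- Ei
    A <- sp$A[frags$species_idx[i]]
    cumE[ev] <- cumE[ev] + Ei * A
    cumA[ev] <- cumA[ev] + A
  }
  it <- which(!is_proj)
  frags$E[it] <- frags$E95[it] * Ep[frags$event[it]] / .const$calib_energy

  frags$theta <- scale_angle(frags$theta95, Ep[frags$event],
                             sp$name[frags$species_idx])
  frags[, c("event", "species_idx", "origin", "pos", "E", "theta")]
}

#' Generate a single fragmentation event
#'
#' Convenience wrapper around [generate_events()] for one event.
#'
#' @inheritParams generate_events
#' @return An object of class `frag_event` with the target element, the
#'   fragment table and a conservation summary (`sum_Z`, `sum_A` over
#'   projectile fragments, total fragment energy and the projectile
#'   energy budget).
#' @export
generate_event <- function(target, E_proj, c_corr = 0.4) {
  ev <- generate_events(target, E_proj, 1, c_corr = c_corr)
  fr <- ev$fragments
  pr <- fr[fr$origin == "projectile", ]
  structure(list(
    element = ev$events$element[1],
    E_proj = E_proj,
    fragments = fr,
    conservation = c(sum_Z = sum(pr$Z), sum_A = sum(pr$A),
                     E_fragments = sum(fr$E * fr$A), E_budget = 12 * E_proj),
    resamples = ev$events$resamples[1]
  ), class = "frag_event")
}

#' @export
print.frag_event <- function(x, ...) {
  cat(sprintf("<frag_event> 12C @ %g MeV/u on %s (%d fragments, %d resamples)\n",
              x$E_proj, x$element, nrow(x$fragments), x$resamples))
  print(x$fragments, row.names = FALSE, digits = 4)
  cat(sprintf("  projectile sum Z = %d, sum A = %d; E_frag = %.1f / %.1f MeV\n",
              x$conservation[["sum_Z"]], x$conservation[["sum_A"]],
              x$conservation[["E_fragments"]], x$conservation[["E_budget"]]))
  invisible(x)
}

#' @export
print.frag_events <- function(x, ...) {
  cat(sprintf("<frag_events> %d events, %d fragments\n",
              nrow(x$events), nrow(x$fragments)))
  cat(sprintf("  mean charged fragments/event: %.2f; resample rate: %.1f%%\n",
              mean(x$events$n_charged),
              100 * sum(x$events$resamples) /
                (nrow(x$events) + sum(x$events$resamples))))
  invisible(x)
}
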