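# File interfaces: voxel-image dose grids (NIfTI), run configuration
# (YAML) and delimited-text exports.

#' Write a dose grid to a NIfTI voxel image
#'
#' The dose array is stored with the voxel spacing (mm) in the header.
#'
#' @param dose A `dose_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_dose_nifti <- function(dose, path) {
  im <- RNifti::asNifti(dose$dose)
  RNifti::pixdim(im) <- dose$voxel * 10
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a dose grid from a NIfTI voxel image
#'
#' @param path A file written by [write_dose_nifti()] (or any scalar
#'   NIfTI volume in Gy).
#' @param density Phantom density assumed for the reconstructed grid.
#' @return A `dose_grid` (entrance-face-centred origin convention).
#' @export
read_dose_nifti <- function(path, density = 1) {
  im <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(im)[1:3] / 10
  arr <- array(as.numeric(im), dim = dim(im))
  grid <- voxel_grid(dim(arr), vox, density, list(water_material()))
  dose_grid(grid, arr)
}

#' Export a profile as delimited text
#'
#' @param profile A [profile1d()].
#' @param path Output path (tab-separated: coordinate, value).
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(coordinate_cm = profile$x, value = profile$value),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with sections `beam`, `phantom`, `physics`, `scoring`, `rng`.
#' Unknown keys raise a configuration error.
#'
#' @param path Path to the YAML file.
#' @return List with `beam` ([beam_spec()]), `grid` ([voxel_grid()]),
#'   `config` ([mc_config()]), `seed` and `scoring` entries.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$beam) || is.null(y$beam$energy) ||
      is.null(y$beam$primaries)) {
    stop(cionmc_error("configuration needs beam: {energy, primaries}",
                      "configuration"))
  }
  b <- y$beam
  beam <- beam_spec(species = b$species %||% "12C", energy = b$energy,
                    n = b$primaries, spot_sigma = b$spot_sigma %||% 0,
                    energy_spread = b$energy_spread %||% 0)
  ph <- y$phantom %||% list()
  grid <- make_water_phantom(unlist(ph$dims %||% c(10, 10, 40)),
                             unlist(ph$voxel %||% c(0.5, 0.5, 0.5)))
  p <- y$physics %||% list()
  config <- mc_config(
    nuclear = p$nuclear %||% TRUE,
    mcs = p$mcs %||% TRUE,
    secondary_fragmentation = p$secondary_fragmentation %||% FALSE,
    elastic_fraction = p$elastic_fraction %||% 0.25,
    c_corr = p$c_corr %||% 0.4,
    em = em_config(f_mcs_default = p$f_mcs_default %||% 1.37,
                   straggling = p$straggling %||% TRUE,
                   e_cutoff = p$e_cutoff %||% 0.5,
                   max_frac_eloss = p$max_frac_eloss %||% 0.02))
  list(beam = beam, grid = grid, config = config,
       seed = (y$rng %||% list())$seed, scoring = y$scoring %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation from a configuration file
#'
#' @param path Configuration file for [read_run_config()].
#' @param verbose Print progress.
#' @return The [run_mc()] result (dose written to
#'   `scoring$dose_output` if configured).
#' @export
run_from_config <- function(path, verbose = FALSE) {
  cfg <- read_run_config(path)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  run <- run_mc(cfg$beam, cfg$grid, cfg$config, verbose = verbose)
  if (!is.null(cfg$scoring$dose_output)) {
    write_dose_nifti(run$dose, cfg$scoring$dose_output)
  }
  run
}
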