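# Independent oracles and small fixture builders shared by the tests.

# Elastic two-body kinematics built from explicit velocity vectors in the
# centre-of-mass frame (non-relativistic), independent of the angle/energy
# formulas used by the implementation.
oracle_elastic <- function(theta_c, E_l, A) {
  u <- sqrt(2 * E_l / A)            # projectile lab speed (mass units of u)
  V <- A * u / (A + 1)              # CoM velocity along z
  up <- u - V                       # projectile speed in CoM
  # projectile after scattering (CoM), rotated by theta_c in the xz plane
  vp <- c(up * sin(theta_c), 0, up * cos(theta_c) + V)
  # target after scattering (CoM speed V, opposite direction); written
  # with half-angle identities so small angles do not cancel
  vt <- 2 * V * sin(theta_c / 2) *
    c(-cos(theta_c / 2), 0, sin(theta_c / 2))
  Ep <- 0.5 * A * sum(vp^2)
  Et <- 0.5 * 1 * sum(vt^2)
  list(theta_l = atan2(abs(vp[1]), vp[3]),
       E_l_prime = Ep,
       phi_l = if (sum(vt^2) == 0) 0 else atan2(abs(vt[1]), vt[3]),
       E_l_p = Et)
}

# Brute-force voxel-level gamma evaluation: exhaustive search over an
# integer-voxel window, no interpolation.
oracle_gamma <- function(ref, eval, dta = 2, dd = 3, search_factor = 3) {
  dmax <- max(ref$dose)
  denom <- dd / 100 * dmax
  vox_mm <- ref$voxel * 10
  d <- ref$dims
  rad <- search_factor * dta
  kmax <- floor(rad / vox_mm)
  g <- array(NA_real_, d)
  for (ix in 1:d[1]) for (iy in 1:d[2]) for (iz in 1:d[3]) {
    best <- Inf
    for (sx in -kmax[1]:kmax[1]) for (sy in -kmax[2]:kmax[2]) {
      for (sz in -kmax[3]:kmax[3]) {
        r2 <- (sx * vox_mm[1])^2 + (sy * vox_mm[2])^2 + (sz * vox_mm[3])^2
        if (r2 > rad^2) next
        jx <- ix + sx; jy <- iy + sy; jz <- iz + sz
        if (jx < 1 || jx > d[1] || jy < 1 || jy > d[2] ||
            jz < 1 || jz > d[3]) next
        val <- ((eval$dose[jx, jy, jz] - ref$dose[ix, iy, iz]) / denom)^2 +
          r2 / dta^2
        if (val < best) best <- val
      }
    }
    g[ix, iy, iz] <- sqrt(best)
  }
  g
}

# Smooth synthetic 3D dose field on a given grid (separable Gaussians).
synthetic_dose_field <- function(grid, centre = NULL, sigma = NULL) {
  d <- grid$dims
  if (is.null(centre)) centre <- (d + 1) / 2
  if (is.null(sigma)) sigma <- d / 4
  gx <- exp(-((1:d[1]) - centre[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-((1:d[2]) - centre[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-((1:d[3]) - centre[3])^2 / (2 * sigma[3]^2))
  arr <- outer(outer(gx, gy), gz)
  dose_grid(grid, arr / max(arr))
}

# Analytic Bragg-like depth-dose kernel used by the SOBP synthetic tests:
# a 1/sqrt(R - z) rise with a Gaussian-smeared distal edge.
synthetic_bragg_kernel <- function(z, R, smear = 0.15) {
  k <- numeric(length(z))
  core <- function(x) ifelse(x < R - 1e-9, 1 / sqrt(pmax(R - x, 1e-3)), 0)
  for (i in seq_along(z)) {
    xs <- z[i] + seq(-3, 3, length.out = 31) * smear
    w <- dnorm(seq(-3, 3, length.out = 31))
    k[i] <- sum(w * core(xs)) / sum(w)
  }
  k
}

# Chi-square goodness-of-fit p-value for observed counts vs expected
# probabilities (expected counts must be reasonably large).
chisq_pvalue <- function(obs, p_expected) {
  e <- sum(obs) * p_expected / sum(p_expected)
  x2 <- sum((obs - e)^2 / e)
  pchisq(x2, df = length(obs) - 1, lower.tail = FALSE)
}
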