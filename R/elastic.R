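# Two-body elastic kinematics for a carbon ion on a hydrogen nucleus,
# non-relativistic, with the target mass number taken as 1.

#' Elastic scattering kinematics (lab frame)
#'
#' Converts a centre-of-mass scattering angle into laboratory-frame
#' angles and energies for a projectile of mass number `A` hitting a
#' free hydrogen nucleus:
#' \deqn{\cos\theta_l = (A + \cos\theta_c)/\sqrt{A^2 + 2A\cos\theta_c + 1}}
#' \deqn{E_l' = \tfrac12[(1+\alpha) + (1-\alpha)\cos\theta_c] E_l,\quad
#'       \alpha = (A-1)^2/(A+1)^2}
#' \deqn{\cos\phi_l = (1+\cos\theta_c)/\sqrt{2(1+\cos\theta_c)}}
#' \deqn{E_l^p = 2AE_l(1-\cos\theta_c)/(A+1)^2}
#' Kinetic energy is conserved exactly: `E_l' + E_l^p = E_l`.
#'
#' @param theta_c Centre-of-mass scattering angle in radians, in \[0, pi\].
#' @param E_l Projectile laboratory kinetic energy in MeV (total, > 0).
#' @param A Projectile mass number (>= 1).
#' @return A data frame with columns `theta_l`, `E_l_prime`, `phi_l`
#'   (recoil-proton lab angle) and `E_l_p` (recoil-proton energy).
#' @examples
#' elastic_kinematics(pi, 2400, 12)  # head-on: E' = 121/169 E
#' @export
elastic_kinematics <- function(theta_c, E_l, A = 12) {
  if (any(theta_c < 0 | theta_c > pi + 1e-12)) {
    stop(cionmc_error("theta_c must lie in [0, pi]", "invalid_angle"))
  }
  if (any(E_l <= 0)) {
    stop(cionmc_error("E_l must be positive", "invalid_energy"))
  }
  ct <- cos(theta_c)
  alpha <- (A - 1)^2 / (A + 1)^2
  # atan2 form of the cosine relation above (better conditioned near 0)
  theta_l <- atan2(sin(theta_c), A + ct)
  E_l_prime <- 0.5 * ((1 + alpha) + (1 - alpha) * ct) * E_l
  # cos(phi_l) = (1+ct)/sqrt(2(1+ct)) = cos(theta_c/2) on [0, pi/2]
  phi_l <- theta_c / 2
  # (1 - cos) written as 2 sin^2(theta/2) to avoid cancellation
  E_l_p <- 4 * A * E_l * sin(theta_c / 2)^2 / (A + 1)^2
  data.frame(theta_l = theta_l, E_l_prime = E_l_prime,
             phi_l = phi_l, E_l_p = E_l_p)
}

#' Sample elastic scattering events
#'
#' Draws the centre-of-mass polar angle isotropically (`cos theta_c`
#' uniform on \[-1, 1\]) and an azimuth uniform on \[0, 2 pi), then maps
#' to the laboratory frame with [elastic_kinematics()].
#'
#' @param n Number of events.
#' @param E_l Projectile laboratory kinetic energy in MeV (scalar or
#'   length-n vector).
#' @param A Projectile mass number.
#' @return Data frame with columns `theta_c`, `phi` (azimuth), plus the
#'   [elastic_kinematics()] outputs.
#' @export
sample_elastic <- function(n, E_l, A = 12) {
  ct <- runif(n, -1, 1)
  theta_c <- acos(ct)
  out <- elastic_kinematics(theta_c, rep_len(E_l, n), A)
  out$theta_c <- theta_c
  out$phi <- runif(n, 0, 2 * pi)
  out
}
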