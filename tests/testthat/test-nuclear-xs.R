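test_that("carbon-carbon fit behaves at the limits and the fitted point", {
  expect_equal(sigma_cc(0), 0)
  # direct substitution of the printed parameters at 95 MeV/u x 12,
  # frozen from an independent scripted evaluation
  expect_equal(sigma_cc(1140), 763.5961885778, tolerance = 1e-9)
  # large-E asymptote: the exponential terms vanish
  p <- cc_fit_params()
  E <- 5000
  expect_equal(sigma_cc(E), p$p0 + p$p1 * E, tolerance = 1e-4)
  expect_error(sigma_cc(-1), class = "cionmc_invalid_energy_error")
  # non-negative under default parameters across the grid
  expect_true(all(sigma_cc(seq(0, 5000, by = 10)) >= 0))
})

test_that("Kox cross-section is symmetric and grows with target mass", {
  for (E in c(50, 95, 200, 400)) {
    expect_equal(kox_sigma("12C", "O", E), kox_sigma("O", "12C", E),
                 tolerance = 1e-12)
  }
  s <- vapply(c("C", "O", "Al", "Ca"), function(t) kox_sigma("12C", t, 95),
              numeric(1))
  expect_true(all(diff(s) > 0))
  expect_error(kox_sigma("12C", "Xx", 95),
               class = "cionmc_configuration_error")
})

test_that("Kox scaling ratio is 1 for carbon-carbon and > 1 for oxygen", {
  for (E in c(30, 95, 200, 400)) {
    expect_equal(scaling_K("12C", "12C", E), 1, tolerance = 1e-12)
    expect_gt(scaling_K("12C", "O", E), 1)
  }
})

test_that("assembled target cross-sections are ordered Ca > O > C > H", {
  for (E in c(95, 200, 400)) {
    sH <- sigma_c_on_h(E)
    sC <- sigma_cc(12 * E)
    sO <- scaling_K("12C", "O", E) * sC
    sCa <- scaling_K("12C", "Ca", E) * sC
    expect_true(sCa > sO && sO > sC && sC > sH)
  }
})

test_that("hydrogen-target cross-section plateaus above 250 MeV/u", {
  expect_equal(sigma_c_on_h(300) / sigma_c_on_h(400), 1, tolerance = 0.03)
  # interpolation identity at a table knot
  tab <- cionmc:::c_on_h_table()
  expect_equal(sigma_c_on_h(tab$E[5]), tab$sigma[5])
  E <- seq(10, 450, by = 1)
  s <- sigma_c_on_h(E)
  expect_true(all(s > 0))
  expect_true(all(abs(diff(s)) < 10))  # continuous, no jumps
  expect_warning(sigma_c_on_h(5), "clamping")
})

test_that("mass attenuation reduces to one term and sums over elements", {
  # single-element material: N_A w sigma / A with w = 1
  gr <- material("graphite", 1.85, data.frame(element = "C", w = 1))
  E <- 200
  expected <- 6.02214076e23 * sigma_cc(12 * E) * 1e-27 / 12.011
  expect_equal(mass_attenuation(gr, "12C", E, elastic_fraction = 0),
               expected, tolerance = 1e-12)
  # water: independent two-term assembly (H data fit + Kox-scaled O)
  w <- water_material()
  sH <- sigma_c_on_h(E) * 1.25          # non-elastic + 25% elastic
  sO <- scaling_K("12C", "O", E) * sigma_cc(12 * E)
  byhand <- 6.02214076e23 *
    (0.1119 * sH / 1.008 + 0.8881 * sO / 15.999) * 1e-27
  expect_equal(mass_attenuation(w, "12C", E), byhand, tolerance = 1e-12)
  # mean free path for 95 MeV/u carbon in water sits in the 10-50 cm decade
  mfp <- 1 / mass_attenuation(w, "12C", 95)
  expect_gt(mfp, 10)
  expect_lt(mfp, 50)
  # continuity of the assembled coefficient on a fine grid
  mu <- mass_attenuation(w, "12C", seq(20, 440, by = 1))
  expect_true(all(abs(diff(mu)) < 0.001))
})

test_that("elastic kinematics match the vector-based oracle to 1e-12", {
  # forward no-scatter limit
  out0 <- elastic_kinematics(0, 2400, 12)
  expect_equal(out0$theta_l, 0)
  expect_equal(out0$E_l_prime, 2400)
  expect_equal(out0$E_l_p, 0)
  # head-on: E' = (121/169) E, Ep = (48/169) E, recoil at pi/2
  outp <- elastic_kinematics(pi, 2400, 12)
  expect_equal(outp$E_l_prime, 121 / 169 * 2400, tolerance = 1e-12)
  expect_equal(outp$E_l_p, 48 / 169 * 2400, tolerance = 1e-12)
  expect_equal(outp$phi_l, pi / 2, tolerance = 1e-9)
  # 1000 random triples against the independent CoM velocity-vector oracle
  set.seed(11)
  th <- runif(1000, 0, pi)
  El <- runif(1000, 10, 5000)
  A <- sample(c(2, 4, 7, 12, 16), 1000, replace = TRUE)
  for (i in c(1:20, sample(1000, 80))) {
    o <- oracle_elastic(th[i], El[i], A[i])
    r <- elastic_kinematics(th[i], El[i], A[i])
    expect_equal(r$theta_l, o$theta_l, tolerance = 1e-12)
    expect_equal(r$E_l_prime, o$E_l_prime, tolerance = 1e-12)
    # the packaged recoil-angle convention is the complement of the
    # momentum-conservation recoil angle (see the methods vignette)
    expect_equal(r$phi_l, pi / 2 - o$phi_l, tolerance = 1e-9)
    expect_equal(r$E_l_p, o$E_l_p, tolerance = 1e-12)
  }
  # event-by-event energy conservation, exactly
  r <- elastic_kinematics(th, El, 12)
  expect_equal(r$E_l_prime + r$E_l_p, El, tolerance = 1e-12)
  expect_error(elastic_kinematics(4, 100), class = "cionmc_invalid_angle_error")
})

test_that("isotropic CoM sampling has the right moments and lab-angle law", {
  set.seed(12)
  n <- 1e6
  s <- sample_elastic(n, 2400, 12)
  # isotropy: mean cos(theta_c) = 0 within 3 sigma
  expect_lt(abs(mean(cos(s$theta_c))), 3 / sqrt(3 * n))
  # mean recoil energy: <E_p> = 2 A E / (A+1)^2
  expect_equal(mean(s$E_l_p), 2 * 12 * 2400 / 169,
               tolerance = 3 * sd(s$E_l_p) / sqrt(n) / (2 * 12 * 2400 / 169))
  # conservation event by event
  expect_equal(s$E_l_prime + s$E_l_p, rep(2400, n), tolerance = 1e-12)
  # marginal lab angle vs deterministic pushforward of the isotropic
  # CoM density (50 equal-probability bins, chi-square)
  cg <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 2e6)
  tl_grid <- acos((12 + cg) / sqrt(144 + 24 * cg + 1))
  qs <- quantile(tl_grid, probs = seq(0, 1, length.out = 51))
  qs[1] <- -Inf; qs[51] <- Inf
  obs <- table(cut(s$theta_l, qs))
  expect_gt(chisq_pvalue(as.numeric(obs), rep(1 / 50, 50)), 0.01)
})
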