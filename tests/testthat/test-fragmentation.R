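test_that("production tables are normalized cumulative distributions", {
  sp <- fragment_species()
  for (t in c("H", "C", "O")) {
    tab <- production_table(t)
    expect_identical(tab$species, sp$name)
    expect_true(all(tab$prob >= 0))
    expect_equal(sum(tab$prob), 1, tolerance = 1e-9)
    expect_true(all(diff(tab$cum) >= 0))
    expect_equal(tab$cum[nrow(tab)], 1, tolerance = 1e-12)
    expect_true(all(tab$source %in% c("measured", "fluka-filled")))
    # neutrons had no experimental acceptance anywhere
    expect_equal(tab$source[tab$species == "n"], "fluka-filled")
  }
  # hydrogen target: no acceptance for species heavier than 7Be
  h <- production_table("H")
  heavy <- match(c("9Be", "10Be", "8B", "10B", "11B", "10C", "11C", "12C"),
                 h$species)
  expect_true(all(h$source[heavy] == "fluka-filled"))
  # unpackaged targets map to the nearest packaged table by mass number
  expect_identical(production_table("N"), production_table("O"))
  expect_identical(production_table("Ca"), production_table("O"))
})

test_that("direct draws recover the packaged probabilities within 3 sigma", {
  set.seed(21)
  n <- 1e6
  checks <- list(c("H", "4He"), c("C", "2H"), c("O", "3H"))
  for (ck in checks) {
    tab <- production_table(ck[1])
    p <- tab$prob[tab$species == ck[2]]
    obs <- mean(sample_species(ck[1], n) == ck[2])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("emission parameter rows are complete and positive", {
  for (t in c("H", "C", "O")) {
    par <- emission_params(t)
    expect_equal(nrow(par), 18)
    expect_true(all(par$E_sigma > 0 & par$theta_sigma > 0 &
                      par$alpha_E > 0 & par$alpha_theta > 0))
    expect_true(all(par$theta_mean == 0))
  }
  expect_error(emission_params("C", "5He"),
               class = "cionmc_configuration_error")
})

test_that("struck-nucleus sampling follows n_i sigma_i / sigma_tot", {
  w <- water_material()
  # degenerate single-element target
  gr <- material("graphite", 1.85, data.frame(element = "C", w = 1))
  expect_true(all(sample_target_nucleus(gr, 200, 50) == "C"))
  # water: P(H) = 2 sigma_H / (2 sigma_H + sigma_K^O), P(H) + P(O) = 1
  E <- 200
  sH <- sigma_c_on_h(E)
  sO <- scaling_K("12C", "O", E) * sigma_cc(12 * E)
  pH <- 2 * sH / (2 * sH + sO)
  set.seed(22)
  n <- 1e6
  obs <- mean(sample_target_nucleus(w, E, n) == "H")
  expect_lt(abs(obs - pH), 3 * sqrt(pH * (1 - pH) / n))
})

test_that("fragment sets respect the projectile charge and mass budget", {
  set.seed(23)
  for (t in c("H", "C", "O")) {
    sets <- cionmc:::sample_fragment_sets(t, 500)
    sp <- fragment_species()
    pr <- sets[sets$origin == "projectile", ]
    sumA <- rowsum(sp$A[pr$species_idx], pr$event)
    sumZ <- rowsum(sp$Z[pr$species_idx], pr$event)
    expect_true(all(sumA == 12))
    expect_true(all(sumZ <= 6))
    # exactly one target-side fragment per event
    expect_equal(sum(sets$origin == "target"), 500)
  }
})

test_that("projectile-origin 4He energy matches the packaged Gaussian", {
  set.seed(24)
  n <- 1e6
  d <- sample_energy_angle("4He", "C", "projectile", n)
  # sample mean of E -> <E> = 83 within 3 standard errors
  expect_lt(abs(mean(d$E95) - 83), 3 * sd(d$E95) / sqrt(n) + 0.01)
  expect_true(all(d$E95 > 0))
  expect_true(all(d$theta95 >= 0 & d$theta95 <= 180))
  # 2D histogram vs the Gaussian component (equal-probability 20 x 20
  # quantile bins, chi-square)
  p0 <- pnorm(0, 83, 15)
  qe <- qnorm(p0 + (1 - p0) * seq(0, 1, length.out = 21), 83, 15)
  qt <- 5.2 * qnorm((1 + seq(0, 1, length.out = 21)) / 2)
  qe[1] <- -Inf; qe[21] <- Inf; qt[1] <- -1e-9; qt[21] <- Inf
  obs <- table(cut(d$E95, qe), cut(d$theta95, qt))
  expect_gt(chisq_pvalue(as.numeric(obs), rep(1 / 400, 400)), 0.01)
})

test_that("target-origin angles follow the truncated exponential", {
  set.seed(25)
  n <- 2e5
  par <- emission_params("O", "7Li")
  d <- sample_energy_angle("7Li", "O", "target", n)
  a <- par$alpha_theta
  m_trunc <- 1 / a - 180 * exp(-a * 180) / (1 - exp(-a * 180))
  expect_lt(abs(mean(d$theta95) - m_trunc), 3 * sd(d$theta95) / sqrt(n))
  expect_true(all(d$theta95 >= 0 & d$theta95 <= 180))
  expect_true(all(d$E95 > 0))
})

test_that("hydrogen-isotope mixture matches a rejection-sampling oracle", {
  set.seed(26)
  par <- emission_params("H", "1H")
  n <- 1e5
  d <- sample_energy_angle("1H", "H", "projectile", n)
  # independent oracle: rejection sampling of the full two-component
  # density over a bounded (E, theta) box
  f <- function(E, th) {
    par$A1 * exp(-(par$alpha_E * E + par$alpha_theta * th)) +
      par$A2 * exp(-(E - par$E_mean)^2 / (2 * par$E_sigma^2) -
                     th^2 / (2 * par$theta_sigma^2))
  }
  fmax <- par$A1 + par$A2
  acc_E <- acc_t <- numeric(0)
  while (length(acc_E) < n) {
    Ep <- runif(4e6, 0, 800)
    tp <- runif(4e6, 0, 180)
    keep <- runif(4e6) * fmax < f(Ep, tp)
    acc_E <- c(acc_E, Ep[keep])
    acc_t <- c(acc_t, tp[keep])
  }
  acc_E <- acc_E[1:n]; acc_t <- acc_t[1:n]
  # two-sample chi-square over a coarse 2D binning
  be <- c(0, 30, 50, 65, 75, 85, 95, 105, 120, 150, 800)
  bt <- c(0, 3, 6, 9, 13, 18, 25, 40, 180)
  o1 <- as.numeric(table(cut(d$E95, be), cut(d$theta95, bt)))
  o2 <- as.numeric(table(cut(acc_E, be), cut(acc_t, bt)))
  keep <- o1 + o2 > 20
  x2 <- sum((o1[keep] - o2[keep])^2 / (o1[keep] + o2[keep]))
  expect_gt(pchisq(x2, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("energy rescaling matches the closed forms and a worked event", {
  # R = 1 (first fragment): identity times E_proj / 95
  expect_equal(scale_energy(83, 200), 83 * 200 / 95, tolerance = 1e-12)
  # identity at the calibration energy
  expect_equal(scale_energy(83, 95), 83, tolerance = 1e-12)
  # three-fragment worked event, evaluated independently step by step
  Ep <- 200; cc <- 0.4
  E1 <- 80 * (Ep / 95)                       # R = 1, k = 0
  R2 <- (E1 * 4 / 4) / Ep
  E2 <- 90 * (Ep / 95) * (1 - cc * (1 - R2))
  R3 <- ((E1 * 4 + E2 * 1) / 5) / Ep
  E3 <- 70 * (Ep / 95) * (1 - cc * (1 - R3))
  expect_equal(scale_energy(80, Ep), E1, tolerance = 1e-12)
  expect_equal(scale_energy(90, Ep, prev_E = E1, prev_A = 4), E2,
               tolerance = 1e-12)
  expect_equal(scale_energy(70, Ep, prev_E = c(E1, E2), prev_A = c(4, 1)),
               E3, tolerance = 1e-12)
  # target fragments: plain E_proj / 95, no correlation factor
  expect_equal(scale_energy(40, 300, origin = "target"), 40 * 300 / 95,
               tolerance = 1e-12)
  expect_error(scale_energy(80, -1), class = "cionmc_invalid_energy_error")
})

test_that("angle rescaling halves at 380 MeV/u and spares nucleons", {
  expect_equal(scale_angle(10, 95, "4He"), 10, tolerance = 1e-12)
  expect_equal(scale_angle(10, 380, "4He"), 5, tolerance = 1e-12)
  expect_equal(scale_angle(10, 380, "1H"), 10, tolerance = 1e-12)
  expect_equal(scale_angle(10, 380, "n"), 10, tolerance = 1e-12)
  expect_equal(scale_angle(10, 380, "2H"), 5, tolerance = 1e-12)
})

test_that("generated events conserve energy, charge and mass", {
  set.seed(27)
  ev <- generate_events(water_material(), 200, 5000)
  fr <- ev$fragments
  # energy budget per event
  expect_true(all(ev$events$E_fragments <= 12 * ev$events$E_proj + 1e-9))
  # projectile-side charge/mass budget
  pr <- fr[fr$origin == "projectile", ]
  expect_true(all(rowsum(pr$A, pr$event) <= 12))
  expect_true(all(rowsum(pr$Z, pr$event) <= 6))
  expect_true(all(fr$E >= 0))
  expect_true(all(fr$theta >= 0 & fr$theta <= 180))
  # protons, deuterons and 4He dominate the charged yield
  cf <- fr[fr$Z > 0, ]
  top <- names(sort(table(cf$species), decreasing = TRUE))[1:3]
  expect_setequal(top, c("1H", "2H", "4He"))
})

test_that("charged multiplicity stays in the therapeutic 2-4 band", {
  set.seed(28)
  mult <- resamp <- numeric(0)
  for (E in c(100, 200, 300, 400)) {
    ev <- generate_events(water_material(), E, 10000)
    mult <- c(mult, mean(ev$events$n_charged))
    resamp <- c(resamp, sum(ev$events$resamples) /
                  (10000 + sum(ev$events$resamples)))
  }
  expect_true(all(mult >= 2 & mult <= 4))
  # resample rate finite and below 50% everywhere
  expect_true(all(resamp < 0.5))
})

test_that("the energy scaling preserves the mean fragment energy per nucleon", {
  # the linear rescaling is mean-preserving where no correlation
  # correction applies (first fragment of an event, R = 1); later
  # fragments are deliberately pulled down by k = c(1 - R), and the
  # event-level energy-conservation filter trims the upper tail further
  set.seed(29)
  fr <- cionmc:::draw_scaled_fragments(rep("C", 30000), rep(200, 30000), 0.4)
  sp <- fragment_species()
  fr$species <- sp$name[fr$species_idx]
  for (s in c("4He", "6Li", "7Be")) {
    sel <- fr$species == s & fr$origin == "projectile" & fr$pos == 1
    if (sum(sel) < 200) next
    par <- emission_params("C", s)
    expect_equal(mean(fr$E[sel]), 200 * par$E_mean / 95, tolerance = 0.1)
  }
  # accepted events sit below the unconstrained mean but in its vicinity
  ev <- generate_events("C", 200, 5000)
  sel <- ev$fragments$species == "4He" & ev$fragments$origin == "projectile"
  expect_equal(mean(ev$fragments$E[sel]), 200 * 83 / 95, tolerance = 0.2)
})

test_that("event records track resampling and print cleanly", {
  set.seed(30)
  e1 <- generate_event(water_material(), 200)
  expect_s3_class(e1, "frag_event")
  expect_true(e1$conservation[["E_fragments"]] <=
                e1$conservation[["E_budget"]])
  expect_gte(e1$resamples, 0)
  expect_output(print(e1), "frag_event")
})
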