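test_that("hansen_delta reproduces an inverse-constructed 27.2 MPa^0.5", {
  # single frame with E/V chosen so CED = 739.84 MPa = 27.2^2
  vol <- (1000 / 6.02214076e23) / (739.84e6 * 1e-30)   # Angstrom^3 for 1 kJ/mol
  ser <- thermo_series(298, volume = vol, energy = 1, energy_unit = "kJ/mol")
  res <- hansen_delta(ser)
  expect_equal(res$delta_mean, 27.2, tolerance = 1e-10)
  expect_equal(res$ced_mean, 739.84, tolerance = 1e-8)
})

test_that("identical frames give zero spread; reordering is irrelevant", {
  ser <- thermo_series(rep(300, 5), volume = rep(32000, 5),
                       energy = rep(-5000, 5))
  res <- hansen_delta(ser)
  expect_equal(res$delta_sd, 0)
  mixed <- make_thermo_series(seed = 6, mass = 25876)
  r1 <- hansen_delta(mixed)
  perm <- withr::with_seed(1, sample(nrow(mixed)))
  shuffled <- thermo_series(mixed$temperature[perm], volume = mixed$volume[perm],
                            energy = mixed$energy[perm])
  expect_equal(hansen_delta(shuffled)$delta_mean, r1$delta_mean,
               tolerance = 1e-12)
  expect_equal(hansen_delta(shuffled)$delta_sd, r1$delta_sd,
               tolerance = 1e-12)
})

test_that("energy-unit declarations convert consistently", {
  # the same physical state expressed in kcal/mol and kJ/mol
  kcal <- thermo_series(300, volume = 30000, energy = -1000,
                        energy_unit = "kcal/mol")
  kj <- thermo_series(300, volume = 30000, energy = -1000 * 4.184,
                      energy_unit = "kJ/mol")
  expect_equal(hansen_delta(kcal)$delta_mean, hansen_delta(kj)$delta_mean,
               tolerance = 1e-10)
  bad <- thermo_series(300, volume = 30000, energy = 1, energy_unit = "eV")
  expect_error(hansen_delta(bad), "unknown energy unit")
})

test_that("sign convention: magnitude default, as-is errors on negatives", {
  ser <- thermo_series(c(300, 301), volume = c(30000, 30000),
                       energy = c(-1000, -1000))
  expect_gt(hansen_delta(ser)$delta_mean, 0)
  expect_error(hansen_delta(ser, sign = "as-is"), "frame 1")
  # sqrt-of-mean differs from mean-of-sqrt only through dispersion
  mixed <- thermo_series(c(300, 301), volume = c(30000, 31000),
                         energy = c(-1000, -1400))
  m1 <- hansen_delta(mixed, method = "mean-of-sqrt")$delta_mean
  m2 <- hansen_delta(mixed, method = "sqrt-of-mean")$delta_mean
  expect_gte(m2, m1)   # Jensen: sqrt of mean >= mean of sqrt
})

test_that("chi parameter: symmetry, hand value, 1/T scaling", {
  expect_equal(chi_parameter(27.2, 27.2, 18, 298), 0)
  # hand arithmetic in SI units: 18e-6 * 100e6 / (8.314462618 * 298)
  expect_equal(chi_parameter(30, 20, 18, 298),
               18e-6 * 100e6 / (8.314462618 * 298), tolerance = 1e-12)
  expect_equal(chi_parameter(30, 20, 18, 298) /
                 chi_parameter(30, 20, 18, 596), 2, tolerance = 1e-12)
  expect_gte(chi_parameter(10, 40, 18, 300), 0)
})

test_that("Flory-Rehner evaluates the printed expression", {
  # independent step-by-step evaluation
  v_s <- 0.5; chi <- 0.5; vsol <- 18; phi <- 0.01
  num <- log(1 - v_s) + v_s + chi * v_s^2
  den <- vsol * (v_s^(1 / 3) - 2 * v_s * phi)
  expect_equal(flory_rehner_crosslink(v_s, chi, vsol, phi), num / den,
               tolerance = 1e-12)
  # v_s -> 0 limit: d -> 0 like -v_s^2 (1/2 - chi) / (vsol v_s^(1/3))
  for (vs in c(1e-3, 1e-4)) {
    d <- flory_rehner_crosslink(vs, 0.4, 18, 0.01)
    approx <- -vs^2 * (0.5 - 0.4) / (18 * vs^(1 / 3))
    expect_equal(d, approx, tolerance = 0.05)
  }
  expect_lt(abs(flory_rehner_crosslink(1e-4, 0.4, 18, 0.01)), 1e-6)
  # singular and sign-flip behaviour of the denominator
  vs_sing <- 0.5; phi_sing <- vs_sing^(1 / 3) / (2 * vs_sing)
  expect_error(flory_rehner_crosslink(vs_sing, 0.5, 18, phi_sing),
               "singular")
  expect_warning(flory_rehner_crosslink(vs_sing, 0.5, 18, phi_sing + 0.1),
                 "sign")
})

test_that("swelling degree is the reciprocal volume fraction", {
  expect_equal(swelling_degree(0.25), 4)
  expect_equal(swelling_degree(1), 1)
  vs <- c(0.1, 0.33, 0.9)
  expect_equal(swelling_degree(vs) * vs, rep(1, 3))
})

test_that("Fujita: forward/fit are inverse on noiseless data", {
  FFV <- c(0.10, 0.12, 0.15, 0.18, 0.22)
  temps <- c(280, 290, 298, 305, 315)
  D <- fujita_forward(D0 = 1e-4, A = 2, B = 0.9, FFV, temps)
  fit <- fujita_fit(D, FFV, temps)
  expect_equal(fit$B, 0.9, tolerance = 1e-10)
  expect_equal(fit$C, log(1e-4 * 8.314462618 * 2), tolerance = 1e-10)
  expect_equal(fit$d0_times_a, 2e-4, tolerance = 1e-10)
  # B = 0: D independent of FFV at fixed temperature
  D0ffv <- fujita_forward(1e-4, 2, 0, FFV, 300)
  expect_equal(D0ffv, rep(D0ffv[1], length(FFV)))
  expect_error(fujita_fit(D, rep(0.2, 5), temps), "collinear")
})

test_that("Fujita fit recovers B within 2 SE on noisy seeded replicates", {
  FFV <- seq(0.08, 0.25, length.out = 15)
  temps <- seq(273, 318, length.out = 15)
  hits <- vapply(1:100, function(seed) {
    D <- withr::with_seed(seed, fujita_forward(1e-4, 2, 0.9, FFV, temps) *
                            exp(rnorm(15, 0, 0.1)))
    fit <- fujita_fit(D, FFV, temps)
    abs(fit$B - 0.9) <= 2 * fit$fit$slope_se
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
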