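test_that("Gaussian smoothing preserves constants and normalizes an impulse", {
  z <- seq(0, 10, length.out = 101)
  const <- tibble::tibble(piezo_height_um = z, deflection_um = rep(2.5, 101))
  expect_equal(smooth_approach(const)$deflection_um, rep(2.5, 101))
  imp <- tibble::tibble(piezo_height_um = z,
                        deflection_um = replace(numeric(101), 51, 1))
  sm <- smooth_approach(imp)$deflection_um
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(which.max(sm), 51)
  expect_error(smooth_approach(const[1:5, ]), "shorter")
})

test_that("smoothing reduces white-noise variance by the kernel power factor", {
  set.seed(4)
  n <- 10000
  noise <- tibble::tibble(piezo_height_um = seq_len(n),
                          deflection_um = rnorm(n))
  sm <- smooth_approach(noise, sigma = 3)$deflection_um
  k <- exp(-(-9:9)^2 / 18); k <- k / sum(k)
  expect_equal(var(sm) / 1, sum(k^2), tolerance = 0.1)
})

test_that("the Sneddon worked value and scaling law hold", {
  # independent arithmetic: (2/pi) * 3000/(1 - 0.25) * tan(17.5 deg) * (1e-6)^2
  oracle <- 2 / pi * 3000 / 0.75 * tan(17.5 * pi / 180) * 1e-12
  expect_equal(sneddon_force(1e-6, 3000), oracle, tolerance = 1e-12)
  expect_equal(sneddon_force(1e-6, 3000), 8.03e-10, tolerance = 1e-3)
  expect_equal(sneddon_force(0, 5000), 0)
  expect_equal(sneddon_force(2e-6, 3000) / sneddon_force(1e-6, 3000), 4)
  expect_error(sneddon_force(-1e-7, 3000), "non-negative")
})

test_that("indentation conversion has the rigid limit and Sneddon round trip", {
  z <- seq(0, 4, length.out = 200)
  # rigid sample: all piezo travel past contact goes into deflection
  rigid <- tibble::tibble(piezo_height_um = z,
                          deflection_um = pmax(0, z - 2))
  ind <- to_indentation(rigid, 2, 0.15)
  expect_lt(max(abs(ind$separation_m)), 1e-18)
  # zero deflection -> zero force everywhere
  flat <- tibble::tibble(piezo_height_um = z, deflection_um = 0 * z)
  expect_true(all(to_indentation(flat, 2, 0.15)$force_n == 0))
  # curve built by inverting the Sneddon law round-trips
  map <- generate_force_map(1, young_modulus = 3000, noise_sd = 0,
                            seed = 1)
  ind2 <- to_indentation(map$data[[1]], map$contact_true_um[1],
                         map$spring_constant[1])
  keep <- ind2$force_n > 1e-12
  pred <- sneddon_force(ind2$separation_m[keep], 3000)
  expect_equal(ind2$force_n[keep], pred, tolerance = 1e-9)
})

test_that("noiseless synthetic curves are refit to the true modulus within 0.1%", {
  for (E in c(500, 1000, 2500, 5000, 10000)) {
    map <- generate_force_map(1, young_modulus = E, noise_sd = 0, seed = 2)
    fit <- fit_sneddon(map$data[[1]], map$spring_constant[1], sigma = 0.5)
    expect_equal(fit$qc, "ok")
    expect_equal(fit$young_modulus_pa, E, tolerance = 1e-3)
  }
})

test_that("5% multiplicative force noise keeps the fitted modulus within 5% most of the time", {
  set.seed(9)
  base <- generate_force_map(1, young_modulus = 2500, noise_sd = 0, seed = 1)
  curve0 <- base$data[[1]]
  ok <- replicate(100, {
    noisy <- curve0
    noisy$deflection_um <- noisy$deflection_um *
      (1 + rnorm(nrow(noisy), 0, 0.05))
    fit <- fit_sneddon(noisy, base$spring_constant[1])
    fit$qc == "ok" && abs(fit$young_modulus_pa - 2500) / 2500 < 0.05
  })
  expect_gte(mean(ok), 0.90)
})

test_that("the fitted modulus is invariant to the curve length unit and spring constant", {
  map <- generate_force_map(1, young_modulus = 3000, noise_sd = 0, seed = 6)
  fit_um <- fit_sneddon(map$data[[1]], map$spring_constant[1], sigma = 0.5)
  curve_nm <- dplyr::mutate(map$data[[1]],
                            piezo_height_um = piezo_height_um * 1000,
                            deflection_um = deflection_um * 1000)
  fit_nm <- fit_sneddon(curve_nm, map$spring_constant[1], sigma = 0.5,
                        length_scale = 1e-9)
  expect_equal(fit_nm$young_modulus_pa, fit_um$young_modulus_pa,
               tolerance = 1e-6)
  # doubling k at fixed true modulus: the generator halves the deflection,
  # the fit multiplies it back
  map2 <- generate_force_map(1, young_modulus = 3000, spring_constant = 0.30,
                             noise_sd = 0, seed = 6)
  fit2 <- fit_sneddon(map2$data[[1]], 0.30, sigma = 0.5)
  expect_equal(fit2$young_modulus_pa, fit_um$young_modulus_pa,
               tolerance = 1e-3)
})

test_that("contactless and degenerate curves are flagged, not fitted", {
  z <- seq(0, 4, length.out = 300)
  flat <- tibble::tibble(piezo_height_um = z, deflection_um = 0 * z)
  fit <- fit_sneddon(flat, 0.15)
  expect_equal(fit$qc, "no_contact")
  expect_true(is.na(fit$young_modulus_pa))
})

test_that("per-spheroid summaries average accepted curves and compare groups", {
  soft <- generate_force_map(6, young_modulus = 2300, noise_sd = 3e-4,
                             spheroid_id = "soft-1", seed = 31)
  stiff <- generate_force_map(6, young_modulus = 3000, noise_sd = 3e-4,
                              spheroid_id = "stiff-1", seed = 32)
  fits <- fit_force_map(dplyr::bind_rows(soft, stiff))
  summ <- spheroid_stiffness_summary(fits)
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$n_curves + summ$n_rejected == 6))
  expect_gt(summ$mean_modulus_pa[summ$spheroid_id == "stiff-1"],
            summ$mean_modulus_pa[summ$spheroid_id == "soft-1"])

  cmp <- summarize_and_compare(c(2, 2, 2), c(10, 10, 10))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.1)
  expect_error(summarize_and_compare(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("groups mimicking the two production conditions separate significantly", {
  # per-spheroid means ~3.0 vs ~2.3 kPa, n = 16 vs 10, sd 0.4 kPa
  set.seed(12)
  sig <- replicate(40, {
    a <- rnorm(16, 3000, 400)
    b <- rnorm(10, 2300, 400)
    mann_whitney(a, b)$p_value < 0.001
  })
  expect_gt(mean(sig), 0.5)
})

test_that("force maps survive a TSV/JSON directory round trip", {
  map <- generate_force_map(3, young_modulus = 2000, noise_sd = 3e-4,
                            seed = 14)
  dir <- tempfile("fm")
  write_force_map(map, dir)
  back <- read_force_curves(dir)
  expect_equal(nrow(back), 3)
  expect_equal(back$spring_constant, map$spring_constant)
  expect_equal(back$data[[2]]$deflection_um, map$data[[2]]$deflection_um,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
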