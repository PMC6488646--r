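test_that("relaxation index arithmetic and domain errors", {
  expect_equal(relaxation_index(0, 450), 0)
  expect_equal(relaxation_index(45, 450), 10)
  expect_equal(relaxation_index(123, 123), 100)
  expect_error(relaxation_index(10, 0), "diameter")
  expect_error(relaxation_index(-1, 10), "non-negative")
})

test_that("incision_observations derives depth fraction and relaxation index", {
  df <- data.frame(spheroid_id = "s1", diameter_um = 450,
                   incision_depth_um = 225, opening_um = 45)
  obs <- incision_observations(df)
  expect_equal(obs$depth_fraction, 0.5)
  expect_equal(obs$relaxation_index, 10)
  expect_error(incision_observations(df[, -2]), "missing columns")
  df_bad <- df; df_bad$incision_depth_um <- 500
  expect_error(incision_observations(df_bad), "incision_depth_um")
})

test_that("fraction-below counts respect the tie rule and curve support", {
  surf <- test_surface()
  curve <- surface_curve(surf, attr(surf, "gammas")[6])
  # observations exactly on the curve count as below (ties <=)
  dd <- seq(0.42, 0.63, length.out = 10)
  on_curve <- tibble::tibble(
    depth_fraction = dd,
    relaxation_index = predict_relaxation(surf, attr(surf, "gammas")[6], dd)
  )
  expect_equal(fraction_below_curve(on_curve, curve)$fraction_below, 1)
  lower <- surface_curve(surf, attr(surf, "gammas")[5])
  higher <- surface_curve(surf, attr(surf, "gammas")[7])
  expect_equal(fraction_below_curve(on_curve, lower)$fraction_below, 0)
  expect_equal(fraction_below_curve(on_curve, higher)$fraction_below, 1)
  # zero observations under any positive-gamma curve are all below
  zeros <- tibble::tibble(depth_fraction = dd, relaxation_index = 0)
  expect_equal(fraction_below_curve(zeros, curve)$fraction_below, 1)
  # support violations are named errors, not extrapolation
  outside <- tibble::tibble(spheroid_id = "weird", depth_fraction = 0.2,
                            relaxation_index = 5)
  expect_error(fraction_below_curve(outside, curve), "weird")
})

test_that("cdf sampling brackets the generating mean", {
  surf <- test_surface()
  coh <- generate_incision_cohort(60, 0.2, 0.03, surf, seed = 7)
  samples <- sample_cdf(coh, surf)
  below <- samples$gamma[samples$fraction_below <= 0.5]
  above <- samples$gamma[samples$fraction_below >= 0.5]
  expect_gt(length(below), 0)
  expect_gt(length(above), 0)
  expect_lt(max(below), 0.2 + 0.04)
  expect_gt(max(above), 0.2 - 0.04)
  expect_true(all(samples$fraction_below ==
                    samples$n_below / samples$n_total))
})

test_that("noiseless Gaussian cdf samples are recovered to 1e-6", {
  gg <- seq(0.05, 0.45, length.out = 10)
  samples <- tibble::tibble(gamma = gg,
                            fraction_below = pnorm(gg, 0.2, 0.05))
  est <- fit_gaussian_cdf(samples)
  expect_equal(est$mu, 0.2, tolerance = 1e-6)
  expect_equal(est$sigma, 0.05, tolerance = 1e-6)
  expect_lt(est$rss, 1e-12)
})

test_that("the optimizer agrees with a brute-force lattice search", {
  set.seed(11)
  gg <- seq(0.02, 0.45, length.out = 12)
  fr <- pnorm(gg, 0.25, 0.06) + rnorm(12, 0, 0.03)
  fr <- pmin(pmax(fr, 0), 1)
  est <- fit_gaussian_cdf(tibble::tibble(gamma = gg, fraction_below = fr))
  mus <- seq(min(gg), max(gg), length.out = 200)
  sigmas <- seq(1e-3, max(gg) - min(gg), length.out = 200)
  rss <- outer(mus, sigmas,
               function(m, s) {
                 vapply(seq_along(m), function(i) {
                   sum((fr - pnorm(gg, m[i], s[i]))^2)
                 }, numeric(1))
               })
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(est$mu - mus[best[1]]), diff(mus[1:2]) * 1.5)
  expect_lt(abs(est$sigma - sigmas[best[2]]), diff(sigmas[1:2]) * 1.5)
  expect_lte(est$rss, min(rss) + 1e-10)
})

test_that("binomial sampling noise leaves the fitted mean within two points of truth", {
  # Monte-Carlo oracle: fractions drawn binomially around the true cdf at
  # the cohort size of the denser study arm
  gg <- seq(0.02, 0.45, length.out = 12)
  truth <- pnorm(gg, 0.276, 0.037)
  set.seed(101)
  hits <- replicate(200, {
    fr <- rbinom(length(gg), 29, truth) / 29
    est <- fit_gaussian_cdf(tibble::tibble(gamma = gg, fraction_below = fr))
    abs(est$mu - 0.276) <= 0.02
  })
  expect_gte(mean(hits), 0.90)
})

test_that("degenerate cdf samples raise identifiability errors", {
  gg <- seq(0.05, 0.45, length.out = 8)
  expect_error(fit_gaussian_cdf(tibble::tibble(gamma = gg,
                                               fraction_below = rep(0, 8))),
               "not identifiable")
  expect_error(fit_gaussian_cdf(tibble::tibble(gamma = gg,
                                               fraction_below = rep(1, 8))),
               "not identifiable")
  expect_error(fit_gaussian_cdf(tibble::tibble(gamma = gg[1:3],
                                               fraction_below = c(0, 0.5, 1))),
               "at least 4")
})

test_that("regression consistency check finds the generating magnitude", {
  surf <- test_surface()
  set.seed(5)
  dd <- runif(24, 0.41, 0.64)
  obs <- tibble::tibble(
    depth_fraction = dd,
    relaxation_index = predict_relaxation(surf, 0.25, dd) + rnorm(24, 0, 0.8)
  )
  g_star <- regression_consistency_check(obs, c(0.15, 0.20, 0.25, 0.30), surf)
  expect_equal(as.numeric(g_star), 0.25)
  expect_equal(as.numeric(
    regression_consistency_check(obs, 0.3, surf)), 0.3)
})

test_that("end-to-end estimation round-trips a tight cohort and is permutation invariant", {
  surf <- test_surface()
  coh <- generate_incision_cohort(40, 0.22, 0, surf, noise_sd = 0.4,
                                  seed = 21)
  est <- estimate_stored_stress(coh, surf)
  expect_equal(est$mu, 0.22, tolerance = 0.05)
  expect_lt(est$sigma, 0.05)
  expect_false(is.na(est$gamma_star))
  shuffled <- coh[sample(nrow(coh)), ]
  est2 <- estimate_stored_stress(shuffled, surf)
  expect_equal(est2$mu, est$mu, tolerance = 1e-12)
  expect_equal(est2$sigma, est$sigma, tolerance = 1e-12)
  expect_error(estimate_stored_stress(coh[0, ], surf), "empty cohort")
})

test_that("cohorts generated at means in ratio 5:3 recover that contrast", {
  surf <- test_surface()
  ratios <- vapply(1:5, function(i) {
    a <- estimate_stored_stress(
      generate_incision_cohort(29, 0.30, 0.037, surf, seed = 300 + i),
      surf, regression_check = FALSE)$mu
    b <- estimate_stored_stress(
      generate_incision_cohort(29, 0.18, 0.037, surf, seed = 600 + i),
      surf, regression_check = FALSE)$mu
    a / b
  }, numeric(1))
  expect_lt(abs(median(ratios) - 5 / 3) / (5 / 3), 0.15)
})

test_that("cohort CSV round trip preserves the derived columns", {
  surf <- test_surface()
  coh <- generate_incision_cohort(8, 0.25, 0.02, surf, seed = 3)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(
    coh[, c("spheroid_id", "diameter_um", "incision_depth_um", "opening_um")],
    path, row.names = FALSE)
  back <- read_incision_cohort(path)
  expect_equal(back$depth_fraction, coh$depth_fraction, tolerance = 1e-6)
  expect_equal(back$relaxation_index, coh$relaxation_index, tolerance = 1e-6)
  unlink(path)
})

test_that("tidy and glance summarize a stress estimate", {
  gg <- seq(0.05, 0.45, length.out = 10)
  est <- fit_gaussian_cdf(tibble::tibble(gamma = gg,
                                         fraction_below = pnorm(gg, 0.2, 0.05)))
  td <- tidy(est)
  expect_equal(td$term, c("mu", "sigma"))
  gl <- glance(est)
  expect_equal(gl$mu, est$mu)
  expect_equal(gl$n_samples, 10L)
})
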