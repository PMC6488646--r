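test_that("thresholding keeps the largest connected component", {
  stack <- array(0, dim = c(8, 8, 8))
  stack[2:6, 2:6, 2:6] <- 10          # big blob (125 voxels)
  stack[8, 8, 8] <- 10                # lone bright voxel
  mask <- threshold_mask(stack, 5)
  expect_equal(sum(mask), 125)
  expect_false(mask[8, 8, 8])
  # uniform stack above threshold -> everything kept
  uni <- array(7, dim = c(4, 4, 4))
  expect_equal(sum(threshold_mask(uni, 7)), 64)
  expect_error(threshold_mask(stack, 99), "intensity range")
})

test_that("a noisy rasterized ball thresholds to nearly the noiseless volume", {
  clean <- generate_voxel_spheroid(c(40, 40, 40), voxel_size = c(1, 1, 1),
                                   intensity = 100)
  noisy <- generate_voxel_spheroid(c(40, 40, 40), voxel_size = c(1, 1, 1),
                                   intensity = 100, noise_sd = 10, seed = 8)
  v_clean <- sum(threshold_mask(clean, 50))
  v_noisy <- sum(threshold_mask(noisy, 50))
  expect_lt(abs(v_noisy - v_clean) / v_clean, 0.03)
})

test_that("shape metrics recover the analytic ball and ellipsoid", {
  ball <- generate_voxel_spheroid(c(50, 50, 50))
  mball <- shape_metrics(threshold_mask(ball, 50))
  expect_equal(mball$volume_um3, 4 / 3 * pi * 50^3, tolerance = 0.02)
  expect_equal(mball$flatness, 1, tolerance = 0.02)

  flat <- generate_voxel_spheroid(c(100, 100, 30))
  mflat <- shape_metrics(threshold_mask(flat, 50))
  expect_equal(mflat$flatness, 0.30, tolerance = 0.02 / 0.30)
  expect_equal(mflat$axis_long_um, 100, tolerance = 0.02)
  expect_equal(mflat$axis_short_um, 30, tolerance = 0.03)
})

test_that("anisotropic voxels give the same metrics as an isotropic raster", {
  aniso <- generate_voxel_spheroid(c(100, 100, 30))            # 0.645/0.645/1
  iso <- generate_voxel_spheroid(c(100, 100, 30),
                                 voxel_size = c(0.8, 0.8, 0.8))
  ma <- shape_metrics(threshold_mask(aniso, 50))
  mi <- shape_metrics(threshold_mask(iso, 50))
  expect_equal(ma$volume_um3, mi$volume_um3, tolerance = 0.02)
  expect_equal(ma$flatness, mi$flatness, tolerance = 0.02)
})

test_that("flatness is bounded and stable under 90-degree rotation", {
  flat <- generate_voxel_spheroid(c(60, 40, 20), voxel_size = c(1, 1, 1))
  mask <- threshold_mask(flat, 50)
  m0 <- shape_metrics(mask, c(1, 1, 1))
  expect_gt(m0$flatness, 0); expect_lte(m0$flatness, 1)
  rot <- aperm(mask, c(3, 2, 1))   # swap z and x
  m1 <- shape_metrics(rot, c(1, 1, 1))
  expect_lt(abs(m1$flatness - m0$flatness), 0.01)
  expect_error(shape_metrics(array(FALSE, dim = c(3, 3, 3))), "degenerate")
})

test_that("volume is exactly voxel count times voxel volume", {
  mask <- array(FALSE, dim = c(5, 5, 5)); mask[1:3, 1:2, 1] <- TRUE
  m <- shape_metrics(mask, c(0.645, 0.645, 1))
  expect_identical(m$n_voxels, 6L)
  expect_equal(m$volume_um3, 6 * 0.645 * 0.645 * 1, tolerance = 1e-12)
})

test_that("voxel stacks survive a TIFF round trip", {
  v <- generate_voxel_spheroid(c(20, 20, 12), voxel_size = c(2, 2, 2),
                               noise_sd = 3, seed = 30)
  path <- tempfile(fileext = ".tif")
  scale <- write_voxel_stack(v, path)
  back <- read_voxel_stack(path, voxel_size = c(2, 2, 2)) * scale
  expect_equal(dim(back), dim(v))
  expect_equal(as.numeric(back), pmax(as.numeric(v), 0), tolerance = 1e-5)
  m1 <- shape_metrics(threshold_mask(back, 50), c(2, 2, 2))
  m2 <- shape_metrics(threshold_mask(array(v, dim(v)), 50), c(2, 2, 2))
  expect_equal(m1$volume_um3, m2$volume_um3)
  unlink(path)
})

test_that("growth rates follow the stated convention", {
  traj <- tibble::tibble(
    spheroid_id = rep(c("a", "b"), each = 3),
    concentration_uM = 0,
    t_h = rep(c(0, 24, 48), 2),
    area_um2 = c(100, 100, 200,                  # a: flat then doubles
                 100, 100 * exp(0.02 * 24), 100 * exp(0.02 * 48))
  )
  r24 <- growth_rate(traj, 24)
  expect_equal(r24$growth_rate[r24$spheroid_id == "a"], 1)
  expect_equal(r24$growth_rate[r24$spheroid_id == "b"], 1.616, tolerance = 1e-3)
  r48 <- growth_rate(traj, 48)
  expect_equal(r48$growth_rate[r48$spheroid_id == "a"], 2)
  off <- growth_rate(traj, 48, convention = "offset")
  expect_equal(off$growth_rate[off$spheroid_id == "a"], 1)
  expect_error(growth_rate(traj, 96), "t = 96")
  # unit rescaling of areas cancels in the ratio
  traj_px <- dplyr::mutate(traj, area_um2 = area_um2 * 3.1)
  expect_equal(growth_rate(traj_px, 48)$growth_rate, r48$growth_rate)
})

test_that("normalization maps the control to exactly 1 and is idempotent", {
  rates <- tibble::tibble(
    concentration_uM = rep(c(0, 5, 50), each = 4),
    t_h = 48,
    growth_rate = c(rnorm(4, 1.6, 0.01), rnorm(4, 1.2, 0.01),
                    rnorm(4, 0.9, 0.01))
  )
  norm <- normalize_to_control(rates)
  expect_equal(norm$normalized_growth[norm$concentration_uM == 0], 1)
  expect_equal(norm$normalized_growth[norm$concentration_uM == 5],
               norm$mean_growth_rate[norm$concentration_uM == 5] /
                 norm$mean_growth_rate[norm$concentration_uM == 0])
  again <- normalize_to_control(
    dplyr::transmute(norm, concentration_uM = concentration_uM, t_h = t_h,
                     growth_rate = normalized_growth))
  expect_equal(again$normalized_growth, norm$normalized_growth)
  expect_error(normalize_to_control(rates[rates$concentration_uM > 0, ]),
               "control")
  # treated mean 1.2 vs control 1.6 -> 0.75
  simple <- tibble::tibble(concentration_uM = c(0, 10),
                           growth_rate = c(1.6, 1.2))
  expect_equal(
    normalize_to_control(simple)$normalized_growth[2], 0.75)
})

test_that("Mann-Whitney matches hand enumeration on the worked examples", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  same <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$p_value, 1)
})

# Independent oracle: enumerate all group assignments and count (a > b) pairs
# directly, without ranks.
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b); n1 <- length(a); N <- length(pooled)
  u_stat <- function(ai) {
    av <- pooled[ai]; bv <- pooled[-ai]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(N, n1), 2, u_stat)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

test_that("exact path agrees with the enumeration oracle on all small random pairs", {
  set.seed(17)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      a <- sample(1:6, n1, replace = TRUE)    # ties likely
      b <- sample(1:6, n2, replace = TRUE)
      expect_equal(mann_whitney(a, b)$p_value, mw_exact_oracle(a, b),
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("approximate path matches the reference implementation without ties", {
  set.seed(23)
  for (i in 1:50) {
    a <- rnorm(10); b <- rnorm(10, 0.4)
    ours <- mann_whitney(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})
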