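test_that("cell_volume reproduces the registry volumes from mean cell sizes", {
  expect_equal(round(cell_volume(cell_geometry("sphere", 10))), 524)
  expect_equal(round(cell_volume(cell_geometry("sphere", 8))), 268)
  expect_equal(round(cell_volume(
    cell_geometry("ellipsoid", c(11.48, 8.61, 8.61)))), 446)
  expect_equal(round(cell_volume(
    cell_geometry("ellipsoid", c(8.61, 5.74, 5.74)))), 149)
  # a degenerate ellipsoid is a sphere
  expect_equal(cell_volume(cell_geometry("ellipsoid", c(7, 7, 7))),
               cell_volume(cell_geometry("sphere", 7)))
  expect_equal(cell_volume(cell_geometry("cylinder", c(10, 5))),
               pi * 100 * 5 / 4)
  expect_equal(cell_volume(
    cell_geometry("fixed", fixed_volume_um3 = 1902)), 1902)
  expect_error(cell_geometry("sphere", -1), "positive")
  expect_error(cell_geometry("fixed"), "fixed_volume_um3")
})

test_that("cell_volume is monotone and scales cubically", {
  v0 <- cell_volume(cell_geometry("ellipsoid", c(4, 6, 9)))
  expect_gt(cell_volume(cell_geometry("ellipsoid", c(5, 6, 9))), v0)
  for (k in c(0.5, 2, 3.1)) {
    expect_equal(cell_volume(cell_geometry("ellipsoid", k * c(4, 6, 9))),
                 k^3 * v0)
    expect_equal(cell_volume(cell_geometry("sphere", k * 8)),
                 k^3 * cell_volume(cell_geometry("sphere", 8)))
  }
})

test_that("V/Vmax normalization scales intensity and inverts exactly", {
  expect_equal(normalize_intensity(42, normalization_context(524, 524)), 42)
  expect_equal(normalize_intensity(100, normalization_context(262, 524)),
               200)
  # a reference-genus volume rescales across genera
  v_ana <- cell_volume(cell_geometry("ellipsoid", c(11.48, 8.61, 8.61)))
  v_mic <- cell_volume(cell_geometry("sphere", 10.28))
  ctx <- normalization_context(v_mic, v_mic, reference_v_um3 = v_ana)
  expect_equal(normalize_intensity(100, ctx), 100 * v_ana / v_mic)
  expect_equal(round(v_ana / v_mic, 2), 0.78)

  for (i in 1:10) {
    vmax <- stats::runif(1, 100, 2000)
    ctx <- normalization_context(stats::runif(1, 10, vmax), vmax,
                                 reference_v_um3 = stats::runif(1, 50, 900))
    x <- stats::runif(1, 0, 1e4)
    expect_equal(denormalize_intensity(normalize_intensity(x, ctx), ctx), x)
  }
  expect_error(normalization_context(600, 500), "vmax")
})

test_that("fit_line matches exact and closed-form solutions", {
  x <- c(0, 1, 2, 5, 9)
  curve <- fit_line(x, 3 * x + 1)
  expect_equal(curve$slope, 3)
  expect_equal(curve$intercept, 1)
  expect_equal(curve$r2, 1)
  expect_equal(curve$x_range, c(0, 9))

  # seeded noise: agreement with an independent sums-based OLS oracle
  set.seed(7)
  xn <- seq(0, 10, length.out = 12)
  yn <- 2.5 * xn + 0.8 + stats::rnorm(12, sd = 0.3)
  curve <- fit_line(xn, yn)
  oracle <- ols_oracle(xn, yn)
  expect_equal(curve$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(curve$intercept, oracle$intercept, tolerance = 1e-12)
  se <- sqrt(sum((yn - oracle$intercept - oracle$slope * xn)^2) / 10 /
               sum((xn - mean(xn))^2))
  expect_lt(abs(curve$slope - 2.5), 3 * se)

  # n = 2 equals the two-point line
  two <- fit_line(c(1, 4), c(5, 17))
  expect_equal(two$slope, 4)
  expect_equal(two$intercept, 1)

  expect_error(fit_line(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  tho <- fit_line(c(1, 2, 4), c(2, 4, 8), through_origin = TRUE)
  expect_equal(tho$slope, 2)
  expect_identical(tho$intercept, 0)
})

test_that("prediction and inversion round trip with boundary policy", {
  curve <- fit_line(c(0, 10), c(0, 20))  # y = 2x
  expect_equal(predict_calibration(curve, 5), 10)
  expect_equal(invert_calibration(curve, 10), 5)
  expect_warning(predict_calibration(curve, 50), "range")

  off <- fit_line(c(0, 10), c(4, 24))  # y = 2x + 4
  expect_warning(x0 <- invert_calibration(off, 1), "clamped")
  expect_identical(x0, 0)
  expect_equal(invert_calibration(off, 1, clamp = FALSE), -1.5)

  zero <- fit_line(c(0, 1, 2), c(3, 3, 3))
  expect_error(invert_calibration(zero, 3), "zero slope")
})

test_that("a simulated calibration series inverts to its concentrations", {
  setup <- closed_loop_setup()
  concs <- c(2e4, 8e4, 1.5e5)
  tab <- generate_calibration_series(
    setup$models$cyanobacteria, c(0, 5e4, 1e5, 2e5), 523,
    setup$windows$phycocyanin,
    noise = noise_model(additive_sigma = 0, multiplicative_cv = 0.005,
                        seed = 3))
  curve <- fit_line(tab$concentration, tab$intensity)
  for (conc in concs) {
    sp <- simulate_emission(setup$models$cyanobacteria, conc, 523)
    y <- find_peak(sp, setup$windows$phycocyanin)$intensity
    expect_equal(invert_calibration(curve, y), conc, tolerance = 0.03)
  }
})

test_that("fit_absorptivity inverts Beer-Lambert exactly and under noise", {
  eps <- 2.05e-8; l <- 0.9
  conc <- seq(0, 3e5, length.out = 7)
  bl <- fit_absorptivity(eps * l * conc, conc, l)
  expect_equal(bl$epsilon, eps, tolerance = 1e-14)
  # pathlength cancels: any positive l returns the generating epsilon
  for (l2 in c(0.1, 0.87, 5)) {
    expect_equal(fit_absorptivity(eps * l2 * conc, conc, l2)$epsilon, eps,
                 tolerance = 1e-12)
  }
  expect_error(fit_absorptivity(c(0, 0), c(0, 0), 0.9), "degenerate")

  set.seed(11)
  conc8 <- seq(2e4, 2.6e5, length.out = 8)
  a_noisy <- eps * l * conc8 * (1 + stats::rnorm(8, sd = 0.01))
  expect_equal(fit_absorptivity(a_noisy, conc8, l)$epsilon, eps,
               tolerance = 0.05)
})

test_that("volume-normalized counts collapse two cell sizes onto one dry-weight line", {
  # one mass-per-volume constant: dry weight tracks total biovolume
  v <- 262; vmax <- 524
  mass_per_um3 <- 1e-10                      # mg per um^3
  counts <- seq(1e5, 8e5, length.out = 6)
  dw_full <- counts * vmax * mass_per_um3 * 1e3   # fully grown, mg/L
  dw_small <- counts * v * mass_per_um3 * 1e3     # growing cells

  x_norm <- c(counts, counts * v / vmax)
  y <- c(dw_full, dw_small)
  curve_norm <- fit_line(x_norm, y)
  curve_raw <- fit_line(c(counts, counts), y)
  expect_gte(curve_norm$r2, 0.99)
  expect_lt(curve_raw$r2, curve_norm$r2)

  ctx <- normalization_context(v, vmax)
  expect_equal(dry_weight_from_counts(counts[3], ctx, curve_norm),
               dw_small[3], tolerance = 1e-9)
  # zero counts map to the intercept; round trip is exact
  expect_equal(dry_weight_from_counts(0, ctx, curve_norm),
               curve_norm$intercept)
  dw <- dry_weight_from_counts(3e5, ctx, curve_norm)
  expect_equal(counts_from_dry_weight(dw, ctx, curve_norm), 3e5)
})
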