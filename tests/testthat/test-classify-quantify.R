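test_that("pure cultures are classified by their pigment signatures", {
  mods <- default_alga_models()
  # red algae: phycoerythrin evidence, phycobilin/chl fully explained
  d <- detect_groups(simulate_eem(mods$porp, 2e5, c(402, 523)),
                     blank_sigma = 1)
  expect_identical(d$group, "red")
  expect_equal(d$emission_nm[d$group == "red"], 580, tolerance = 2)

  # Cylindrospermum at 402 nm: cyanobacteria with the 619 nm marker
  d2 <- detect_groups(simulate_eem(mods$cyl, 3e5, 402), blank_sigma = 1)
  expect_identical(d2$group, "cyanobacteria")
  expect_true(d2$cyl_marker)
  # Anabaena lacks the marker
  d3 <- detect_groups(simulate_eem(mods$ana, 3e5, 523), blank_sigma = 1)
  expect_identical(d3$group, "cyanobacteria")
  expect_false(d3$cyl_marker)

  # all-zero spectra carry no groups
  grid <- default_grid()
  z <- eem(list(emission_spectrum(grid, rep(0, length(grid)), 523,
                                  blank_corrected = TRUE)))
  expect_identical(nrow(detect_groups(z, blank_sigma = 1)), 0L)

  # golden-brown algae only via the fucoxanthin absorbance bands
  ab <- simulate_absorbance(mods$cyc, 3e5)
  d4 <- detect_groups(z, abs_spec = ab, blank_sigma = 1)
  expect_identical(d4$group, "golden_brown")
})

test_that("detection and recovery are exact over all presence scenarios", {
  setup <- closed_loop_setup()
  truth_all <- c(green = 5e5, cyanobacteria = 2e5, red = 1e5)
  for (mask in 0:7) {
    present <- names(truth_all)[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    cells <- ifelse(names(truth_all) %in% present, truth_all, 0)
    ee <- simulate_mixture_eem(setup$models, cells, 523)
    d <- detect_groups(ee, blank_sigma = 1, ctx = setup$ctx)
    expect_setequal(d$group, present)
    q <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                              setup$ctx, blank_sigma = 1))
    for (g in names(truth_all)) {
      got <- q$cells_per_ml[q$group == g]
      if (g %in% present) {
        expect_lt(abs(got - truth_all[[g]]) / truth_all[[g]], 0.01)
      } else {
        expect_lt(got, 0.01 * max(truth_all))
      }
    }
  }
})

test_that("deconvolution conserves intensity and scales homogeneously", {
  setup <- closed_loop_setup()
  ee <- simulate_mixture_eem(setup$models, c(5e5, 2e5, 1e5), 523)
  q <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                            setup$ctx))
  expect_equal(q$share_subtracted + q$residual_intensity,
               q$measured_intensity, tolerance = 1e-12)

  # scaling every spectrum by alpha scales every concentration by alpha
  alpha <- 1.7
  scaled <- eem(lapply(ee$spectra, function(s) {
    s$intensity <- alpha * s$intensity
    s
  }))
  q2 <- suppressWarnings(deconvolve_quantify(scaled, setup$calibrations,
                                             setup$ctx))
  expect_equal(q2$cells_per_ml, alpha * q$cells_per_ml, tolerance = 1e-9)
})

test_that("pure-culture inputs keep the other groups at zero", {
  setup <- closed_loop_setup()
  # pure cyanobacteria: no green residual beyond the noise floor
  ee <- simulate_eem(setup$models$cyanobacteria, 2e5, 523)
  q <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                            setup$ctx, blank_sigma = 1))
  expect_equal(q$cells_per_ml[q$group == "cyanobacteria"], 2e5,
               tolerance = 0.01)
  expect_identical(q$cells_per_ml[q$group == "green"], 0)
  expect_false(q$residual_clamped[q$group == "green"])
  expect_true(q$below_noise[q$group == "green"])

  # pure red at 1% noise: phycocyanin fully explained by the beta share
  for (seed in 1:5) {
    eer <- simulate_eem(setup$models$red, 1e5, 523,
                        noise = noise_model(additive_sigma = 0,
                                            multiplicative_cv = 0.01,
                                            seed = seed))
    qr <- suppressWarnings(deconvolve_quantify(eer, setup$calibrations,
                                               setup$ctx,
                                               blank_sigma = 0.5))
    expect_identical(qr$cells_per_ml[qr$group == "cyanobacteria"], 0)
    expect_equal(qr$cells_per_ml[qr$group == "red"], 1e5,
                 tolerance = 0.05)
  }
})

test_that("noisy mixtures recover concentrations within a few percent", {
  setup <- closed_loop_setup()
  truth <- c(red = 1e5, cyanobacteria = 2e5, green = 5e5)
  errs <- sapply(1:100, function(seed) {
    ee <- simulate_mixture_eem(setup$models, c(5e5, 2e5, 1e5), 523,
                               noise = noise_model(additive_sigma = 0,
                                                   multiplicative_cv = 0.01,
                                                   seed = seed))
    q <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                              setup$ctx))
    abs(100 * (q$cells_per_ml[match(names(truth), q$group)] - truth) /
          truth)
  })
  expect_lt(stats::median(errs), 5)
})

test_that("a missing calibration errors for its group only", {
  setup <- closed_loop_setup()
  ee <- simulate_mixture_eem(setup$models, c(5e5, 2e5, 1e5), 523)
  cal <- setup$calibrations
  cal$green <- NULL
  q <- suppressWarnings(deconvolve_quantify(ee, cal, setup$ctx))
  expect_identical(q$status[q$group == "green"], "error")
  expect_true(is.na(q$cells_per_ml[q$group == "green"]))
  expect_identical(q$status[q$group != "green"], c("ok", "ok"))
  expect_false(any(is.na(q$cells_per_ml[q$group != "green"])))
})

test_that("inner-filter-aware deconvolution undoes the attenuation", {
  setup <- closed_loop_setup()
  reg <- default_genus_registry()
  ifp <- inner_filter_params(reg$porp$absorptivity[["523"]],
                            reg$porp$absorptivity[["580"]])
  conc <- 2.5e5
  ee <- simulate_eem(setup$models$red, conc, 523, inner_filter = ifp)
  plain <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                                setup$ctx))
  corrected <- suppressWarnings(deconvolve_quantify(ee, setup$calibrations,
                                                    setup$ctx, ifp = ifp))
  err_plain <- abs(plain$cells_per_ml[plain$group == "red"] - conc) / conc
  err_corr <- abs(corrected$cells_per_ml[corrected$group == "red"] - conc) /
    conc
  expect_gt(err_plain, 0.1)   # ~20% attenuation at this concentration
  expect_lt(err_corr, 0.01)
})

test_that("absorbance quantification inverts both fucoxanthin bands", {
  mods <- default_alga_models()
  w <- default_pigment_windows()
  l <- 0.9
  concs <- c(0, 1e5, 2e5, 4e5)
  series <- lapply(concs, function(conc)
    simulate_absorbance(mods$cyc, conc, pathlength_cm = l))
  peak_at <- function(win) vapply(series, function(ab)
    find_absorbance_peak(ab, w[[win]])$absorbance, numeric(1))
  cal <- list(fucoxanthin_449 = fit_line(concs, peak_at("fucoxanthin_449"),
                                         through_origin = TRUE),
              fucoxanthin_486 = fit_line(concs, peak_at("fucoxanthin_486"),
                                         through_origin = TRUE))
  # fitted slopes recover the printed absorptivities through A = eps*l*C
  expect_equal(fit_absorptivity(peak_at("fucoxanthin_449"), concs,
                                l)$epsilon, 2.05e-8, tolerance = 1e-3)
  expect_equal(fit_absorptivity(peak_at("fucoxanthin_486"), concs,
                                l)$epsilon, 1.54e-8, tolerance = 1e-3)
  ab <- simulate_absorbance(mods$cyc, 3e5, pathlength_cm = l)
  q <- quantify_absorbance(ab, cal)
  expect_equal(unname(q$per_band["fucoxanthin_449"]), 3e5,
               tolerance = 0.01)
  expect_equal(unname(q$per_band["fucoxanthin_486"]), 3e5,
               tolerance = 0.01)
  expect_lt(abs(q$per_band[1] - q$per_band[2]) / q$mean, 0.01)

  z <- simulate_absorbance(mods$cyc, 0)
  expect_equal(quantify_absorbance(z, cal)$mean, 0)
})

test_that("mixture additivity flags deliberate peak scaling", {
  grid <- seq(500, 800, 1)
  comp <- gaussian_spectrum(683, 8, grid = grid, amplitude = 200)
  mixture <- comp
  mixture$intensity <- comp$intensity * 1.075
  pd <- mixture_additivity(list(comp), mixture)
  expect_equal(unname(pd["chlorophyll_a"]), 100 * 0.075 / 1.0375,
               tolerance = 1e-9)
  expect_equal(round(unname(pd["chlorophyll_a"]), 1), 7.2)

  other_grid <- gaussian_spectrum(683, 8, grid = seq(501, 801, 1))
  expect_error(mixture_additivity(list(other_grid), mixture), "grid")
})

test_that("noisy four-genus mixtures sit in the expected additivity range", {
  mods <- default_alga_models()
  mix <- simulate_mixture(mods[c("anki", "chlor", "ana", "cyl")],
                          c(1e5, 2e5, 2e5, 2e5), 523,
                          noise = noise_model(additive_sigma = 0,
                                              multiplicative_cv = 0.02,
                                              seed = 11))
  pd <- mixture_additivity(mix$components, mix$mixture)
  key <- pd[c("phycocyanin", "chlorophyll_a")]
  # same order of magnitude as single-percent discrepancies, never tens
  expect_true(all(key > 0.01 & key < 30))
})

test_that("the field workflow matches truth through both pigment routes", {
  mods <- default_alga_models()
  reg <- default_genus_registry()
  w <- default_pigment_windows()
  concs <- c(0, 1e5, 3e5, 5e5)
  cal_pc <- fit_line(concs, generate_calibration_series(
    mods$ana, concs, 612, w$phycocyanin)$intensity)
  cal_chl <- fit_line(concs, generate_calibration_series(
    mods$ana, concs, 612, w$chlorophyll_a)$intensity)
  truth <- 4.56e5
  ee <- simulate_eem(mods$microcystis, truth, 612)
  fw <- field_sample_workflow(ee, list(phycocyanin = cal_pc,
                                       chlorophyll_a = cal_chl),
                              reference_v_um3 = reg$ana$volume_um3,
                              target_v_um3 = reg$microcystis$volume_um3,
                              reference_count = truth)
  expect_equal(round(fw$volume_ratio, 2), 0.78)
  expect_lt(abs(fw$cells_via_phycocyanin - truth) / truth, 0.02)
  expect_lt(abs(fw$cells_via_chlorophyll_a - truth) / truth, 0.02)
  expect_lt(fw$percent_difference_routes, 2)

  # identical volumes reduce to plain calibration inversion
  ee_ana <- simulate_eem(mods$ana, 3e5, 612)
  fw2 <- field_sample_workflow(ee_ana, list(phycocyanin = cal_pc,
                                            chlorophyll_a = cal_chl),
                               reference_v_um3 = reg$ana$volume_um3,
                               target_v_um3 = reg$ana$volume_um3)
  expect_identical(fw2$volume_ratio, 1)
  expect_equal(fw2$cells_via_phycocyanin, 3e5, tolerance = 1e-6)
})
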