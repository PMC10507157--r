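test_that("library: six classes, shared reporter and IS bands, distinct signatures", {
  lib <- aldehyde_library()
  expect_setequal(unique(lib$class), aldehyde_classes())

  for (cl in aldehyde_classes()) {
    peaks <- lib[lib$class == cl, ]
    expect_setequal(peaks$center[peaks$role == "reporter"],
                    c(1141, 1179, 1593))
    expect_equal(peaks$center[peaks$role == "internal_standard"], 1985)
    expect_gte(sum(peaks$role == "characteristic"), 1)
  }

  # no two classes share an identical multiset of characteristic centers
  sigs <- lapply(aldehyde_classes(), function(cl) {
    sort(lib$center[lib$class == cl & lib$role == "characteristic"])
  })
  for (i in seq_along(sigs)) {
    for (j in seq_along(sigs)) {
      if (i < j) expect_false(identical(sigs[[i]], sigs[[j]]))
    }
  }

  # all peaks live on the working axis
  expect_true(all(lib$center >= 1000 & lib$center <= 2300))
  # one strongest characteristic band per class, all within the C=N/C-C band
  sp <- strongest_peaks()
  expect_equal(nrow(sp), 6)
  expect_true(all(sp$center >= 1545 & sp$center < 1800))
})

test_that("generator degenerate cases match closed forms", {
  x <- default_axis()

  # blank at zero amplitudes, zero noise, zero baseline -> all-zero spectrum
  cfg0 <- generator_config("easy", noise_sd = 0, center_jitter_sd = 0,
                           misc_peak_rate = 0, baseline_coefs = c(0, 0, 0),
                           reporter_amplitude = 0, is_amplitude = 0)
  blank <- generate_spectrum("benzaldehyde", 0, cfg0, seed = 1)
  expect_equal(max(abs(blank$intensity)), 0)

  # deterministic oxalaldehyde: local maximum at the axis point nearest 1632
  cfg <- generator_config("easy", noise_sd = 0, center_jitter_sd = 0,
                          misc_peak_rate = 0)
  sp <- generate_spectrum("oxalaldehyde", 1e-7, cfg, seed = 1)
  near <- which.min(abs(x - 1632))
  band <- which(x > 1620 & x < 1645)
  expect_equal(band[which.max(sp$intensity[band])], near)

  # single on-grid Lorentzian evaluates to its amplitude at the center
  center <- x[200]
  expect_equal(lor(center, center, 5, 10), 5)
  y <- sersvoc:::peak_profile(x, center, 5, 10, "lorentzian")
  expect_identical(y[200], 5)
  expect_equal(y, lor(x, center, 5, 10))
  yg <- sersvoc:::peak_profile(x, center, 5, 10, "gaussian")
  expect_identical(yg[200], 5)
  # half maximum at half the FWHM from the center, by definition
  expect_equal(sersvoc:::peak_profile(center + 5, center, 5, 10, "gaussian"),
               2.5)
  expect_equal(sersvoc:::peak_profile(center - 5, center, 5, 10,
                                      "lorentzian"), 2.5)
})

test_that("generator rejects invalid inputs", {
  cfg <- generator_config("easy")
  expect_error(generate_spectrum("acetone", 1e-7, cfg), "unknown class")
  expect_error(generate_spectrum("benzaldehyde", -1, cfg), ">= 0")
  expect_error(generate_dataset(classes = character(0)), "empty class list")
  expect_error(generate_calibration_series(concentrations = c(1e-6, 0)),
               "> 0")
  expect_error(generator_config("easy", noise_sd = -1), ">= 0")
})

test_that("dataset generation: exact counts, replicate cycling, determinism", {
  cfg <- generator_config("easy")
  ds <- generate_dataset(n_per_class = 4, config = cfg, seed = 9)
  meta <- spectra_meta(ds)
  expect_equal(nrow(meta), 24)
  expect_true(all(table(meta$label) == 4))
  expect_equal(sort(unique(meta$replicate)), 1:4)

  ds2 <- generate_dataset(n_per_class = 4, config = cfg, seed = 9)
  expect_identical(ds, ds2)

  one <- generate_dataset(n_per_class = 1, classes = "formaldehyde",
                          config = cfg, seed = 2)
  expect_equal(spectra_meta(one)$label, "formaldehyde")
})

test_that("per-spectrum seed streams make class draws independent", {
  cfg <- generator_config("easy")
  all6 <- generate_dataset(n_per_class = 3, config = cfg, seed = 5)
  sub <- generate_dataset(n_per_class = 3,
                          classes = aldehyde_classes()[1:2],
                          config = cfg, seed = 5)
  # first two classes unchanged when later classes are dropped
  a <- all6[all6$label %in% aldehyde_classes()[1:2], ]
  expect_equal(a$intensity, sub$intensity)
})

test_that("class identifiability: band argmax recovers the strongest peak", {
  cfg <- generator_config("easy", center_jitter_sd = 2, misc_peak_rate = 0)
  ds <- generate_dataset(n_per_class = 100, config = cfg, seed = 21)
  feats <- featurize_spectra(ds, normalize = FALSE)
  sp <- strongest_peaks()
  expected <- setNames(sp$center, sp$class)
  err <- abs(feats$f11 - expected[feats$label])
  expect_true(all(err <= 8))  # 4 jitter SDs + one grid step
})

test_that("mean measured ratio converges to the configured log-linear law", {
  expected <- function(cfg) cfg$response_slope * log10(1e-6) +
    cfg$response_intercept

  # additive noise averages out: mean of 200 replicates within 3 SE
  cfg <- generator_config("easy", center_jitter_sd = 0)
  ser <- generate_calibration_series(concentrations = 1e-6, config = cfg,
                                     seed = 13, n_replicates = 200)
  r <- ratiometric_signal(ser)
  se <- sd(r$ratio) / sqrt(nrow(r))
  expect_lt(abs(mean(r$ratio) - expected(cfg)), 3 * se)

  # center jitter attenuates the windowed maximum slightly; the systematic
  # effect stays small (~1%) at the easy-preset jitter of 1 cm^-1
  cfgj <- generator_config("easy")
  rj <- ratiometric_signal(generate_calibration_series(
    concentrations = 1e-6, config = cfgj, seed = 14, n_replicates = 200))
  expect_lt(abs(mean(rj$ratio) - expected(cfgj)) / expected(cfgj), 0.02)
})

test_that("calibration series covers the five decades with expected ratios", {
  cfg <- generator_config("easy", noise_sd = 0, center_jitter_sd = 0,
                          misc_peak_rate = 0)
  ser <- generate_calibration_series(config = cfg, seed = 1,
                                     n_replicates = 1)
  meta <- spectra_meta(ser)
  expect_equal(sort(unique(meta$concentration)), 10^seq(-8, -4))
  r <- ratiometric_signal(ser)
  expected <- pmax(0, cfg$response_slope * log10(r$concentration) +
                     cfg$response_intercept)
  expect_equal(r$ratio, expected, tolerance = 1e-5)
})
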