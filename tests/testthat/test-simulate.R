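test_that("a single noiseless band evaluates to its Lorentzian peak", {
  axis <- seq(400, 3200, by = 1)
  prof <- one_band_profile(center = 1349, amplitude = 100, fwhm = 10)
  sp <- simulate_spectrum(prof, axis, seed = 1)
  expect_equal(sp$intensities[axis == 1349], 100)
  expect_lt(sp$intensities[axis == 3000], 0.01)
})

test_that("a zero-amplitude band leaves exactly the baseline", {
  axis <- short_axis()
  prof <- one_band_profile(amplitude = 0, baseline_poly = c(10, 5, -3, 1),
                           hump_height = 20)
  sp <- simulate_spectrum(prof, axis, seed = 3)
  expect_equal(sp$intensities, sersml:::baseline_curve(prof, axis))
})

test_that("simulation is a pure function of profile, axis and seed", {
  prof <- preset_profile("a549-like")
  axis <- default_axis()
  a <- simulate_spectrum(prof, axis, seed = 11)
  b <- simulate_spectrum(prof, axis, seed = 11)
  c <- simulate_spectrum(prof, axis, seed = 12)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))

  d1 <- simulate_dataset(list(trimmed_preset("a549-like", short_axis()),
                              trimmed_preset("beas2b-like", short_axis())),
                         5, axis = short_axis(), seed = 2)
  d2 <- simulate_dataset(list(trimmed_preset("a549-like", short_axis()),
                              trimmed_preset("beas2b-like", short_axis())),
                         5, axis = short_axis(), seed = 2)
  expect_identical(d1$matrix, d2$matrix)
})

test_that("band centers outside the axis raise a configuration error", {
  expect_error(
    simulate_spectrum(one_band_profile(center = 2000), short_axis(), 1),
    "outside")
})

test_that("a campaign of 135 spectra per class yields balanced labels", {
  d <- simulate_dataset(list(trimmed_preset("cancer-like", short_axis()),
                             trimmed_preset("normal-like", short_axis())),
                        135, axis = short_axis(), seed = 4)
  expect_equal(n_spectra(d), 270L)
  expect_equal(unname(table(d$labels)["cancer-like"]), 135L)
  expect_equal(unname(table(d$labels)["normal-like"]), 135L)
  expect_false(anyDuplicated(d$ids) > 0)
})

test_that("duplicate class names are rejected", {
  expect_error(
    simulate_dataset(list(preset_profile("a549-like"),
                          preset_profile("a549-like")), 2),
    "distinct")
})

test_that("cancer-like presets are stronger at 1349/1437, normal-like at 1078/1221", {
  axis <- default_axis()
  ca <- preset_profile("cancer-like")
  no <- preset_profile("normal-like")
  tc <- class_template(ca, axis)
  tn <- class_template(no, axis)
  at <- function(v, w) v[which.min(abs(axis - w))]
  expect_gt(at(tc, 1349), at(tn, 1349))
  expect_gt(at(tc, 1437), at(tn, 1437))
  expect_gt(at(tn, 1078), at(tc, 1078))
  expect_gt(at(tn, 1221), at(tc, 1221))

  # the same ordering holds for mean simulated (noisy) intensities
  nd <- 60
  mc <- colMeans(simulate_dataset(list(ca), nd, axis, seed = 9)$matrix)
  mn <- colMeans(simulate_dataset(list(no), nd, axis, seed = 10)$matrix)
  expect_gt(at(mc, 1349), at(mn, 1349))
  expect_gt(at(mn, 1078), at(mc, 1078))
  expect_gt(at(mn, 1221), at(mc, 1221))
})

test_that("five presets share the band list and differ only in amplitudes", {
  profs <- lapply(preset_names(), preset_profile)
  centers <- lapply(profs, function(p) vapply(p$bands, `[[`, 0, "center"))
  fwhms <- lapply(profs, function(p) vapply(p$bands, `[[`, 0, "fwhm"))
  for (i in 2:5) {
    expect_identical(centers[[i]], centers[[1]])
    expect_identical(fwhms[[i]], fwhms[[1]])
  }
  amps <- vapply(profs, function(p) vapply(p$bands, `[[`, 0, "amplitude_mean"),
                 numeric(8))
  expect_true(all(apply(amps, 2, function(a) any(a != amps[, 1])) [-1]))
})

test_that("the empirical mean over many draws converges to the template", {
  axis <- short_axis()
  prof <- one_band_profile(center = 1000, amplitude = 80, fwhm = 12,
                           cv = 0, noise_sd = 5,
                           baseline_poly = c(20, 10, 0, 0))
  n <- 1000
  d <- simulate_dataset(list(prof), n, axis, seed = 21)
  template <- class_template(prof, axis)
  dev <- abs(colMeans(d$matrix) - template)
  # at the band center the mean sits within 4 standard errors; across all
  # 601 grid points allow for the maximum of that many z-scores
  expect_lt(dev[which.min(abs(axis - 1000))], 4 * 5 / sqrt(n))
  expect_lt(max(dev), 5 * 5 / sqrt(n))
})

test_that("mixtures are convex combinations of the pure templates", {
  axis <- short_axis()
  pa <- one_band_profile(center = 800, amplitude = 100)
  pb <- one_band_profile(center = 1200, amplitude = 60,
                         baseline_poly = c(5, 0, 0, 0))
  pa$name <- "pa"; pb$name <- "pb"
  ta <- class_template(pa, axis); tb <- class_template(pb, axis)

  half <- simulate_mixture(pa, pb, 0.5, axis, seed = 5)
  expect_equal(half$intensities, 0.5 * ta + 0.5 * tb, tolerance = 1e-12)

  pure <- simulate_mixture(pa, pb, 1.0, axis, seed = 5)
  ref <- simulate_spectrum(pa, axis, seed = 5)
  expect_identical(pure$intensities, ref$intensities)

  near <- simulate_mixture(pa, pb, 0.99, axis, seed = 5)
  expect_equal(near$intensities, 0.99 * ta + 0.01 * tb, tolerance = 1e-12)
  expect_lte(max(abs(near$intensities - ta)),
             0.01 * (max(ta) + max(tb)) + 1e-9)

  expect_error(simulate_mixture(pa, pb, 1.2, axis, 1), "\\[0, 1\\]")
})

test_that("mixture datasets carry one ratio label per group", {
  pa <- preset_profile("a549-like"); pb <- preset_profile("beas2b-like")
  d <- simulate_mixture_dataset(pa, pb, n_per_fraction = 3, seed = 2)
  expect_setequal(unique(d$labels), c("99:1", "90:10", "75:25", "50:50"))
  expect_equal(n_spectra(d), 12L)
})

test_that("raising class contrast raises downstream two-class accuracy", {
  acc_at <- function(contrast, seed) {
    profs <- list(preset_profile("cancer-like", contrast = contrast),
                  preset_profile("normal-like", contrast = contrast))
    d <- simulate_dataset(profs, 40, seed = seed)
    cl <- preprocess(d)
    parts <- split_dataset(cl, c(0.6, 0.1, 0.3), seed = seed + 1000)
    pca <- fit_pca(parts$train$matrix, 2)
    svm <- train_svm(pca$scores, parts$train$labels,
                     svm_config("linear", 10, 100))
    pred <- svm_predict(svm, pca_transform(pca, parts$test$matrix))$classes
    mean(pred == parts$test$labels)
  }
  lo <- vapply(1:5, function(s) acc_at(0.3, s), 0)
  hi <- vapply(1:5, function(s) acc_at(1.0, s), 0)
  expect_gt(mean(hi), mean(lo))
})
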