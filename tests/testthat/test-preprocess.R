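test_that("an injected cosmic-ray spike is removed and nothing else changes", {
  sp <- smooth_spectrum(300)
  sigma <- stats::mad(diff(sp$intensities)) / sqrt(2)
  spiked <- sp
  spiked$intensities[150] <- spiked$intensities[150] + 50 * max(sigma, 1)
  out <- despike(spiked)
  expect_equal(out$intensities[-150], sp$intensities[-150])
  expect_lt(abs(out$intensities[150] - sp$intensities[150]),
            5 * max(sigma, 1))
})

test_that("a spike-free smooth spectrum passes through despiking unchanged", {
  sp <- smooth_spectrum(300)
  expect_identical(despike(sp)$intensities, sp$intensities)
})

test_that("edge spikes are handled by padded windows", {
  sp <- smooth_spectrum(100)
  spiked <- sp
  spiked$intensities[1] <- spiked$intensities[1] + 500
  out <- despike(spiked)
  expect_lt(abs(out$intensities[1] - sp$intensities[1]), 5)
  expect_equal(out$intensities[-1], sp$intensities[-1])
})

test_that("despiking is idempotent on noisy spiked spectra", {
  set.seed(31)
  for (rep in 1:5) {
    x <- 100 + 20 * sin(seq_len(400) / 25) + rnorm(400, 0, 2)
    x[sample(400, 3)] <- x[sample(400, 3)] + 300
    sp <- sers_spectrum(seq_len(400), x)
    once <- despike(sp)
    twice <- despike(once)
    expect_identical(twice$intensities, once$intensities)
  }
})

test_that("despike validates its window", {
  sp <- smooth_spectrum(50)
  expect_error(despike(sp, window = 4), "odd")
  expect_error(despike(sp, window = 51), "smaller")
})

test_that("MPLS on a constant spectrum returns the constant and zero residual", {
  sp <- sers_spectrum(seq_len(200), rep(5, 200))
  out <- mpls_baseline(sp, mpls_params(struct_width = 21))
  expect_equal(out$baseline$intensities, rep(5, 200), tolerance = 1e-8)
  expect_equal(out$corrected$intensities, rep(0, 200), tolerance = 1e-8)
})

test_that("MPLS recovers a known linear baseline under a Lorentzian peak", {
  n <- 1000
  axis <- seq_len(n)
  base <- 0.01 * axis
  peak <- 100 * sersml:::lorentzian(axis, 500, 10)
  sp <- sers_spectrum(axis, base + peak)
  out <- mpls_baseline(sp, mpls_params(struct_width = 75))
  corrected <- out$corrected$intensities
  expect_lt(abs(max(corrected[480:520]) - 100) / 100, 0.05)
  off_peak <- c(60:400, 600:950)
  expect_lt(abs(stats::median(corrected[off_peak])), 0.5)
})

test_that("a pure cubic baseline is removed almost completely", {
  n <- 1401
  t <- seq(0, 1, length.out = n)
  base <- 100 + 50 * t - 80 * t^2 + 40 * t^3
  sp <- sers_spectrum(seq_len(n), base)
  out <- mpls_baseline(sp)
  expect_lt(max(abs(out$corrected$intensities)),
            0.01 * diff(range(base)))
})

test_that("baseline plus corrected reconstructs the input exactly", {
  set.seed(41)
  x <- 200 + 100 * sersml:::lorentzian(1:500, 250, 12) + rnorm(500, 0, 5)
  sp <- sers_spectrum(1:500, x)
  out <- mpls_baseline(sp, mpls_params(struct_width = 51))
  expect_identical(out$baseline$intensities + out$corrected$intensities, x)
})

test_that("the refined baseline is smoother than the raw opening", {
  set.seed(42)
  x <- 100 + 0.1 * (1:600) + rnorm(600, 0, 8)
  sp <- sers_spectrum(1:600, x)
  out <- mpls_baseline(sp)
  opening <- sersml:::morphological_opening(x, 75)
  d2 <- function(v) sum(diff(v, differences = 2)^2)
  expect_lt(d2(out$baseline$intensities), d2(opening))
})

test_that("MPLS parameter invariants are enforced", {
  expect_error(mpls_params(struct_width = 74), "odd")
  expect_error(mpls_params(penalty = 0), "positive")
  expect_error(mpls_params(flat_proportion = 0.7), "0.5")
  expect_error(mpls_params(diff_order = 3), "1 or 2")
  sp <- smooth_spectrum(50)
  expect_error(mpls_baseline(sp, mpls_params(struct_width = 75)), "smaller")
})

test_that("DFT smoothing leaves constants and passband cosines unchanged", {
  n <- 512
  sp <- sers_spectrum(seq_len(n), rep(7, n))
  expect_equal(dft_smooth(sp)$intensities, rep(7, n), tolerance = 1e-10)

  w <- window_spec(cutoff_fraction = 0.2, rolloff_fraction = 0.05)
  k <- 10   # frequency fraction 2*10/512 = 0.039 << 0.15 passband edge
  x <- cos(2 * pi * k * seq(0, n - 1) / n)
  sp2 <- sers_spectrum(seq_len(n), x)
  expect_equal(dft_smooth(sp2, w)$intensities, x, tolerance = 1e-8)
})

test_that("DFT smoothing equals explicit circular convolution and shrinks noise", {
  set.seed(51)
  n <- 256
  x <- rnorm(n)
  w <- window_spec()
  ww <- window_weights(w, n)
  h <- Re(stats::fft(ww, inverse = TRUE)) / n   # impulse response
  oracle <- vapply(seq_len(n), function(i) {
    sum(x * h[((i - seq_len(n)) %% n) + 1])
  }, 0)
  sp <- sers_spectrum(seq_len(n), x)
  out <- dft_smooth(sp, w)$intensities
  expect_equal(out, oracle, tolerance = 1e-9)
  expect_lt(stats::var(out), stats::var(x))
  expect_equal(mean(out), mean(x), tolerance = 1e-12)   # DC preserved
})

test_that("DFT smoothing is linear", {
  set.seed(52)
  x <- rnorm(128); y <- rnorm(128)
  sp <- function(v) sers_spectrum(seq_len(128), v)
  lhs <- dft_smooth(sp(2 * x - 3 * y))$intensities
  rhs <- 2 * dft_smooth(sp(x))$intensities - 3 * dft_smooth(sp(y))$intensities
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("window specifications are validated", {
  expect_error(window_spec(cutoff_fraction = 0), "cutoff")
  expect_error(window_spec(rolloff_fraction = 0.2, cutoff_fraction = 0.1),
               "rolloff")
  expect_error(window_spec(kind = "highpass"), "unknown")
  expect_error(dft_smooth(sers_spectrum(1:3, 1:3)), "short")
})

test_that("the full chain preserves band-center locations", {
  axis <- default_axis()
  prof <- preset_profile("cancer-like")
  template <- class_template(prof, axis)
  win <- which(abs(axis - 1349) <= 30)
  true_center <- win[which.max(template[win])]
  for (seed in 1:3) {
    sp <- simulate_spectrum(prof, axis, seed = seed)
    clean <- preprocess(sp)
    got <- win[which.max(clean$intensities[win])]
    expect_lte(abs(got - true_center), 1L)
  }
})
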