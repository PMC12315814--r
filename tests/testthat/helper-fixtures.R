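# Shared fixtures: small axes and profiles keep module tests fast; the
# full-scale pipeline runs used by the acceptance tests are cached so the
# same fitted models can be interrogated by several test blocks.

short_axis <- function() seq(400, 1600, by = 2)   # 601 points

smooth_spectrum <- function(n = 200, axis = seq_len(n)) {
  sers_spectrum(axis, 50 + 10 * sin(axis / 15) + 0.02 * axis)
}

one_band_profile <- function(center = 1000, amplitude = 100, fwhm = 10,
                             cv = 0, noise_sd = 0, spike_rate = 0,
                             baseline_poly = c(0, 0, 0, 0), hump_height = 0) {
  class_profile("test",
                list(band_spec(center, amplitude, cv, fwhm)),
                baseline_poly = baseline_poly,
                hump = c(1200, 80, hump_height),
                noise_sd = noise_sd, spike_rate = spike_rate)
}

# preset profile with bands outside the axis dropped, for short-axis tests
trimmed_preset <- function(name, axis, noise_sd = 5, spike_rate = 0) {
  p <- preset_profile(name, noise_sd = noise_sd, spike_rate = spike_rate)
  keep <- vapply(p$bands, function(b) {
    b$center >= axis[1] && b$center <= axis[length(axis)]
  }, TRUE)
  p$bands <- p$bands[keep]
  p
}

# two small well-separated Gaussian blobs for SVM tests
blob_data <- function(n = 50, gap = 5, seed = 1, p = 2) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n * p), n, p),
             matrix(stats::rnorm(n * p, mean = gap), n, p))
  list(X = X, y = rep(c("a", "b"), each = n))
}

# memoised full-scale pipeline runs shared across acceptance blocks
.pipeline_cache <- new.env(parent = emptyenv())

cached_two_class_run <- function(seed) {
  key <- paste0("svm2_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_two_class_svm(seed = seed)
  }
  .pipeline_cache[[key]]
}
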