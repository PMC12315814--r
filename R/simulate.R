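#' Default wavenumber grid
#'
#' 400-3200 cm^-1 at 2 cm^-1 spacing (1401 points), spanning every band used
#' by the built-in class profiles (493-2913 cm^-1) at a realistic dispersion.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_axis <- function() seq(400, 3200, by = 2)

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Describe one Raman band
#'
#' @param center Band position in cm^-1.
#' @param amplitude_mean Mean peak amplitude in counts (>= 0).
#' @param amplitude_cv Coefficient of variation of the per-spectrum amplitude
#'   draw (unitless, >= 0).
#' @param fwhm Full width at half maximum in cm^-1 (> 0). Lorentzian shape.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(center, amplitude_mean, amplitude_cv = 0.06, fwhm = 14) {
  stopifnot(amplitude_mean >= 0, amplitude_cv >= 0, fwhm > 0)
  structure(list(center = center, amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv, fwhm = fwhm),
            class = "band_spec")
}

#' Describe the generating model of one spectral class
#'
#' A class is a list of Lorentzian bands on top of a smooth drifting baseline
#' (cubic polynomial in normalised axis position plus one broad Gaussian
#' hump), Gaussian point noise, and occasional single-point cosmic-ray
#' spikes.
#'
#' @param name Class name.
#' @param bands List of [band_spec()] objects (at least one).
#' @param baseline_poly Polynomial coefficients (intercept first, order <= 3)
#'   evaluated in the normalised coordinate t in \[0, 1\] along the axis.
#' @param hump `c(center, width, height)` of a broad Gaussian baseline hump
#'   (cm^-1, cm^-1 standard deviation, counts); height 0 disables it.
#' @param noise_sd Additive Gaussian noise standard deviation (counts, >= 0).
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson mean,
#'   >= 0).
#' @param spike_amplitude Spike height in counts.
#' @return A list of class `class_profile`.
#' @export
class_profile <- function(name, bands, baseline_poly = c(0, 0, 0, 0),
                          hump = c(1598, 80, 0), noise_sd = 0,
                          spike_rate = 0, spike_amplitude = 800) {
  stopifnot(length(bands) >= 1L, noise_sd >= 0, spike_rate >= 0)
  if (!all(vapply(bands, inherits, TRUE, "band_spec"))) {
    stop("bands must be a list of band_spec objects", call. = FALSE)
  }
  if (length(baseline_poly) > 4L) {
    stop("baseline polynomial order must be <= 3", call. = FALSE)
  }
  structure(list(name = name, bands = bands, baseline_poly = baseline_poly,
                 hump = hump, noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amplitude = spike_amplitude),
            class = "class_profile")
}

# Unit-amplitude Lorentzian: value 1 at the centre.
lorentzian <- function(axis, center, fwhm) {
  h <- (fwhm / 2)^2
  h / ((axis - center)^2 + h)
}

baseline_curve <- function(profile, axis) {
  t <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
  out <- rep(0, length(axis))
  for (k in seq_along(profile$baseline_poly)) {
    out <- out + profile$baseline_poly[k] * t^(k - 1L)
  }
  if (profile$hump[3L] != 0) {
    out <- out + profile$hump[3L] *
      exp(-0.5 * ((axis - profile$hump[1L]) / profile$hump[2L])^2)
  }
  out
}

#' Noiseless template of a class
#'
#' Mean-amplitude Lorentzian bands plus the baseline, with no noise or
#' spikes: the expectation of [simulate_spectrum()] over draws.
#'
#' @param profile A [class_profile()].
#' @param axis Wavenumber grid.
#' @return Numeric intensity vector.
#' @export
class_template <- function(profile, axis) {
  check_bands_on_axis(profile, axis)
  sig <- baseline_curve(profile, axis)
  for (b in profile$bands) {
    sig <- sig + b$amplitude_mean * lorentzian(axis, b$center, b$fwhm)
  }
  sig
}

check_bands_on_axis <- function(profile, axis) {
  ctr <- vapply(profile$bands, `[[`, 0, "center")
  if (any(ctr < axis[1L] | ctr > axis[length(axis)])) {
    stop("band center outside the wavenumber axis", call. = FALSE)
  }
  invisible(TRUE)
}

# Signal draw shared by simulate_spectrum and simulate_mixture: bands with
# per-spectrum amplitude jitter, plus baseline. Consumes length(bands)
# normal deviates.
draw_signal <- function(profile, axis) {
  sig <- baseline_curve(profile, axis)
  for (b in profile$bands) {
    amp <- b$amplitude_mean * max(0, 1 + b$amplitude_cv * stats::rnorm(1L))
    sig <- sig + amp * lorentzian(axis, b$center, b$fwhm)
  }
  sig
}

add_noise_and_spikes <- function(sig, axis, noise_sd, spike_rate,
                                 spike_amplitude) {
  sig <- sig + stats::rnorm(length(axis), 0, noise_sd)
  n_sp <- stats::rpois(1L, spike_rate)
  if (n_sp > 0L) {
    pos <- sample.int(length(axis), min(n_sp, length(axis)))
    sig[pos] <- sig[pos] + spike_amplitude * stats::runif(length(pos), 0.8, 1.2)
  }
  sig
}

#' Simulate one SERS spectrum
#'
#' Intensity = sum of Lorentzian bands with amplitudes drawn around their
#' means + baseline + Gaussian noise + Poisson-count single-point positive
#' spikes. The output is a pure function of `(profile, axis, seed)`.
#'
#' @param profile A [class_profile()].
#' @param axis Strictly increasing wavenumber grid.
#' @param seed Integer seed.
#' @param sample_id Sample id for the resulting spectrum.
#' @return A [sers_spectrum()] labelled with the profile's class name.
#' @export
simulate_spectrum <- function(profile, axis, seed, sample_id = NULL) {
  if (any(diff(axis) <= 0)) {
    stop("axis must be strictly increasing", call. = FALSE)
  }
  check_bands_on_axis(profile, axis)
  if (is.null(sample_id)) sample_id <- paste0(profile$name, "_", seed)
  intens <- with_seed(seed, {
    add_noise_and_spikes(draw_signal(profile, axis), axis, profile$noise_sd,
                         profile$spike_rate, profile$spike_amplitude)
  })
  sers_spectrum(axis, intens, sample_id = sample_id, label = profile$name)
}

#' Simulate a labelled dataset of spectra
#'
#' `n_per_class` seeded draws from each class profile, mirroring an
#' acquisition campaign of equal per-class sample counts.
#'
#' @param profiles List of [class_profile()] objects with distinct names.
#' @param n_per_class Spectra per class (>= 1).
#' @param axis Wavenumber grid; defaults to [default_axis()].
#' @param seed Integer seed; each spectrum uses a sub-seed derived from it.
#' @return A [sers_set()] with `n_per_class * length(profiles)` rows.
#' @export
simulate_dataset <- function(profiles, n_per_class, axis = default_axis(),
                             seed = 1L) {
  stopifnot(n_per_class >= 1L)
  nms <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("class profiles must have distinct names", call. = FALSE)
  }
  sets <- vector("list", length(profiles) * n_per_class)
  k <- 0L
  for (p in seq_along(profiles)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sub_seed <- (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
      sets[[k]] <- simulate_spectrum(
        profiles[[p]], axis, sub_seed,
        sample_id = sprintf("%s_%03d", nms[p], i))
    }
  }
  sers_set(axis, do.call(rbind, lapply(sets, `[[`, "intensities")),
           labels = unlist(lapply(sets, `[[`, "label")),
           ids = vapply(sets, `[[`, "", "sample_id"))
}

#' Simulate a two-class mixture spectrum
#'
#' The noiseless expectation is the convex combination
#' `fraction_a * template_a + (1 - fraction_a) * template_b`; noise and
#' spikes are drawn once with mixed parameters. At `fraction_a` 0 or 1 the
#' output is identical to the corresponding pure-class simulation at the
#' same seed.
#'
#' @param profile_a,profile_b [class_profile()] objects.
#' @param fraction_a Mixing proportion of `profile_a` in \[0, 1\].
#' @param axis Wavenumber grid.
#' @param seed Integer seed.
#' @param sample_id Sample id.
#' @return A [sers_spectrum()] labelled `"<a>:<b>:<fraction_a>"`.
#' @export
simulate_mixture <- function(profile_a, profile_b, fraction_a,
                             axis = default_axis(), seed = 1L,
                             sample_id = NULL) {
  if (fraction_a < 0 || fraction_a > 1) {
    stop("fraction_a must be in [0, 1]", call. = FALSE)
  }
  if (fraction_a == 1) {
    sp <- simulate_spectrum(profile_a, axis, seed, sample_id)
  } else if (fraction_a == 0) {
    sp <- simulate_spectrum(profile_b, axis, seed, sample_id)
  } else {
    check_bands_on_axis(profile_a, axis)
    check_bands_on_axis(profile_b, axis)
    f <- fraction_a
    intens <- with_seed(seed, {
      sig <- f * draw_signal(profile_a, axis) +
        (1 - f) * draw_signal(profile_b, axis)
      add_noise_and_spikes(
        sig, axis,
        f * profile_a$noise_sd + (1 - f) * profile_b$noise_sd,
        f * profile_a$spike_rate + (1 - f) * profile_b$spike_rate,
        f * profile_a$spike_amplitude + (1 - f) * profile_b$spike_amplitude)
    })
    if (is.null(sample_id)) {
      sample_id <- sprintf("%s_%s_%g_%d", profile_a$name, profile_b$name,
                           fraction_a, seed)
    }
    sp <- sers_spectrum(axis, intens, sample_id = sample_id)
  }
  sp$label <- sprintf("%s:%s:%g", profile_a$name, profile_b$name, fraction_a)
  sp
}

#' Simulate a dataset of two-class mixtures at several ratios
#'
#' One class per mixing ratio (labelled e.g. `"99:1"`), emulating mixture
#' series measured at ratios 99:1, 90:10, 75:25 and 50:50.
#'
#' @param profile_a,profile_b [class_profile()] objects.
#' @param fractions Proportions of `profile_a`; default the four ratios
#'   above.
#' @param n_per_fraction Spectra per ratio.
#' @param axis Wavenumber grid.
#' @param seed Integer seed.
#' @return A [sers_set()] with labels of the form `"99:1"`.
#' @export
simulate_mixture_dataset <- function(profile_a, profile_b,
                                     fractions = c(0.99, 0.90, 0.75, 0.50),
                                     n_per_fraction = 135L,
                                     axis = default_axis(), seed = 1L) {
  rows <- list(); labs <- character(); ids <- character()
  k <- 0L
  for (f in fractions) {
    lab <- sprintf("%g:%g", 100 * f, 100 * (1 - f))
    for (i in seq_len(n_per_fraction)) {
      k <- k + 1L
      sub_seed <- (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
      sp <- simulate_mixture(profile_a, profile_b, f, axis, sub_seed,
                             sample_id = sprintf("mix%s_%03d", lab, i))
      rows[[k]] <- sp$intensities
      labs[k] <- lab
      ids[k] <- sp$sample_id
    }
  }
  sers_set(axis, do.call(rbind, rows), labs, ids)
}

# Common band list shared by all five presets: positions (cm^-1) with
# assignments glycogen 493; amide IV 741; benzene-ring breathing 1011;
# C-C / C-N stretching 1078; amide III 1221; CH bending / C-C stretching
# 1349; CH2 bending of lipids 1437; C-H stretching of lipids/proteins 2913.
preset_band_table <- function() {
  data.frame(
    center = c(493, 741, 1011, 1078, 1221, 1349, 1437, 2913),
    amplitude = c(40, 35, 50, 55, 45, 70, 60, 100),
    fwhm = c(14, 14, 12, 14, 16, 16, 14, 30))
}

# Per-class amplitude multipliers on the common bands. Cancer-like classes
# (a549, hela, hepg2) are raised at 1349/1437; normal-like (beas2b, hek) at
# 1078/1221; each class additionally carries a small distinctive pattern so
# the five classes are mutually separable.
preset_multipliers <- function() {
  m <- rbind(
    `a549-like`   = c(1.25, 1.0, 1.25, 1.0, 1.0, 1.3, 1.3, 1.25),
    `beas2b-like` = c(1.0,  1.0, 1.0,  1.3, 1.3, 1.0, 1.0, 1.0),
    `hek-like`    = c(0.7,  1.5, 1.0,  1.3, 1.3, 1.0, 1.0, 0.75),
    `hela-like`   = c(1.0,  1.3, 0.6,  1.0, 1.0, 1.3, 1.3, 1.0),
    `hepg2-like`  = c(1.0,  0.7, 1.0,  1.2, 1.0, 1.3, 1.3, 0.7))
  colnames(m) <- as.character(preset_band_table()$center)
  m
}

#' Built-in synthetic class profiles
#'
#' Five presets (`a549-like`, `beas2b-like`, `hek-like`, `hela-like`,
#' `hepg2-like`) share one common band list and differ only in stated
#' per-band amplitude multipliers: cancer-like classes are ~30% stronger at
#' 1349 and 1437 cm^-1, normal-like classes ~30% stronger at 1078 and
#' 1221 cm^-1. `cancer-like` and `normal-like` are aliases of `a549-like`
#' and `beas2b-like`. All presets share a gentle cubic baseline with a broad
#' hump near 1598 cm^-1 (mimicking citrate background on gold
#' nanoparticles), noise_sd 10 counts (signal-to-noise about 10 at the
#' strongest band), and a 0.1 per-spectrum cosmic-ray spike rate.
#'
#' @param name One of the preset names above.
#' @param noise_sd,spike_rate Override the default noise level or spike
#'   rate.
#' @param contrast Scales the deviation of every amplitude multiplier from 1
#'   (1 = default contrast, 0 = all classes identical).
#' @return A [class_profile()].
#' @export
preset_profile <- function(name, noise_sd = 10, spike_rate = 0.1,
                           contrast = 1) {
  alias <- c(`cancer-like` = "a549-like", `normal-like` = "beas2b-like")
  key <- if (name %in% names(alias)) alias[[name]] else name
  mult <- preset_multipliers()
  if (!key %in% rownames(mult)) {
    stop("unknown preset: ", name, call. = FALSE)
  }
  tab <- preset_band_table()
  m <- 1 + contrast * (mult[key, ] - 1)
  bands <- lapply(seq_len(nrow(tab)), function(i) {
    band_spec(tab$center[i], tab$amplitude[i] * m[[i]], amplitude_cv = 0.06,
              fwhm = tab$fwhm[i])
  })
  class_profile(name, bands,
                baseline_poly = c(120, -60, 30, -15),
                hump = c(1598, 90, 60),
                noise_sd = noise_sd, spike_rate = spike_rate,
                spike_amplitude = 800)
}

#' @rdname preset_profile
#' @return `preset_names()` returns the five preset class names.
#' @export
preset_names <- function() {
  c("a549-like", "beas2b-like", "hek-like", "hela-like", "hepg2-like")
}
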