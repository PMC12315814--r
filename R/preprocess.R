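#' Remove cosmic-ray spikes by a windowed modified z-score filter
#'
#' Hampel-style despiking: each point is compared with the median of its
#' centred window; points whose modified z-score
#' `0.6745 * |x - med| / MAD` exceeds `z_threshold` are replaced by that
#' local median. Edges are handled by mirror-padding the window, so a spike
#' in the first or last point is still caught. The window MAD is floored at
#' half the global robust noise scale so that locally flat windows do not
#' produce spurious detections. The pass is repeated until a fixed point is
#' reached (almost always 1-2 passes), which makes the filter idempotent;
#' points that are never flagged are returned bit-identical.
#'
#' @param spectrum A [sers_spectrum()].
#' @param window Odd window width in points (>= 3).
#' @param z_threshold Modified z-score threshold (unitless).
#' @return A despiked [sers_spectrum()].
#' @export
despike <- function(spectrum, window = 5L, z_threshold = 8) {
  x <- spectrum$intensities
  n <- length(x)
  if (window %% 2L != 1L || window < 3L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (window >= n) {
    stop("window must be smaller than the spectrum length", call. = FALSE)
  }
  k <- (window - 1L) %/% 2L
  scale_floor <- max(0.5 * stats::mad(diff(x)) / sqrt(2),
                     1e-9 * (max(abs(x)) + 1))
  one_pass <- function(v) {
    padded <- c(v[(k + 1L):2L], v, v[(n - 1L):(n - k)])
    cols <- lapply(seq_len(window), function(j) padded[j:(j + n - 1L)])
    med <- row_median_odd(cols)
    mad_ <- row_median_odd(lapply(cols, function(cc) abs(cc - med)))
    mad_ <- pmax(mad_, scale_floor)
    z <- 0.6745 * abs(v - med) / mad_
    v[z > z_threshold] <- med[z > z_threshold]
    v
  }
  for (pass in 1:10) {
    nxt <- one_pass(x)
    if (identical(nxt, x)) break
    x <- nxt
  }
  spectrum$intensities <- x
  spectrum
}

#' MPLS parameters
#'
#' Parameters of the morphologically weighted penalized least squares
#' baseline: structuring-element width (in grid points), Whittaker penalty,
#' the proportion of points at each end treated as guaranteed-flat baseline,
#' and the finite-difference order of the roughness penalty.
#'
#' @param struct_width Odd positive integer width of the flat structuring
#'   element, in points.
#' @param penalty Whittaker roughness penalty lambda (> 0).
#' @param flat_proportion Fraction of the spectrum length anchored as
#'   baseline at each end (0 < p < 0.5).
#' @param diff_order Difference order of the penalty, 1 or 2.
#' @return A list of class `mpls_params`.
#' @export
mpls_params <- function(struct_width = 75L, penalty = 10,
                        flat_proportion = 1 / 2000, diff_order = 1L) {
  if (struct_width < 1L || struct_width %% 2L != 1L) {
    stop("struct_width must be an odd positive integer", call. = FALSE)
  }
  if (penalty <= 0) stop("penalty must be positive", call. = FALSE)
  if (flat_proportion <= 0 || flat_proportion >= 0.5) {
    stop("flat_proportion must be in (0, 0.5)", call. = FALSE)
  }
  if (!diff_order %in% c(1L, 2L)) {
    stop("diff_order must be 1 or 2", call. = FALSE)
  }
  structure(list(struct_width = as.integer(struct_width), penalty = penalty,
                 flat_proportion = flat_proportion,
                 diff_order = as.integer(diff_order)),
            class = "mpls_params")
}

# Elementwise median across an odd number of equal-length vectors, via an
# elementwise bubble sort with pmin/pmax (fast for small window widths).
row_median_odd <- function(cols) {
  k <- length(cols)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      cols[[j + 1L]] <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
    }
  }
  cols[[(k + 1L) %/% 2L]]
}

# cache of D'D penalty matrices keyed by length and difference order
.whittaker_cache <- new.env(parent = emptyenv())

# Running min/max over a centred window of w points; the window is clipped
# at the signal ends (equivalent to +/-Inf padding).
running_extreme <- function(x, w, fn_pad) {
  k <- (w - 1L) %/% 2L
  padded <- c(rep(fn_pad, k), x, rep(fn_pad, k))
  cols <- lapply(seq_len(w), function(j) {
    padded[j:(j + length(x) - 1L)]
  })
  if (identical(fn_pad, Inf)) do.call(pmin, cols) else do.call(pmax, cols)
}

morphological_opening <- function(x, w) {
  eroded <- running_extreme(x, w, Inf)
  running_extreme(eroded, w, -Inf)
}

# Weighted Whittaker smoother: minimises
# sum_i w_i (z_i - y_i)^2 + lambda * sum (d-th difference of z)^2.
whittaker <- function(y, weights, lambda, diff_order) {
  n <- length(y)
  key <- paste(n, diff_order)
  DtD <- .whittaker_cache[[key]]
  if (is.null(DtD)) {
    D <- Matrix::bandSparse(n, n, k = 0:diff_order,
                            diagonals = lapply(0:diff_order, function(j) {
                              rep(choose(diff_order, j) * (-1)^j, n)
                            }))[seq_len(n - diff_order), , drop = FALSE]
    DtD <- Matrix::crossprod(D)
    .whittaker_cache[[key]] <- DtD
  }
  A <- Matrix::Diagonal(x = weights) + lambda * DtD
  as.numeric(Matrix::solve(A, weights * y))
}

#' MPLS baseline estimation and correction
#'
#' Morphologically weighted penalized least squares: the background contour
#' is roughly estimated by a morphological opening (erosion then dilation
#' with a flat structuring element of `struct_width` points), averaged with
#' its own dilation/erosion pair to cancel the noise bias of the bare
#' opening, then refined by a weighted Whittaker smoother. Points where the opening agrees with
#' the spectrum (baseline regions) receive weight 1, points under peaks
#' weight 0.001, and the first and last `ceiling(flat_proportion * n)`
#' points are forced to weight 1. The corrected spectrum is the input minus
#' the fitted baseline, exactly.
#'
#' @param spectrum A [sers_spectrum()].
#' @param params An [mpls_params()] object.
#' @return A list with elements `baseline` and `corrected`, both
#'   [sers_spectrum()] objects on the input axis.
#' @export
mpls_baseline <- function(spectrum, params = mpls_params()) {
  x <- spectrum$intensities
  n <- length(x)
  if (params$struct_width >= n) {
    stop("struct_width must be smaller than the spectrum length",
         call. = FALSE)
  }
  sw <- params$struct_width
  # linear extrapolation padding so the morphology window never truncates
  # at the spectrum ends (a bare clipped window biases sloped baselines)
  k <- sw - 1L
  sl <- (x[1L + k] - x[1L]) / k
  sr <- (x[n] - x[n - k]) / k
  xp <- c(x[1L] - sl * (k:1), x, x[n] + sr * (1:k))
  core <- k + seq_len(n)
  opening_p <- morphological_opening(xp, sw)
  # classical morphological background: average of dilation and erosion of
  # the opening, which cancels most of the noise bias of the bare opening
  target_p <- (running_extreme(opening_p, sw, -Inf) +
                 running_extreme(opening_p, sw, Inf)) / 2
  opening <- opening_p[core]
  # noise scale from first differences; used only to decide peak regions
  noise <- stats::mad(diff(x)) / sqrt(2)
  thresh <- 3 * noise + 1e-9 * (max(abs(x)) + 1)
  w <- ifelse(abs(x - opening) <= thresh, 1, 0.001)
  m <- ceiling(params$flat_proportion * n)
  w[seq_len(m)] <- 1
  w[seq.int(n - m + 1L, n)] <- 1
  # smooth on the padded support so Whittaker end effects fall in the
  # padding, not the spectrum
  wp <- c(rep(1, k), w, rep(1, k))
  base <- whittaker(target_p, wp, params$penalty, params$diff_order)[core]
  bspec <- spectrum; bspec$intensities <- base
  cspec <- spectrum; cspec$intensities <- x - base
  list(baseline = bspec, corrected = cspec)
}

#' Low-pass window specification for DFT smoothing
#'
#' A raised-cosine (Tukey) low-pass window over the DFT frequency axis:
#' unity up to `(cutoff_fraction - rolloff_fraction)` of Nyquist, a cosine
#' taper to zero at `cutoff_fraction`, zero beyond.
#'
#' @param kind Window family; only `"lowpass_tukey"` is defined.
#' @param cutoff_fraction Fraction of Nyquist retained (0 < c <= 1).
#' @param rolloff_fraction Width of the cosine taper (0 <= r < c).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(kind = "lowpass_tukey", cutoff_fraction = 0.15,
                        rolloff_fraction = 0.05) {
  if (!identical(kind, "lowpass_tukey")) {
    stop("unknown window kind: ", kind, call. = FALSE)
  }
  if (cutoff_fraction <= 0 || cutoff_fraction > 1) {
    stop("cutoff_fraction must be in (0, 1]", call. = FALSE)
  }
  if (rolloff_fraction < 0 || rolloff_fraction >= cutoff_fraction) {
    stop("rolloff_fraction must satisfy 0 <= r < cutoff", call. = FALSE)
  }
  structure(list(kind = kind, cutoff_fraction = cutoff_fraction,
                 rolloff_fraction = rolloff_fraction),
            class = "window_spec")
}

#' Frequency-domain weights of a window over an n-point DFT
#'
#' @param window A [window_spec()].
#' @param n Length of the transformed vector.
#' @return Numeric vector of n weights, symmetric in frequency so that the
#'   filtered signal stays real; the DC weight is exactly 1.
#' @export
window_weights <- function(window, n) {
  k <- 0:(n - 1L)
  folded <- pmin(k, n - k)          # distance from DC, symmetric
  f <- folded / (n / 2)             # fraction of Nyquist
  c0 <- window$cutoff_fraction
  r <- window$rolloff_fraction
  lo <- c0 - r
  w <- numeric(n)
  w[f <= lo] <- 1
  taper <- f > lo & f < c0
  if (r > 0) w[taper] <- 0.5 * (1 + cos(pi * (f[taper] - lo) / r))
  w
}

#' Smooth a spectrum by windowed discrete Fourier transform
#'
#' The intensity vector is transformed to the frequency domain, multiplied
#' pointwise by the low-pass window, and transformed back; the imaginary
#' residue (numerically <= 1e-10 relative) is discarded. The DC component is
#' preserved exactly.
#'
#' @param spectrum A [sers_spectrum()] with at least 4 points.
#' @param window A [window_spec()].
#' @return The smoothed [sers_spectrum()].
#' @export
dft_smooth <- function(spectrum, window = window_spec()) {
  x <- spectrum$intensities
  n <- length(x)
  if (n < 4L) stop("spectrum too short for DFT smoothing", call. = FALSE)
  if (!inherits(window, "window_spec")) {
    stop("window must be a window_spec object", call. = FALSE)
  }
  w <- window_weights(window, n)
  y <- stats::fft(x) * w
  out <- stats::fft(y, inverse = TRUE) / n
  resid <- max(abs(Im(out))) / max(1, max(abs(Re(out))))
  if (resid > 1e-10) {
    stop("imaginary residue exceeded tolerance: ", format(resid),
         call. = FALSE)
  }
  spectrum$intensities <- Re(out)
  spectrum
}

#' Full preprocessing chain for one spectrum or a whole set
#'
#' Despike, then MPLS baseline correction, then DFT smoothing, optionally
#' followed by per-spectrum max-normalization (off by default).
#'
#' @param x A [sers_spectrum()] or [sers_set()].
#' @param run_despike Logical: run the cosmic-ray filter first.
#' @param despike_window,z_threshold Despiking parameters, see [despike()].
#' @param mpls An [mpls_params()] object.
#' @param window A [window_spec()] for the smoothing step.
#' @param normalize Logical: divide each spectrum by its maximum.
#' @return The preprocessed object of the same class as `x`.
#' @export
preprocess <- function(x, run_despike = TRUE, despike_window = 5L,
                       z_threshold = 8, mpls = mpls_params(),
                       window = window_spec(), normalize = FALSE) {
  one <- function(sp) {
    if (run_despike) sp <- despike(sp, despike_window, z_threshold)
    sp <- mpls_baseline(sp, mpls)$corrected
    sp <- dft_smooth(sp, window)
    if (normalize) {
      m <- max(abs(sp$intensities))
      if (m > 0) sp$intensities <- sp$intensities / m
    }
    sp
  }
  if (inherits(x, "sers_spectrum")) one(x)
  else if (inherits(x, "sers_set")) map_spectra(x, one)
  else stop("x must be a sers_spectrum or sers_set", call. = FALSE)
}
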