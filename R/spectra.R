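#' Construct a single Raman spectrum
#'
#' A spectrum is a wavenumber axis (cm^-1, strictly increasing) paired with an
#' intensity vector in arbitrary counts, plus identifying metadata.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of intensities (counts), same length as
#'   `wavenumbers`, all finite.
#' @param sample_id Character scalar identifying the acquisition.
#' @param label Optional class name (character scalar or `NA`).
#' @param replicate Optional replicate index (integer or `NA`).
#' @return An object of class `sers_spectrum`.
#' @export
sers_spectrum <- function(wavenumbers, intensities, sample_id = "s1",
                          label = NA_character_, replicate = NA_integer_) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L) {
    stop("spectrum must have at least 2 points", call. = FALSE)
  }
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(diff(wavenumbers) <= 0)) {
    stop("wavenumber axis must be finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         sample_id = as.character(sample_id),
         label = if (is.na(label)) NA_character_ else as.character(label),
         replicate = as.integer(replicate)),
    class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %s: %d points, %.1f-%.1f cm-1%s\n",
              x$sample_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers),
              if (!is.na(x$label)) paste0(", label=", x$label) else ""))
  invisible(x)
}

#' Construct a set of spectra sharing one wavenumber axis
#'
#' The dataset unit for modelling: an n_samples x n_points intensity matrix
#' (one spectrum per row), a shared axis, class labels, and sample ids.
#'
#' @param axis Shared wavenumber vector (cm^-1, strictly increasing).
#' @param matrix Numeric matrix, one row per spectrum, `ncol == length(axis)`.
#' @param labels Character vector of class names (or `NA`), one per row.
#' @param ids Character vector of sample ids, one per row; defaults to
#'   `s1, s2, ...`.
#' @return An object of class `sers_set`.
#' @export
sers_set <- function(axis, matrix, labels = NULL, ids = NULL) {
  axis <- as.numeric(axis)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (any(!is.finite(axis)) || any(diff(axis) <= 0)) {
    stop("axis must be finite and strictly increasing", call. = FALSE)
  }
  if (ncol(matrix) != length(axis)) {
    stop("matrix column count must match axis length", call. = FALSE)
  }
  if (any(!is.finite(matrix))) {
    stop("intensity matrix must be finite", call. = FALSE)
  }
  n <- nrow(matrix)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  ids <- as.character(ids)
  if (length(labels) != n || length(ids) != n) {
    stop("labels and ids must have one entry per spectrum", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  dimnames(matrix) <- NULL
  structure(list(axis = axis, matrix = matrix, labels = labels, ids = ids),
            class = "sers_set")
}

#' @export
print.sers_set <- function(x, ...) {
  tab <- table(x$labels, useNA = "no")
  cat(sprintf("<sers_set> %d spectra x %d points, %.1f-%.1f cm-1\n",
              nrow(x$matrix), length(x$axis), min(x$axis), max(x$axis)))
  if (length(tab)) {
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `sers_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(set) nrow(set$matrix)

#' Subset a spectrum set by row
#'
#' @param x A `sers_set`.
#' @param i Row index vector (integer or logical).
#' @param ... Unused.
#' @return A `sers_set` with the selected spectra, axis unchanged.
#' @export
`[.sers_set` <- function(x, i, ...) {
  sers_set(x$axis, x$matrix[i, , drop = FALSE], x$labels[i], x$ids[i])
}

#' Extract one spectrum from a set
#' @param set A `sers_set`.
#' @param i Row index (single integer).
#' @return A `sers_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n_spectra(set))
  sers_spectrum(set$axis, set$matrix[i, ], sample_id = set$ids[i],
                label = set$labels[i])
}

#' Combine spectrum sets sharing an axis
#' @param ... `sers_set` objects with identical axes.
#' @return A single `sers_set` with rows stacked in argument order.
#' @export
bind_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  ax <- sets[[1L]]$axis
  for (s in sets[-1L]) {
    if (length(s$axis) != length(ax) || any(abs(s$axis - ax) > 1e-9)) {
      stop("cannot bind sets with differing axes", call. = FALSE)
    }
  }
  sers_set(ax,
           do.call(rbind, lapply(sets, `[[`, "matrix")),
           unlist(lapply(sets, `[[`, "labels")),
           unlist(lapply(sets, `[[`, "ids")))
}

#' Apply a per-spectrum transform to every row of a set
#'
#' @param set A `sers_set`.
#' @param fn Function taking and returning a `sers_spectrum` (axis must be
#'   preserved).
#' @return A `sers_set` with transformed intensities.
#' @export
map_spectra <- function(set, fn) {
  out <- set$matrix
  for (i in seq_len(nrow(out))) {
    sp <- fn(get_spectrum(set, i))
    if (length(sp$intensities) != ncol(out)) {
      stop("transform changed the number of points", call. = FALSE)
    }
    out[i, ] <- sp$intensities
  }
  sers_set(set$axis, out, set$labels, set$ids)
}
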