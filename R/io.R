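#' Read spectra from disk
#'
#' Two plain-text layouts are supported. `two_column` is a single spectrum per
#' file: wavenumber then intensity, whitespace- or comma-separated, optional
#' header. `matrix_csv` is one file for many spectra: a header row
#' (`wavenumber_cm-1` then one sample id per column), the wavenumber axis in
#' the first column and one intensity column per spectrum.
#'
#' When a sidecar label table `<path stem>_labels.csv` (columns
#' `sample_id,label`) exists next to a `matrix_csv` file, labels are attached
#' by sample id.
#'
#' @param path File path (for `two_column`, may be a vector of paths, one
#'   spectrum each; all must share the axis).
#' @param format `"two_column"` or `"matrix_csv"`.
#' @param labels_path Optional explicit path to a label CSV; overrides the
#'   sidecar convention.
#' @return A [sers_set()] with spectra in file order.
#' @export
read_spectra <- function(path, format = c("matrix_csv", "two_column"),
                         labels_path = NULL) {
  format <- match.arg(format)
  if (format == "two_column") {
    specs <- lapply(path, read_two_column_file)
    ax <- specs[[1L]]$wavenumbers
    for (s in specs[-1L]) {
      if (length(s$wavenumbers) != length(ax) ||
          any(abs(s$wavenumbers - ax) > 1e-9)) {
        stop("spectra do not share a common wavenumber axis", call. = FALSE)
      }
    }
    ids <- vapply(specs, `[[`, "", "sample_id")
    set <- sers_set(ax, do.call(rbind, lapply(specs, `[[`, "intensities")),
                    ids = ids)
  } else {
    set <- read_matrix_csv(path)
  }
  lp <- labels_path
  if (is.null(lp) && format == "matrix_csv") {
    cand <- paste0(sub("\\.csv$", "", path), "_labels.csv")
    if (file.exists(cand)) lp <- cand
  }
  if (!is.null(lp)) set <- attach_labels(set, read_label_table(lp))
  set
}

read_two_column_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  # tolerate a single non-numeric header line
  first <- strsplit(lines[[1L]], "[,;\t ]+")[[1L]]
  if (suppressWarnings(anyNA(as.numeric(first)))) lines <- lines[-1L]
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[,;\t ]+")
  wn <- numeric(length(parts)); it <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 2L || anyNA(p)) {
      stop(sprintf("malformed numeric field in %s at data line %d",
                   path, i), call. = FALSE)
    }
    wn[i] <- p[1L]; it[i] <- p[2L]
  }
  if (any(!is.finite(it))) {
    stop("non-finite intensity in ", path, call. = FALSE)
  }
  if (any(diff(wn) <= 0)) {
    stop("wavenumber column must be strictly increasing in ", path,
         call. = FALSE)
  }
  sers_spectrum(wn, it,
                sample_id = sub("\\.[^.]*$", "", basename(path)))
}

read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df) || ncol(df) < 2L) {
    stop("matrix CSV needs a wavenumber column and at least one spectrum: ",
         path, call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(wn)) {
    stop("malformed numeric field in wavenumber column of ", path,
         call. = FALSE)
  }
  if (any(diff(wn) <= 0)) {
    stop("wavenumber column must be strictly increasing in ", path,
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) {
    stop("non-finite or malformed intensity values in ", path, call. = FALSE)
  }
  sers_set(wn, t(mat), ids = colnames(df)[-1L])
}

#' Read a sample_id,label table
#' @param path CSV path with columns `sample_id` and `label`.
#' @return A data.frame with character columns `sample_id` and `label`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label table must have columns sample_id,label: ", path,
         call. = FALSE)
  }
  df[, c("sample_id", "label")]
}

attach_labels <- function(set, label_df) {
  idx <- match(set$ids, label_df$sample_id)
  lab <- set$labels
  lab[!is.na(idx)] <- label_df$label[idx[!is.na(idx)]]
  sers_set(set$axis, set$matrix, lab, set$ids)
}

#' Write spectra to disk
#'
#' Inverse of [read_spectra()]: `matrix_csv` writes one CSV (header
#' `wavenumber_cm-1` then sample ids) plus, when any labels are present, a
#' sidecar `<stem>_labels.csv`; `two_column` writes one file per spectrum into
#' the directory `path`, named by sample id.
#'
#' @param set A non-empty [sers_set()].
#' @param path Output CSV path (`matrix_csv`) or directory (`two_column`).
#' @param format `"matrix_csv"` or `"two_column"`.
#' @return The main path written, invisibly.
#' @export
write_spectra <- function(set, path, format = c("matrix_csv", "two_column")) {
  format <- match.arg(format)
  if (!inherits(set, "sers_set") || n_spectra(set) == 0L) {
    stop("cannot write an empty spectrum set", call. = FALSE)
  }
  if (format == "matrix_csv") {
    df <- data.frame(set$axis, t(set$matrix), check.names = FALSE)
    names(df) <- c("wavenumber_cm-1", set$ids)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    if (any(!is.na(set$labels))) {
      utils::write.csv(
        data.frame(sample_id = set$ids, label = set$labels),
        paste0(sub("\\.csv$", "", path), "_labels.csv"),
        row.names = FALSE, quote = FALSE)
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(n_spectra(set))) {
      f <- file.path(path, paste0(set$ids[i], ".txt"))
      utils::write.table(
        data.frame(set$axis, set$matrix[i, ]), f,
        row.names = FALSE, col.names = FALSE, sep = "\t")
    }
  }
  invisible(path)
}

#' Read or write a pipeline configuration
#'
#' The configuration is a YAML file mirroring the pipeline's tunables:
#' simulator settings, preprocessing parameters, model choice (`svm` or
#' `cnn`), split fractions, seed and output paths. Unknown keys are kept
#' verbatim; the declared invariants are validated.
#'
#' @param path YAML file path.
#' @return A named list of class `sers_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
  structure(cfg, class = "sers_config")
}

#' @rdname read_pipeline_config
#' @param config A list as returned by [default_pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  structure(list(
    classes = c("a549-like", "beas2b-like"),
    n_per_class = 135L,
    model = "svm",
    pca_components = 2L,
    split = c(train = 0.6, val = 0.1, test = 0.3),
    seed = 1L,
    preprocessing = list(despike = TRUE, mpls_width = 75L, mpls_penalty = 10,
                         dft_cutoff = 0.15),
    out_dir = "."), class = "sers_config")
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$split)) {
    s <- unlist(cfg$split)
    if (length(s) != 3L || any(s <= 0) || abs(sum(s) - 1) > 1e-9) {
      stop("split fractions must be three positive numbers summing to 1",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$seed)) {
    if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
      stop("seed must be a non-negative integer", call. = FALSE)
    }
  }
  if (!is.null(cfg$model) && !cfg$model %in% c("svm", "cnn")) {
    stop("model must be 'svm' or 'cnn'", call. = FALSE)
  }
  invisible(TRUE)
}
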