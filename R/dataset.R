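#' Ordered collection of spectra on a common ppm grid
#'
#' @param spectra List of [nmr_spectrum] objects with pointwise-identical
#'   ppm axes; at least one.
#' @param class_labels One label per spectrum.  Defaults to the first
#'   line of each spectrum's Bruker title when available, else
#'   `"unknown"`.
#' @param options A [preproc_options] object.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(spectra, class_labels = NULL,
                        options = preproc_options()) {
  if (length(spectra) < 1) abort_input("a spectra_set needs >= 1 spectrum")
  if (!all(vapply(spectra, inherits, logical(1), "nmr_spectrum")))
    abort_input("all elements must be nmr_spectrum objects")
  ax <- spectra[[1]]$ppm_axis
  for (s in spectra[-1])
    if (length(s$ppm_axis) != length(ax) || any(s$ppm_axis != ax))
      abort_input("all spectra must share an identical ppm axis")
  if (is.null(class_labels)) {
    class_labels <- vapply(spectra, function(s) {
      ttl <- if (!is.null(s$acq)) s$acq$title else ""
      first <- strsplit(ttl, "\n", fixed = TRUE)[[1]][1]
      if (is.na(first) || !nzchar(first)) "unknown" else first
    }, character(1))
  }
  if (length(class_labels) != length(spectra))
    abort_input("class_labels must have one entry per spectrum")
  structure(list(spectra = spectra,
                 class_labels = as.character(class_labels),
                 options = options, log = character(),
                 multiplet_fits = list(), glog_applied = FALSE),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, classes: %s\n",
              length(x$spectra), length(x$spectra[[1]]$points),
              paste(unique(x$class_labels), collapse = ", ")))
  invisible(x)
}

#' @export
length.spectra_set <- function(x) length(x$spectra)

#' Samples x points matrix of real intensities
#'
#' @param set A [spectra_set].
#' @return Numeric matrix, one row per spectrum.
#' @export
set_matrix <- function(set) {
  do.call(rbind, lapply(set$spectra, function(s) Re(s$points)))
}

set_replace_real <- function(set, m) {
  for (i in seq_along(set$spectra)) {
    s <- set$spectra[[i]]
    s$points <- complex(real = m[i, ], imaginary = Im(s$points))
    set$spectra[[i]] <- s
  }
  set
}

#' Samples x features matrix with ppm feature labels
#'
#' @param values Numeric samples x features matrix; no NaN.
#' @param feature_ppm Descending ppm label per feature (bucket centres).
#' @param class_labels One label per sample.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_ppm, class_labels) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) abort_input("feature matrix must be finite")
  if (ncol(values) != length(feature_ppm))
    abort_input("feature_ppm must label every column")
  if (any(diff(feature_ppm) >= 0))
    abort_input("feature_ppm must be strictly decreasing")
  if (nrow(values) != length(class_labels))
    abort_input("class_labels must label every row")
  structure(list(values = values, feature_ppm = as.numeric(feature_ppm),
                 class_labels = as.character(class_labels),
                 glog_applied = FALSE),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features (%.3f .. %.3f ppm)\n",
              nrow(x$values), ncol(x$values), max(x$feature_ppm),
              min(x$feature_ppm)))
  invisible(x)
}
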