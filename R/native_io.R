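NATIVE_FORMAT_VERSION <- "nmrmetab-dataset-1"

write_array_bin <- function(x, path) {
  writeBin(as.numeric(x), path, size = 8L, endian = "little")
}
read_array_bin <- function(path, n_expected) {
  sz <- file.size(path)
  if (is.na(sz) || sz != 8L * n_expected)
    abort_format(sprintf("array %s is truncated or corrupt (%s bytes, %d expected)",
                         basename(path), format(sz), 8L * n_expected))
  readBin(path, "double", n = n_expected, size = 8L, endian = "little")
}

#' Save a spectra set in the native dataset format
#'
#' The native format is a single zip container holding a JSON manifest
#' (format version, per-spectrum metadata, phase state, pre-processing
#' options, multiplet analyses, transform flags) and one little-endian
#' float64 binary array per data block.  The round trip through
#' [load_dataset()] is lossless.
#'
#' @param set A [spectra_set].
#' @param path Output file path (conventionally `.nmds`).
#' @return Invisibly, `path`.
#' @export
save_dataset <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  tmp <- tempfile("nmds")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  ns <- length(set$spectra)
  manifest <- list(
    format = NATIVE_FORMAT_VERSION,
    n_spectra = ns,
    n_points = length(set$spectra[[1]]$points),
    class_labels = set$class_labels,
    glog_applied = isTRUE(set$glog_applied),
    options = unclass(set$options),
    log = set$log,
    multiplet_fits = set$multiplet_fits,
    spectra = lapply(set$spectra, function(s) list(
      phi0_deg = s$phi0_deg, phi1_deg = s$phi1_deg,
      proc = unclass(s$proc),
      acq = if (!is.null(s$acq)) unclass(s$acq) else NULL,
      log = s$log))
  )
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  write_array_bin(set$spectra[[1]]$ppm_axis, file.path(tmp, "ppm_axis.bin"))
  for (i in seq_len(ns)) {
    write_array_bin(Re(set$spectra[[i]]$points),
                    file.path(tmp, sprintf("spec_%03d_re.bin", i)))
    write_array_bin(Im(set$spectra[[i]]$points),
                    file.path(tmp, sprintf("spec_%03d_im.bin", i)))
  }
  files <- list.files(tmp)
  zip::zip(zipfile = path.expand(path), files = files, root = tmp,
           mode = "cherry-pick")
  invisible(path)
}

relist_pars <- function(x, ctor) {
  # manifest lists come back from JSON as plain lists; rebuild the
  # parameter objects through their validating constructors
  x <- x[names(x) %in% names(formals(ctor))]
  x <- x[!vapply(x, is.null, logical(1))]
  do.call(ctor, x)
}

#' Load a spectra set saved by [save_dataset()]
#'
#' @param path Path to a native dataset file.
#' @return The reconstructed [spectra_set].
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  tmp <- tempfile("nmds")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  ok <- tryCatch({
    zip::unzip(path, exdir = tmp)
    TRUE
  }, error = function(e) FALSE)
  mf <- file.path(tmp, "manifest.json")
  if (!ok || !file.exists(mf))
    abort_format(sprintf("%s is not a readable native dataset", path))
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE,
                                           simplifyMatrix = FALSE),
                       error = function(e)
                         abort_format("manifest.json is corrupt"))
  if (!identical(manifest$format, NATIVE_FORMAT_VERSION))
    abort(sprintf("unsupported dataset format version '%s' (expected '%s')",
                  manifest$format, NATIVE_FORMAT_VERSION),
          "nmrmetab_version_error")
  np <- manifest$n_points
  ppm <- read_array_bin(file.path(tmp, "ppm_axis.bin"), np)
  spectra <- vector("list", manifest$n_spectra)
  for (i in seq_len(manifest$n_spectra)) {
    re <- read_array_bin(file.path(tmp, sprintf("spec_%03d_re.bin", i)), np)
    im <- read_array_bin(file.path(tmp, sprintf("spec_%03d_im.bin", i)), np)
    meta <- manifest$spectra[[i]]
    spectra[[i]] <- nmr_spectrum(
      complex(real = re, imaginary = im), ppm,
      phi0_deg = meta$phi0_deg, phi1_deg = meta$phi1_deg,
      proc = relist_pars(meta$proc, proc_pars),
      acq = if (!is.null(meta$acq)) relist_pars(meta$acq, acq_pars),
      log = unlist(meta$log))
  }
  opts <- manifest$options
  opt_obj <- preproc_options(
    exclude = opts$exclude %||% list(),
    align_segments = opts$align_segments %||% list(),
    noise_region = unlist(opts$noise_region %||% c(10, 10.5)),
    noise_factor = opts$noise_factor %||% 0,
    bucket_ppm = opts$bucket_ppm,
    normalization = opts$normalization %||% "none",
    glog_lambda = opts$glog_lambda,
    export = opts$export %||% "none")
  set <- spectra_set(spectra, class_labels = unlist(manifest$class_labels),
                     options = opt_obj)
  set$glog_applied <- isTRUE(manifest$glog_applied)
  set$log <- unlist(manifest$log) %||% character()
  set$multiplet_fits <- manifest$multiplet_fits %||% list()
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a
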