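#' Parse a JCAMP-DX-style Bruker parameter file
#'
#' Extracts `##$KEY= value` entries into a named list.  Scalars are
#' returned as numbers, `<bracketed>` strings without the brackets, and
#' array declarations (`##$D= (0..63)` followed by value lines) as
#' numeric/character vectors.  The parser is total: any text yields a
#' map; unknown or malformed lines are preserved or skipped without
#' raising.
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @return Named list of parameter values.
#' @export
parse_param_file <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  i <- 1L
  n <- length(text)
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^<.*>$", v)) return(sub("^<(.*)>$", "\\1", v))
    num <- suppressWarnings(as.numeric(v))
    if (length(num) == 1 && !is.na(num)) num else v
  }
  while (i <= n) {
    line <- text[i]
    m <- regmatches(line, regexec("^##\\$?([^=]+)=(.*)$", line))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      if (grepl("^\\(\\d+\\.\\.\\d+\\)", val)) {
        # multi-line array: collect value lines until the next ## entry
        vals <- character(0)
        j <- i + 1L
        while (j <= n && !grepl("^##", text[j])) {
          vals <- c(vals, strsplit(trimws(text[j]), "\\s+")[[1]])
          j <- j + 1L
        }
        num <- suppressWarnings(as.numeric(vals))
        out[[key]] <- if (length(vals) > 0 && !anyNA(num)) num else vals
        i <- j
        next
      }
      out[[key]] <- parse_val(val)
    }
    i <- i + 1L
  }
  out
}

#' Read a Bruker 1D experiment directory
#'
#' Reads the raw `fid` and the `acqus` parameter file of a Bruker 1D
#' experiment, decoding the binary according to the byte order
#' (`BYTORDA`) and data type (`DTYPA`: int32 or float64) declared in
#' `acqus`, resolving the real/imaginary interleaving, and attaching the
#' `pdata/1/title` text when present (its absence is not an error).
#'
#' @param dir_path Path to the experiment directory.
#' @return A list with `fid` (an [nmr_fid]) and `acq` (an [acq_pars]).
#' @export
read_bruker <- function(dir_path) {
  fid_path <- file.path(dir_path, "fid")
  acqus_path <- file.path(dir_path, "acqus")
  if (!file.exists(acqus_path))
    abort_input(sprintf("missing parameter file: %s", acqus_path))
  if (!file.exists(fid_path))
    abort_input(sprintf("missing raw data file: %s", fid_path))
  pars <- parse_param_file(readLines(acqus_path, warn = FALSE))
  need <- c("TD", "SW_h", "SFO1")
  miss <- need[!need %in% names(pars)]
  if (length(miss) > 0)
    abort_format(sprintf("acqus lacks required key(s): %s",
                         paste(miss, collapse = ", ")))
  byte_order <- if (isTRUE(pars$BYTORDA == 1)) "big" else "little"
  dbl <- isTRUE(pars$DTYPA == 2)
  endian <- byte_order
  sz <- file.size(fid_path)
  unit <- if (dbl) 8L else 4L
  n_vals <- sz %/% unit
  if (sz %% unit != 0 || n_vals %% 2 != 0)
    abort_format(sprintf(
      "fid has %d bytes: not an even count of %d-byte values", sz, unit))
  con <- file(fid_path, "rb")
  on.exit(close(con))
  raw_vals <- if (dbl)
    readBin(con, "double", n = n_vals, size = 8L, endian = endian)
  else
    readBin(con, "integer", n = n_vals, size = 4L, endian = endian)
  pts <- complex(real = raw_vals[c(TRUE, FALSE)],
                 imaginary = raw_vals[c(FALSE, TRUE)])
  title_path <- file.path(dir_path, "pdata", "1", "title")
  title <- if (file.exists(title_path))
    paste(readLines(title_path, warn = FALSE), collapse = "\n") else ""
  acq <- acq_pars(
    spectral_width_hz = pars$SW_h,
    spectrometer_freq_mhz = pars$SFO1,
    n_points_td = length(pts),
    carrier_offset_hz = if (!is.null(pars$O1)) pars$O1 else 0,
    group_delay = if (!is.null(pars$GRPDLY) && pars$GRPDLY > 0)
      pars$GRPDLY else 0,
    pulse_program = if (!is.null(pars$PULPROG)) as.character(pars$PULPROG)
      else "",
    byte_order = byte_order,
    int_size = unit,
    title = title)
  list(fid = nmr_fid(pts, acq), acq = acq)
}

#' Write a processed spectrum in Bruker format
#'
#' Writes `pdata/1/1r` (and `1i` unless the imaginary part is dropped)
#' as 32-bit integers with the scaling exponent recorded as `NC_proc` in
#' `pdata/1/procs` (stored value = real value / 2^NC_proc).  The scaling
#' is chosen so the largest magnitude uses at least 2^28, bounding the
#' read-back quantization error by 2^-28 of the maximum intensity.
#'
#' @param spec An [nmr_spectrum].
#' @param dir_path Experiment directory to write into.
#' @param keep_imaginary Write `1i` as well.
#' @return Invisibly, the `NC_proc` exponent used.
#' @export
write_bruker <- function(spec, dir_path, keep_imaginary = TRUE) {
  pdir <- file.path(dir_path, "pdata", "1")
  ok <- dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(pdir))
    abort(sprintf("cannot create %s", pdir), "nmrmetab_io_error")
  re <- Re(spec$points)
  im <- Im(spec$points)
  m <- max(abs(c(re, if (keep_imaginary) im)))
  nc <- if (m > 0) ceiling(log2(m / (2^29 - 1))) else 0
  scl <- 2^-nc
  writeBin(as.integer(round(re * scl)), file.path(pdir, "1r"),
           size = 4L, endian = "little")
  if (keep_imaginary)
    writeBin(as.integer(round(im * scl)), file.path(pdir, "1i"),
             size = 4L, endian = "little")
  si <- length(spec$points)
  sf <- if (!is.null(spec$acq)) spec$acq$spectrometer_freq_mhz else 0
  swp <- if (!is.null(spec$acq)) spec$acq$spectral_width_hz else 0
  lines <- c(
    "##TITLE= Parameter file, procs",
    "##JCAMPDX= 5.0",
    sprintf("##$SI= %d", si),
    sprintf("##$NC_proc= %d", nc),
    sprintf("##$SF= %.8f", sf),
    sprintf("##$SW_p= %.6f", swp),
    sprintf("##$OFFSET= %.6f", spec$ppm_axis[1]),
    "##$BYTORDP= 0",
    "##$DTYPP= 0",
    sprintf("##$PHC0= %.6f", spec$phi0_deg),
    sprintf("##$PHC1= %.6f", spec$phi1_deg),
    "##END=")
  writeLines(lines, file.path(pdir, "procs"))
  invisible(nc)
}

#' Read back a spectrum written by [write_bruker()]
#'
#' @param dir_path Experiment directory containing `pdata/1`.
#' @return List with `real`, `imaginary` (or NULL), and the parsed
#'   `procs` parameters.
#' @export
read_bruker_processed <- function(dir_path) {
  pdir <- file.path(dir_path, "pdata", "1")
  procs <- file.path(pdir, "procs")
  r1 <- file.path(pdir, "1r")
  if (!file.exists(procs) || !file.exists(r1))
    abort_input(sprintf("no processed data under %s", pdir))
  pars <- parse_param_file(readLines(procs, warn = FALSE))
  scl <- 2^(if (!is.null(pars$NC_proc)) pars$NC_proc else 0)
  rd <- function(p) readBin(p, "integer", n = file.size(p) %/% 4L,
                            size = 4L, endian = "little") * scl
  i1 <- file.path(pdir, "1i")
  list(real = rd(r1),
       imaginary = if (file.exists(i1)) rd(i1) else NULL,
       procs = pars)
}
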