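#' Acquisition parameters of a 1D NMR experiment
#'
#' Container for the acquisition-side metadata needed to reconstruct the
#' frequency axis and decode the raw data: spectral width, observe
#' frequency, number of complex points, transmitter (carrier) offset, the
#' digital-filter group delay and the binary dialect of the raw file.
#'
#' @param spectral_width_hz Spectral width (sweep width) in Hz; `> 0`.
#' @param spectrometer_freq_mhz Observe (spectrometer) frequency in MHz;
#'   `> 0`.  1 ppm corresponds to this many Hz.
#' @param n_points_td Number of acquired complex time-domain points;
#'   `>= 2`.
#' @param carrier_offset_hz Transmitter offset from 0 ppm, in Hz.  The
#'   carrier sits at `carrier_offset_hz / spectrometer_freq_mhz` ppm.
#' @param group_delay Digital-filter group delay in points; may be
#'   fractional (Bruker `GRPDLY`); `>= 0`.
#' @param pulse_program Pulse program name (free text).
#' @param byte_order `"little"` or `"big"`; binary dialect of the raw fid.
#' @param int_size Bytes per stored value: `4` (int32) or `8` (float64).
#' @param title Free-text title (contents of `pdata/1/title`), or `""`.
#' @return An object of class `acq_pars`.
#' @export
acq_pars <- function(spectral_width_hz, spectrometer_freq_mhz, n_points_td,
                     carrier_offset_hz = 0, group_delay = 0,
                     pulse_program = "", byte_order = c("little", "big"),
                     int_size = 4L, title = "") {
  byte_order <- match.arg(byte_order)
  if (!is_number(spectral_width_hz) || spectral_width_hz <= 0)
    abort_input("spectral_width_hz must be a positive number")
  if (!is_number(spectrometer_freq_mhz) || spectrometer_freq_mhz <= 0)
    abort_input("spectrometer_freq_mhz must be a positive number")
  if (!is_number(n_points_td) || n_points_td < 2)
    abort_input("n_points_td must be >= 2")
  if (!is_number(group_delay) || group_delay < 0)
    abort_input("group_delay must be >= 0")
  if (!int_size %in% c(4L, 8L))
    abort_input("int_size must be 4 (int32) or 8 (float64)")
  structure(list(
    spectral_width_hz = as.numeric(spectral_width_hz),
    spectrometer_freq_mhz = as.numeric(spectrometer_freq_mhz),
    n_points_td = as.integer(n_points_td),
    carrier_offset_hz = as.numeric(carrier_offset_hz),
    group_delay = as.numeric(group_delay),
    pulse_program = as.character(pulse_program),
    byte_order = byte_order,
    int_size = as.integer(int_size),
    title = as.character(title)
  ), class = "acq_pars")
}

#' Processing parameters for a 1D NMR spectrum
#'
#' @param zero_fill_size Target number of complex points after zero
#'   filling; must be at least the acquired size when applied.
#' @param line_broadening_hz Exponential apodization constant `lb` in Hz;
#'   `>= 0`.
#' @param phi0_deg,phi1_deg Stored zero- and first-order phase (degrees).
#' @param water_suppression_mode One of `"none"`, `"poly"`,
#'   `"conv_gauss"`, `"conv_sine"`, `"wavelet"`.  `"wavelet"` is a
#'   reserved hook and raises a not-implemented error when selected.
#' @param reference_mode One of `"tmsp"`, `"water"`, `"manual"`.
#' @param reference_ppm Manual referencing anchor (ppm).
#' @return An object of class `proc_pars`.
#' @export
proc_pars <- function(zero_fill_size = NA_integer_, line_broadening_hz = 0,
                      phi0_deg = 0, phi1_deg = 0,
                      water_suppression_mode = c("none", "poly",
                                                 "conv_gauss", "conv_sine",
                                                 "wavelet"),
                      reference_mode = c("tmsp", "water", "manual"),
                      reference_ppm = 0) {
  water_suppression_mode <- match.arg(water_suppression_mode)
  reference_mode <- match.arg(reference_mode)
  if (!is.na(line_broadening_hz) && line_broadening_hz < 0)
    abort_input("line_broadening_hz must be >= 0")
  structure(list(
    zero_fill_size = as.integer(zero_fill_size),
    line_broadening_hz = as.numeric(line_broadening_hz),
    phi0_deg = as.numeric(phi0_deg),
    phi1_deg = as.numeric(phi1_deg),
    water_suppression_mode = water_suppression_mode,
    reference_mode = reference_mode,
    reference_ppm = as.numeric(reference_ppm)
  ), class = "proc_pars")
}

#' @export
print.acq_pars <- function(x, ...) {
  cat(sprintf(
    "<acq_pars> %.2f MHz, sw %.1f Hz, %d complex points, O1 %.1f Hz, grpdly %.2f\n",
    x$spectrometer_freq_mhz, x$spectral_width_hz, x$n_points_td,
    x$carrier_offset_hz, x$group_delay))
  invisible(x)
}

#' @export
print.proc_pars <- function(x, ...) {
  cat(sprintf(
    "<proc_pars> zf %s, lb %.2f Hz, phase (%.2f, %.2f) deg, watersup %s, ref %s\n",
    ifelse(is.na(x$zero_fill_size), "-", x$zero_fill_size),
    x$line_broadening_hz, x$phi0_deg, x$phi1_deg,
    x$water_suppression_mode, x$reference_mode))
  invisible(x)
}
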