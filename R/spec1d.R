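#' Free induction decay (time-domain NMR record)
#'
#' @param points Complex vector of time-domain points (length >= 2).
#' @param acq An [acq_pars] object.  `n_points_td` is updated to
#'   `length(points)`.
#' @return An object of class `nmr_fid` with elements `points`, `dwell_s`
#'   (sampling interval, `1/spectral_width_hz`) and `acq`.
#' @export
nmr_fid <- function(points, acq) {
  if (!inherits(acq, "acq_pars")) abort_input("acq must be an acq_pars object")
  if (length(points) < 2) abort_input("an fid needs at least 2 points")
  points <- as.complex(points)
  acq$n_points_td <- length(points)
  structure(list(points = points,
                 dwell_s = 1 / acq$spectral_width_hz,
                 acq = acq),
            class = "nmr_fid")
}

#' Frequency-domain 1D NMR spectrum
#'
#' @param points Complex spectrum, ordered from high to low ppm.
#' @param ppm_axis Strictly decreasing ppm value per point.
#' @param phi0_deg,phi1_deg Accumulated phase state (degrees).
#' @param proc A [proc_pars] object (optional).
#' @param acq The originating [acq_pars] (optional, kept for export).
#' @param log Character vector of applied operations.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(points, ppm_axis, phi0_deg = 0, phi1_deg = 0,
                         proc = proc_pars(), acq = NULL, log = character()) {
  points <- as.complex(points)
  if (length(points) != length(ppm_axis))
    abort_input("points and ppm_axis must have equal length")
  if (any(diff(ppm_axis) >= 0))
    abort_input("ppm_axis must be strictly decreasing")
  if (!is.finite(phi0_deg) || !is.finite(phi1_deg))
    abort_input("phase values must be finite")
  structure(list(points = points, ppm_axis = as.numeric(ppm_axis),
                 phi0_deg = phi0_deg, phi1_deg = phi1_deg,
                 proc = proc, acq = acq, log = log),
            class = "nmr_spectrum")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d complex points, dwell %.3g s\n",
              length(x$points), x$dwell_s))
  invisible(x)
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f .. %.3f ppm, phase (%.2f, %.2f) deg\n",
              length(x$points), x$ppm_axis[1],
              x$ppm_axis[length(x$ppm_axis)], x$phi0_deg, x$phi1_deg))
  invisible(x)
}

log_op <- function(obj, msg) {
  obj$log <- c(obj$log, msg)
  obj
}

#' Exponential apodization (line broadening)
#'
#' Multiplies time-domain point \eqn{k} (0-based) by
#' \eqn{\exp(-\pi \cdot lb \cdot k \cdot dwell)}.  An `lb` of x Hz adds
#' x Hz to the Lorentzian full width at half maximum of every line.
#'
#' @param fid An [nmr_fid].
#' @param lb Line broadening in Hz; `>= 0`.
#' @return The apodized [nmr_fid].
#' @export
apodize_exponential <- function(fid, lb) {
  if (!is_number(lb) || lb < 0) abort_input("lb must be >= 0")
  k <- seq_along(fid$points) - 1
  fid$points <- fid$points * exp(-pi * lb * k * fid$dwell_s)
  fid
}

#' Zero filling
#'
#' Appends zeros to an fid to reach `target_n` complex points, which
#' interpolates the spectrum after Fourier transformation.
#'
#' @param fid An [nmr_fid].
#' @param target_n Target length; `>= length(fid$points)`.
#' @return The zero-filled [nmr_fid].
#' @export
zero_fill <- function(fid, target_n) {
  n <- length(fid$points)
  if (!is_number(target_n) || target_n < n)
    abort_input(sprintf("target_n (%s) must be >= current length (%d)",
                        format(target_n), n))
  fid$points <- c(fid$points, complex(real = numeric(target_n - n)))
  fid$acq$n_points_td <- as.integer(target_n)
  fid
}

#' Fourier transform an fid into a frequency-domain spectrum
#'
#' Performs the complex FFT, reorders the points so the ppm axis descends
#' left to right, computes the ppm axis from spectral width, observe
#' frequency and carrier offset, and compensates the Bruker digital-filter
#' group delay (circular shift by the rounded delay plus a first-order
#' phase ramp for the fractional remainder).
#'
#' @param fid An [nmr_fid].
#' @param proc Optional [proc_pars] carried onto the spectrum.
#' @param first_point_scale Factor applied to the first time-domain point
#'   before the FFT.  `1` (default) is the plain FFT (energy-conserving);
#'   `0.5` is the conventional correction for one-sided sampling, which
#'   removes the constant baseline offset every resonance otherwise
#'   contributes.  The processing chain uses `0.5`.
#' @return An [nmr_spectrum].
#' @export
fourier_transform <- function(fid, proc = proc_pars(),
                              first_point_scale = 1) {
  acq <- fid$acq
  x <- fid$points
  n <- length(x)
  gd <- acq$group_delay
  r <- round(gd)
  frac <- gd - r
  if (r > 0) x <- c(x[(r + 1):n], x[1:r])  # undo integer part of the delay
  x[1] <- x[1] * first_point_scale
  X <- stats::fft(x)
  j <- 0:(n - 1)
  f_hz <- ifelse(j < n / 2, j, j - n) * (acq$spectral_width_hz / n)
  if (frac != 0) X <- X * exp(2i * pi * f_hz * frac / acq$spectral_width_hz)
  ord <- order(f_hz, decreasing = TRUE)
  ppm <- (acq$carrier_offset_hz + f_hz[ord]) / acq$spectrometer_freq_mhz
  nmr_spectrum(X[ord], ppm, proc = proc, acq = acq,
               log = sprintf("fourier_transform(n=%d, group_delay=%g)", n, gd))
}

#' Apply zero- and first-order phase correction
#'
#' Point \eqn{k} (0-based, counted from the left / high-ppm edge) is
#' multiplied by \eqn{\exp(i \pi/180 (\phi_0 + \phi_1 f_k))} with
#' \eqn{f_k = k/(N-1)}; the pivot of the first-order ramp is the left
#' (high-ppm) edge.  The stored phase state accumulates.
#'
#' @param spec An [nmr_spectrum].
#' @param phi0,phi1 Phases in degrees.
#' @return The phased [nmr_spectrum].
#' @export
apply_phase <- function(spec, phi0, phi1) {
  if (!is.finite(phi0) || !is.finite(phi1))
    abort_input("phase values must be finite")
  n <- length(spec$points)
  fk <- (seq_len(n) - 1) / (n - 1)
  spec$points <- spec$points * exp(1i * pi / 180 * (phi0 + phi1 * fk))
  spec$phi0_deg <- spec$phi0_deg + phi0
  spec$phi1_deg <- spec$phi1_deg + phi1
  log_op(spec, sprintf("apply_phase(%g, %g)", phi0, phi1))
}

#' Chemical shift referencing
#'
#' Shifts the ppm axis so that the tallest real point inside a search
#' window sits at a target position: 0.0 ppm for `"tmsp"` (TMS/TMSP/DSS),
#' 4.70 ppm for `"water"`, or a user anchor for `"manual"` (e.g. the
#' anomeric proton of glucose at 5.22 ppm).  Only the axis moves; the data
#' are unchanged.  Accuracy is half a point spacing (no interpolation).
#'
#' @param spec An [nmr_spectrum].
#' @param mode `"tmsp"`, `"water"` or `"manual"`.
#' @param anchor_ppm Target position for `mode = "manual"`.
#' @param search_window Length-2 ppm interval `c(lo, hi)` to search;
#'   defaults to target +/- 0.3 ppm.
#' @return The re-referenced [nmr_spectrum].
#' @export
reference_spectrum <- function(spec, mode = c("tmsp", "water", "manual"),
                               anchor_ppm = 0, search_window = NULL) {
  mode <- match.arg(mode)
  target <- switch(mode, tmsp = 0.0, water = 4.70, manual = anchor_ppm)
  if (is.null(search_window)) search_window <- c(target - 0.3, target + 0.3)
  idx <- ppm_indices(spec$ppm_axis, search_window[1], search_window[2])
  if (length(idx) == 0)
    abort(sprintf("referencing window [%g, %g] contains no points",
                  search_window[1], search_window[2]),
          "nmrmetab_reference_error")
  re <- Re(spec$points[idx])
  if (max(re) <= 0)
    abort("no positive maximum in the referencing window",
          "nmrmetab_reference_error")
  peak_ppm <- spec$ppm_axis[idx[which.max(re)]]
  spec$ppm_axis <- spec$ppm_axis + (target - peak_ppm)
  log_op(spec, sprintf("reference_spectrum(%s, shift=%+.5f ppm)",
                       mode, target - peak_ppm))
}

conv_kernel <- function(window, width) {
  if (width == 1) return(1)
  k <- switch(window,
    gauss = {
      u <- seq(-1, 1, length.out = width)
      exp(-0.5 * (u / 0.4)^2)   # sigma = width/5
    },
    sine = sin(pi * (seq_len(width) - 0.5) / width),
    abort_input("window must be 'gauss' or 'sine'"))
  k / sum(k)
}

#' Post-acquisition water suppression by fid convolution
#'
#' Estimates the slowly varying (on-carrier, i.e. water) component of the
#' fid by a moving weighted average with a Gaussian or sine kernel and
#' subtracts it.  At the fid edges the kernel is renormalized over the
#' in-range points, so a pure DC component is removed exactly.
#'
#' @param fid An [nmr_fid].
#' @param window Kernel shape, `"gauss"` or `"sine"`.
#' @param width_points Kernel length in points; `1 <= width < n`.  Width 1
#'   makes the estimate equal the signal (output identically zero).
#' @return The suppressed [nmr_fid].
#' @export
suppress_water_conv <- function(fid, window = c("gauss", "sine"),
                                width_points = 32) {
  window <- match.arg(window)
  n <- length(fid$points)
  if (!is_number(width_points) || width_points < 1 || width_points >= n)
    abort_input("width_points must satisfy 1 <= width < length(points)")
  w <- as.integer(width_points)
  k <- conv_kernel(window, w)
  c0 <- ((w - 1L) %/% 2L) + 1L
  wt <- as.numeric(stats::convolve(rep(1, n), rev(k), type = "open"))
  wt <- wt[c0:(c0 + n - 1L)]
  sm <- function(x) {
    yf <- as.numeric(stats::convolve(x, rev(k), type = "open"))
    # kernel weights are renormalized at the edges so DC is removed exactly
    yf[c0:(c0 + n - 1L)] / wt
  }
  est <- complex(real = sm(Re(fid$points)), imaginary = sm(Im(fid$points)))
  fid$points <- fid$points - est
  fid
}

#' Post-acquisition water suppression by polynomial fid correction
#'
#' Fits a least-squares polynomial of the given order over time to the
#' real and imaginary fid channels and subtracts it, removing the slow
#' solvent component.
#'
#' @param fid An [nmr_fid].
#' @param order Polynomial order, `0 <= order <= 10` and `< n`.
#' @return The corrected [nmr_fid].
#' @export
suppress_water_poly <- function(fid, order = 3) {
  n <- length(fid$points)
  if (!is_number(order) || order < 0 || order > 10)
    abort_input("order must be in [0, 10]")
  if (order >= n) abort_input("order must be < length(points)")
  t <- seq(-1, 1, length.out = n)
  B <- stats::poly(t, degree = max(order, 1), raw = FALSE)
  if (order == 0) B <- matrix(numeric(0), nrow = n, ncol = 0)
  B <- cbind(1, B)
  fit <- function(y) drop(B %*% qr.coef(qr(B), y))
  est <- complex(real = fit(Re(fid$points)), imaginary = fit(Im(fid$points)))
  fid$points <- fid$points - est
  fid
}

#' Spline baseline specification
#'
#' @param anchor_ppms Baseline anchor positions (ppm); at least 2.
#' @param max_gap_points Maximum allowed index gap between adjacent
#'   anchors before straight-line intermediate anchors are inserted
#'   ("linear-spline" behaviour); `>= 2`.
#' @return An object of class `spline_baseline_spec`.
#' @export
spline_baseline_spec <- function(anchor_ppms, max_gap_points = 1000) {
  if (length(anchor_ppms) < 2) abort_input("need at least 2 baseline anchors")
  if (!is_number(max_gap_points) || max_gap_points < 2)
    abort_input("max_gap_points must be >= 2")
  structure(list(anchor_ppms = as.numeric(anchor_ppms),
                 max_gap_points = as.integer(max_gap_points)),
            class = "spline_baseline_spec")
}

#' Cubic spline baseline correction with linear gap filling
#'
#' Anchor values are the median of the real part in a +/-2 point window
#' around each anchor.  When two adjacent anchors are more than
#' `max_gap_points` apart, intermediate anchors are simulated on the
#' straight line between them at spacing `<= max_gap_points`; this
#' prevents the spline from over-correcting dense signal regions.  A
#' natural cubic spline through the augmented anchor set is subtracted
#' from the real part.
#'
#' @param spec An [nmr_spectrum].
#' @param bspec A [spline_baseline_spec].
#' @return A list with the corrected `spectrum` and the subtracted
#'   `baseline` (real vector).
#' @export
spline_baseline <- function(spec, bspec) {
  if (!inherits(bspec, "spline_baseline_spec"))
    abort_input("bspec must be a spline_baseline_spec")
  n <- length(spec$points)
  re <- Re(spec$points)
  idx <- vapply(bspec$anchor_ppms,
                function(p) which.min(abs(spec$ppm_axis - p)), integer(1))
  rng <- range(spec$ppm_axis)
  if (any(bspec$anchor_ppms < rng[1] | bspec$anchor_ppms > rng[2]))
    abort_input("baseline anchors must lie inside the ppm axis")
  idx <- sort(unique(idx))
  if (length(idx) < 2) abort_input("need at least 2 distinct anchor points")
  vals <- vapply(idx, function(i) {
    stats::median(re[max(1, i - 2):min(n, i + 2)])
  }, numeric(1))
  # augment: straight-line anchors across wide gaps
  ax <- idx[1]; ay <- vals[1]
  for (j in seq_len(length(idx) - 1)) {
    gap <- idx[j + 1] - idx[j]
    if (gap > bspec$max_gap_points) {
      nseg <- ceiling(gap / bspec$max_gap_points)
      ii <- idx[j] + round(seq_len(nseg - 1) * gap / nseg)
      vv <- vals[j] + (vals[j + 1] - vals[j]) * (ii - idx[j]) / gap
      ax <- c(ax, ii); ay <- c(ay, vv)
    }
    ax <- c(ax, idx[j + 1]); ay <- c(ay, vals[j + 1])
  }
  sp <- stats::spline(ax, ay, xout = seq_len(n), method = "natural")
  baseline <- sp$y
  attr(baseline, "anchor_idx") <- ax   # augmented anchor set, for inspection
  spec$points <- complex(real = re - baseline, imaginary = Im(spec$points))
  spec <- log_op(spec, sprintf("spline_baseline(%d anchors, max_gap=%d)",
                               length(idx), bspec$max_gap_points))
  list(spectrum = spec, baseline = baseline)
}

#' Dispatch post-acquisition water suppression by mode
#'
#' @param fid An [nmr_fid].
#' @param mode One of `"none"`, `"poly"`, `"conv_gauss"`, `"conv_sine"`,
#'   `"wavelet"`.  The wavelet mode (WAVEWAT) is a reserved interface
#'   slot and raises a not-implemented error.
#' @param ... Passed to the mode's implementation.
#' @return The processed [nmr_fid].
#' @export
suppress_water <- function(fid, mode = c("none", "poly", "conv_gauss",
                                         "conv_sine", "wavelet"), ...) {
  mode <- match.arg(mode)
  switch(mode,
    none = fid,
    poly = suppress_water_poly(fid, ...),
    conv_gauss = suppress_water_conv(fid, window = "gauss", ...),
    conv_sine = suppress_water_conv(fid, window = "sine", ...),
    wavelet = abort(
      "wavelet-based water suppression (WAVEWAT) is a reserved hook and not implemented",
      "nmrmetab_not_implemented_error"))
}
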