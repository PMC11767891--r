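#' Synthetic peak specification
#'
#' One resonance of a synthetic spectrum.  A peak is a Lorentzian line,
#' optionally split into multiplet sticks.
#'
#' @param ppm Chemical shift of the multiplet centre (ppm).
#' @param amplitude Time-domain amplitude (arbitrary units, `>= 0`).  The
#'   default mixture uses concentration (mM) x number of protons.
#' @param linewidth_hz Lorentzian full width at half maximum (Hz); `> 0`.
#' @param sticks Optional data frame with columns `offset_hz` and
#'   `weight` describing multiplet fine structure; weights are
#'   renormalized to sum to 1.  `NULL` means a singlet.
#' @param shiftable Logical: whether per-spectrum segment shifts from a
#'   [series_spec] apply to this peak.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(ppm, amplitude, linewidth_hz = 1.2, sticks = NULL,
                      shiftable = FALSE) {
  if (!is_number(linewidth_hz) || linewidth_hz <= 0)
    abort_input("linewidth_hz must be > 0")
  if (!is_number(amplitude) || amplitude < 0)
    abort_input("amplitude must be >= 0")
  if (!is.null(sticks)) {
    stopifnot(is.data.frame(sticks), all(c("offset_hz", "weight") %in%
                                           names(sticks)))
    sticks$weight <- sticks$weight / sum(sticks$weight)
  }
  structure(list(ppm = ppm, amplitude = amplitude,
                 linewidth_hz = linewidth_hz, sticks = sticks,
                 shiftable = isTRUE(shiftable)),
            class = "peak_spec")
}

#' Default acquisition parameters of the synthetic world
#'
#' Emulates a 600 MHz system: 7200 Hz (12 ppm) sweep centred on the water
#' resonance at 4.7 ppm, 32k complex points.  The resulting axis spans
#' roughly 10.7 to -1.3 ppm, which covers both autophase baseline edge
#' regions.
#'
#' @param n_points Number of complex points (default 32768).
#' @return An [acq_pars] object.
#' @export
default_acq <- function(n_points = 32768) {
  acq_pars(spectral_width_hz = 7200, spectrometer_freq_mhz = 600,
           n_points_td = n_points, carrier_offset_hz = 4.7 * 600,
           pulse_program = "noesygppr1d")
}

#' Synthetic metabolite-mixture peak table
#'
#' Five-component aqueous mixture used throughout the test suite:
#' urea (50 mM, broad), creatinine (0.78 mM), alanine (0.68 mM),
#' isoleucine (0.23 mM), TMSP (0.5 mM) and a residual water hump.
#' Amplitudes are concentration x protons.
#'
#' By default the table also carries a very broad (1.5 kHz) probe/solvent
#' background resonance.  Experimental 1D spectra always contain such a
#' smooth baseline component (it is particularly strong on cryogenically
#' cooled probes), its shape is shared across a series acquired on one
#' instrument, and its phase-sensitive tails at the spectrum edges are
#' precisely what reference-baseline automatic phasing measures; a
#' background-free spectrum would be an unrealistically uninformative
#' edge case for that algorithm.  Its amplitude is set so the edge-region
#' baseline is a few times the point noise of the default generator
#' settings, matching the visibly distorted baselines of real data.
#'
#' @param background Include the broad probe background resonance.
#' @return List of [peak_spec] objects.
#' @export
metabolite_mix_peaks <- function(background = TRUE) {
  peaks <- list(
    peak_spec(0.00, 0.5 * 9),                       # TMSP
    peak_spec(0.93, 0.23 * 3), peak_spec(1.00, 0.23 * 3),  # isoleucine CH3
    peak_spec(1.47, 0.68 * 3), peak_spec(3.77, 0.68 * 1),  # alanine
    peak_spec(3.04, 0.78 * 3), peak_spec(4.06, 0.78 * 2),  # creatinine
    peak_spec(5.78, 50 * 2, linewidth_hz = 8),      # urea (broad NH2)
    peak_spec(4.70, 20, linewidth_hz = 20)          # residual water
  )
  if (isTRUE(background))
    peaks <- c(peaks, list(peak_spec(4.70, 240, linewidth_hz = 1500)))
  peaks
}

#' Generate a synthetic fid
#'
#' Sum of exponentially decaying complex sinusoids (frequency from the
#' ppm position, decay from the Lorentzian linewidth) plus complex
#' circular Gaussian noise.  Deterministic for a given seed; the caller's
#' RNG stream is left untouched.
#'
#' @param peaks List of [peak_spec] objects; all must lie inside the
#'   spectral window.
#' @param acq An [acq_pars]; defaults to [default_acq()].
#' @param noise_sd Time-domain noise standard deviation per channel.  The
#'   default 0.05 puts the frequency-domain SNR of the creatinine 3.04
#'   ppm line of [metabolite_mix_peaks()] near 500.
#' @param seed Integer seed, or `NULL` for no noise reproducibility.
#' @return An [nmr_fid].
#' @export
gen_fid <- function(peaks, acq = default_acq(), noise_sd = 0.05,
                    seed = NULL) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  n <- acq$n_points_td
  t <- (0:(n - 1)) / acq$spectral_width_hz
  x <- complex(real = numeric(n))
  for (p in peaks) {
    f0 <- p$ppm * acq$spectrometer_freq_mhz - acq$carrier_offset_hz
    sticks <- p$sticks
    if (is.null(sticks)) sticks <- data.frame(offset_hz = 0, weight = 1)
    for (s in seq_len(nrow(sticks))) {
      f <- f0 + sticks$offset_hz[s]
      if (abs(f) > acq$spectral_width_hz / 2)
        abort_input(sprintf("peak at %.3f ppm falls outside the spectral window",
                            p$ppm))
      x <- x + p$amplitude * sticks$weight[s] *
        exp((2i * pi * f - pi * p$linewidth_hz) * t)
    }
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, complex(real = stats::rnorm(n, sd = noise_sd),
                                     imaginary = stats::rnorm(n, sd = noise_sd)))
    x <- x + noise
  }
  nmr_fid(x, acq)
}

#' Specification of a synthetic spectrum series
#'
#' Describes the ground truth of a series sharing one template peak set:
#' per-spectrum phase errors, ppm displacements of the shiftable peaks,
#' dilution factors and baseline polynomials.
#'
#' @param n_spectra Number of spectra.
#' @param peaks Template peak list ([peak_spec] objects).
#' @param phase_errors `n x 2` matrix of (phi0, phi1) distortions in
#'   degrees, or `NULL` for none.
#' @param segment_shifts ppm displacement of the shiftable peaks, one per
#'   spectrum, or `NULL`.
#' @param dilution_factors Intensity scale per spectrum, or `NULL`.
#' @param baseline_coefs Optional `n x k` matrix of polynomial baseline
#'   coefficients (added to the real part over a [-1, 1] grid).
#' @param noise_sd Time-domain noise SD per channel.
#' @param acq An [acq_pars].
#' @param seed Integer seed for the noise.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(n_spectra, peaks, phase_errors = NULL,
                        segment_shifts = NULL, dilution_factors = NULL,
                        baseline_coefs = NULL, noise_sd = 0.05,
                        acq = default_acq(), seed = 1L) {
  if (!is.null(phase_errors)) {
    phase_errors <- as.matrix(phase_errors)
    stopifnot(nrow(phase_errors) == n_spectra, ncol(phase_errors) == 2)
  }
  if (!is.null(segment_shifts)) stopifnot(length(segment_shifts) == n_spectra)
  if (!is.null(dilution_factors)) stopifnot(length(dilution_factors) == n_spectra)
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  structure(list(n_spectra = n_spectra, peaks = peaks,
                 phase_errors = phase_errors,
                 segment_shifts = segment_shifts,
                 dilution_factors = dilution_factors,
                 baseline_coefs = baseline_coefs,
                 noise_sd = noise_sd, acq = acq, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a synthetic spectrum series with known ground truth
#'
#' Each spectrum is built from the template peaks (with its own shift,
#' dilution and noise), Fourier transformed, and distorted by its phase
#' error in the frequency domain (the stored phase state stays 0, so the
#' distortion is "unknown" to downstream code).  The ground truth is
#' returned alongside for recovery tests.
#'
#' @param sspec A [series_spec].
#' @return A list with `set` (a [spectra_set]) and `truth` (list of
#'   `phase_errors`, `segment_shifts`, `dilution_factors`).
#' @export
gen_series <- function(sspec) {
  stopifnot(inherits(sspec, "series_spec"))
  spectra <- vector("list", sspec$n_spectra)
  for (i in seq_len(sspec$n_spectra)) {
    peaks <- sspec$peaks
    if (!is.null(sspec$segment_shifts)) {
      peaks <- lapply(peaks, function(p) {
        if (p$shiftable) p$ppm <- p$ppm + sspec$segment_shifts[i]
        p
      })
    }
    if (!is.null(sspec$dilution_factors)) {
      peaks <- lapply(peaks, function(p) {
        p$amplitude <- p$amplitude * sspec$dilution_factors[i]
        p
      })
    }
    fid <- gen_fid(peaks, sspec$acq, sspec$noise_sd,
                   seed = sspec$seed + 1000L * i)
    sp <- fourier_transform(fid, first_point_scale = 0.5)
    if (!is.null(sspec$phase_errors)) {
      sp <- apply_phase(sp, sspec$phase_errors[i, 1], sspec$phase_errors[i, 2])
      sp$phi0_deg <- 0; sp$phi1_deg <- 0   # distortion is unknown downstream
    }
    if (!is.null(sspec$baseline_coefs)) {
      u <- seq(-1, 1, length.out = length(sp$points))
      b <- drop(outer(u, seq_len(ncol(sspec$baseline_coefs)) - 1, `^`) %*%
                  sspec$baseline_coefs[i, ])
      sp$points <- sp$points + b
    }
    spectra[[i]] <- sp
  }
  set <- spectra_set(spectra, class_labels = rep("synthetic", sspec$n_spectra))
  list(set = set,
       truth = list(phase_errors = sspec$phase_errors,
                    segment_shifts = sspec$segment_shifts,
                    dilution_factors = sspec$dilution_factors))
}

#' Synthetic HSQC multiplet trace from a ground-truth isotopomer
#' distribution
#'
#' Builds the carbon-dimension trace of one HSQC multiplet: the multiplet
#' components predicted by [forward_multiplet()] are rendered as
#' unit-area Lorentzian sticks of the given linewidth and summed, plus
#' Gaussian noise.
#'
#' @param x An [isotopomer_distribution].
#' @param entry A [metabolite_entry].
#' @param carbon Carbon index.
#' @param linewidth_hz Lorentzian FWHM of each stick (Hz).
#' @param noise_sd Noise SD in trace intensity units.
#' @param seed Integer seed.
#' @param span_hz Half-range of the Hz axis around the multiplet centre.
#' @param n_points Number of trace points.
#' @return List with `hz` (axis), `intensity`, and `truth` (the component
#'   fractions used).
#' @export
gen_multiplet_trace <- function(x, entry, carbon, linewidth_hz = 2,
                                noise_sd = 0, seed = NULL,
                                span_hz = NULL, n_points = 1024) {
  fr <- forward_multiplet(x, entry, carbon)
  model <- build_multiplet_model(entry, carbon)
  if (is.null(span_hz)) {
    pos <- unlist(lapply(model$components, function(c) c$positions_hz))
    span_hz <- max(abs(pos)) + 20 * linewidth_hz
    if (!is.finite(span_hz) || span_hz <= 0) span_hz <- 20 * linewidth_hz
  }
  hz <- seq(-span_hz, span_hz, length.out = n_points)
  y <- numeric(n_points)
  for (comp in model$components) {
    f <- fr[[comp$label]]
    if (is.null(f) || f == 0) next
    for (s in seq_along(comp$positions_hz)) {
      y <- y + f * comp$weights[s] *
        lorentzian(hz, comp$positions_hz[s], linewidth_hz)
    }
  }
  if (noise_sd > 0) y <- y + with_seed(seed, stats::rnorm(n_points, sd = noise_sd))
  list(hz = hz, intensity = y, truth = fr)
}

#' Write a synthetic on-disk Bruker fixture
#'
#' Writes a minimal, standard-conforming Bruker 1D experiment directory
#' (`fid`, `acqus`, optional `pdata/1/title`) readable by [read_bruker()].
#' For integer dialects the fid values are scaled to use the int32 range
#' and rounded; the values as written are returned so round trips can be
#' checked bit-identically.
#'
#' @param dir Target directory (created if needed).
#' @param fid An [nmr_fid].
#' @param byte_order `"little"` or `"big"`.
#' @param dtype `"int32"` (Bruker `DTYPA 0`) or `"double"` (`DTYPA 2`).
#' @param title Optional title text; `NULL` writes no title file.
#' @return Invisibly, the [nmr_fid] exactly as written (after any integer
#'   scaling).
#' @export
gen_bruker_fixture <- function(dir, fid, byte_order = c("little", "big"),
                               dtype = c("int32", "double"),
                               title = "synthetic fixture") {
  byte_order <- match.arg(byte_order)
  dtype <- match.arg(dtype)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- fid$points
  inter <- as.numeric(rbind(Re(pts), Im(pts)))  # interleave re, im
  endian <- if (byte_order == "little") "little" else "big"
  if (dtype == "int32") {
    m <- max(abs(inter))
    scale <- if (m > 0) 2^floor(log2(2^27 / m)) else 1
    inter <- round(inter * scale)
    pts <- complex(real = inter[c(TRUE, FALSE)],
                   imaginary = inter[c(FALSE, TRUE)])
    writeBin(as.integer(inter), file.path(dir, "fid"), size = 4L,
             endian = endian)
  } else {
    writeBin(inter, file.path(dir, "fid"), size = 8L, endian = endian)
  }
  acq <- fid$acq
  lines <- c(
    "##TITLE= Parameter file, synthetic",
    "##JCAMPDX= 5.0",
    "##DATATYPE= Parameter Values",
    sprintf("##$BYTORDA= %d", if (byte_order == "little") 0L else 1L),
    sprintf("##$DTYPA= %d", if (dtype == "int32") 0L else 2L),
    sprintf("##$TD= %d", 2L * length(fid$points)),
    sprintf("##$SW_h= %.6f", acq$spectral_width_hz),
    sprintf("##$SFO1= %.8f", acq$spectrometer_freq_mhz),
    sprintf("##$O1= %.6f", acq$carrier_offset_hz),
    sprintf("##$GRPDLY= %.6f", acq$group_delay),
    sprintf("##$PULPROG= <%s>", acq$pulse_program),
    "##$D= (0..7)",
    "0 4.0 0 0 0 0 0 0",
    "##END="
  )
  writeLines(lines, file.path(dir, "acqus"))
  if (!is.null(title)) {
    dir.create(file.path(dir, "pdata", "1"), recursive = TRUE,
               showWarnings = FALSE)
    writeLines(title, file.path(dir, "pdata", "1", "title"))
  }
  out <- fid
  out$points <- pts
  invisible(out)
}
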