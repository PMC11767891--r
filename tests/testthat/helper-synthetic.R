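# Shared generators for the test suite.  Everything is built in code at
# test time; sizes are kept small unless a scenario needs the full grid.

small_acq <- function(n = 2048) default_acq(n)

# One-peak fid on a small grid
one_peak_fid <- function(ppm = 5.5, amp = 1, lw = 1.2, n = 2048,
                         noise = 0, seed = 1) {
  gen_fid(list(peak_spec(ppm, amp, lw)), small_acq(n), noise_sd = noise,
          seed = seed)
}

# Small spectra set with flat spectra built directly on an axis
flat_set <- function(values, n = 1000, lo = 0, hi = 10) {
  ppm <- seq(hi, lo, length.out = n + 1)[1:n]
  spectra <- lapply(values, function(v)
    nmr_spectrum(complex(real = rep(v, n)), ppm))
  spectra_set(spectra, class_labels = rep("t", length(values)))
}

# Series for the segmental-alignment scenarios: a narrowly split (2 Hz)
# doublet inside the [3.75, 4.05] ppm segment, reference unshifted.
make_align_series <- function(shifts, seed, noise_sd = 0.05) {
  dbl <- data.frame(offset_hz = c(-1, 1), weight = c(0.5, 0.5))
  peaks <- list(peak_spec(3.9, 2, 1.2, sticks = dbl, shiftable = TRUE),
                peak_spec(1.0, 1, 1.2), peak_spec(7.0, 1, 1.2))
  gen_series(series_spec(length(shifts), peaks, segment_shifts = shifts,
                         noise_sd = noise_sd, seed = seed))
}

lactate_entry <- function() {
  load_mlinfo(system.file("extdata", "mlinfo", "lactate.mlinfo",
                          package = "nmrmetab"))
}

lactate_truth <- function() {
  isotopomer_distribution(c("000" = 0.5, "001" = 0.2, "011" = 0.3))
}
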