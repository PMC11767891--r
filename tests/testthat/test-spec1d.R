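test_that("exponential apodization follows the closed form", {
  fid <- nmr_fid(rep(1 + 0i, 2048), acq_pars(1000, 600, 2048))  # dwell 1 ms
  expect_identical(apodize_exponential(fid, 0)$points, fid$points)
  ap <- apodize_exponential(fid, 0.3)
  expect_equal(Mod(ap$points[1]), 1)                   # first point unchanged
  expect_equal(Mod(ap$points[1001]), exp(-pi * 0.3 * 1.0), tolerance = 1e-12)
  expect_error(apodize_exponential(fid, -1), class = "nmrmetab_input_error")
})

test_that("apodization broadens a Lorentzian line by lb Hz", {
  lw_fit <- function(lb) {
    fid <- apodize_exponential(one_peak_fid(lw = 2, n = 8192), lb)
    sp <- fourier_transform(zero_fill(fid, 65536))  # interpolate the line
    re <- Re(sp$points)
    hz <- sp$ppm_axis * sp$acq$spectrometer_freq_mhz
    k <- which.max(re)
    half <- re[k] / 2
    cross <- function(side) {
      i <- k
      while (re[i + side] > half) i <- i + side
      # linear interpolation of the half-height crossing
      frac <- (re[i] - half) / (re[i] - re[i + side])
      hz[i] + frac * (hz[i + side] - hz[i])
    }
    abs(cross(1L) - cross(-1L))
  }
  expect_equal(lw_fit(0.3) - lw_fit(0), 0.3, tolerance = 0.05)
})

test_that("zero filling appends exact zeros and conserves content", {
  fid <- one_peak_fid(n = 65536 / 32)  # keep small; exact arithmetic is size-free
  zf <- zero_fill(fid, 4096)
  expect_length(zf$points, 4096)
  expect_identical(zf$points[1:2048], fid$points)
  expect_true(all(zf$points[2049:4096] == 0))
  expect_equal(sum(Mod(zf$points)), sum(Mod(fid$points)))
  expect_identical(zero_fill(fid, 2048)$points, fid$points)
  expect_error(zero_fill(fid, 100), class = "nmrmetab_input_error")
})

test_that("the batch settings produce the contracted zero-fill size", {
  fid <- nmr_fid(complex(real = stats::rnorm(65536)), default_acq(65536))
  expect_length(zero_fill(fid, 131072)$points, 131072)
})

test_that("fourier transform puts a +500 Hz line at the right ppm", {
  acq <- small_acq(4096)
  t <- (0:4095) / acq$spectral_width_hz
  fid <- nmr_fid(exp((2i * pi * 500 - pi * 1.2) * t), acq)
  sp <- fourier_transform(fid)
  peak_ppm <- sp$ppm_axis[which.max(Re(sp$points))]
  expected <- (acq$carrier_offset_hz + 500) / acq$spectrometer_freq_mhz
  spacing <- abs(diff(sp$ppm_axis[1:2]))
  expect_lt(abs(peak_ppm - expected), spacing)
  expect_true(all(diff(sp$ppm_axis) < 0))
})

test_that("plain FFT satisfies Parseval on noise", {
  fid <- nmr_fid(complex(real = stats::rnorm(4096),
                         imaginary = stats::rnorm(4096)),
                 small_acq(4096))
  sp <- fourier_transform(fid)
  e_t <- sum(Mod(fid$points)^2)
  e_f <- sum(Mod(sp$points)^2) / 4096
  expect_equal(e_f / e_t, 1, tolerance = 1e-9)
})

test_that("group delay compensation undoes integer and fractional delays", {
  acq <- small_acq(4096)
  t <- (0:4095) / acq$spectral_width_hz
  x <- exp((2i * pi * 500 - pi * 1.2) * t)
  sp0 <- fourier_transform(nmr_fid(x, acq))
  # integer delay: circularly delayed fid + declared group delay
  gd <- 68L
  acq_g <- acq; acq_g$group_delay <- 68
  xd <- c(x[(4096 - gd + 1):4096], x[1:(4096 - gd)])
  spg <- fourier_transform(nmr_fid(xd, acq_g))
  expect_equal(spg$points, sp0$points, tolerance = 1e-12)
  # no delay -> no residual phase ramp: two on-grid lines far apart both
  # come out absorptive
  df <- acq$spectral_width_hz / 4096
  f1 <- 300 * df; f2 <- 3000 * df - acq$spectral_width_hz / 2
  x2 <- exp((2i * pi * f1 - pi * 5) * t) + exp((2i * pi * f2 - pi * 5) * t)
  sp2 <- fourier_transform(nmr_fid(x2, acq), first_point_scale = 0.5)
  ii <- order(Re(sp2$points), decreasing = TRUE)[1:2]
  expect_lt(max(abs(Arg(sp2$points[ii]))) * 180 / pi, 2)
})

test_that("apply_phase is a group action with exact special cases", {
  sp <- fourier_transform(one_peak_fid())
  expect_equal(apply_phase(sp, 0, 0)$points, sp$points)
  expect_equal(Re(apply_phase(sp, 180, 0)$points), -Re(sp$points),
               tolerance = 1e-12)
  back <- apply_phase(apply_phase(sp, 37.5, -81.2), -37.5, 81.2)
  expect_equal(back$points, sp$points, tolerance = 1e-12)
  expect_equal(back$phi0_deg, 0)
  # composition accumulates the stored state
  two <- apply_phase(apply_phase(sp, 10, 20), 5, -3)
  one <- apply_phase(sp, 15, 17)
  expect_equal(two$points, one$points, tolerance = 1e-12)
  expect_equal(two$phi0_deg, 15)
  expect_equal(two$phi1_deg, 17)
})

test_that("zero-fill interpolation keeps peak positions stable", {
  fid <- one_peak_fid(ppm = 6.13, n = 2048)
  sp1 <- fourier_transform(fid)
  sp2 <- fourier_transform(zero_fill(fid, 8192))
  p1 <- sp1$ppm_axis[which.max(Re(sp1$points))]
  p2 <- sp2$ppm_axis[which.max(Re(sp2$points))]
  expect_lt(abs(p1 - p2), abs(diff(sp1$ppm_axis[1:2])))
})

test_that("referencing shifts the axis, not the data", {
  # TMSP singlet deliberately placed at 0.05 ppm
  sp <- fourier_transform(one_peak_fid(ppm = 0.05, n = 8192),
                          first_point_scale = 0.5)
  ref <- reference_spectrum(sp, "tmsp")
  spacing <- abs(diff(sp$ppm_axis[1:2]))
  expect_lt(abs(ref$ppm_axis[which.max(Re(ref$points))]), spacing / 2 + 1e-12)
  expect_identical(ref$points, sp$points)
  # manual anchor at the glucose anomeric proton position
  sp2 <- fourier_transform(one_peak_fid(ppm = 5.25, n = 8192),
                           first_point_scale = 0.5)
  ref2 <- reference_spectrum(sp2, "manual", anchor_ppm = 5.22)
  expect_lt(abs((ref2$ppm_axis[1] - sp2$ppm_axis[1]) - (-0.03)), spacing)
  # an already-referenced spectrum moves by less than a point
  ref3 <- reference_spectrum(ref, "tmsp")
  expect_lt(abs(ref3$ppm_axis[1] - ref$ppm_axis[1]), spacing)
  expect_error(reference_spectrum(sp, "manual", anchor_ppm = 40,
                                  search_window = c(39.7, 40.3)),
               class = "nmrmetab_reference_error")
})

test_that("convolution water suppression removes DC and keeps off-carrier signal", {
  acq <- small_acq(4096)
  const <- nmr_fid(rep(1 + 0i, 4096), acq)
  out <- suppress_water_conv(const, "gauss", 32)
  expect_lt(max(Mod(out$points)), 1e-10)
  expect_true(all(suppress_water_conv(const, "sine", 1)$points == 0))
  t <- (0:4095) / acq$spectral_width_hz
  y <- nmr_fid(1 + 0.5 * exp(2i * pi * 1500 * t), acq)
  sup <- suppress_water_conv(y, "gauss", 32)
  S0 <- stats::fft(y$points); S1 <- stats::fft(sup$points)
  i_sig <- round(1500 / acq$spectral_width_hz * 4096) + 1
  expect_lt(Mod(S1[1]) / Mod(S0[1]), 0.1)
  expect_equal(Mod(S1[i_sig]) / Mod(S0[i_sig]), 1, tolerance = 0.05)
  expect_error(suppress_water_conv(y, "gauss", 5000),
               class = "nmrmetab_input_error")
})

test_that("polynomial water suppression is an exact projection", {
  acq <- small_acq(1024)
  t <- seq(-1, 1, length.out = 1024)
  drift <- nmr_fid(complex(real = 2 + 3 * t - 1.5 * t^2,
                           imaginary = 1 - t + 0.5 * t^2), acq)
  out <- suppress_water_poly(drift, 2)
  expect_lt(max(Mod(out$points)), 1e-9)
  # projection is idempotent: a residual is unchanged by re-application
  y <- nmr_fid(complex(real = stats::rnorm(1024), imaginary = stats::rnorm(1024)), acq)
  r1 <- suppress_water_poly(y, 3)
  r2 <- suppress_water_poly(r1, 3)
  expect_equal(r2$points, r1$points, tolerance = 1e-10)
  # oscillation at 2 kHz survives an order-3 correction
  osc <- nmr_fid(complex(real = 2 + 3 * t) + 0.5 * exp(2i * pi * 2000 * (0:1023) / acq$spectral_width_hz), acq)
  so <- suppress_water_poly(osc, 3)
  i_sig <- round(2000 / acq$spectral_width_hz * 1024) + 1
  a0 <- Mod(stats::fft(osc$points))[i_sig]
  a1 <- Mod(stats::fft(so$points))[i_sig]
  expect_equal(a1 / a0, 1, tolerance = 0.02)
  expect_error(suppress_water_poly(y, 11), class = "nmrmetab_input_error")
})

test_that("the wavelet water suppression slot raises not-implemented", {
  fid <- one_peak_fid()
  expect_error(suppress_water(fid, "wavelet"),
               class = "nmrmetab_not_implemented_error")
  expect_identical(suppress_water(fid, "none"), fid)
})

test_that("spline baseline reproduces lines exactly and fills gaps linearly", {
  n <- 2000
  ppm <- seq(10, 0, length.out = n)
  line <- seq(5, -3, length.out = n)
  sp <- nmr_spectrum(complex(real = line), ppm)
  bs <- spline_baseline(sp, spline_baseline_spec(c(ppm[5], ppm[n - 4]),
                                                 max_gap_points = 100))
  expect_lt(max(abs(Re(bs$spectrum$points))), 1e-9 * diff(range(line)))
  # peak cluster between two anchors: baseline under it stays linear
  peaky <- line
  idx <- 800:1200
  peaky[idx] <- peaky[idx] + 50 * exp(-((idx - 1000) / 40)^2)
  sp2 <- nmr_spectrum(complex(real = peaky), ppm)
  bs2 <- spline_baseline(sp2, spline_baseline_spec(c(ppm[5], ppm[n - 4]),
                                                   max_gap_points = 100))
  second_diff <- diff(diff(bs2$baseline[500:1500]))
  expect_lt(max(abs(second_diff)), 1e-9)
  # anchors exactly at the max gap: no synthetic anchors inserted
  a1 <- 100L; a2 <- a1 + 300L
  bs3 <- spline_baseline(sp, spline_baseline_spec(c(ppm[a1], ppm[a2]),
                                                  max_gap_points = 300))
  expect_length(attr(bs3$baseline, "anchor_idx"), 2L)
  bs4 <- spline_baseline(sp, spline_baseline_spec(c(ppm[a1], ppm[a2]),
                                                  max_gap_points = 299))
  expect_gt(length(attr(bs4$baseline, "anchor_idx")), 2L)
  expect_error(spline_baseline_spec(1.0), class = "nmrmetab_input_error")
})

test_that("the processing chain is deterministic", {
  run <- function() {
    fid <- gen_fid(metabolite_mix_peaks(), small_acq(2048),
                   noise_sd = 0.05, seed = 11)
    sp <- process_fid(fid, lb = 0.3, zero_fill_to = 4096)
    sp <- apply_phase(sp, 12.5, -30)
    reference_spectrum(sp, "water")
  }
  a <- run(); b <- run()
  expect_identical(a$points, b$points)
  expect_identical(a$ppm_axis, b$ppm_axis)
})
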