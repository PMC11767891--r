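test_that("exclude_regions zeroes exactly the stated half-open interval", {
  set <- flat_set(c(1, 1), n = 1000)   # axis 10 .. 0.01, spacing 0.01
  out <- exclude_regions(set, list(c(4.5, 5.0)))
  ax <- out$spectra[[1]]$ppm_axis
  zeroed <- Re(out$spectra[[1]]$points) == 0
  expect_identical(zeroed, ax >= 4.5 & ax < 5.0)
  # empty region list is the identity
  expect_identical(set_matrix(exclude_regions(set, list())),
                   set_matrix(set))
  # overlapping regions zero the union; operation is idempotent
  o1 <- exclude_regions(set, list(c(2, 3), c(2.5, 3.5)))
  o2 <- exclude_regions(set, list(c(2, 3.5)))
  expect_identical(set_matrix(o1), set_matrix(o2))
  expect_identical(set_matrix(exclude_regions(o1, list(c(2, 3), c(2.5, 3.5)))),
                   set_matrix(o1))
  expect_error(exclude_regions(set, list(c(5, 4))),
               class = "nmrmetab_input_error")
})

test_that("segment_align recovers exact displacements and respects the no-signal rule", {
  n <- 1000
  ppm <- seq(10, 0.01, length.out = n)
  base <- numeric(n)
  base[480:520] <- exp(-((480:520 - 500) / 6)^2)   # peak mid-segment
  displaced <- c(numeric(5), base[1:(n - 5)])       # shifted +5 points
  set <- spectra_set(list(nmr_spectrum(complex(real = base), ppm),
                          nmr_spectrum(complex(real = displaced), ppm)),
                     class_labels = c("r", "s"))
  seg <- c(ppm[560], ppm[440])
  res <- segment_align(set, seg, ref_index = 1, max_shift = 20)
  expect_identical(res$shifts, c(0L, -5L))
  expect_equal(res$correlations_after[2], 1.0, tolerance = 1e-12)
  # points outside the segment are untouched
  idx_out <- which(!(ppm >= seg[1] & ppm < seg[2]))
  expect_identical(Re(res$set$spectra[[2]]$points)[idx_out],
                   displaced[idx_out])
  # all-zero reference segment: no-op
  set0 <- spectra_set(list(nmr_spectrum(complex(real = numeric(n)), ppm),
                           nmr_spectrum(complex(real = displaced), ppm)),
                      class_labels = c("r", "s"))
  res0 <- segment_align(set0, seg, ref_index = 1, max_shift = 20)
  expect_identical(res0$shifts, c(0L, 0L))
  expect_identical(set_matrix(res0$set), set_matrix(set0))
  expect_error(segment_align(set, c(ppm[5], ppm[1]), 1),
               class = "nmrmetab_input_error")
})

test_that("segmental alignment fixes a shifted synthetic series", {
  set.seed(42)
  shifts <- c(0, runif(3, -0.02, 0.02))
  g <- make_align_series(shifts, seed = 42)
  res <- segment_align(g$set, c(3.75, 4.05), ref_index = 1)
  expect_true(all(res$correlations_after[-1] > 0.95))
})

test_that("noise_filter pools the noise region and thresholds the max", {
  n <- 2000
  ppm <- seq(10.6, 0.01, length.out = n)
  mk <- function(seed) {
    set.seed(seed)
    y <- stats::rnorm(n, sd = 1)
    y[c(300, 900, 1500)] <- 50
    y
  }
  set <- spectra_set(list(nmr_spectrum(complex(real = mk(1)), ppm),
                          nmr_spectrum(complex(real = mk(2)), ppm)),
                     class_labels = c("a", "b"))
  out <- noise_filter(set, c(10.0, 10.5), k = 4)
  m <- set_matrix(out)
  expect_true(all(m[, c(300, 900, 1500)] == 50))     # peaks retained
  noise_cols <- setdiff(seq_len(n), c(300, 900, 1500))
  expect_gt(mean(colSums(m[, noise_cols] != 0) == 0), 0.95)
  # k = 0 is the identity
  expect_identical(set_matrix(noise_filter(set, c(10.0, 10.5), 0)),
                   set_matrix(set))
  # threshold above everything zeroes every point
  all0 <- noise_filter(set, c(10.0, 10.5), k = 1000)
  expect_true(all(set_matrix(all0) == 0))
  expect_error(noise_filter(set, c(10.0, 10.0), 4),
               class = "nmrmetab_input_error")
})

test_that("bucketing conserves total intensity and labels bin centres", {
  set <- flat_set(c(1), n = 1000)
  m0 <- set_matrix(set)
  set$spectra[[1]]$points <- complex(real = stats::rnorm(1000))
  fm1 <- bucket_spectra(set, 0.01)    # width = spacing: identity
  expect_equal(ncol(fm1$values), 1000)
  expect_equal(as.numeric(fm1$values), Re(set$spectra[[1]]$points))
  fm2 <- bucket_spectra(set, 0.05)
  expect_equal(ncol(fm2$values), 200)
  expect_equal(sum(fm2$values), sum(Re(set$spectra[[1]]$points)),
               tolerance = 1e-9)
  expect_true(all(diff(fm2$feature_ppm) < 0))
  # all-zero spectrum gives all-zero buckets
  zset <- flat_set(c(0), n = 100)
  expect_true(all(bucket_spectra(zset, 0.5)$values == 0))
  expect_error(bucket_spectra(set, 0.001), class = "nmrmetab_input_error")
})

test_that("TSA equalizes totals; PQN recovers dilution factors", {
  template <- c(5, 1, 3, 2, 8, 0.5)
  c_j <- c(1, 0.5, 0.25)
  vals <- t(vapply(c_j, function(c) c * template, numeric(6)))
  fm <- feature_matrix(vals, seq(6, 1), c("a", "b", "c"))
  tsa <- normalize_features(fm, "tsa")
  expect_equal(rowSums(tsa$matrix$values),
               rep(mean(rowSums(vals)), 3), tolerance = 1e-10)
  # tsa on already-equal-total samples is the identity
  eq <- feature_matrix(rbind(template, rev(template)), seq(6, 1),
                       c("a", "b"))
  expect_equal(normalize_features(eq, "tsa")$matrix$values, eq$values,
               tolerance = 1e-12)
  pqn <- normalize_features(fm, "pqn")
  expect_equal(stats::cor(pqn$factors, c_j), 1.0, tolerance = 1e-12)
  expect_lt(max(abs(pqn$matrix$values[2, ] - pqn$matrix$values[1, ])), 1e-10)
  expect_error(normalize_features(
    feature_matrix(rbind(template, -template), seq(6, 1), c("a", "b")),
    "tsa"), class = "nmrmetab_normalization_error")
})

test_that("PQN factors equal brute-force median quotients on a toy matrix", {
  vals <- rbind(c(1, 2, 3, 4),
                c(2, 2, 6, 9),
                c(4, 9, 12, 15))
  fm <- feature_matrix(vals, seq(4, 1), letters[1:3])
  res <- normalize_features(fm, "pqn")
  # oracle: explicit tsa, median reference, median quotients
  totals <- rowSums(vals)
  tsa_f <- totals / mean(totals)
  m1 <- vals / tsa_f
  ref <- apply(m1, 2, stats::median)
  q <- apply(m1, 1, function(r) stats::median(r / ref))
  expect_equal(res$factors, tsa_f * q, tolerance = 1e-12)
  expect_equal(res$matrix$values, m1 / q, tolerance = 1e-12)
})

test_that("glog matches its closed forms and is monotone", {
  x <- c(0.5, 1, 2, 10)
  expect_equal(glog_transform(x, 0), log(2 * x), tolerance = 1e-12)
  expect_equal(glog_transform(0, 2.5), 0.5 * log(2.5), tolerance = 1e-12)
  set.seed(1)
  for (lambda in c(0.1, 1, 100)) {
    xs <- sort(stats::runif(50, -5, 5))
    ys <- glog_transform(xs, lambda)
    expect_true(all(diff(ys) > 0))
  }
  expect_error(glog_transform(c(1, -1), 0), class = "nmrmetab_domain_error")
  expect_error(glog_transform(1, -2), class = "nmrmetab_input_error")
  # double application is guarded
  fm <- feature_matrix(matrix(1:4, 2), c(2, 1), c("a", "b"))
  g1 <- glog_transform(fm, 1)
  expect_warning(g2 <- glog_transform(g1, 1), "already")
  expect_identical(g2$values, g1$values)
})

test_that("run_pipeline applies stages in order and logs skips", {
  g <- gen_series(series_spec(3, metabolite_mix_peaks(),
                              acq = small_acq(1024), seed = 9))
  # all stages disabled: matrix = raw points
  fm0 <- run_pipeline(g$set, preproc_options())
  expect_equal(fm0$values, set_matrix(g$set))
  expect_true(any(grepl("bucket: skipped", attr(fm0, "pipeline_log"))))
  # doubling the bucket width halves the feature count
  fa <- run_pipeline(g$set, preproc_options(bucket_ppm = 0.05))
  fb <- run_pipeline(g$set, preproc_options(bucket_ppm = 0.10))
  expect_equal(ncol(fa$values), 2 * ncol(fb$values))
  # full pipeline runs end to end and exports a valid CSV
  opts <- preproc_options(exclude = list(c(4.5, 5.0)),
                          noise_region = c(10.0, 10.5), noise_factor = 0,
                          bucket_ppm = 0.05, normalization = "pqn",
                          glog_lambda = 1e-4)
  fm <- run_pipeline(g$set, opts)
  expect_false(any(!is.finite(fm$values)))
  expect_true(fm$glog_applied)
  td <- withr::local_tempdir()
  export_statistics(fm, "metaboanalyst", file.path(td, "out.csv"))
  expect_identical(strsplit(readLines(file.path(td, "out.csv"), n = 1),
                            ",")[[1]][1:2], c("Sample", "Class"))
})

test_that("alignment segments overlapping excluded regions are a config error", {
  g <- gen_series(series_spec(2, metabolite_mix_peaks(),
                              acq = small_acq(1024), seed = 9))
  opts <- preproc_options(exclude = list(c(3.8, 4.2)),
                          align_segments = list(list(segment = c(3.9, 4.1),
                                                     ref_index = 1)))
  expect_error(run_pipeline(g$set, opts), class = "nmrmetab_config_error")
})
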