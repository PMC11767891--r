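test_that("parse_param_file handles scalars, strings and arrays", {
  p <- parse_param_file(c("##$SW_h= 7211.54", "##$GRPDLY= 67.98",
                          "##$PULPROG= <noesygppr1d>"))
  expect_equal(p$SW_h, 7211.54)
  expect_equal(p$GRPDLY, 67.98)
  expect_equal(p$PULPROG, "noesygppr1d")
  # multi-line array
  arr_txt <- c("##$D= (0..63)",
               paste(rep(c("0", "4.0"), 32)[1:32], collapse = " "),
               paste(rep("0", 32), collapse = " "),
               "##END=")
  p2 <- parse_param_file(arr_txt)
  expect_length(p2$D, 64)
  expect_equal(p2$D[2], 4.0)
  # total: arbitrary junk yields a map without raising
  expect_silent(p3 <- parse_param_file(c("garbage", "", "## weird",
                                         "##$X= 1")))
  expect_equal(p3$X, 1)
  expect_type(parse_param_file(""), "list")
})

test_that("Bruker fixtures round trip bit-identically in both endiannesses", {
  td <- withr::local_tempdir()
  fid <- gen_fid(metabolite_mix_peaks(), small_acq(1024), noise_sd = 0.05,
                 seed = 3)
  w_le <- gen_bruker_fixture(file.path(td, "le"), fid, byte_order = "little")
  w_be <- gen_bruker_fixture(file.path(td, "be"), fid, byte_order = "big")
  r_le <- read_bruker(file.path(td, "le"))
  r_be <- read_bruker(file.path(td, "be"))
  expect_identical(r_le$fid$points, w_le$points)
  expect_identical(r_be$fid$points, r_le$fid$points)
  expect_equal(r_le$acq$n_points_td, 1024L)
  expect_equal(r_le$acq$spectral_width_hz, fid$acq$spectral_width_hz)
  expect_match(r_le$acq$title, "synthetic")
  # double dialect round trips without quantization at all
  w_db <- gen_bruker_fixture(file.path(td, "db"), fid, dtype = "double")
  expect_identical(read_bruker(file.path(td, "db"))$fid$points, fid$points)
})

test_that("read_bruker errors name the missing ingredient", {
  td <- withr::local_tempdir()
  expect_error(read_bruker(td), class = "nmrmetab_input_error")
  fid <- one_peak_fid(n = 64)
  gen_bruker_fixture(file.path(td, "e"), fid)
  file.remove(file.path(td, "e", "fid"))
  expect_error(read_bruker(file.path(td, "e")), "fid",
               class = "nmrmetab_input_error")
  # undecodable length (odd value count)
  gen_bruker_fixture(file.path(td, "f"), fid)
  writeBin(raw(4 * 7), file.path(td, "f", "fid"))
  expect_error(read_bruker(file.path(td, "f")),
               class = "nmrmetab_format_error")
  # title is optional
  gen_bruker_fixture(file.path(td, "g"), fid, title = NULL)
  expect_silent(r <- read_bruker(file.path(td, "g")))
  expect_identical(r$acq$title, "")
})

test_that("write_bruker round trips within the quantization bound", {
  td <- withr::local_tempdir()
  sp <- process_fid(one_peak_fid(n = 2048), lb = 0.3, zero_fill_to = 4096)
  write_bruker(sp, td)
  back <- read_bruker_processed(td)
  mx <- max(abs(Re(sp$points)))
  expect_lt(max(abs(back$real - Re(sp$points))), 2^-28 * mx)
  expect_equal(back$procs$SI, 4096)
  expect_equal(length(back$imaginary), 4096)
  # all-zero spectrum -> all-zero 1r
  z <- nmr_spectrum(complex(real = numeric(128)), seq(10, 0.1, length.out = 128))
  td2 <- withr::local_tempdir()
  write_bruker(z, td2)
  expect_true(all(read_bruker_processed(td2)$real == 0))
})

test_that("a 131072-point spectrum records SI = 131072", {
  td <- withr::local_tempdir()
  sp <- process_fid(one_peak_fid(n = 2048), lb = 0.3, zero_fill_to = 131072)
  write_bruker(sp, td, keep_imaginary = FALSE)
  expect_equal(read_bruker_processed(td)$procs$SI, 131072)
})

test_that("the native dataset format round trips losslessly", {
  td <- withr::local_tempdir()
  g <- gen_series(series_spec(4, metabolite_mix_peaks(),
                              acq = small_acq(1024), seed = 5))
  set <- g$set
  set$options <- preproc_options(exclude = list(c(4.5, 5.0)),
                                 bucket_ppm = 0.05, normalization = "pqn")
  path <- file.path(td, "set.nmds")
  save_dataset(set, path)
  back <- load_dataset(path)
  expect_equal(set_matrix(back), set_matrix(set))
  expect_identical(back$class_labels, set$class_labels)
  expect_equal(back$spectra[[1]]$ppm_axis, set$spectra[[1]]$ppm_axis)
  expect_equal(back$options$exclude[[1]], c(4.5, 5.0))
  expect_equal(back$options$bucket_ppm, 0.05)
  expect_identical(back$options$normalization, "pqn")
  expect_false(back$glog_applied)
  # glog flag survives the round trip
  set$glog_applied <- TRUE
  save_dataset(set, path)
  expect_true(load_dataset(path)$glog_applied)
})

test_that("native load rejects corrupt and mismatched files", {
  td <- withr::local_tempdir()
  g <- gen_series(series_spec(2, metabolite_mix_peaks(),
                              acq = small_acq(512), seed = 5))
  path <- file.path(td, "set.nmds")
  save_dataset(g$set, path)
  # truncation
  full <- readBin(path, "raw", file.size(path))
  writeBin(full[1:(length(full) %/% 3)], file.path(td, "trunc.nmds"))
  expect_error(load_dataset(file.path(td, "trunc.nmds")),
               class = "nmrmetab_format_error")
  expect_error(load_dataset(file.path(td, "missing.nmds")),
               class = "nmrmetab_input_error")
})

test_that("version mismatches are an explicit error", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "x"))
  jsonlite::write_json(list(format = "nmrmetab-dataset-999", n_spectra = 0,
                            n_points = 0),
                       file.path(td, "x", "manifest.json"),
                       auto_unbox = TRUE)
  zip::zip(file.path(td, "bad.nmds"), files = "manifest.json",
           root = file.path(td, "x"), mode = "cherry-pick")
  expect_error(load_dataset(file.path(td, "bad.nmds")),
               class = "nmrmetab_version_error")
})

test_that("MetaboAnalyst CSV export follows the schema and drops excluded buckets", {
  set <- flat_set(c(1, 2), n = 1000)
  for (i in 1:2) {
    pts <- Re(set$spectra[[i]]$points) + seq(0, 0.999, length.out = 1000)
    set$spectra[[i]]$points <- complex(real = pts)
  }
  set <- exclude_regions(set, list(c(4.5, 5.0)))
  fm <- bucket_spectra(set, 0.05)
  n_bucket <- ncol(fm$values)
  n_zero <- sum(colSums(fm$values != 0) == 0)
  td <- withr::local_tempdir()
  csv <- file.path(td, "ma.csv")
  export_statistics(fm, "metaboanalyst", csv)
  lines <- readLines(csv)
  header <- strsplit(lines[1], ",")[[1]]
  expect_identical(header[1:2], c("Sample", "Class"))
  expect_length(lines, 3)                         # header + 2 samples
  expect_length(header, 2 + n_bucket - n_zero)    # excluded buckets dropped
  ppm_lab <- as.numeric(header[-(1:2)])
  expect_true(all(diff(ppm_lab) < 0))
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]{4}$", header[-(1:2)])))
  # numeric round trip at 6 significant digits
  back <- utils::read.csv(csv, check.names = FALSE)
  keep <- colSums(fm$values != 0) > 0
  expect_equal(as.matrix(back[, -(1:2)]), fm$values[, keep],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("empty matrices are refused at export", {
  fm <- feature_matrix(matrix(1, 1, 1), 5.0, "a")
  fm$values <- fm$values[, 0, drop = FALSE]
  expect_error(export_statistics(fm, "metaboanalyst", tempfile()),
               class = "nmrmetab_input_error")
})

test_that("Excel export mirrors the feature table plus multiplet sheets", {
  skip_if_not_installed("readxl")
  set <- flat_set(c(1, 2), n = 200)
  fm <- bucket_spectra(set, 0.1)
  td <- withr::local_tempdir()
  xlsx <- file.path(td, "out.xlsx")
  fits <- list(lactate = data.frame(carbon = c(2, 3), s = c(0.4, 0.6),
                                    d1 = c(0.6, 0.4), r2 = c(0.99, 0.98)))
  export_statistics(fm, "excel", xlsx, multiplet_fits = fits)
  expect_identical(readxl::excel_sheets(xlsx), c("features", "lactate"))
  feats <- readxl::read_excel(xlsx, sheet = "features")
  expect_equal(nrow(feats), 2)
  expect_equal(as.numeric(feats[[3]]), fm$values[, 1], tolerance = 1e-12)
  lac <- readxl::read_excel(xlsx, sheet = "lactate")
  expect_equal(lac$s, c(0.4, 0.6))
})
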