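#' Pre-processing options for a spectrum series
#'
#' Bundles every stage of the fixed pre-processing chain:
#' exclude -> segmental alignment -> noise filter -> bucket ->
#' normalize -> glog.  A stage whose options are `NULL`/`"none"` is
#' skipped (and logged as skipped by [run_pipeline()]).
#'
#' @param exclude List of ppm intervals `c(lo, hi)` to zero.
#' @param align_segments List of lists with fields `segment` (ppm
#'   interval), `ref_index`, and optional `max_shift` (points).
#' @param noise_region ppm interval used to estimate the noise SD;
#'   default `c(10.0, 10.5)`.
#' @param noise_factor Threshold multiplier k (points whose across-sample
#'   maximum is below `k * sd` are zeroed); `0` disables the filter.
#' @param bucket_ppm Bucket width in ppm; `NULL` disables bucketing.
#' @param normalization `"none"`, `"tsa"` or `"pqn"`.
#' @param glog_lambda glog transform parameter `lambda >= 0`; `NULL`
#'   disables the transform.
#' @param export `"none"`, `"metaboanalyst"` or `"excel"`.
#' @return An object of class `preproc_options`.
#' @export
preproc_options <- function(exclude = list(), align_segments = list(),
                            noise_region = c(10.0, 10.5), noise_factor = 0,
                            bucket_ppm = NULL,
                            normalization = c("none", "tsa", "pqn"),
                            glog_lambda = NULL,
                            export = c("none", "metaboanalyst", "excel")) {
  normalization <- match.arg(normalization)
  export <- match.arg(export)
  if (!is.null(glog_lambda) && glog_lambda < 0)
    abort_input("glog_lambda must be >= 0")
  if (!is.null(bucket_ppm) && bucket_ppm <= 0)
    abort_input("bucket_ppm must be > 0")
  structure(list(exclude = exclude, align_segments = align_segments,
                 noise_region = noise_region, noise_factor = noise_factor,
                 bucket_ppm = bucket_ppm, normalization = normalization,
                 glog_lambda = glog_lambda, export = export),
            class = "preproc_options")
}

#' Zero excluded ppm regions
#'
#' Sets the real and imaginary parts of every point inside the given ppm
#' regions to exactly 0 in every spectrum (a region `c(lo, hi)` covers
#' `lo <= ppm < hi`).  Zeroed features are dropped at export.  Idempotent;
#' overlapping regions zero their union.
#'
#' @param set A [spectra_set].
#' @param regions List of ppm intervals `c(lo, hi)`, or a single interval.
#' @return The modified [spectra_set].
#' @export
exclude_regions <- function(set, regions) {
  if (is.numeric(regions)) regions <- list(regions)
  if (length(regions) == 0) return(set)
  ax <- set$spectra[[1]]$ppm_axis
  idx <- sort(unique(unlist(lapply(regions, function(r)
    ppm_indices(ax, r[1], r[2])))))
  if (length(idx) > 0) {
    for (i in seq_along(set$spectra))
      set$spectra[[i]]$points[idx] <- 0 + 0i
  }
  set$log <- c(set$log, sprintf("exclude_regions(%d regions, %d points zeroed)",
                                length(regions), length(idx)))
  set
}

shift_segment <- function(seg, s, fill) {
  L <- length(seg)
  out <- rep(fill, L)
  src <- seq_len(L) - s
  ok <- src >= 1 & src <= L
  out[ok] <- seg[src[ok]]
  out
}

#' Correlation-based segmental alignment
#'
#' For every non-reference spectrum, finds the integer point shift `s` in
#' `[-max_shift, max_shift]` maximizing the Pearson correlation between
#' the shifted segment and the reference segment (computed on the
#' overlap), moves the segment content by `s` (vacated positions filled
#' with the mean of the segment's two edge values), and leaves everything
#' outside the segment untouched.  Ties are broken toward minimal `|s|`,
#' then toward negative `s`.  If the reference segment lacks signal
#' (maximum below `min_signal`), no alignment occurs.
#'
#' @param set A [spectra_set].
#' @param segment ppm interval `c(lo, hi)`; at least 8 points.
#' @param ref_index Index of the reference spectrum.
#' @param max_shift Maximum shift in points; default segment length / 4.
#' @param min_signal Reference-signal threshold (default 0: only an
#'   all-nonpositive reference segment suppresses alignment).
#' @return List with the aligned `set`, integer `shifts`, and
#'   `correlations_before` / `correlations_after` (vs the reference;
#'   `NA` for the reference itself).
#' @export
segment_align <- function(set, segment, ref_index = 1, max_shift = NULL,
                          min_signal = 0) {
  ax <- set$spectra[[1]]$ppm_axis
  idx <- ppm_indices(ax, segment[1], segment[2])
  if (length(idx) < 8) abort_input("alignment segment must span >= 8 points")
  if (ref_index < 1 || ref_index > length(set$spectra))
    abort_input("ref_index out of range")
  if (is.null(max_shift)) max_shift <- floor(length(idx) / 4)
  ns <- length(set$spectra)
  shifts <- integer(ns)
  cb <- ca <- rep(NA_real_, ns)
  ref_seg <- Re(set$spectra[[ref_index]]$points[idx])
  if (max(ref_seg) <= min_signal) {
    set$log <- c(set$log, "segment_align: no reference signal, skipped")
    return(list(set = set, shifts = shifts, correlations_before = cb,
                correlations_after = ca))
  }
  L <- length(idx)
  svals <- (-max_shift):max_shift
  for (i in seq_len(ns)) {
    if (i == ref_index) next
    seg <- Re(set$spectra[[i]]$points[idx])
    cb[i] <- stats::cor(seg, ref_seg)
    corr <- vapply(svals, function(s) {
      kk <- max(1, 1 + s):min(L, L + s)
      a <- seg[kk - s]; b <- ref_seg[kk]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    best <- corr[which.max(corr)]
    cand <- which(corr >= best - 1e-12)
    cand <- cand[order(abs(svals[cand]), svals[cand])]
    s <- svals[cand[1]]
    shifts[i] <- s
    fill <- mean(c(seg[1], seg[L]))
    new_seg <- shift_segment(seg, s, fill)
    pts <- set$spectra[[i]]$points
    pts[idx] <- complex(real = new_seg,
                        imaginary = shift_segment(Im(pts[idx]), s,
                                                  mean(Im(pts[idx])[c(1, L)])))
    set$spectra[[i]]$points <- pts
    ca[i] <- stats::cor(new_seg, ref_seg)
  }
  set$log <- c(set$log, sprintf("segment_align([%g, %g], ref=%d): shifts %s",
                                segment[1], segment[2], ref_index,
                                paste(shifts, collapse = ",")))
  list(set = set, shifts = shifts, correlations_before = cb,
       correlations_after = ca)
}

#' Noise filtering
#'
#' Estimates the noise SD from the real points of a signal-free region
#' pooled over all spectra, then zeroes every point (in all spectra)
#' whose maximum across spectra is below `k * sd`.  `k = 0` disables the
#' filter.
#'
#' @param set A [spectra_set].
#' @param noise_region ppm interval assumed signal-free.
#' @param k Threshold multiplier; `>= 0`.
#' @return The filtered [spectra_set]; the number of zeroed points is
#'   recorded in the set log and as attribute `"n_zeroed"`.
#' @export
noise_filter <- function(set, noise_region = c(10.0, 10.5), k = 4) {
  if (k < 0) abort_input("noise factor k must be >= 0")
  if (k == 0) {
    attr(set, "n_zeroed") <- 0L
    return(set)
  }
  ax <- set$spectra[[1]]$ppm_axis
  idx <- ppm_indices(ax, noise_region[1], noise_region[2])
  if (length(idx) < 2) abort_input("noise region contains too few points")
  m <- set_matrix(set)
  sigma <- stats::sd(as.numeric(m[, idx]))
  kill <- which(apply(m, 2, max) < k * sigma)
  if (length(kill) > 0) {
    m[, kill] <- 0
    set <- set_replace_real(set, m)
    for (i in seq_along(set$spectra)) {
      im <- Im(set$spectra[[i]]$points); im[kill] <- 0
      set$spectra[[i]]$points <- complex(real = Re(set$spectra[[i]]$points),
                                         imaginary = im)
    }
  }
  set$log <- c(set$log, sprintf("noise_filter(k=%g): sigma=%.4g, %d points zeroed",
                                k, sigma, length(kill)))
  attr(set, "n_zeroed") <- length(kill)
  set
}

#' Bucketing (binning) into a feature matrix
#'
#' Aggregates points into contiguous ppm bins of fixed width, laid out
#' from the high-ppm end.  The default aggregation is the sum, which
#' conserves total intensity; labels are the bin centres.
#'
#' @param set A [spectra_set].
#' @param width_ppm Bucket width in ppm; at least the point spacing.
#' @param aggregate `"sum"` (default, conserves area) or `"mean"`.
#' @return A [feature_matrix].
#' @export
bucket_spectra <- function(set, width_ppm, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  ax <- set$spectra[[1]]$ppm_axis
  spacing <- abs(ax[1] - ax[2])
  if (!is_number(width_ppm) || width_ppm < spacing - 1e-12)
    abort_input("bucket width must be at least the point spacing")
  hi <- ax[1]
  bin <- floor((hi - ax) / width_ppm + 1e-9)
  m <- set_matrix(set)
  groups <- sort(unique(bin))
  vals <- vapply(groups, function(g) {
    cols <- which(bin == g)
    if (aggregate == "sum") rowSums(m[, cols, drop = FALSE])
    else rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1) vals <- matrix(vals, nrow = 1)
  centers <- hi - (groups + 0.5) * width_ppm
  feature_matrix(vals, centers, set$class_labels)
}

#' Normalize a feature matrix (TSA or PQN)
#'
#' TSA (total-sum/area normalization) divides each sample by its feature
#' total and rescales by the cohort-mean total.  PQN (probabilistic
#' quotient normalization) first applies TSA, takes the feature-wise
#' median sample as reference, and divides each sample by the median of
#' its feature-wise quotients against the reference.
#'
#' The returned `factors` are the overall per-sample divisors (for PQN,
#' the TSA factor times the median quotient), so an exact dilution series
#' yields factors proportional to the dilutions.
#'
#' @param matrix A [feature_matrix].
#' @param mode `"tsa"` or `"pqn"`.
#' @return List with the normalized `matrix` and the per-sample
#'   `factors`.
#' @export
normalize_features <- function(matrix, mode = c("tsa", "pqn")) {
  mode <- match.arg(mode)
  m <- matrix$values
  totals <- rowSums(m)
  bad <- which(totals <= 0)
  if (length(bad) > 0)
    abort(sprintf("sample(s) %s have non-positive total intensity",
                  paste(bad, collapse = ", ")), "nmrmetab_normalization_error")
  tsa_factor <- totals / mean(totals)
  m1 <- m / tsa_factor
  if (mode == "tsa") {
    matrix$values <- m1
    return(list(matrix = matrix, factors = tsa_factor))
  }
  ref <- apply(m1, 2, stats::median)
  pos <- ref > 0
  if (!any(pos))
    abort("PQN reference has no positive features", "nmrmetab_normalization_error")
  q <- apply(m1[, pos, drop = FALSE], 1, function(r)
    stats::median(r / ref[pos]))
  matrix$values <- m1 / q
  list(matrix = matrix, factors = tsa_factor * q)
}

#' Generalized logarithm variance stabilization
#'
#' Applies \eqn{y = \ln(x + \sqrt{x^2 + \lambda})} elementwise.  For
#' `lambda = 0` this is `ln(2x)` and requires strictly positive values;
#' for `x = 0` it is `0.5 ln(lambda)`.  Guarded against double
#' application via the `glog_applied` flag.
#'
#' @param matrix A [feature_matrix] (or plain numeric input).
#' @param lambda `lambda >= 0`.
#' @return The transformed object.
#' @export
glog_transform <- function(matrix, lambda) {
  if (!is_number(lambda) || lambda < 0) abort_input("lambda must be >= 0")
  tf <- function(x) {
    if (lambda == 0 && any(x <= 0))
      abort("glog with lambda = 0 requires all values > 0",
            "nmrmetab_domain_error")
    log(x + sqrt(x^2 + lambda))
  }
  if (is.numeric(matrix)) return(tf(matrix))
  if (isTRUE(matrix$glog_applied)) {
    warning("glog already applied; returning input unchanged")
    return(matrix)
  }
  matrix$values <- tf(matrix$values)
  matrix$glog_applied <- TRUE
  matrix
}

validate_preproc_options <- function(set, opts) {
  ax <- set$spectra[[1]]$ppm_axis
  for (r in opts$exclude) ppm_indices(ax, r[1], r[2])
  for (a in opts$align_segments) {
    seg <- ppm_indices(ax, a$segment[1], a$segment[2])
    for (r in opts$exclude) {
      ex <- ppm_indices(ax, r[1], r[2])
      if (length(intersect(seg, ex)) > 0)
        abort_config(sprintf(
          "alignment segment [%g, %g] overlaps an excluded region",
          a$segment[1], a$segment[2]))
    }
  }
  invisible(TRUE)
}

#' Run the full pre-processing pipeline
#'
#' Applies the stages in the fixed order exclude -> align -> noise
#' filter -> bucket -> normalize -> glog.  Every stage is logged with its
#' parameters; disabled stages are logged as skipped.  Regions are
#' excluded before alignment, and alignment segments overlapping excluded
#' regions are a configuration error.
#'
#' @param set A [spectra_set].
#' @param opts A [preproc_options]; defaults to the options stored in the
#'   set.
#' @return A [feature_matrix] with the pipeline log in attribute
#'   `"pipeline_log"` and normalization factors (if any) in attribute
#'   `"factors"`.
#' @export
run_pipeline <- function(set, opts = set$options) {
  validate_preproc_options(set, opts)
  lg <- character()
  say <- function(...) lg <<- c(lg, sprintf(...))
  if (length(opts$exclude) > 0) {
    set <- exclude_regions(set, opts$exclude)
    say("exclude: %d regions", length(opts$exclude))
  } else say("exclude: skipped")
  if (length(opts$align_segments) > 0) {
    for (a in opts$align_segments) {
      res <- segment_align(set, a$segment, a$ref_index,
                           max_shift = a$max_shift)
      set <- res$set
      say("align [%g, %g]: shifts %s", a$segment[1], a$segment[2],
          paste(res$shifts, collapse = ","))
    }
  } else say("align: skipped")
  if (opts$noise_factor > 0) {
    set <- noise_filter(set, opts$noise_region, opts$noise_factor)
    say("noise_filter: k=%g, %d points zeroed", opts$noise_factor,
        attr(set, "n_zeroed"))
  } else say("noise_filter: skipped")
  if (!is.null(opts$bucket_ppm)) {
    fm <- bucket_spectra(set, opts$bucket_ppm)
    say("bucket: width %g ppm -> %d features", opts$bucket_ppm,
        ncol(fm$values))
  } else {
    fm <- feature_matrix(set_matrix(set), set$spectra[[1]]$ppm_axis,
                         set$class_labels)
    say("bucket: skipped (raw points)")
  }
  factors <- NULL
  if (opts$normalization != "none") {
    nr <- normalize_features(fm, opts$normalization)
    fm <- nr$matrix
    factors <- nr$factors
    say("normalize: %s", opts$normalization)
  } else say("normalize: skipped")
  if (!is.null(opts$glog_lambda)) {
    fm <- glog_transform(fm, opts$glog_lambda)
    say("glog: lambda=%g", opts$glog_lambda)
  } else say("glog: skipped")
  attr(fm, "pipeline_log") <- lg
  attr(fm, "factors") <- factors
  fm
}
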