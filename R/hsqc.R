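#' Metabolite library entry
#'
#' Describes one metabolite for HSQC multiplet analysis: per-carbon
#' proton/carbon chemical shifts (absent for unprotonated carbons) and
#' the one-bond carbon-carbon scalar couplings (JCC, Hz) between
#' neighbouring carbons.  The carbon topology defaults to a linear chain
#' in index order; couplings define the effective neighbour graph.
#'
#' @param name Metabolite name.
#' @param shifts Data frame with columns `carbon` (1-based index),
#'   `h_ppm`, `c_ppm`; `NA` shifts mark unobservable carbons.
#' @param jcc Data frame with columns `i`, `j`, `hz` (symmetric pairs
#'   stored once), or `NULL` when no coupling information is available
#'   (the model is then limited to singlet analysis).
#' @return An object of class `metabolite_entry`.
#' @export
metabolite_entry <- function(name, shifts, jcc = NULL) {
  stopifnot(is.data.frame(shifts),
            all(c("carbon", "h_ppm", "c_ppm") %in% names(shifts)))
  n <- max(shifts$carbon)
  if (!is.null(jcc)) {
    stopifnot(is.data.frame(jcc), all(c("i", "j", "hz") %in% names(jcc)))
    if (any(jcc$hz <= 0)) abort_input("couplings must be > 0 Hz")
    if (any(jcc$i < 1 | jcc$j < 1 | jcc$i > n | jcc$j > n))
      abort_input("coupling indices out of carbon range")
  }
  structure(list(name = name, n_carbons = n, shifts = shifts, jcc = jcc),
            class = "metabolite_entry")
}

#' @export
print.metabolite_entry <- function(x, ...) {
  cat(sprintf("<metabolite_entry> %s: %d carbons, %d couplings\n",
              x$name, x$n_carbons, if (is.null(x$jcc)) 0 else nrow(x$jcc)))
  invisible(x)
}

carbon_observable <- function(entry, carbon) {
  row <- entry$shifts[entry$shifts$carbon == carbon, ]
  nrow(row) == 1 && !is.na(row$h_ppm) && !is.na(row$c_ppm)
}

coupled_neighbors <- function(entry, carbon) {
  if (is.null(entry$jcc)) return(data.frame(neighbor = integer(0),
                                            hz = numeric(0)))
  sel <- entry$jcc$i == carbon | entry$jcc$j == carbon
  nb <- ifelse(entry$jcc$i[sel] == carbon, entry$jcc$j[sel],
               entry$jcc$i[sel])
  o <- order(nb)
  data.frame(neighbor = nb[o], hz = entry$jcc$hz[sel][o])
}

#' Load a metabolite entry from a `.mlinfo` library file
#'
#' The `.mlinfo` schema is line-oriented plain text so users can add
#' their own metabolites: a `metabolite:` section with `name:` and
#' `n_carbons:`, a `carbons:` section with one `index h_ppm c_ppm` line
#' per carbon (`-` for unprotonated/unobservable carbons), and an
#' optional `jcc:` section with `i j value_hz` lines.  `#` starts a
#' comment.
#'
#' @param path Path to a `.mlinfo` file.
#' @return A [metabolite_entry].
#' @export
load_mlinfo <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  name <- NULL
  carbons <- list()
  jcc <- list()
  for (ln in lines) {
    if (grepl("^(metabolite|carbons|jcc):\\s*$", ln)) {
      section <- sub(":\\s*$", "", ln)
      next
    }
    if (section == "metabolite") {
      kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3)
        abort(sprintf("malformed metabolite line: '%s'", ln),
              "nmrmetab_schema_error")
      if (kv[2] == "name") name <- kv[3]
    } else if (section == "carbons") {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 3)
        abort(sprintf("malformed carbon line: '%s' (need index h_ppm c_ppm)",
                      ln), "nmrmetab_schema_error")
      num <- function(v) if (v == "-") NA_real_ else {
        x <- suppressWarnings(as.numeric(v))
        if (is.na(x)) abort(sprintf("malformed carbon line: '%s'", ln),
                            "nmrmetab_schema_error")
        x
      }
      carbons[[length(carbons) + 1]] <-
        data.frame(carbon = as.integer(f[1]), h_ppm = num(f[2]),
                   c_ppm = num(f[3]))
    } else if (section == "jcc") {
      f <- strsplit(ln, "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(f) != 3 || anyNA(v))
        abort(sprintf("malformed jcc line: '%s' (need i j value_hz)", ln),
              "nmrmetab_schema_error")
      jcc[[length(jcc) + 1]] <- data.frame(i = v[1], j = v[2], hz = v[3])
    }
  }
  miss <- c(if (is.null(name)) "metabolite/name",
            if (length(carbons) == 0) "carbons")
  if (length(miss) > 0)
    abort(sprintf("%s lacks mandatory key(s): %s", basename(path),
                  paste(miss, collapse = ", ")), "nmrmetab_schema_error")
  metabolite_entry(name, do.call(rbind, carbons),
                   if (length(jcc) > 0) do.call(rbind, jcc) else NULL)
}

#' Build the multiplet model of one carbon
#'
#' Enumerates the multiplet components an HSQC carbon signal can show,
#' one per labelling pattern of its coupled neighbours: no labelled
#' neighbour gives a singlet (`s`), one labelled neighbour a doublet
#' (`d1`/`d2`, split by that JCC), two labelled neighbours a doublet of
#' doublets (`dd`).  Stick weights are uniform within a component.
#'
#' @param entry A [metabolite_entry].
#' @param carbon Carbon index; must be observable (protonated with
#'   shifts).
#' @param linewidth_hz Initial linewidth carried by the model.
#' @return An object of class `multiplet_model` with `components`, each
#'   holding `label`, `positions_hz` (relative to the multiplet centre)
#'   and `weights`.
#' @export
build_multiplet_model <- function(entry, carbon, linewidth_hz = 2) {
  if (!carbon_observable(entry, carbon))
    abort_input(sprintf("carbon %d of %s is not observable", carbon,
                        entry$name))
  nb <- coupled_neighbors(entry, carbon)
  comps <- list(list(label = "s", positions_hz = 0, weights = 1))
  if (nrow(nb) >= 1) {
    j1 <- nb$hz[1]
    comps <- c(comps, list(list(label = "d1",
                                positions_hz = c(-j1 / 2, j1 / 2),
                                weights = c(0.5, 0.5))))
  }
  if (nrow(nb) >= 2) {
    j1 <- nb$hz[1]; j2 <- nb$hz[2]
    comps <- c(comps, list(
      list(label = "d2", positions_hz = c(-j2 / 2, j2 / 2),
           weights = c(0.5, 0.5)),
      list(label = "dd",
           positions_hz = c(-j1 / 2 - j2 / 2, -j1 / 2 + j2 / 2,
                            j1 / 2 - j2 / 2, j1 / 2 + j2 / 2),
           weights = rep(0.25, 4))))
  }
  if (nrow(nb) > 2)
    abort_input("more than two coupled neighbours is not supported")
  structure(list(carbon_index = carbon, components = comps,
                 linewidth_hz = linewidth_hz, center_hz = 0,
                 neighbors = nb$neighbor),
            class = "multiplet_model")
}

lorentzian <- function(x, x0, fwhm) {
  hw <- fwhm / 2
  (hw / pi) / ((x - x0)^2 + hw^2)
}

model_sticks <- function(model) {
  do.call(rbind, lapply(model$components, function(cp)
    data.frame(label = cp$label, position_hz = cp$positions_hz,
               weight = cp$weights)))
}

#' Automatic peak picking of a multiplet trace
#'
#' For every stick of the model, searches for a local maximum within
#' `max(0.25 * J_min, 2 points)` of its predicted position and updates
#' the model centre to the weighted mean displacement of the successful
#' picks.  Failure on more than half of the sticks raises a pick error
#' (which downstream maps to a red quality flag).
#'
#' @param hz Hz axis of the trace (ascending).
#' @param intensity Real trace values.
#' @param model A [multiplet_model].
#' @return List with `picked` (data frame of stick label, predicted and
#'   picked positions) and `model` (centre-updated copy).
#' @export
autopick_peaks <- function(hz, intensity, model) {
  sticks <- model_sticks(model)
  dx <- hz[2] - hz[1]
  spans <- vapply(model$components, function(cp)
    diff(range(cp$positions_hz)), numeric(1))
  jmin <- suppressWarnings(min(spans[spans > 0]))
  if (!is.finite(jmin)) jmin <- 8 * dx
  tol <- max(0.25 * jmin, 2 * dx)
  n <- length(hz)
  picked <- numeric(nrow(sticks))
  okv <- logical(nrow(sticks))
  for (s in seq_len(nrow(sticks))) {
    p <- model$center_hz + sticks$position_hz[s]
    win <- which(hz >= p - tol & hz <= p + tol)
    win <- win[win > 1 & win < n]
    if (length(win) == 0) next
    loc <- win[intensity[win] > intensity[win - 1] &
               intensity[win] >= intensity[win + 1]]
    if (length(loc) == 0) next
    best <- loc[which.max(intensity[loc])]
    picked[s] <- hz[best]
    okv[s] <- TRUE
  }
  if (sum(okv) <= nrow(sticks) / 2)
    abort(sprintf("peak picking failed for %d of %d sticks",
                  sum(!okv), nrow(sticks)), "nmrmetab_pick_error")
  disp <- picked[okv] - (model$center_hz + sticks$position_hz[okv])
  w <- sticks$weight[okv]
  model$center_hz <- model$center_hz + sum(w * disp) / sum(w)
  list(picked = data.frame(label = sticks$label,
                           predicted_hz = model$center_hz +
                             sticks$position_hz,
                           picked_hz = ifelse(okv, picked, NA_real_)),
       model = model)
}

#' Fit a multiplet line shape and component fractions
#'
#' Nonlinear least squares of the trace against a sum of multiplet
#' components rendered as unit-area Lorentzian sticks with a shared
#' linewidth and a common centre offset.  Component amplitudes are
#' constrained non-negative (inner Lawson-Hanson NNLS); linewidth and
#' centre are profiled by bounded quasi-Newton optimization.  Fractions
#' are the normalized component amplitudes; the coefficient of
#' determination `r2 = 1 - RSS/TSS` over the fitted window is clamped to
#' `[0, 1]` and mapped to a traffic-light quality flag.
#'
#' @param hz Hz axis (ascending).
#' @param intensity Real trace values.
#' @param model A [multiplet_model] (centre ideally updated by
#'   [autopick_peaks()]).
#' @return An object of class `multiplet_fit`: `fractions`, `r2`,
#'   `fitted_linewidth_hz`, `fitted_center_hz`, `flag`, `converged`.
#' @export
fit_multiplet <- function(hz, intensity, model) {
  labels <- vapply(model$components, `[[`, character(1), "label")
  design <- function(lw, ctr) {
    vapply(model$components, function(cp) {
      y <- numeric(length(hz))
      for (s in seq_along(cp$positions_hz))
        y <- y + cp$weights[s] * lorentzian(hz, ctr + cp$positions_hz[s], lw)
      y
    }, numeric(length(hz)))
  }
  rss_of <- function(par) {
    A <- design(exp(par[1]), par[2])
    a <- nnls_fit(A, intensity)
    sum((intensity - A %*% a)^2)
  }
  span <- diff(range(hz))
  start <- c(log(model$linewidth_hz), model$center_hz)
  run_opt <- function(p0) tryCatch(
    stats::optim(p0, rss_of, method = "L-BFGS-B",
                 lower = c(log(span * 1e-4), model$center_hz - span / 4),
                 upper = c(log(span), model$center_hz + span / 4),
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL)
  fit <- run_opt(start)
  converged <- !is.null(fit) && fit$convergence == 0
  if (!is.null(fit) && fit$convergence != 0) {
    # one restart from the best iterate; a stationary value (e.g. an
    # "abnormal line search" at an RSS of numerically zero) counts as
    # converged
    refit <- run_opt(fit$par)
    if (!is.null(refit)) {
      converged <- refit$convergence == 0 ||
        refit$value >= fit$value * (1 - 1e-8)
      if (refit$value <= fit$value) fit <- refit
    }
  }
  if (is.null(fit)) fit <- list(par = start, value = rss_of(start))
  lw <- exp(fit$par[1]); ctr <- fit$par[2]
  A <- design(lw, ctr)
  a <- nnls_fit(A, intensity)
  total <- sum(a)
  fractions <- if (total > 0) a / total else rep(1 / length(a), length(a))
  names(fractions) <- labels
  # r2 over the fitted window: the multiplet region (sticks +/- 5
  # linewidths), not whatever extra baseline the caller supplied
  pos <- ctr + unlist(lapply(model$components, `[[`, "positions_hz"))
  win <- hz >= min(pos) - 5 * lw & hz <= max(pos) + 5 * lw
  if (!any(win)) win <- rep(TRUE, length(hz))
  resid <- intensity - drop(A %*% a)
  rss <- sum(resid[win]^2)
  tss <- sum((intensity[win] - mean(intensity[win]))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  flag <- if (total == 0 || !converged) "red" else quality_flag(r2)
  structure(list(fractions = fractions, r2 = r2,
                 fitted_linewidth_hz = lw, fitted_center_hz = ctr,
                 flag = flag, converged = converged),
            class = "multiplet_fit")
}

#' @export
print.multiplet_fit <- function(x, ...) {
  cat(sprintf("<multiplet_fit> r2 = %.4f [%s]; fractions: %s\n", x$r2,
              x$flag, paste(sprintf("%s=%.3f", names(x$fractions),
                                    x$fractions), collapse = ", ")))
  invisible(x)
}

#' Traffic-light quality flag from a coefficient of determination
#'
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param green Threshold at or above which the analysis is good.
#' @param amber Threshold at or above which it is uncertain; below is an
#'   unsuccessful analysis.
#' @return `"green"`, `"amber"` or `"red"`.
#' @export
quality_flag <- function(r2, green = 0.90, amber = 0.50) {
  if (!is_number(r2) || r2 < 0 || r2 > 1)
    abort_input("r2 must be in [0, 1]")
  if (r2 >= green) "green" else if (r2 >= amber) "amber" else "red"
}
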