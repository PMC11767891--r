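#' Enumerate the binary isotopomer labels of an n-carbon metabolite
#'
#' An isotopomer is one specific 12C/13C pattern over the carbon
#' positions; an n-carbon metabolite has `2^n` of them.  Labels are
#' binary strings with carbon 1 leftmost (`"011"` = carbons 2 and 3
#' labelled), in lexicographic order.
#'
#' @param n Number of carbons, `1 <= n <= 12`.
#' @return Character vector of `2^n` labels.
#' @export
enumerate_isotopomers <- function(n) {
  if (!is_number(n) || n < 1 || n > 12)
    abort_input("n must be an integer in [1, 12]")
  n <- as.integer(n)
  vapply(0:(2^n - 1), function(k)
    paste(rev(as.integer(intToBits(k)[1:n])), collapse = ""), character(1))
}

label_bits <- function(labels) {
  t(vapply(strsplit(labels, ""), function(ch) as.integer(ch),
           integer(nchar(labels[1]))))
}

#' Isotopomer distribution
#'
#' @param x Named numeric vector: fractions by binary label (absent
#'   labels are 0).  Must be non-negative and sum to 1.
#' @param n_carbons Number of carbons; inferred from the label width if
#'   missing.
#' @return An object of class `isotopomer_distribution` holding the full
#'   `2^n` vector.
#' @export
isotopomer_distribution <- function(x, n_carbons = NULL) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    abort_input("x must be named by binary labels")
  if (is.null(n_carbons)) n_carbons <- nchar(names(x)[1])
  labels <- enumerate_isotopomers(n_carbons)
  if (!all(names(x) %in% labels))
    abort_input("labels must be binary strings of the stated width")
  full <- stats::setNames(numeric(length(labels)), labels)
  full[names(x)] <- x
  if (any(full < -1e-12)) abort_input("fractions must be >= 0")
  full <- pmax(full, 0)
  if (abs(sum(full) - 1) > 1e-9)
    abort_input(sprintf("fractions must sum to 1 (got %.12g)", sum(full)))
  structure(list(n_carbons = as.integer(n_carbons), x = full),
            class = "isotopomer_distribution")
}

#' @export
print.isotopomer_distribution <- function(x, ...) {
  nz <- x$x[x$x > 0]
  cat(sprintf("<isotopomer_distribution> %d carbons: %s\n", x$n_carbons,
              paste(sprintf("%s=%.4g", names(nz), nz), collapse = ", ")))
  invisible(x)
}

#' Mass isotopologue distribution (MID)
#'
#' GC-MS measures the fractions `M0..Mn` of molecules carrying 0..n
#' heavy carbons (no positional information).
#'
#' @param m Numeric vector `M0..Mn`; non-negative, summing to 1.
#' @return An object of class `mid`.
#' @export
mid <- function(m) {
  if (any(m < -1e-12)) abort_input("MID fractions must be >= 0")
  m <- pmax(as.numeric(m), 0)
  if (abs(sum(m) - 1) > 1e-9)
    abort_input("MID fractions must sum to 1")
  structure(list(m = m), class = "mid")
}

#' Forward map: isotopomer distribution to MID
#'
#' `M_k` is the total fraction of isotopomers with exactly k labelled
#' carbons.
#'
#' @param x An [isotopomer_distribution].
#' @return A [mid] of length `n_carbons + 1`.
#' @export
forward_mid <- function(x) {
  stopifnot(inherits(x, "isotopomer_distribution"))
  k <- rowSums(label_bits(names(x$x)))
  m <- vapply(0:x$n_carbons, function(j) sum(x$x[k == j]), numeric(1))
  mid(m)
}

#' Forward map: isotopomer distribution to HSQC multiplet fractions
#'
#' NMR sees only the 13C-labelled molecules of a carbon, split by the
#' labelling pattern of its coupled neighbours.  The fraction of
#' component `c` is the probability of that neighbour pattern
#' conditional on the carbon being labelled.
#'
#' @param x An [isotopomer_distribution].
#' @param entry A [metabolite_entry].
#' @param carbon Carbon index (observable).
#' @return Named numeric vector of component fractions (summing to 1).
#' @export
forward_multiplet <- function(x, entry, carbon) {
  stopifnot(inherits(x, "isotopomer_distribution"))
  if (!carbon_observable(entry, carbon))
    abort_input(sprintf("carbon %d is not observable", carbon))
  bits <- label_bits(names(x$x))
  sel <- bits[, carbon] == 1
  p_lab <- sum(x$x[sel])
  if (p_lab <= 0)
    abort(sprintf("carbon %d is never labelled under x: multiplet undefined",
                  carbon), "nmrmetab_observation_error")
  nb <- coupled_neighbors(entry, carbon)$neighbor
  comp_of <- function(b) {
    if (length(nb) == 0) return("s")
    l1 <- b[nb[1]] == 1
    l2 <- length(nb) >= 2 && b[nb[2]] == 1
    if (l1 && l2) "dd" else if (l1) "d1" else if (l2) "d2" else "s"
  }
  comps <- apply(bits, 1, comp_of)
  out <- tapply(x$x[sel], comps[sel], sum) / p_lab
  labs <- if (length(nb) == 0) "s"
          else if (length(nb) == 1) c("s", "d1")
          else c("s", "d1", "d2", "dd")
  full <- stats::setNames(numeric(length(labs)), labs)
  full[names(out)] <- out
  full
}

#' Observations for isotopomer fitting
#'
#' @param multiplets Named list: one element per observed carbon (name =
#'   carbon index), each a named component-fraction vector summing to 1
#'   (e.g. from [fit_multiplet()]).
#' @param mid_obs A [mid] (GC-MS mass isotopologue distribution), or
#'   `NULL`.
#' @param weights Optional per-observation precision weights: a list
#'   with elements `mid` (scalar) and `multiplets` (scalar or per
#'   carbon).  Defaults to equal weights.
#' @return An object of class `tracer_observations`.
#' @export
tracer_observations <- function(multiplets = list(), mid_obs = NULL,
                                weights = NULL) {
  for (m in multiplets) {
    if (abs(sum(m) - 1) > 1e-6)
      abort_input("each multiplet component map must sum to 1")
  }
  if (!is.null(mid_obs)) stopifnot(inherits(mid_obs, "mid"))
  if (is.null(weights)) weights <- list(mid = 1, multiplets = 1)
  if (any(unlist(weights) <= 0)) abort_input("weights must be > 0")
  structure(list(multiplets = multiplets, mid = mid_obs,
                 weights = weights),
            class = "tracer_observations")
}

# Count of *independent* observations: each block (the MID, one
# carbon's component fractions) sums to 1, so it carries length - 1
# independent values.
n_observations <- function(obs) {
  n <- 0L
  if (!is.null(obs$mid)) n <- n + length(obs$mid$m) - 1L
  for (m in obs$multiplets) n <- n + length(m) - 1L
  n
}

# Build a weighted residual function of the full isotopomer vector
# (2^n).  Multiplet fractions are conditional ratios; their residuals
# are cross-multiplied (pred_numerator - obs_fraction *
# pred_denominator) to keep the objective polynomial in x.  All label
# pattern matching is precomputed into indicator matrices so the
# returned closure is cheap.
make_tracer_residuals <- function(bits, obs, entry) {
  blocks <- list()
  if (!is.null(obs$mid)) {
    k <- rowSums(bits)
    P <- t(vapply(0:ncol(bits), function(j) as.numeric(k == j),
                  numeric(nrow(bits))))
    blocks[[length(blocks) + 1]] <- local({
      P_ <- P; w_ <- sqrt(obs$weights$mid); t_ <- obs$mid$m
      function(x) w_ * (drop(P_ %*% x) - t_)
    })
  }
  wmult <- sqrt(obs$weights$multiplets)
  for (cn in names(obs$multiplets)) {
    carbon <- as.integer(cn)
    target <- obs$multiplets[[cn]]
    sel <- as.numeric(bits[, carbon] == 1)
    nb <- coupled_neighbors(entry, carbon)$neighbor
    l1 <- if (length(nb) >= 1) bits[, nb[1]] == 1 else rep(FALSE, nrow(bits))
    l2 <- if (length(nb) >= 2) bits[, nb[2]] == 1 else rep(FALSE, nrow(bits))
    M <- vapply(names(target), function(lab) {
      pat <- switch(lab, s = !l1 & !l2, d1 = l1 & !l2,
                    d2 = !l1 & l2, dd = l1 & l2, rep(FALSE, nrow(bits)))
      as.numeric(pat) * sel
    }, numeric(nrow(bits)))
    tv <- as.numeric(target)
    blocks[[length(blocks) + 1]] <- local({
      M_ <- M; sel_ <- sel; tv_ <- tv; w_ <- wmult
      function(x) w_ * (drop(crossprod(M_, x)) - tv_ * sum(x * sel_))
    })
  }
  function(x) unlist(lapply(blocks, function(f) f(x)), use.names = FALSE)
}

#' Fit an isotopomer distribution to tracer observations
#'
#' Weighted constrained least squares of the forward-model predictions
#' (MID via [forward_mid()]-equivalent sums, multiplet fractions via
#' cross-multiplied ratio residuals) against the observations, subject
#' to `x >= 0`, `sum(x) = 1`, and `x = 0` outside the user-selected
#' subset.  Because the number of independent observations is generally
#' smaller than the number of isotopomers, the subset pre-selection is
#' essential; the diagnostics report the degrees of freedom
#' `n_obs - |subset| + 1` and warn when they are non-positive
#' (underdetermined fit).
#'
#' The simplex constraint is enforced by a softmax parameterization and
#' the non-convex objective is multi-started from Dirichlet-random
#' initial points (fixed internal seed), keeping the result
#' deterministic.
#'
#' @param obs A [tracer_observations].
#' @param entry A [metabolite_entry].
#' @param subset Character vector of binary labels allowed to be
#'   non-zero.
#' @param n_starts Number of random multi-starts.
#' @return List with `distribution` (an [isotopomer_distribution]),
#'   `residual` (weighted RSS at the optimum) and `diagnostics`
#'   (`n_obs`, `dof`, `underdetermined`, `converged`).
#' @export
fit_isotopomers <- function(obs, entry, subset, n_starts = 5) {
  stopifnot(inherits(obs, "tracer_observations"))
  if (length(subset) == 0) abort_input("subset must be non-empty")
  labels <- enumerate_isotopomers(entry$n_carbons)
  if (!all(subset %in% labels))
    abort_input("subset contains labels outside the isotopomer space")
  subset <- unique(subset)
  bits <- label_bits(labels)
  idx <- match(subset, labels)
  nobs <- n_observations(obs)
  dof <- nobs - length(subset) + 1L
  if (dof <= 0)
    warning(sprintf(
      "underdetermined fit: %d observations for %d isotopomers (dof = %d)",
      nobs, length(subset), dof))
  resid_fn <- make_tracer_residuals(bits, obs, entry)
  objective <- function(theta) {
    e <- exp(c(0, theta))
    xs <- e / sum(e)
    xfull <- numeric(length(labels))
    xfull[idx] <- xs
    sum(resid_fn(xfull)^2)
  }
  k <- length(subset)
  if (k == 1) {
    xfull <- stats::setNames(numeric(length(labels)), labels)
    xfull[idx] <- 1
    rss <- sum(make_tracer_residuals(bits, obs, entry)(xfull)^2)
    return(list(distribution = isotopomer_distribution(xfull),
                residual = rss,
                diagnostics = list(n_obs = nobs, dof = dof,
                                   underdetermined = dof <= 0,
                                   converged = TRUE)))
  }
  starts <- with_seed(1234L, {
    s <- matrix(stats::rgamma(n_starts * k, shape = 1), n_starts, k)
    s / rowSums(s)
  })
  starts[1, ] <- rep(1 / k, k)   # deterministic uniform start first
  best <- NULL
  for (r in seq_len(n_starts)) {
    th0 <- log(pmax(starts[r, -1], 1e-8) / pmax(starts[r, 1], 1e-8))
    fit <- tryCatch(
      stats::optim(th0, objective, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    abort("isotopomer fit failed to converge from any start",
          "nmrmetab_fit_error")
  e <- exp(c(0, best$par))
  xs <- e / sum(e)
  xfull <- stats::setNames(numeric(length(labels)), labels)
  xfull[idx] <- xs
  list(distribution = isotopomer_distribution(xfull),
       residual = best$value,
       diagnostics = list(n_obs = nobs, dof = dof,
                          underdetermined = dof <= 0,
                          converged = best$convergence == 0))
}
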