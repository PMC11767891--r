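# Internal helpers shared across modules.

# Classed error constructors so callers can distinguish user/input errors,
# file-format errors and configuration errors programmatically.
abort <- function(msg, class) {
  stop(structure(class = c(class, "nmrmetab_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
abort_input  <- function(msg) abort(msg, "nmrmetab_input_error")
abort_format <- function(msg) abort(msg, "nmrmetab_format_error")
abort_config <- function(msg) abort(msg, "nmrmetab_config_error")

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  All stochastic generators in the package go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Indices of axis points falling in a ppm interval [lo, hi): closed at the
# low-ppm end, open at the high-ppm end (axis is stored descending).
ppm_indices <- function(ppm_axis, lo, hi) {
  if (!is_number(lo) || !is_number(hi) || lo >= hi)
    abort_input(sprintf("malformed ppm interval [%s, %s]: need lo < hi",
                        format(lo), format(hi)))
  which(ppm_axis >= lo & ppm_axis < hi)
}

# Powell's conjugate direction minimiser (derivative-free).  Line searches
# scan `n_scan` points over a fixed bracket around the current point and
# refine the best with golden-section between its neighbours (robust when
# the objective has |.| kinks); after each cycle the direction of largest
# single-direction decrease is replaced by the overall displacement
# direction.
powell_minimize <- function(fn, par, xtol = 1e-4, ftol = 1e-6,
                            maxit = 200, bracket = 90, n_scan = 25) {
  n <- length(par)
  line_min <- function(g, b) {
    a <- seq(-b, b, length.out = n_scan)
    v <- vapply(a, g, numeric(1))
    k <- which.min(v)
    lo <- a[max(1, k - 1)]; hi <- a[min(n_scan, k + 1)]
    ls <- stats::optimize(g, interval = c(lo, hi), tol = xtol / 10)
    if (ls$objective <= v[k]) ls else list(minimum = a[k], objective = v[k])
  }
  dirs <- diag(n)
  f <- fn(par)
  b <- bracket
  for (iter in seq_len(maxit)) {
    p0 <- par
    f0 <- f
    biggest <- 0
    ibig <- 1L
    for (i in seq_len(n)) {
      d <- dirs[, i]
      ls <- line_min(function(a) fn(par + a * d), b)
      if (ls$objective < f) {
        if (f - ls$objective > biggest) {
          biggest <- f - ls$objective
          ibig <- i
        }
        f <- ls$objective
        par <- par + ls$minimum * d
      }
    }
    d <- par - p0
    step <- sqrt(sum(d^2))
    if (step > xtol / 2) {
      ls <- line_min(function(a) fn(par + a * d), 1.5)
      if (ls$objective < f) {
        f <- ls$objective
        par <- par + ls$minimum * d
        dirs[, ibig] <- d / step
      }
    }
    # shrink the scan bracket as the iterate settles
    b <- max(min(b, 4 * max(step, xtol)), 100 * xtol)
    if (2 * abs(f0 - f) <= ftol * (abs(f0) + abs(f) + 1e-30) &&
        max(abs(par - p0)) <= xtol) break
  }
  list(par = par, value = f, iterations = iter)
}

# Centred running mean with edge renormalization (window w, odd).
runmean <- function(x, w) {
  n <- length(x)
  w <- min(w, if (n %% 2 == 1) n else n - 1)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Lawson-Hanson non-negative least squares: minimise ||A x - b||, x >= 0.
nnls_fit <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  it <- 0L
  while (any(!passive) && any(w[!passive] > tol) && it < 30L * n) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      if (!any(passive)) { z <- numeric(n); break }
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}
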