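# Brute-force oracles, independent of the package implementation: label
# popcounts via string matching, neighbour patterns read off per label.
oracle_mid <- function(x) {
  ones <- vapply(names(x$x), function(l)
    sum(gregexpr("1", l, fixed = TRUE)[[1]] > 0), numeric(1))
  vapply(0:x$n_carbons, function(k) sum(x$x[ones == k]), numeric(1))
}

oracle_multiplet <- function(x, nb, carbon) {
  out <- c(s = 0, d1 = 0, d2 = 0, dd = 0)
  den <- 0
  for (l in names(x$x)) {
    b <- as.integer(strsplit(l, "")[[1]])
    if (b[carbon] != 1) next
    den <- den + x$x[[l]]
    l1 <- length(nb) >= 1 && b[nb[1]] == 1
    l2 <- length(nb) >= 2 && b[nb[2]] == 1
    key <- if (l1 && l2) "dd" else if (l1) "d1" else if (l2) "d2" else "s"
    out[key] <- out[key] + x$x[[l]]
  }
  out / den
}

rand_dist <- function(n, seed) {
  labels <- enumerate_isotopomers(n)
  w <- withr::with_seed(seed, stats::rgamma(length(labels), 1))
  isotopomer_distribution(stats::setNames(w / sum(w), labels))
}
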