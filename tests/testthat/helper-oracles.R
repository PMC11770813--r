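# Independent oracles, deliberately implemented by different routes than the
# package (exhaustive enumeration instead of polynomial convolution; direct
# interval summation / pracma::trapz instead of the package trapezoid).

# all compositions of n identical atoms into m isotope slots
compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1, 1))
  out <- NULL
  for (k in 0:n) {
    sub <- compositions(n - k, m - 1L)
    out <- rbind(out, cbind(k, sub))
  }
  unname(out)
}

# brute-force isotopologue mass-shift distribution of a formula: enumerate
# every isotope combination of every element, multiply multinomial
# probabilities, accumulate by total shift
oracle_isotopologue_dist <- function(counts, abundances, max_shift) {
  per_el <- list()
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    p <- abundances[[el]]
    m <- length(p)
    if (m == 1L) { per_el[[el]] <- c(shift = 0, prob = 1); next }
    comb <- compositions(n, m)
    shifts <- as.numeric(comb %*% (seq_len(m) - 1L))
    probs <- apply(comb, 1, function(k) stats::dmultinom(k, prob = p))
    agg <- tapply(probs, shifts, sum)
    per_el[[el]] <- cbind(shift = as.numeric(names(agg)), prob = as.numeric(agg))
  }
  dist <- c(1)  # indexed by shift+1
  for (el in names(per_el)) {
    tab <- per_el[[el]]
    if (is.null(dim(tab))) next
    new <- numeric(length(dist) + max(tab[, "shift"]))
    for (r in seq_len(nrow(tab)))
      for (s in seq_along(dist))
        new[s + tab[r, "shift"]] <- new[s + tab[r, "shift"]] +
          dist[s] * tab[r, "prob"]
    dist <- new
  }
  out <- numeric(max_shift + 1L)
  keep <- seq_len(min(length(dist), max_shift + 1L))
  out[keep] <- dist[keep]
  out
}

# oracle for a species with `nlab` labelled hydrogens at purity `pur`:
# enumerate the retained-label count, convolve with the enumerated natural
# distribution of the remaining atoms
oracle_labeled_dist <- function(counts, abundances, nlab, pur, max_shift) {
  counts[["H"]] <- counts[["H"]] - nlab
  nat <- oracle_isotopologue_dist(counts, abundances, max_shift)
  out <- numeric(max_shift + 1L)
  for (b in 0:nlab) {
    w <- choose(nlab, b) * pur^b * (1 - pur)^(nlab - b)
    for (s in 0:(max_shift - b))
      out[s + b + 1L] <- out[s + b + 1L] + w * nat[s + 1L]
  }
  out
}

# one-line independent trapezoid
oracle_trapz <- function(t, y) sum((diff(t)) * (y[-length(y)] + y[-1]) / 2)
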