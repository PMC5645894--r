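# Independent reference implementations used as test oracles. These stay
# deliberately naive and share no code with the package internals.

# Exact-rational evaluation of the overlap tail probability. Every factorial
# is represented by its prime-factorization exponent vector (Legendre's
# formula), each term collapses to a product of integer prime powers, and
# floating point enters only in the final per-term product. Practical for
# n up to a few hundred.
oracle_overlap_tail <- function(n, x, y, c) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97)
  primes <- primes[primes <= max(n, 2)]
  # fe[m + 1, ] = exponent vector of m!
  fe <- matrix(0, n + 1, length(primes))
  for (m in seq_len(n)) {
    e <- vapply(primes, function(p) {
      tot <- 0; q <- p
      while (q <= m) { tot <- tot + m %/% q; q <- q * p }
      tot
    }, numeric(1))
    fe[m + 1, ] <- e
  }
  is <- seq.int(c, min(x, y))
  is <- is[is >= x + y - n]  # factorial arguments must be nonnegative
  if (!length(is)) return(0)
  terms <- vapply(is, function(i) {
    e <- fe[x + 1, ] + fe[y + 1, ] + fe[n - x + 1, ] + fe[n - y + 1, ] -
      fe[n + 1, ] - fe[i + 1, ] - fe[x - i + 1, ] - fe[y - i + 1, ] -
      fe[n + i - x - y + 1, ]
    prod(primes^e)
  }, numeric(1))
  sum(terms)
}

# Whole-genome brute-force stratification: concatenate every base of every
# scaffold, sort the full vector by depth (stable), cut into the geometric
# rank groups, and report per-group aligned-base shares and mean BPKM.
oracle_stratify <- function(track) {
  scafs <- track$scaffolds[order(names(track$scaffolds))]
  depth <- unlist(scafs, use.names = FALSE)
  total <- sum(depth)
  sorted <- sort(depth, decreasing = TRUE, method = "radix")
  n <- length(sorted)
  bounds <- 400 * 2^(0:18)
  los <- c(0, bounds[-19])
  share <- mean_bpkm <- numeric(19)
  for (g in 1:19) {
    lo <- min(los[g], n); hi <- min(bounds[g], n)
    if (hi <= lo) next
    mass <- sum(sorted[(lo + 1):hi])
    share[g] <- mass / total
    mean_bpkm[g] <- mass * 1e9 / total / (hi - lo)
  }
  list(share = share, mean_bpkm = mean_bpkm,
       remainder = 1 - sum(share))
}

# A small deterministic FPKM fixture shared across expression tests.
toy_fpkm <- function() {
  vals <- rbind(
    g_low   = c(0.2, 0.9, 0.8, 0.5),
    g_flat  = c(5, 5, 5, 5),
    g_spike = c(200, 2, 3, 1),
    g_mid   = c(40, 120, 30, 20),
    g_zero  = c(0, 0, 0, 0)
  )
  colnames(vals) <- paste0("lib", 1:4)
  fpkm_matrix(vals)
}
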