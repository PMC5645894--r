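# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) without overflow/underflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-row standardization shared by the expression and coverage modules.
# ddof = 1 is the sample standard deviation; rows with zero spread map to 0.
row_zscores <- function(mat, ddof = 1) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  mu <- rowMeans(mat)
  centered <- mat - mu
  ss <- rowSums(centered^2)
  s <- sqrt(ss / (n - ddof))
  z <- centered / s
  z[s == 0 | !is.finite(s), ] <- 0
  list(z = z, mean = mu, sd = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
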