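# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_normalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(rep(0, length(x)))
  out <- numeric(length(x))
  for (j in seq_along(x)) out[j] <- 2 * (x[j] - lo) / (hi - lo) - 1
  out
}

# level-1 periodized DWT by explicit convolution with modulo indexing
oracle_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
)

oracle_dwt <- function(x, basis = "haar") {
  h <- oracle_filters[[basis]]
  L <- length(h)
  g <- numeric(L)
  for (n in seq_len(L)) g[n] <- (-1)^(n - 1) * h[L - n + 1]
  N <- length(x)
  a <- d <- numeric(N / 2)
  for (k in seq_len(N / 2)) {
    for (n in seq_len(L)) {
      pos <- (2 * (k - 1) + n - 1) %% N + 1
      a[k] <- a[k] + h[n] * x[pos]
      d[k] <- d[k] + g[n] * x[pos]
    }
  }
  c(a, d)
}

oracle_pearson <- function(u, v) {
  mu <- mean(u); mv <- mean(v)
  su <- sqrt(sum((u - mu)^2) / (length(u) - 1))
  sv <- sqrt(sum((v - mv)^2) / (length(v) - 1))
  if (su == 0 || sv == 0) return(0)
  sum((u - mu) * (v - mv)) / (length(u) - 1) / (su * sv)
}

# whole chain on raw profile matrices (one per condition):
# normalize -> haar -> pearson -> |r| >= tau adjacency -> degrees -> m
oracle_chain <- function(mats, tau = 0.7) {
  res <- lapply(mats, function(M) {
    FV <- t(apply(M, 1, function(x) oracle_dwt(oracle_normalize(x))))
    n <- nrow(FV)
    R <- diag(n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (i != j) R[i, j] <- oracle_pearson(FV[i, ], FV[j, ])
    Lm <- matrix(0L, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (i != j && abs(R[i, j]) >= tau && abs(R[i, j]) <= 1 + 1e-12)
          Lm[i, j] <- 1L
    list(R = R, L = Lm, degrees = rowSums(Lm))
  })
  res$m <- res[[1]]$degrees - res[[2]]$degrees
  res
}

oracle_euclid <- function(x, y) {
  acc <- 0
  for (j in seq_along(x)) acc <- acc + (x[j] - y[j])^2
  sqrt(acc)
}

# random two-condition dataset with given dimensions
random_dataset <- function(np = 6, nt = 12, nr = 1, seed = 1) {
  set.seed(seed)
  vals <- list(LD = array(rnorm(np * nt * nr), c(np, nt, nr)),
               DD = array(rnorm(np * nt * nr), c(np, nt, nr)))
  expression_dataset(vals, probe_ids = sprintf("p%02d", seq_len(np)))
}
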