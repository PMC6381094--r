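## Independent from-definition TMM oracle: explicit loops over the doubly
## trimmed, precision-weighted mean of M-values.
tmm_oracle <- function(m, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(m)
  uq <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    uq[j] <- quantile(m[, j], 0.75, names = FALSE) / lib[j]
  }
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    M <- A <- W <- c()
    for (i in seq_len(nrow(m))) {
      o <- m[i, j]; r <- m[i, ref]
      if (o > 0 && r > 0) {
        M <- c(M, log2((o / lib[j]) / (r / lib[ref])))
        A <- c(A, (log2(o / lib[j]) + log2(r / lib[ref])) / 2)
        W <- c(W, (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA & W > 0
    f[j] <- if (j == ref) 1 else 2^(sum(M[keep] / W[keep]) / sum(1 / W[keep]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

## Random overdispersed count matrix with a spiked final column.
random_count_matrix <- function(n = 200, k = 6, seed = 1, spike_frac = 0.05) {
  set.seed(seed)
  mu <- 10^runif(n, 1, 3)
  m <- matrix(rnbinom(n * k, mu = rep(mu, k), size = 10), n, k,
              dimnames = list(sprintf("b%03d", seq_len(n)),
                              sprintf("s%d", seq_len(k))))
  spiked <- sample(n, round(spike_frac * n))
  m[spiked, k] <- m[spiked, k] * 20
  m
}
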