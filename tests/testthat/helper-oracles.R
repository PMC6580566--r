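# Independent reference implementations used as oracles: written as
# explicit element-wise loops, deliberately sharing no code with the
# package internals.

# Random count matrix with log-normal gene means and NB noise.
rand_counts <- function(ng, ns, mu_meanlog = 4, mu_sdlog = 1.2, phi = 0.2,
                        min_one_positive = TRUE) {
  mu <- exp(rnorm(ng, mu_meanlog, mu_sdlog))
  m <- matrix(rnbinom(ng * ns, mu = rep(mu, ns), size = 1 / phi), nrow = ng,
              dimnames = list(sprintf("g%04d", seq_len(ng)),
                              sprintf("s%02d", seq_len(ns))))
  storage.mode(m) <- "double"
  if (min_one_positive) m[rowSums(m) == 0, 1] <- 1
  m
}

# Average ranks by explicit counting (matches ties.method = "average").
avg_rank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

# Naive trimmed-mean-of-M-values fold factor of sample `obs` against
# reference `ref`: explicit per-gene loop, sort-free trimming via
# counted ranks, inverse-variance weights.
naive_tmm_factor <- function(obs, ref, No, Nr, trim_m = 0.30, trim_a = 0.05) {
  M <- numeric(0); A <- numeric(0); w <- numeric(0)
  for (g in seq_along(obs)) {
    if (obs[g] > 0 && ref[g] > 0) {
      po <- obs[g] / No
      pr <- ref[g] / Nr
      M <- c(M, log2(po / pr))
      A <- c(A, 0.5 * log2(po * pr))
      w <- c(w, 1 / ((No - obs[g]) / (No * obs[g]) +
                       (Nr - ref[g]) / (Nr * ref[g])))
    }
  }
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- avg_rank(M); rA <- avg_rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# Naive TMM scale factors for a whole matrix: reference picked by the
# closest-to-mean upper-quartile fraction, factors f_j * N_j rescaled
# to geometric mean one.
naive_tmm_factors <- function(m) {
  N <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) N[j] <- sum(m[, j])
  frac <- numeric(ncol(m))
  for (j in seq_len(ncol(m)))
    frac[j] <- quantile(m[, j], 0.75, names = FALSE) / N[j]
  r <- which.min(abs(frac - mean(frac)))
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m)))
    f[j] <- if (j == r) 1 else naive_tmm_factor(m[, j], m[, r], N[j], N[r])
  s <- f * N
  s / exp(mean(log(s)))
}

# Brute-force median-of-ratios size factors.
naive_mor_factors <- function(m) {
  keep <- logical(nrow(m))
  gm <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    keep[i] <- all(m[i, ] > 0)
    gm[i] <- prod(m[i, ])^(1 / ncol(m))
  }
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- numeric(0)
    for (i in seq_len(nrow(m)))
      if (keep[i]) ratios <- c(ratios, m[i, j] / gm[i])
    out[j] <- median(ratios)
  }
  out
}

# Brute-force evaluation of the log-ratio bias/variance formulas for
# one gene's values.
naive_bias_var <- function(x) {
  n <- length(x)
  kbar <- sum(x) / n
  lr <- numeric(n)
  for (j in seq_len(n)) lr[j] <- log2(x[j] / kbar)
  bias <- sqrt(sum(lr^2) / n)
  mlr <- sum(lr) / n
  v <- 0
  for (j in seq_len(n)) v <- v + (lr[j] - mlr)^2
  c(bias = bias, variance = v / (n - 1))
}

# Convenience: CV table built directly (for selection tests).
make_cv_table <- function(genes, cv, method = "test") {
  out <- data.frame(gene = genes, mean = 1, sd = cv, cv = cv,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("cv_table", "data.frame")
  out
}
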