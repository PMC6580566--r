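dm <- function(v, genes, samples) {
  matrix(v, nrow = length(genes), dimnames = list(genes, samples))
}

test_that("identical columns give unit factors for every factor method", {
  m <- dm(rep(c(3, 7, 12, 25), 3), paste0("g", 1:4), paste0("s", 1:3))
  for (method in c("tc", "library_size", "uq", "median", "tmm", "deseq")) {
    f <- scaling_factors(m, method)
    expect_equal(as.numeric(f), rep(1, 3), tolerance = 1e-12,
                 label = paste(method, "factors"))
  }
})

test_that("median-of-ratios factors match the hand-worked example and a brute-force oracle", {
  m <- dm(c(2, 4, 8, 4, 8, 16), paste0("g", 1:3), c("s1", "s2"))
  expect_equal(as.numeric(scaling_factors(m, "deseq")),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:10) {
    m <- rand_counts(60, sample(3:8, 1))
    expect_equal(as.numeric(scaling_factors(m, "deseq")), naive_mor_factors(m),
                 tolerance = 1e-12)
  }
})

test_that("upper-quartile factors use type-7 percentiles over all counts", {
  m <- dm(c(1, 2, 3, 4, 2, 4, 6, 8), paste0("g", 1:4), c("c1", "c2"))
  # P75 = (3.25, 6.5) by linear interpolation, mean 4.875
  expect_equal(as.numeric(scaling_factors(m, "uq")), c(3.25, 6.5) / 4.875,
               tolerance = 1e-12)
})

test_that("TMM factors agree with a naive sort-trim-weight oracle to 1e-10", {
  set.seed(22)
  for (ng in c(50, 200, 500)) {
    for (ns in c(3, 8, 12)) {
      m <- rand_counts(ng, ns)
      expect_equal(as.numeric(scaling_factors(m, "tmm")), naive_tmm_factors(m),
                   tolerance = 1e-10,
                   label = sprintf("tmm %dx%d", ng, ns))
    }
  }
})

test_that("TMM fold factors reproduce the published algorithm's implementation", {
  set.seed(23)
  m <- rand_counts(400, 6)
  N <- colSums(m)
  frac <- apply(m, 2, quantile, 0.75, names = FALSE) / N
  r <- which.min(abs(frac - mean(frac)))
  f_mine <- vapply(seq_len(ncol(m)), function(j)
    if (j == r) 1 else
      hkgscout:::.tmm_pair(m[, j], m[, r], N[j], N[r], tmm_params()),
    numeric(1))
  f_edger <- edgeR::calcNormFactors(m, method = "TMM", refColumn = r)
  expect_equal(f_mine / exp(mean(log(f_mine))), unname(f_edger),
               tolerance = 1e-12)
})

test_that("median-of-ratios factors match the DESeq-style reference implementation", {
  set.seed(24)
  m <- rand_counts(300, 8)
  # restrict to an odd number of everywhere-positive genes: with an even
  # count the reference implementation averages the two middle ratios on
  # the log scale, whereas the median-of-ratios definition averages the
  # ratios themselves, so the medians would differ by construction
  m <- m[rowSums(m > 0) == ncol(m), ]
  if (nrow(m) %% 2 == 0) m <- m[-1, ]
  expect_equal(as.numeric(scaling_factors(m, "deseq")),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("quantile normalization maps columns onto the rank-mean reference", {
  m <- dm(c(1, 3, 2, 4), c("a", "b"), c("s1", "s2"))
  q <- quantile_normalize(m)
  expect_equal(unname(q), matrix(c(1.5, 3.5, 1.5, 3.5), 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # tied values receive the mean of the reference over the tied ranks
  mt <- dm(c(5, 5, 2, 4), c("a", "b"), c("s1", "s2"))
  qt <- quantile_normalize(mt)
  expect_equal(unname(qt), matrix(c(4, 4, 3.5, 4.5), 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  # identical columns are a fixed point
  mi <- dm(rep(c(2, 9, 30), 2), paste0("g", 1:3), c("s1", "s2"))
  expect_equal(unname(quantile_normalize(mi)), unname(mi),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("quantile-normalized columns share one multiset of values and equal means", {
  set.seed(25)
  for (i in 1:10) {
    m <- sapply(1:5, function(j) sample(1:100000, 80))  # tie-free columns
    dimnames(m) <- list(paste0("g", 1:80), paste0("s", 1:5))
    storage.mode(m) <- "double"
    q <- quantile_normalize(m)
    ref <- sort(q[, 1])
    for (j in 2:ncol(q))
      expect_equal(sort(q[, j]), ref, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(max(colMeans(q)) - min(colMeans(q)), 0, tolerance = 1e-9)
  }
})

test_that("quantile normalization matches limma on tie-free columns", {
  set.seed(26)
  m <- sapply(1:6, function(j) sample(1:5000, 100))
  dimnames(m) <- list(paste0("g", 1:100), paste0("s", 1:6))
  storage.mode(m) <- "double"
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("RPKM follows depth-then-length scaling", {
  m <- dm(c(10, 0), c("gA", "gB"), "s1")
  lengths <- c(gA = 2000, gB = 500)
  r <- rpkm(m, lengths, lib_sizes = c(s1 = 1e6))
  expect_equal(unname(r[, 1]), c(5, 0), tolerance = 1e-12)

  # doubling the library size halves every value in that column
  r2 <- rpkm(m, lengths, lib_sizes = c(s1 = 2e6))
  expect_equal(unname(r2), unname(r) / 2, tolerance = 1e-12)

  expect_error(rpkm(m, c(gA = 2000)), "gB")
  expect_warning(r3 <- rpkm(m, c(gA = 2000), lib_sizes = c(s1 = 1e6),
                            drop_missing = TRUE), "dropped")
  expect_identical(rownames(r3), "gA")
})

test_that("TPM applies length before depth and conserves a million per column", {
  m <- dm(c(10, 30), c("gA", "gB"), "s1")
  t1 <- tpm(m, c(gA = 2000, gB = 1000))
  expect_equal(unname(t1[, 1]), c(1e6 * 5 / 35, 1e6 * 30 / 35),
               tolerance = 1e-9)

  set.seed(27)
  m <- rand_counts(120, 6)
  lengths <- setNames(sample(200:5000, nrow(m)), rownames(m))
  tt <- tpm(m, lengths)
  expect_equal(unname(colSums(tt)), rep(1e6, 6), tolerance = 1e-6)

  # equal counts and equal lengths spread the million evenly
  me <- dm(rep(7, 8), paste0("g", 1:4), c("s1", "s2"))
  te <- tpm(me, setNames(rep(1000, 4), paste0("g", 1:4)))
  expect_equal(unname(te), matrix(1e6 / 4, 4, 2),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("factor methods recover per-column scale multiples exactly", {
  set.seed(28)
  base <- sample(5:500, 40)
  cj <- c(1, 2, 4, 8)
  m <- outer(base, cj)
  dimnames(m) <- list(paste0("g", 1:40), paste0("s", 1:4))
  for (method in c("tc", "library_size", "uq", "median", "tmm", "deseq")) {
    f <- scaling_factors(m, method)
    expect_equal(as.numeric(f / f[1]), cj, tolerance = 1e-9,
                 label = paste(method, "scale recovery"))
    nm <- apply_scaling(m, f)
    expect_lt(max(abs(nm - nm[, 1])), 1e-6)
  }
})

test_that("all outputs are invariant to gene-row permutation", {
  set.seed(29)
  m <- rand_counts(60, 4)
  lengths <- setNames(sample(500:3000, 60), rownames(m))
  perm <- sample(nrow(m))
  for (method in hkg_norm_methods()) {
    a <- normalize_counts(m, method, lengths = lengths)
    b <- normalize_counts(m[perm, ], method, lengths = lengths)
    expect_equal(b, a[perm, ], ignore_attr = TRUE, tolerance = 1e-10,
                 label = paste(method, "permutation invariance"))
  }
})

test_that("normalize_counts dispatches consistently across the nine labels", {
  set.seed(30)
  m <- rand_counts(50, 4)
  lengths <- setNames(sample(500:3000, 50), rownames(m))

  expect_equal(normalize_counts(m, "tc"),
               apply_scaling(m, scaling_factors(m, "tc")), tolerance = 1e-12)
  expect_error(normalize_counts(m, "rpkm"), "lengths")
  expect_error(normalize_counts(m, "nope"))

  mats <- lapply(hkg_norm_methods(), normalize_counts, m = m,
                 lengths = lengths)
  for (nm in mats) {
    expect_identical(dim(nm), dim(m))
    expect_true(all(is.finite(nm)) && all(nm >= 0))
  }
  expect_setequal(vapply(mats, attr, "", "method"), hkg_norm_methods())
})

test_that("degenerate inputs fail with instructive errors", {
  m <- dm(c(0, 1, 1, 0), c("g1", "g2"), c("s1", "s2"))
  expect_error(scaling_factors(m, "deseq"), "strictly positive")

  mostly_zero <- dm(c(0, 0, 5, 1, 2, 3), paste0("g", 1:3), c("s1", "s2"))
  expect_error(scaling_factors(mostly_zero, "median"), "filter")

  sparse <- dm(c(1, 0, 0, 2), c("g1", "g2"), c("s1", "s2"))
  expect_error(scaling_factors(sparse, "tmm"), "no positive gene")

  expect_error(apply_scaling(m, c(s1 = 1)), "s2")
  expect_error(scaling_factors(m, "tc", lib_sizes = c(s1 = 10)), NA)
  expect_error(scaling_factors(m, "library_size", lib_sizes = c(s1 = 10)),
               "missing sample")
})
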