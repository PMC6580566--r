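test_that("per-gene CV uses the n-1 standard deviation over samples", {
  m <- matrix(c(5, 2, 20, 5, 4, 40), nrow = 3,
              dimnames = list(c("const", "g24", "g2040"), c("s1", "s2")))
  cvt <- gene_cv(m)
  expect_equal(cvt$cv[cvt$gene == "const"], 0)
  expect_equal(cvt$mean[cvt$gene == "g24"], 3)
  expect_equal(cvt$sd[cvt$gene == "g24"], sqrt(2), tolerance = 1e-12)
  expect_equal(cvt$cv[cvt$gene == "g24"], sqrt(2) / 3, tolerance = 1e-12)
  # CV is scale invariant: (20, 40) equals (2, 4)
  expect_equal(cvt$cv[cvt$gene == "g2040"], cvt$cv[cvt$gene == "g24"],
               tolerance = 1e-12)

  expect_error(gene_cv(m[, 1, drop = FALSE]), "2 samples")
})

test_that("zero-mean genes are excluded from the CV table with a note", {
  m <- matrix(c(0, 1, 0, 2), nrow = 2,
              dimnames = list(c("zero", "ok"), c("s1", "s2")))
  expect_message(cvt <- gene_cv(m), "1 gene")
  expect_identical(cvt$gene, "ok")
})

test_that("CV (hence selection) is invariant to a global rescale of factors", {
  set.seed(41)
  m <- rand_counts(100, 6)
  f <- scaling_factors(m, "uq")
  f10 <- f * 10
  attributes(f10) <- attributes(f)
  a <- gene_cv(apply_scaling(m, f))
  b <- gene_cv(apply_scaling(m, f10))
  expect_equal(a$cv, b$cv, tolerance = 1e-12)
})

test_that("selection size is floor(percentile/100 * N) with lexicographic ties", {
  cvt <- make_cv_table(sprintf("G%05d", 1:100), seq(0.01, 1, length.out = 100))
  sel <- select_hkg(cvt, 2)
  expect_identical(nrow(sel), 2L)
  expect_identical(sel$gene, c("G00001", "G00002"))

  # five genes all at CV 0, 40th percentile -> the two smallest IDs
  tie <- make_cv_table(c("E", "C", "A", "D", "B"), rep(0, 5))
  expect_identical(select_hkg(tie, 40)$gene, c("A", "B"))

  expect_error(select_hkg(make_cv_table("A", 0.1), 2), "larger percentile")
  expect_error(select_hkg(cvt, 0), "percentile")
})

test_that("raising the percentile yields a superset of the selection", {
  set.seed(42)
  cvt <- make_cv_table(sprintf("G%04d", 1:500), runif(500))
  prev <- character(0)
  for (p in c(1, 2, 5, 10, 25, 60, 100)) {
    cur <- select_hkg(cvt, p)$gene
    expect_true(all(prev %in% cur), label = sprintf("p=%g superset", p))
    prev <- cur
  }
  expect_length(prev, 500L)
})

test_that("near-proportional columns drive every CV toward zero", {
  set.seed(43)
  base <- sample(10:500, 30)
  m <- outer(base, c(1, 3, 5, 9))
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:4))
  for (method in c("tc", "uq", "median", "tmm", "deseq")) {
    cvt <- gene_cv(normalize_counts(m, method))
    expect_lt(max(cvt$cv), 1e-9)
  }
})

test_that("expression ratios bin against the selection-wide maximum", {
  nm <- matrix(c(100, 3, 50, 100, 3, 50), nrow = 3,
               dimnames = list(c("top", "low", "mid"), c("s1", "s2")))
  attr(nm, "method") <- "tc"
  sel <- data.frame(gene = c("top", "low", "mid"), cv = 0, rank = 1:3)
  rb <- expression_ratios(nm, sel)
  expect_equal(unname(rb$ratios["top"]), 1.0)
  expect_equal(unname(rb$ratios["low"]), 0.03, tolerance = 1e-12)
  expect_identical(
    rb$bins$count[rb$bins$bin == "0.80-1.0"], 1L)
  expect_identical(
    rb$bins$count[rb$bins$bin == "0.01-0.05"], 1L)
  expect_identical(sum(rb$bins$count), 3L)
  expect_equal(sum(rb$bins$percent), 100, tolerance = 1e-9)

  # global-max denominator can only shrink ratios
  nm2 <- rbind(nm, huge = c(1000, 1000))
  rb2 <- expression_ratios(nm2, sel, denominator = "global_max")
  expect_true(all(rb2$ratios <= rb$ratios + 1e-12))
  expect_equal(unname(rb2$ratios["top"]), 0.1, tolerance = 1e-12)

  zero <- matrix(0, 1, 2, dimnames = list("z", c("s1", "s2")))
  expect_error(expression_ratios(zero, "z"), "zero")
})

test_that("consensus is the exact intersection across method selections", {
  sel <- function(genes, method) {
    out <- data.frame(gene = genes, cv = seq_along(genes) / 100,
                      rank = seq_along(genes))
    attr(out, "method") <- method
    class(out) <- c("hkg_selection", "data.frame")
    out
  }
  a <- sel(c("A", "B", "C"), "uq")
  b <- sel(c("B", "C", "D"), "tmm")
  cons <- consensus_hkg(list(a, b))
  expect_setequal(cons$members, c("B", "C"))
  expect_identical(colnames(cons$cv), c("uq", "tmm"))
  expect_lte(length(cons$members), min(nrow(a), nrow(b)))

  # nine identical selections collapse to the selection itself
  nine <- consensus_hkg(rep(list(a), 9))
  expect_identical(nine$members, a$gene)

  expect_warning(empty <- consensus_hkg(list(a, sel(c("X", "Y"), "tpm"))),
                 "empty")
  expect_length(empty$members, 0L)
  expect_error(consensus_hkg(list(a)), "at least 2")
})
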