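# The nine count-normalization schemes, implemented from first
# principles. Factor-based methods (library size, total count, upper
# quartile, median, TMM, median-of-ratios) produce per-sample scaling
# factors that divide each column; quantile, RPKM and TPM transform the
# matrix directly. Percentiles use linear interpolation between order
# statistics (quantile type 7) over all counts of the filtered matrix,
# zeros included.

#' The nine normalization method labels
#'
#' @return Character vector of the labels accepted by
#'   [normalize_counts()]: `"library_size"`, `"tc"` (total count), `"uq"`
#'   (upper quartile), `"median"`, `"quantile"`, `"rpkm"`, `"tpm"`,
#'   `"tmm"`, `"deseq"` (median-of-ratios size factors).
#' @export
hkg_norm_methods <- function() {
  c("library_size", "tc", "uq", "median", "quantile",
    "rpkm", "tpm", "tmm", "deseq")
}

.factor_methods <- c("library_size", "tc", "uq", "median", "tmm", "deseq")

#' TMM trimming and weighting parameters
#'
#' Defaults are the published defaults of the trimmed-mean-of-M-values
#' algorithm: trim the top and bottom 30% of log-ratios (M) and 5% of
#' average log-expression (A), weight the surviving log-ratios by the
#' inverse of their approximate binomial variance, and pick as reference
#' the sample whose upper-quartile-to-total fraction is closest to the
#' mean fraction.
#'
#' @param logratio_trim Fraction of M values trimmed from each tail
#'   (default 0.30).
#' @param abs_expr_trim Fraction of A values trimmed from each tail
#'   (default 0.05).
#' @param weighted Use inverse-asymptotic-variance weights (default
#'   `TRUE`).
#' @param reference_sample Optional sample ID to use as the reference;
#'   by default chosen by the upper-quartile-fraction rule.
#' @return List of class `"tmm_params"`.
#' @export
tmm_params <- function(logratio_trim = 0.30, abs_expr_trim = 0.05,
                       weighted = TRUE, reference_sample = NULL) {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5)
  structure(list(logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim,
                 weighted = isTRUE(weighted),
                 reference_sample = reference_sample),
            class = "tmm_params")
}

# Library sizes used by a method: external totals when supplied, else
# in-matrix column sums.
.lib_sizes <- function(m, lib_sizes = NULL) {
  if (is.null(lib_sizes)) return(colSums(m))
  if (is.null(names(lib_sizes)))
    stop("lib_sizes must be a named vector (sample ID -> total reads)",
         call. = FALSE)
  missing <- setdiff(colnames(m), names(lib_sizes))
  if (length(missing))
    stop("lib_sizes missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ls <- lib_sizes[colnames(m)]
  if (any(!is.finite(ls) | ls <= 0))
    stop("library sizes must be positive and finite", call. = FALSE)
  ls
}

# TMM factor of sample `obs` against reference `ref` (counts), with
# library sizes No, Nr. Returns 2^(weighted trimmed mean of M).
.tmm_pair <- function(obs, ref, No, Nr, p) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("TMM: sample shares no positive gene with the reference sample",
         call. = FALSE)
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / No) / (r / Nr))
  A <- 0.5 * log2((o / No) * (r / Nr))
  n <- length(M)
  loM <- floor(n * p$logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * p$abs_expr_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  use <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(use))
    stop("TMM: no genes left after trimming; matrix too small for the trim fractions",
         call. = FALSE)
  if (p$weighted) {
    v <- (No - o) / (No * o) + (Nr - r) / (Nr * r)  # asymptotic var of M
    w <- 1 / v
  } else {
    w <- rep(1, n)
  }
  2 ^ (sum(w[use] * M[use]) / sum(w[use]))
}

.geomean <- function(x) exp(mean(log(x)))

#' Per-sample scaling factors
#'
#' Computes the scale factor \eqn{s_j} of each sample for a factor-based
#' normalization method. Normalized counts are then `count / s_j` (see
#' [apply_scaling()]).
#'
#' Definitions, with \eqn{P_q(j)} the q-th percentile of sample j's
#' counts over the filtered gene set (linear interpolation, zeros
#' included):
#' \describe{
#'   \item{tc}{column sum divided by the mean column sum.}
#'   \item{library_size}{as `tc` but using externally supplied total
#'     aligned reads when `lib_sizes` is given.}
#'   \item{uq}{\eqn{P_{75}(j)} divided by the mean of the \eqn{P_{75}}.}
#'   \item{median}{\eqn{P_{50}(j)} divided by the mean of the
#'     \eqn{P_{50}}.}
#'   \item{deseq}{median-of-ratios: per sample, the median over genes
#'     (restricted to genes with strictly positive counts in all
#'     samples) of the count divided by the gene's geometric mean across
#'     samples.}
#'   \item{tmm}{trimmed mean of M-values: reference sample = the one
#'     whose P75/column-sum fraction is closest to the mean fraction;
#'     per sample a weighted mean of doubly trimmed log2 expression
#'     ratios against the reference gives a fold factor \eqn{f_j}; the
#'     scale factor is \eqn{f_j N_j} rescaled to geometric mean 1.}
#' }
#'
#' @param m Filtered count matrix (genes x samples, no all-zero genes).
#' @param method One of `"tc"`, `"library_size"`, `"uq"`, `"median"`,
#'   `"tmm"`, `"deseq"`.
#' @param lib_sizes Optional named vector of external library sizes
#'   (total aligned reads per sample); used by `"library_size"` and as
#'   the TMM depth; column sums are used when absent.
#' @param tmm A [tmm_params()] object.
#' @return Named numeric vector of positive factors, one per sample,
#'   with attribute `method`.
#' @examples
#' m <- matrix(c(2, 4, 8, 4, 8, 16), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' scaling_factors(m, "deseq")  # (1/sqrt(2), sqrt(2))
#' @export
scaling_factors <- function(m, method = .factor_methods, lib_sizes = NULL,
                            tmm = tmm_params()) {
  method <- match.arg(method)
  validate_counts(m, min_samples = 2L)
  ns <- ncol(m)
  s <- switch(method,
    tc = {
      cs <- colSums(m)
      cs / mean(cs)
    },
    library_size = {
      N <- .lib_sizes(m, lib_sizes)
      N / mean(N)
    },
    uq = {
      p75 <- apply(m, 2L, stats::quantile, probs = 0.75, names = FALSE)
      if (any(p75 <= 0))
        stop("upper-quartile factor is zero for sample(s) ",
             paste(colnames(m)[p75 <= 0], collapse = ", "),
             "; filter low-count genes first", call. = FALSE)
      p75 / mean(p75)
    },
    median = {
      p50 <- apply(m, 2L, stats::quantile, probs = 0.50, names = FALSE)
      if (any(p50 <= 0))
        stop("median count is zero for sample(s) ",
             paste(colnames(m)[p50 <= 0], collapse = ", "),
             "; filter low-count genes before median normalization",
             call. = FALSE)
      p50 / mean(p50)
    },
    deseq = {
      allpos <- rowSums(m > 0) == ns
      if (!any(allpos))
        stop("median-of-ratios: no gene has strictly positive counts in all samples",
             call. = FALSE)
      gm <- apply(m[allpos, , drop = FALSE], 1L, .geomean)
      apply(m[allpos, , drop = FALSE] / gm, 2L, stats::median)
    },
    tmm = {
      N <- .lib_sizes(m, lib_sizes)
      if (is.null(tmm$reference_sample)) {
        frac <- apply(m, 2L, stats::quantile, probs = 0.75, names = FALSE) / N
        ref_j <- which.min(abs(frac - mean(frac)))
      } else {
        ref_j <- match(tmm$reference_sample, colnames(m))
        if (is.na(ref_j))
          stop("reference_sample '", tmm$reference_sample,
               "' not found among samples", call. = FALSE)
      }
      f <- vapply(seq_len(ns), function(j) {
        if (j == ref_j) return(1)
        .tmm_pair(m[, j], m[, ref_j], N[j], N[ref_j], tmm)
      }, numeric(1L))
      s <- f * N
      s / .geomean(s)
    })
  s <- stats::setNames(as.numeric(s), colnames(m))
  if (any(!is.finite(s) | s <= 0))
    stop("non-positive scaling factor computed for sample(s) ",
         paste(names(s)[!is.finite(s) | s <= 0], collapse = ", "),
         call. = FALSE)
  attr(s, "method") <- method
  s
}

#' Divide each sample by its scaling factor
#'
#' @param m Count matrix.
#' @param f Named factor vector from [scaling_factors()], covering every
#'   sample of `m`.
#' @return Normalized numeric matrix with a `method` attribute.
#' @export
apply_scaling <- function(m, f) {
  validate_counts(m)
  missing <- setdiff(colnames(m), names(f))
  if (length(missing))
    stop("scaling factors missing for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- sweep(m, 2L, f[colnames(m)], "/")
  attr(out, "method") <- attr(f, "method") %||% "scaled"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile normalization
#'
#' Forces every sample onto a common reference distribution: the
#' reference value at rank r is the mean over samples of each column's
#' r-th smallest count, and each observation is replaced by the
#' reference value at its within-column rank. Tied values within a
#' column receive the mean of the reference values over the tied ranks.
#'
#' @param m Count matrix with at least 2 samples.
#' @return Normalized matrix (`method = "quantile"`); after
#'   normalization every column holds the same multiset of values.
#' @export
quantile_normalize <- function(m) {
  validate_counts(m, min_samples = 2L)
  ref <- rowMeans(apply(m, 2L, sort, method = "radix"))
  cref0 <- c(0, cumsum(ref))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    out[, j] <- (cref0[hi + 1L] - cref0[lo]) / (hi - lo + 1)
  }
  attr(out, "method") <- "quantile"
  out
}

.check_lengths <- function(m, lengths, drop_missing) {
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing)) {
    if (!drop_missing)
      stop("no gene length for: ",
           paste(utils::head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L),
           "; pass drop_missing = TRUE to drop them", call. = FALSE)
    warning(length(missing), " gene(s) without length dropped", call. = FALSE)
    m <- m[setdiff(rownames(m), missing), , drop = FALSE]
  }
  if (any(lengths[rownames(m)] <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  m
}

#' RPKM normalization
#'
#' Reads per kilobase per million mapped reads: counts are scaled first
#' for sequencing depth (per million reads) and then for gene length (in
#' kilobases): \eqn{K_{ij} / (N_j/10^6) / (L_i/10^3)}.
#'
#' @param m Count matrix.
#' @param lengths Named vector of gene lengths in bases.
#' @param lib_sizes Optional external library sizes \eqn{N_j}; column
#'   sums are used when absent.
#' @param drop_missing Drop (with a warning) genes absent from `lengths`
#'   instead of erroring.
#' @return Normalized matrix (`method = "rpkm"`).
#' @export
rpkm <- function(m, lengths, lib_sizes = NULL, drop_missing = FALSE) {
  validate_counts(m)
  m <- .check_lengths(m, lengths, drop_missing)
  N <- .lib_sizes(m, lib_sizes)
  L <- lengths[rownames(m)]
  out <- sweep(m, 2L, N / 1e6, "/") / (L / 1e3)
  attr(out, "method") <- "rpkm"
  out
}

#' TPM normalization
#'
#' Transcripts per million: the length correction precedes the depth
#' correction. Counts are divided by gene length in kilobases to give
#' rates, and each sample's rates are rescaled to sum to one million.
#'
#' @inheritParams rpkm
#' @return Normalized matrix (`method = "tpm"`); every column sums to
#'   \eqn{10^6}.
#' @export
tpm <- function(m, lengths, drop_missing = FALSE) {
  validate_counts(m)
  m <- .check_lengths(m, lengths, drop_missing)
  L <- lengths[rownames(m)]
  rate <- m / (L / 1e3)
  denom <- colSums(rate)
  if (any(denom <= 0))
    stop("TPM undefined for all-zero sample(s): ",
         paste(colnames(m)[denom <= 0], collapse = ", "), call. = FALSE)
  out <- sweep(rate, 2L, denom, "/") * 1e6
  attr(out, "method") <- "tpm"
  out
}

#' Normalize a count matrix by any of the nine methods
#'
#' Single dispatch point over the nine normalization schemes. Factor
#' methods route through [scaling_factors()] + [apply_scaling()];
#' `"quantile"`, `"rpkm"` and `"tpm"` call their dedicated
#' implementations.
#'
#' @param m Filtered count matrix.
#' @param method One of [hkg_norm_methods()].
#' @param lengths Gene lengths in bases, required for `"rpkm"`/`"tpm"`.
#' @param lib_sizes Optional external library sizes.
#' @param tmm [tmm_params()] for `method = "tmm"`.
#' @param drop_missing Passed to [rpkm()]/[tpm()].
#' @return Normalized matrix tagged with the method label.
#' @export
normalize_counts <- function(m, method = hkg_norm_methods(), lengths = NULL,
                             lib_sizes = NULL, tmm = tmm_params(),
                             drop_missing = FALSE) {
  method <- match.arg(method)
  if (method %in% c("rpkm", "tpm") && is.null(lengths))
    stop("method '", method, "' requires gene lengths", call. = FALSE)
  switch(method,
    quantile = quantile_normalize(m),
    rpkm = rpkm(m, lengths, lib_sizes, drop_missing),
    tpm = tpm(m, lengths, drop_missing),
    apply_scaling(m, scaling_factors(m, method, lib_sizes, tmm)))
}
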