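# Housekeeping-gene selection: per-gene coefficient of variation on a
# normalized matrix, rank-based percentile cut, expression-ratio
# binning, and consensus intersection across normalization methods.

#' Per-gene coefficient of variation
#'
#' For each gene, the arithmetic mean \eqn{\mu} and sample standard
#' deviation \eqn{\sigma} (denominator n-1) across samples, and their
#' ratio \eqn{CV = \sigma/\mu}. Genes with zero mean are excluded (CV
#' undefined); their count is reported in a message. Note CV is
#' invariant to any global rescale of the scaling factors, so
#' downstream selection does not depend on factor-centering
#' conventions.
#'
#' @param nm Normalized (or raw) matrix, genes x samples, >= 2 samples.
#' @return Data frame of class `"cv_table"` with columns `gene`,
#'   `mean`, `sd`, `cv`, in the matrix's gene order; the source
#'   normalization label is kept in the `method` attribute.
#' @export
gene_cv <- function(nm) {
  if (!is.matrix(nm) || ncol(nm) < 2L)
    stop("CV needs a matrix with at least 2 samples", call. = FALSE)
  if (is.null(rownames(nm)))
    stop("matrix needs gene rownames", call. = FALSE)
  mu <- rowMeans(nm)
  n <- ncol(nm)
  sd <- sqrt(rowSums((nm - mu)^2) / (n - 1))
  keep <- mu > 0
  if (any(!keep))
    message(sum(!keep), " gene(s) with zero mean excluded from CV table")
  out <- data.frame(gene = rownames(nm)[keep], mean = mu[keep],
                    sd = sd[keep], cv = (sd / mu)[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "method") <- attr(nm, "method")
  class(out) <- c("cv_table", "data.frame")
  out
}

#' Select housekeeping genes at a CV percentile
#'
#' Rank-based cut: the selection size is `floor(percentile/100 * N)`
#' where N is the number of genes in the CV table, and the genes with
#' the lowest CV are taken, ties broken lexicographically by gene ID.
#' With the default 2nd percentile, a table of 47,613 genes yields 952
#' selected genes.
#'
#' @param cvt A `"cv_table"` from [gene_cv()].
#' @param percentile Percentile threshold in (0, 100]; default 2.
#' @return Data frame of class `"hkg_selection"` with columns `gene`,
#'   `cv`, `rank` (ascending CV), plus `method` and `percentile`
#'   attributes.
#' @export
select_hkg <- function(cvt, percentile = 2) {
  stopifnot(is.data.frame(cvt), all(c("gene", "cv") %in% names(cvt)))
  if (!nrow(cvt)) stop("empty CV table", call. = FALSE)
  if (!(percentile > 0 && percentile <= 100))
    stop("percentile must be in (0, 100]", call. = FALSE)
  size <- floor(percentile / 100 * nrow(cvt))
  if (size < 1L)
    stop(sprintf(
      "percentile %g of %d genes selects 0 genes; use a larger percentile",
      percentile, nrow(cvt)), call. = FALSE)
  ord <- order(cvt$cv, cvt$gene)[seq_len(size)]
  out <- data.frame(gene = cvt$gene[ord], cv = cvt$cv[ord],
                    rank = seq_len(size), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- attr(cvt, "method")
  attr(out, "percentile") <- percentile
  class(out) <- c("hkg_selection", "data.frame")
  out
}

#' @export
print.hkg_selection <- function(x, ...) {
  cat(sprintf("HKG selection: %d genes (%s percentile%s)\n", nrow(x),
              attr(x, "percentile") %||% "?",
              if (!is.null(attr(x, "method")))
                paste0(", method ", attr(x, "method")) else ""))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more rows\n", sep = "")
  invisible(x)
}

# Fixed expression-ratio bin edges (fractions of the set maximum).
.ratio_breaks <- c(0, 0.01, 0.05, 0.20, 0.40, 0.60, 0.80, 1.0)
.ratio_labels <- c("0-0.01", "0.01-0.05", "0.05-0.20", "0.20-0.40",
                   "0.40-0.60", "0.60-0.80", "0.80-1.0")

#' Expression ratios of a housekeeping-gene set
#'
#' For each selected gene, its mean normalized count divided by a
#' maximum normalized count, binned into fixed intervals (right-closed;
#' the first bin includes 0). The default denominator is the maximum
#' over the selected genes and all samples; `denominator =
#' "global_max"` instead uses the maximum over the whole matrix.
#'
#' @param nm Normalized matrix.
#' @param sel An `"hkg_selection"` whose genes are all present in `nm`.
#' @param denominator `"selection_max"` (default) or `"global_max"`.
#' @return List of class `"ratio_bin_table"`: `ratios` (named per-gene
#'   ratios in \[0, 1\]), `bins` (data frame with `bin`, `count`,
#'   `percent`), `denominator`, `max_value`.
#' @export
expression_ratios <- function(nm, sel,
                              denominator = c("selection_max", "global_max")) {
  denominator <- match.arg(denominator)
  genes <- if (is.data.frame(sel)) sel$gene else as.character(sel)
  missing <- setdiff(genes, rownames(nm))
  if (length(missing))
    stop("selection gene(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  sub <- nm[genes, , drop = FALSE]
  mx <- if (denominator == "selection_max") max(sub) else max(nm)
  if (mx <= 0)
    stop("maximum normalized value is zero; ratios undefined", call. = FALSE)
  ratios <- stats::setNames(rowMeans(sub) / mx, genes)
  bin <- cut(ratios, breaks = .ratio_breaks, labels = .ratio_labels,
             include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  out <- list(ratios = ratios,
              bins = data.frame(bin = .ratio_labels, count = counts,
                                percent = 100 * counts / length(ratios),
                                stringsAsFactors = FALSE),
              denominator = denominator, max_value = mx)
  class(out) <- "ratio_bin_table"
  out
}

#' @export
print.ratio_bin_table <- function(x, ...) {
  cat(sprintf("expression ratios of %d genes (denominator: %s)\n",
              length(x$ratios), x$denominator))
  df <- x$bins
  df$percent <- sprintf("%.2f", df$percent)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Consensus housekeeping-gene set across normalization methods
#'
#' Intersects the gene lists of two or more per-method selections. An
#' empty intersection is a warning, not an error.
#'
#' @param selections List of `"hkg_selection"` objects (>= 2).
#' @return A `"gene_set"` named `"consensus"` with an extra `cv` element:
#'   a gene-by-method matrix of the surviving genes' CVs.
#' @export
consensus_hkg <- function(selections) {
  if (!is.list(selections) || length(selections) < 2L)
    stop("consensus needs at least 2 selections", call. = FALSE)
  lists <- lapply(selections, function(s) s$gene)
  common <- Reduce(intersect, lists)
  if (!length(common))
    warning("consensus is empty: no gene is shared by all selections",
            call. = FALSE)
  methods <- vapply(seq_along(selections), function(i)
    attr(selections[[i]], "method") %||% paste0("method", i), character(1L))
  cvm <- matrix(NA_real_, nrow = length(common), ncol = length(selections),
                dimnames = list(common, methods))
  for (i in seq_along(selections)) {
    s <- selections[[i]]
    cvm[, i] <- s$cv[match(common, s$gene)]
  }
  out <- gene_set("consensus", common)
  out$members <- common            # preserve original order/case of IDs
  out$cv <- cvm
  out
}
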