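# Scoring of normalization methods: per-gene log-ratio bias and
# variance over a stable gene set, five-number CV summaries, and
# overlap validation of selections against external gene lists.

#' Bias and variance of normalized expression over a gene set
#'
#' For gene i with normalized counts \eqn{K_{ij}} over n samples and
#' mean \eqn{\bar K_{i\cdot}}, let \eqn{r_{ij} = \log_2(K_{ij}/\bar
#' K_{i\cdot})}. Then
#' \deqn{Bias_i = \sqrt{\tfrac1n \sum_j r_{ij}^2}, \qquad
#'       Variance_i = \tfrac1{n-1} \sum_j (r_{ij} - \bar r_{i\cdot})^2.}
#' Both are scale-invariant (a constant gene scores exactly 0, 0).
#' Method-level scores are arithmetic means over the retained genes.
#' Genes containing a zero normalized value are skipped and counted
#' (the log-ratio is undefined) unless a positive `pseudocount` is
#' added to every value first.
#'
#' @param nm Normalized matrix, >= 2 samples.
#' @param genes Optional gene IDs (character vector, `"gene_set"`, or
#'   `"hkg_selection"`) restricting the evaluation; defaults to all
#'   genes of `nm`.
#' @param pseudocount Nonnegative value added to every normalized count
#'   before taking logs; default 0 (skip zero-containing genes).
#' @return List of class `"bias_variance_report"`: `per_gene` (data
#'   frame `gene`, `bias`, `variance`), `mean_bias`, `mean_variance`,
#'   `n_samples`, `n_genes`, `n_skipped`, `method`.
#' @export
bias_variance <- function(nm, genes = NULL, pseudocount = 0) {
  if (!is.matrix(nm) || ncol(nm) < 2L)
    stop("bias/variance need >= 2 samples", call. = FALSE)
  if (!is.null(genes)) {
    ids <- if (inherits(genes, "gene_set")) genes$members
           else if (is.data.frame(genes)) genes$gene
           else as.character(genes)
    missing <- setdiff(ids, rownames(nm))
    if (length(missing))
      stop("gene(s) absent from matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    nm <- nm[ids, , drop = FALSE]
  }
  stopifnot(pseudocount >= 0)
  x <- nm + pseudocount
  ok <- rowSums(x <= 0) == 0L
  n_skipped <- sum(!ok)
  if (!any(ok))
    stop("every gene contains a zero normalized value; consider a pseudocount",
         call. = FALSE)
  x <- x[ok, , drop = FALSE]
  n <- ncol(x)
  lr <- log2(x / rowMeans(x))
  bias <- sqrt(rowMeans(lr^2))
  v <- rowSums((lr - rowMeans(lr))^2) / (n - 1)
  out <- list(per_gene = data.frame(gene = rownames(x), bias = bias,
                                    variance = v, row.names = NULL,
                                    stringsAsFactors = FALSE),
              mean_bias = mean(bias), mean_variance = mean(v),
              n_samples = n, n_genes = nrow(x), n_skipped = n_skipped,
              method = attr(nm, "method"))
  class(out) <- "bias_variance_report"
  out
}

#' @export
print.bias_variance_report <- function(x, ...) {
  cat(sprintf(
    "bias/variance over %d genes (%d skipped for zeros), %d samples%s\n",
    x$n_genes, x$n_skipped, x$n_samples,
    if (!is.null(x$method)) paste0(", method ", x$method) else ""))
  cat(sprintf("  mean bias %.4f, mean variance %.4f\n",
              x$mean_bias, x$mean_variance))
  invisible(x)
}

#' Five-number summary of a CV distribution
#'
#' Minimum, first quartile, median, third quartile and maximum of the
#' CVs in a CV table (quartiles by linear interpolation), optionally
#' restricted to a gene set — e.g. the consensus housekeeping set.
#'
#' @param cvt A `"cv_table"`, or a list of them (one row per method in
#'   the output).
#' @param genes Optional restriction (character vector or
#'   `"gene_set"`).
#' @return Data frame with columns `method`, `min`, `q1`, `median`,
#'   `q3`, `max`, `n`.
#' @export
cv_summary <- function(cvt, genes = NULL) {
  if (is.data.frame(cvt)) cvt <- list(cvt)
  ids <- if (is.null(genes)) NULL
         else if (inherits(genes, "gene_set")) genes$members
         else as.character(genes)
  rows <- lapply(seq_along(cvt), function(i) {
    tab <- cvt[[i]]
    cv <- if (is.null(ids)) tab$cv else tab$cv[tab$gene %in% ids]
    if (!length(cv))
      stop("no genes left after restriction in CV table ", i, call. = FALSE)
    q <- stats::quantile(cv, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(method = attr(tab, "method") %||% paste0("method", i),
               min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
               max = q[5L], n = length(cv), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap of HKG selections with external gene lists
#'
#' Counts shared genes between each per-method selection and each
#' external list (differentially expressed genes of a disease state, or
#' a published housekeeping set), after symbol normalization. A low
#' overlap with disease DE lists supports the housekeeping designation.
#'
#' Percentages divide the overlap count by the external list's size
#' (`basis = "list_size"`, the convention of both validation tables in
#' the source study: 3 shared genes against a 206-gene DE list is
#' 1.46%) or by the selection's size (`basis = "hkg_size"`).
#'
#' @param selections List of `"hkg_selection"` objects (or character
#'   vectors of gene IDs).
#' @param lists List of `"gene_set"` objects.
#' @param basis `"list_size"` (default) or `"hkg_size"`.
#' @return Data frame of class `"overlap_table"`, one row per (list,
#'   method) pair: `list`, `list_size`, `method`, `hkg_size`,
#'   `overlap`, `percent`; the percentage basis is recorded in the
#'   `basis` attribute.
#' @export
overlap_report <- function(selections, lists,
                           basis = c("list_size", "hkg_size")) {
  basis <- match.arg(basis)
  if (!length(selections) || !length(lists))
    stop("selections and lists must be non-empty", call. = FALSE)
  if (inherits(lists, "gene_set")) lists <- list(lists)
  rows <- list()
  for (gs in lists) {
    stopifnot(inherits(gs, "gene_set"))
    for (i in seq_along(selections)) {
      s <- selections[[i]]
      genes <- normalize_symbols(if (is.data.frame(s)) s$gene else s)
      ov <- length(intersect(genes, gs$members))
      denom <- if (basis == "list_size") length(gs$members) else length(genes)
      rows[[length(rows) + 1L]] <- data.frame(
        list = gs$name, list_size = length(gs$members),
        method = attr(s, "method") %||% paste0("method", i),
        hkg_size = length(genes), overlap = ov,
        percent = 100 * ov / denom, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "basis") <- basis
  class(out) <- c("overlap_table", "data.frame")
  out
}
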