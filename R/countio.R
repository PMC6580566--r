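# Count-matrix, gene-length and gene-list I/O.
#
# A count matrix is a base integer matrix with unique rownames (gene IDs)
# and unique colnames (sample IDs); normalized matrices are numeric
# matrices with the same dimnames plus a "method" attribute. All readers
# skip `#`-prefixed metadata comment lines, which the writers emit.

#' Validate a count matrix
#'
#' Checks the contract shared by all downstream operations: a matrix with
#' unique gene rownames, unique sample colnames, and nonnegative integer
#' counts.
#'
#' @param m Matrix to validate, genes in rows.
#' @param min_samples Minimum number of sample columns (CV, variance and
#'   quantile normalization all need at least 2).
#' @return `m`, invisibly, if valid; otherwise an error.
#' @keywords internal
validate_counts <- function(m, min_samples = 1L) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("counts must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  dup_g <- rownames(m)[duplicated(rownames(m))]
  if (length(dup_g))
    stop("duplicated gene ID(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_s <- colnames(m)[duplicated(colnames(m))]
  if (length(dup_s))
    stop("duplicated sample ID(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  if (ncol(m) < min_samples)
    stop("at least ", min_samples, " samples required, got ", ncol(m),
         call. = FALSE)
  bad <- which(!is.finite(m) | m < 0 | m != round(m))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf(
      "counts must be nonnegative integers; offending value %s at gene '%s', sample '%s'",
      format(m[bad[1L]]), rownames(m)[i[1L]], colnames(m)[i[2L]]),
      call. = FALSE)
  }
  invisible(m)
}

#' Read a gene-by-sample count matrix
#'
#' Expects a header row of sample IDs and a first column of gene IDs; the
#' remaining cells must be nonnegative integers. Row and column order of
#' the file is preserved. Lines starting with `#` are treated as metadata
#' comments and skipped.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Integer matrix, genes in rows, with gene/sample dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "ACTB\t10\t12", "GAPDH\t5\t7"), tf)
#' read_count_matrix(tf)
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  # read.table uniquifies duplicate header names; catch them from the raw line
  raw <- readLines(path, n = 100L)
  header <- raw[!grepl("^#", raw)][1L]
  ids <- strsplit(header, sep, fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(ids))
    stop("duplicated sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, colClasses = "character",
                          quote = "\"")
  if (ncol(df) < 2L)
    stop("count matrix file needs a gene-ID column plus >= 1 sample column",
         call. = FALSE)
  genes <- trimws(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  samples <- colnames(vals)
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  num <- matrix(num, nrow = nrow(vals), dimnames = NULL)
  bad <- which(is.na(num) | num < 0 | num != round(num))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(num))
    stop(sprintf(
      "invalid count '%s' at row %d (gene '%s'), column '%s': must be a nonnegative integer",
      vals[i[1L], i[2L]], i[1L], genes[i[1L]], samples[i[2L]]),
      call. = FALSE)
  }
  m <- matrix(as.numeric(num), nrow = length(genes),
              dimnames = list(genes, samples))
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Drop genes with zero counts in every sample
#'
#' Expressed-gene filter applied before normalization: keeps exactly the
#' genes with at least one nonzero count, in their original order. Column
#' sums are unchanged by construction.
#'
#' @param m Count matrix (genes x samples).
#' @return Filtered count matrix.
#' @export
filter_all_zero_genes <- function(m) {
  validate_counts(m)
  keep <- rowSums(m) > 0
  if (!any(keep))
    stop("all genes have zero counts in every sample; nothing to analyze",
         call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Read a gene-length table
#'
#' Two-column TSV: gene ID and length in bases (strictly positive
#' integers). Used by [rpkm()] and [tpm()].
#'
#' @param path Path to the TSV file. A header line is optional and
#'   detected by a non-numeric second field.
#' @return Named numeric vector of lengths in bases.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", colClasses = "character",
                          quote = "\"")
  if (ncol(df) < 2L)
    stop("gene-length table must have two columns: gene ID and length (bp)",
         call. = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[2L][[1L]][1L]))))
    df <- df[-1L, , drop = FALSE]  # header line
  genes <- trimws(df[[1L]])
  len <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(is.na(len) | len <= 0 | len != round(len))
  if (length(bad))
    stop(sprintf("gene '%s' has invalid length '%s': must be a positive integer",
                 genes[bad[1L]], df[[2L]][bad[1L]]), call. = FALSE)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene ID(s) in length table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  stats::setNames(len, genes)
}

#' Normalize gene symbols for set matching
#'
#' Uppercases and strips surrounding whitespace. No alias or cross-ID
#' mapping is attempted.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(x) toupper(trimws(x))

#' Construct a gene set
#'
#' @param name Label for the set.
#' @param members Character vector of gene identifiers; normalized with
#'   [normalize_symbols()] and de-duplicated.
#' @return Object of class `"gene_set"`: a list with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(normalize_symbols(members))
  members <- members[nzchar(members)]
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s': %d genes\n", x$name, length(x$members)))
  show <- utils::head(x$members, 8L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x$members) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read external gene lists
#'
#' Supports one-symbol-per-line plain lists (set name = file stem) and
#' the standard GMT format (name, description, members per line). Symbols
#' are normalized with [normalize_symbols()]; blank lines are skipped.
#'
#' @param path Path to the file.
#' @param format `"plain"` or `"gmt"`.
#' @return List of `"gene_set"` objects (length 1 for plain files).
#' @export
read_gene_sets <- function(path, format = c("plain", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (format == "plain") {
    members <- trimws(lines)
    members <- members[nzchar(members)]
    if (!length(members))
      stop("gene list '", path, "' is empty after parsing", call. = FALSE)
    name <- sub("\\.[^.]*$", "", basename(path))
    return(list(gene_set(name, members)))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("GMT file '", path, "' is empty", call. = FALSE)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >= 1 member): ", l,
           call. = FALSE)
    gene_set(f[1L], f[-(1:2)])
  })
  empty <- vapply(sets, function(s) length(s$members) == 0L, logical(1L))
  if (any(empty))
    stop("GMT set(s) with no members: ",
         paste(vapply(sets[empty], `[[`, "", "name"), collapse = ", "),
         call. = FALSE)
  sets
}

#' Read a per-sample library-size table
#'
#' Two-column TSV mapping sample ID to total aligned reads (positive
#' integers).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of library sizes.
#' @export
read_library_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", colClasses = "character")
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[[2L]][1L]))))
    df <- df[-1L, , drop = FALSE]
  ids <- trimws(df[[1L]])
  n <- suppressWarnings(as.numeric(df[[2L]]))
  if (any(is.na(n) | n <= 0))
    stop("library sizes must be positive numbers", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated sample ID(s) in library-size table", call. = FALSE)
  stats::setNames(n, ids)
}

#' Write tabular results as TSV
#'
#' Generic writer for the package's tabular objects. All outputs are TSV
#' with a header row; matrix writers emit the gene-ID column first, and
#' normalized matrices record their method in a `#`-prefixed comment line
#' so that re-reading reproduces the values.
#'
#' @param obj Object to write (count/normalized matrix, data frame, CV
#'   table, selection, ...).
#' @param path Output file path.
#' @param ... Passed to methods.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, ...) UseMethod("write_table")

.write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.matrix <- function(obj, path, ...) {
  comments <- character()
  if (!is.null(attr(obj, "method")))
    comments <- paste0("method: ", attr(obj, "method"))
  df <- data.frame(gene = rownames(obj), obj, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path, comments)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(obj, path, ...) {
  comments <- character()
  for (a in c("method", "percentile", "basis"))
    if (!is.null(attr(obj, a)))
      comments <- c(comments, paste0(a, ": ", attr(obj, a)))
  .write_tsv(obj, path, comments)
}

#' Read a normalized matrix written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with the `method` attribute restored if the
#'   file carries a `# method:` comment.
#' @export
read_normalized_matrix <- function(path) {
  first <- readLines(path, n = 5L)
  method <- NULL
  mline <- grep("^# method: ", first, value = TRUE)
  if (length(mline)) method <- sub("^# method: ", "", mline[1L])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!is.null(method)) attr(m, "method") <- method
  m
}
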