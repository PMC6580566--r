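# One-shot pipeline: (optionally simulate) -> filter -> normalize by
# every requested method -> CV -> percentile selection -> consensus ->
# bias/variance, CV summaries, expression-ratio bins -> overlap
# validation. All tabular outputs are TSV; a JSON manifest records the
# configuration and checksums of every file written, so a run is fully
# auditable and bit-reproducible given the same seed.

.stage <- function(quiet, ...) if (!quiet) message("[hkgscout] ", ...)

#' Run the full housekeeping-gene discovery pipeline
#'
#' Chains every stage of the analysis and writes its outputs under
#' `out_dir`: per-method normalized matrices (`norm_<method>.tsv`), CV
#' tables (`cv_<method>.tsv`), selections (`hkg_<method>.tsv`), the
#' consensus set (`consensus.tsv`), bias/variance scores per method
#' (`bias_variance.tsv`), five-number CV summaries for all selected
#' genes and for the consensus subset (`cv_summary.tsv`,
#' `cv_summary_consensus.tsv`), expression-ratio bins
#' (`ratio_bins.tsv`), an overlap table when external gene lists are
#' given (`overlap.tsv`), and `manifest.json`.
#'
#' When `counts` is `NULL` a dataset is simulated with `sim_config` and
#' `seed`, and the simulated inputs plus ground truth are written too
#' (`counts.tsv`, `lengths.tsv`, `libsizes.tsv`, `truth.tsv`,
#' `recovery.tsv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param counts Count matrix (genes x samples), or `NULL` to simulate.
#' @param lengths Named gene-length vector (bp); required when
#'   `methods` includes `"rpkm"` or `"tpm"` and counts are supplied.
#' @param lib_sizes Optional named library-size vector.
#' @param gene_lists Optional list of `"gene_set"` objects for overlap
#'   validation.
#' @param methods Normalization methods to run (default all nine).
#' @param percentile CV percentile for selection (default 2).
#' @param sim_config [simulation_config()] used when simulating.
#' @param seed Seed for the simulation stage (required then; the rest
#'   of the pipeline is deterministic).
#' @param overlap_basis Percentage basis for [overlap_report()].
#' @param quiet Suppress stage log messages.
#' @return Invisibly, a list with every in-memory result: `counts`
#'   (filtered), `factors`, `normalized`, `cv`, `selections`,
#'   `consensus`, `bias_variance`, `cv_summary`,
#'   `cv_summary_consensus`, `ratio_bins`, `overlap`, `recovery`,
#'   `truth`, `manifest`.
#' @export
run_hkg_pipeline <- function(out_dir, counts = NULL, lengths = NULL,
                             lib_sizes = NULL, gene_lists = NULL,
                             methods = hkg_norm_methods(), percentile = 2,
                             sim_config = simulation_config(), seed = NULL,
                             overlap_basis = c("list_size", "hkg_size"),
                             quiet = FALSE) {
  overlap_basis <- match.arg(overlap_basis)
  methods <- match.arg(methods, hkg_norm_methods(), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  if (is.null(counts)) {
    .stage(quiet, "simulate: ", sim_config$n_genes, " genes, ",
           length(sim_config$groups) * sim_config$n_per_group, " samples")
    sim <- simulate_dataset(sim_config, seed = seed)
    counts <- sim$counts
    lengths <- sim$lengths
    lib_sizes <- sim$lib_sizes
    truth <- sim$truth
    write_table(counts, file.path(out_dir, "counts.tsv"))
    .write_tsv(data.frame(gene = names(lengths), length = lengths),
               file.path(out_dir, "lengths.tsv"))
    .write_tsv(data.frame(sample = names(lib_sizes), lib_size = lib_sizes),
               file.path(out_dir, "libsizes.tsv"))
    tdf <- data.frame(gene = names(truth$classes), class = truth$classes,
                      base_mean = truth$base_means, length = truth$lengths,
                      dispersion = truth$dispersions,
                      de_group = NA_character_, log2fc = 0,
                      row.names = NULL, stringsAsFactors = FALSE)
    i <- match(truth$de$gene, tdf$gene)
    tdf$de_group[i] <- truth$de$group
    tdf$log2fc[i] <- truth$de$log2fc
    .write_tsv(tdf, file.path(out_dir, "truth.tsv"))
  }
  needs_len <- intersect(methods, c("rpkm", "tpm"))
  if (length(needs_len) && is.null(lengths))
    stop("method(s) ", paste(needs_len, collapse = ", "),
         " require gene lengths", call. = FALSE)

  .stage(quiet, "filter: ", nrow(counts), " genes in")
  counts <- filter_all_zero_genes(counts)
  .stage(quiet, "filter: ", nrow(counts), " genes retained")

  normalized <- list(); factors <- list(); cvs <- list(); sels <- list()
  for (method in methods) {
    .stage(quiet, "normalize: ", method)
    if (method %in% .factor_methods)
      factors[[method]] <- scaling_factors(counts, method, lib_sizes)
    nm <- normalize_counts(counts, method, lengths = lengths,
                           lib_sizes = lib_sizes)
    normalized[[method]] <- nm
    write_table(nm, file.path(out_dir, paste0("norm_", method, ".tsv")))
    cvs[[method]] <- gene_cv(nm)
    write_table(cvs[[method]], file.path(out_dir, paste0("cv_", method, ".tsv")))
    sels[[method]] <- select_hkg(cvs[[method]], percentile)
    write_table(sels[[method]],
                file.path(out_dir, paste0("hkg_", method, ".tsv")))
  }

  cons <- NULL
  if (length(sels) >= 2L) {
    .stage(quiet, "consensus over ", length(sels), " methods")
    cons <- consensus_hkg(sels)
    cdf <- data.frame(gene = cons$members, cons$cv, check.names = FALSE,
                      row.names = NULL, stringsAsFactors = FALSE)
    .write_tsv(cdf, file.path(out_dir, "consensus.tsv"))
  }

  .stage(quiet, "evaluate: bias/variance and CV summaries")
  bv <- lapply(methods, function(method)
    bias_variance(normalized[[method]], sels[[method]]))
  names(bv) <- methods
  bvdf <- data.frame(
    method = methods,
    mean_bias = vapply(bv, `[[`, numeric(1L), "mean_bias"),
    mean_variance = vapply(bv, `[[`, numeric(1L), "mean_variance"),
    n_genes = vapply(bv, `[[`, numeric(1L), "n_genes"),
    n_skipped = vapply(bv, `[[`, numeric(1L), "n_skipped"),
    stringsAsFactors = FALSE)
  .write_tsv(bvdf, file.path(out_dir, "bias_variance.tsv"))

  cvsum <- cv_summary(lapply(methods, function(m) {
    tab <- cvs[[m]]
    tab[tab$gene %in% sels[[m]]$gene, , drop = FALSE]
  }))
  cvsum$method <- methods   # restriction drops the attribute
  .write_tsv(cvsum, file.path(out_dir, "cv_summary.tsv"))
  cvsum_cons <- NULL
  if (!is.null(cons) && length(cons$members)) {
    cvsum_cons <- cv_summary(cvs, genes = cons$members)
    .write_tsv(cvsum_cons, file.path(out_dir, "cv_summary_consensus.tsv"))
  }

  bins <- lapply(methods, function(m)
    expression_ratios(normalized[[m]], sels[[m]]))
  names(bins) <- methods
  bindf <- do.call(rbind, lapply(methods, function(m)
    cbind(method = m, bins[[m]]$bins, stringsAsFactors = FALSE)))
  .write_tsv(bindf, file.path(out_dir, "ratio_bins.tsv"))

  ov <- NULL
  if (!is.null(gene_lists) && length(gene_lists)) {
    .stage(quiet, "overlap validation against ", length(gene_lists), " list(s)")
    ov <- overlap_report(sels, gene_lists, basis = overlap_basis)
    write_table(ov, file.path(out_dir, "overlap.tsv"))
  }

  recov <- NULL
  if (!is.null(truth)) {
    recov <- t(vapply(sels, function(s) recovery_score(truth, s),
                      numeric(2L)))
    rdf <- data.frame(method = rownames(recov), recov, row.names = NULL,
                      stringsAsFactors = FALSE)
    .write_tsv(rdf, file.path(out_dir, "recovery.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "hkgscout",
    version = as.character(utils::packageVersion("hkgscout")),
    seed = if (is.null(seed)) NA else as.integer(seed),
    methods = methods, percentile = percentile,
    overlap_basis = overlap_basis,
    n_genes_retained = nrow(counts), n_samples = ncol(counts),
    simulated = !is.null(truth),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stage(quiet, "done: ", length(files) + 1L, " files in ", out_dir)

  invisible(list(counts = counts, factors = factors, normalized = normalized,
                 cv = cvs, selections = sels, consensus = cons,
                 bias_variance = bv, bias_variance_table = bvdf,
                 cv_summary = cvsum, cv_summary_consensus = cvsum_cons,
                 ratio_bins = bins, overlap = ov, recovery = recov,
                 truth = truth, manifest = manifest))
}
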