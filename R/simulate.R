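# Negative-binomial count simulator with planted housekeeping genes,
# group-specific differentially expressed genes, heterogeneous library
# depths and per-gene lengths, plus full ground truth for recovery
# benchmarking. The default design mirrors a 30-biopsy study: six
# condition groups of five samples each.

#' Simulation configuration
#'
#' Defines the generative model: gene i in sample j of group g draws
#' counts from NB(mean = mu_i * 2^fc_{i,g} * l_j, dispersion = phi_i),
#' where mu_i is a log-normal baseline mean, l_j a log-normal library
#' depth factor, fc a group-specific log2 fold change (nonzero only for
#' planted DE genes, in a single disease group each), and phi_i the
#' dispersion. Planted housekeeping genes have fc = 0 in every group
#' and a low dispersion — both constancy properties the housekeeping
#' definition implies.
#'
#' @param n_genes Number of genes (default 10000).
#' @param groups Condition group labels (default six groups echoing a
#'   transplant-biopsy design: stable function, acute tubular injury,
#'   T-cell-mediated rejection, fibrosis/atrophy, polyomavirus
#'   nephropathy, interstitial nephritis).
#' @param n_per_group Samples per group (default 5, giving 30 samples).
#' @param fraction_hkg Fraction of genes planted as housekeeping
#'   (default 0.04).
#' @param fraction_de Fraction planted as differentially expressed
#'   (default 0.06); HKG and DE fractions must sum to at most 1.
#' @param hkg_dispersion NB dispersion of planted HKG (default 0.005).
#' @param base_dispersion NB dispersion of all other genes (default
#'   0.2); must exceed `hkg_dispersion`.
#' @param log2fc_mean,log2fc_sd Magnitude of DE log2 fold changes ~
#'   Normal(2, 0.5), sign random.
#' @param libfactor_sdlog Library depth factors ~ logNormal(0, 0.3).
#' @param length_meanlog,length_sdlog,min_length Gene lengths (bp) ~
#'   logNormal(log 1500, 0.6), floored at 100.
#' @param mean_meanlog,mean_sdlog Baseline means ~ logNormal(log 50,
#'   1.5).
#' @param seed Optional integer seed recorded in the config and used by
#'   [simulate_dataset()].
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 10000L,
                              groups = c("STA", "ATI", "TCMR", "IFTA",
                                         "BKVN", "ISN"),
                              n_per_group = 5L,
                              fraction_hkg = 0.04, fraction_de = 0.06,
                              hkg_dispersion = 0.005, base_dispersion = 0.2,
                              log2fc_mean = 2, log2fc_sd = 0.5,
                              libfactor_sdlog = 0.3,
                              length_meanlog = log(1500),
                              length_sdlog = 0.6, min_length = 100L,
                              mean_meanlog = log(50), mean_sdlog = 1.5,
                              seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes), groups = as.character(groups),
              n_per_group = as.integer(n_per_group),
              fraction_hkg = fraction_hkg, fraction_de = fraction_de,
              hkg_dispersion = hkg_dispersion,
              base_dispersion = base_dispersion,
              log2fc_mean = log2fc_mean, log2fc_sd = log2fc_sd,
              libfactor_sdlog = libfactor_sdlog,
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              min_length = as.integer(min_length),
              mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
              seed = seed)
  if (cfg$n_genes < 2L) stop("n_genes must be >= 2", call. = FALSE)
  if (length(cfg$groups) < 2L || anyDuplicated(cfg$groups))
    stop("groups must be >= 2 distinct labels", call. = FALSE)
  if (cfg$n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (cfg$fraction_hkg < 0 || cfg$fraction_de < 0 ||
      cfg$fraction_hkg + cfg$fraction_de > 1)
    stop("fractions must be in [0,1] with fraction_hkg + fraction_de <= 1",
         call. = FALSE)
  if (cfg$hkg_dispersion <= 0 || cfg$base_dispersion <= 0)
    stop("dispersions must be > 0", call. = FALSE)
  if (cfg$hkg_dispersion >= cfg$base_dispersion)
    stop("hkg_dispersion must be below base_dispersion", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a count dataset with ground truth
#'
#' Draws a gene-by-sample negative-binomial count matrix under the
#' model of [simulation_config()], together with gene lengths, library
#' sizes (column totals of the unfiltered matrix) and the exact truth:
#' the planted HKG set, the DE genes with their group and log2 fold
#' change, library depth factors, baseline means, lengths and
#' dispersions. The same config and seed always reproduce the same
#' dataset.
#'
#' @param cfg A `"simulation_config"`.
#' @param seed Integer seed; overrides `cfg$seed`. One of the two must
#'   be set.
#' @return List of class `"hkg_simulation"`: `counts` (integer matrix),
#'   `lengths` (named vector, bp), `lib_sizes` (named vector), `truth`
#'   (list: `hkg`, `de` data frame with `gene`, `group`, `log2fc`,
#'   `lib_factors`, `base_means`, `lengths`, `dispersions`, `classes`,
#'   `seed`), and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  ng <- cfg$n_genes
  samples <- paste(rep(cfg$groups, each = cfg$n_per_group),
                   rep(seq_len(cfg$n_per_group), length(cfg$groups)),
                   sep = "_")
  group_of <- rep(cfg$groups, each = cfg$n_per_group)
  ns <- length(samples)
  genes <- sprintf("G%05d", seq_len(ng))

  n_hkg <- round(cfg$fraction_hkg * ng)
  n_de <- round(cfg$fraction_de * ng)
  cls <- rep("background", ng)
  planted <- sample.int(ng, n_hkg + n_de)
  cls[planted[seq_len(n_hkg)]] <- "hkg"
  if (n_de > 0) cls[planted[n_hkg + seq_len(n_de)]] <- "de"

  mu <- stats::rlnorm(ng, cfg$mean_meanlog, cfg$mean_sdlog)
  len <- pmax(round(stats::rlnorm(ng, cfg$length_meanlog, cfg$length_sdlog)),
              cfg$min_length)
  phi <- ifelse(cls == "hkg", cfg$hkg_dispersion, cfg$base_dispersion)
  ell <- stats::rlnorm(ns, 0, cfg$libfactor_sdlog)

  # each DE gene perturbed in exactly one disease group (never the
  # first, reference group); magnitude ~ N(log2fc_mean, log2fc_sd),
  # random sign
  fc <- matrix(0, nrow = ng, ncol = length(cfg$groups),
               dimnames = list(genes, cfg$groups))
  de_idx <- which(cls == "de")
  de <- data.frame(gene = character(0), group = character(0),
                   log2fc = numeric(0), stringsAsFactors = FALSE)
  if (length(de_idx)) {
    de_group <- sample(cfg$groups[-1L], length(de_idx), replace = TRUE)
    mag <- stats::rnorm(length(de_idx), cfg$log2fc_mean, cfg$log2fc_sd)
    sgn <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    lfc <- sgn * mag
    fc[cbind(de_idx, match(de_group, cfg$groups))] <- lfc
    de <- data.frame(gene = genes[de_idx], group = de_group, log2fc = lfc,
                     stringsAsFactors = FALSE)
  }

  mu_mat <- (mu * 2^fc[, match(group_of, cfg$groups), drop = FALSE]) *
    rep(ell, each = ng)
  counts <- matrix(stats::rnbinom(ng * ns, mu = as.vector(mu_mat),
                                  size = rep(1 / phi, ns)),
                   nrow = ng, dimnames = list(genes, samples))
  storage.mode(counts) <- "double"

  out <- list(
    counts = counts,
    lengths = stats::setNames(as.numeric(len), genes),
    lib_sizes = colSums(counts),
    truth = list(hkg = genes[cls == "hkg"], de = de,
                 lib_factors = stats::setNames(ell, samples),
                 base_means = stats::setNames(mu, genes),
                 lengths = stats::setNames(as.numeric(len), genes),
                 dispersions = stats::setNames(phi, genes),
                 classes = stats::setNames(cls, genes),
                 seed = as.integer(seed)),
    config = cfg)
  class(out) <- "hkg_simulation"
  out
}

#' @export
print.hkg_simulation <- function(x, ...) {
  cat(sprintf(
    "simulated dataset: %d genes x %d samples (%d HKG, %d DE planted), seed %d\n",
    nrow(x$counts), ncol(x$counts), length(x$truth$hkg), nrow(x$truth$de),
    x$truth$seed))
  invisible(x)
}

#' Score a selection against the simulation truth
#'
#' Precision = fraction of selected genes that are planted housekeeping
#' genes; DE contamination = fraction that are planted differentially
#' expressed genes. A faithful method has precision near 1 and
#' contamination near 0 — the simulated analogue of finding near-zero
#' overlap between housekeeping selections and disease DE lists.
#'
#' @param truth The `truth` element of an `"hkg_simulation"` (or the
#'   simulation itself).
#' @param sel An `"hkg_selection"` (or character vector of gene IDs).
#' @return Named numeric vector `c(precision, de_contamination)`.
#' @export
recovery_score <- function(truth, sel) {
  if (inherits(truth, "hkg_simulation")) truth <- truth$truth
  genes <- if (is.data.frame(sel)) sel$gene else as.character(sel)
  if (!length(genes)) stop("empty selection", call. = FALSE)
  unknown <- setdiff(genes, names(truth$classes))
  if (length(unknown))
    stop("selection contains gene(s) not in the simulation: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  c(precision = length(intersect(genes, truth$hkg)) / length(genes),
    de_contamination = length(intersect(genes, truth$de$gene)) / length(genes))
}
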