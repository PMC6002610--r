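#' Configuration for the synthetic enrichment experiment
#'
#' Describes a litter-matched two-treatment (`EE` enriched vs `B` barren),
#' two-timepoint (1 h, 4 h post stimulus) brain RNA-seq design with one male
#' sample per (litter, treatment, timepoint) cell. Counts are negative
#' binomial around gene-specific baselines; per-(litter, gene) Gaussian
#' random effects on the log mean are shared by all samples of a litter;
#' an immediate-early-gene (IEG) signature is shifted up in EE at 1 h only
#' (transient), and a microglial signature is shifted down in EE at both
#' timepoints (persistent).
#'
#' Signature sizes default to the prevalence seen in cortex-wide studies
#' (roughly 0.6% IEG and 2.6% microglial of the expressed-gene universe),
#' scaled to `n_genes`.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_litters number of litters (default 6).
#' @param timepoints timepoint labels, subset of `c("1h", "4h")`.
#' @param treatments treatment labels (fixed design: `c("EE", "B")`).
#' @param baseline_log_mean_range range (natural log) of gene baseline mean
#'   expression; baselines are drawn uniformly on this log scale.
#' @param nb_dispersion negative binomial dispersion `phi` (variance
#'   `mu + phi * mu^2`; NB size parameter is `1/phi`).
#' @param litter_sd SD of the per-(litter, gene) random effect on the
#'   natural-log mean; 0 disables litter structure.
#' @param ieg_genes,microglia_genes signature sizes (disjoint subsets of the
#'   genes).
#' @param ieg_log2fc log2 fold change (EE minus B) of IEG genes at 1 h only.
#' @param microglia_log2fc log2 fold change of microglial genes at both
#'   timepoints (negative for a down signature).
#' @param library_size_range range of per-sample sequencing depths.
#' @param seed integer RNG seed; the simulation is bit-reproducible given it.
#' @return a validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, ieg_genes = 5, microglia_genes = 10)
sim_config <- function(n_genes = 2000,
                       n_litters = 6,
                       timepoints = c("1h", "4h"),
                       treatments = c("EE", "B"),
                       baseline_log_mean_range = c(log(20), log(2000)),
                       nb_dispersion = 0.05,
                       litter_sd = 0.1,
                       ieg_genes = 11,
                       ieg_log2fc = 1,
                       microglia_genes = 52,
                       microglia_log2fc = -1,
                       library_size_range = c(8e5, 1.2e6),
                       seed = 1) {
  stopifnot(n_genes >= 1, n_litters >= 1,
            length(baseline_log_mean_range) == 2L,
            diff(baseline_log_mean_range) >= 0,
            length(library_size_range) == 2L)
  if (!all(timepoints %in% c("1h", "4h")) || length(timepoints) < 1L) {
    stop("timepoints must be a nonempty subset of c('1h','4h')")
  }
  if (!identical(sort(treatments), c("B", "EE"))) {
    stop("treatments must be c('EE','B')")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be strictly positive")
  if (litter_sd < 0) stop("litter_sd must be nonnegative")
  if (any(library_size_range <= 0)) stop("library sizes must be strictly positive")
  if (ieg_genes < 0 || microglia_genes < 0) stop("signature sizes must be nonnegative")
  if (ieg_genes + microglia_genes > n_genes) {
    stop("signature gene counts (", ieg_genes + microglia_genes,
         ") exceed n_genes (", n_genes, ")")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_litters = as.integer(n_litters),
    timepoints = timepoints, treatments = c("EE", "B"),
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    nb_dispersion = nb_dispersion, litter_sd = litter_sd,
    ieg_genes = as.integer(ieg_genes), ieg_log2fc = ieg_log2fc,
    microglia_genes = as.integer(microglia_genes),
    microglia_log2fc = microglia_log2fc,
    library_size_range = as.numeric(library_size_range),
    seed = as.integer(seed)), class = "sim_config")
}

# expected counts, gene lengths, truth table and sample sheet for a config;
# everything downstream of the RNG seed set by the caller
sim_model <- function(config) {
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  lengths <- exp(runif(n, log(500), log(10000)))
  b <- runif(n, config$baseline_log_mean_range[1], config$baseline_log_mean_range[2])
  rel <- exp(b) / sum(exp(b))

  sig <- rep("none", n)
  picked <- sample.int(n, config$ieg_genes + config$microglia_genes)
  ieg_idx <- picked[seq_len(config$ieg_genes)]
  mic_idx <- picked[config$ieg_genes + seq_len(config$microglia_genes)]
  sig[ieg_idx] <- "IEG"
  sig[mic_idx] <- "microglia"

  log2fc_1h <- numeric(n)
  log2fc_4h <- numeric(n)
  log2fc_1h[ieg_idx] <- config$ieg_log2fc
  log2fc_1h[mic_idx] <- config$microglia_log2fc
  log2fc_4h[mic_idx] <- config$microglia_log2fc

  litters <- sprintf("L%d", seq_len(config$n_litters))
  grid <- expand.grid(litter = litters, treatment = config$treatments,
                      timepoint = config$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(grid$litter, grid$treatment, grid$timepoint, sep = "_"),
    litter = grid$litter, treatment = grid$treatment,
    timepoint = grid$timepoint, sex = "M", stringsAsFactors = FALSE)

  depth <- runif(nrow(samples), config$library_size_range[1],
                 config$library_size_range[2])
  litter_eff <- matrix(rnorm(n * config$n_litters, sd = config$litter_sd),
                       nrow = n, dimnames = list(gene_ids, litters))

  mu <- matrix(0, n, nrow(samples), dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    delta <- if (samples$timepoint[j] == "1h") log2fc_1h else log2fc_4h
    eff <- if (samples$treatment[j] == "EE") 2^delta else 1
    mu[, j] <- depth[j] * rel * exp(litter_eff[, samples$litter[j]]) * eff
  }
  truth <- data.frame(gene_id = gene_ids, signature = sig,
                      log2fc_1h = log2fc_1h, log2fc_4h = log2fc_4h,
                      length = lengths, baseline_log_mean = b,
                      stringsAsFactors = FALSE)
  list(mu = mu, samples = samples, truth = truth, lengths = lengths)
}

#' Simulate a litter-matched enrichment RNA-seq experiment
#'
#' Draws negative binomial counts from the mean model described in
#' [sim_config()] and derives TPM using gene lengths sampled log-uniformly
#' in 500-10,000 nt. The expected EE/B mean ratio of an IEG gene is
#' `2^ieg_log2fc` at 1 h and 1 at 4 h; of a microglial gene,
#' `2^microglia_log2fc` at both timepoints. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_experiment` with elements `counts` and `tpm`
#'   ([expression_matrix()]), `samples` (metadata data.frame), `truth`
#'   (per-gene signature membership, true log2 fold changes per timepoint,
#'   gene length and baseline), and `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 100, ieg_genes = 3,
#'                                       microglia_genes = 5, seed = 7))
#' dim(sim$counts)
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_rng_seed(config$seed, {
    mod <- sim_model(config)
    counts <- matrix(
      rnbinom(length(mod$mu), mu = as.vector(mod$mu),
              size = 1 / config$nb_dispersion),
      nrow = nrow(mod$mu), dimnames = dimnames(mod$mu))
    counts <- expression_matrix(counts, "counts")
    tpm <- counts_to_tpm(counts, mod$lengths)
    structure(list(counts = counts, tpm = tpm, samples = mod$samples,
                   truth = mod$truth, config = config),
              class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d genes x %d samples (%d IEG, %d microglial)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$truth$signature == "IEG"),
              sum(x$truth$signature == "microglia")))
  invisible(x)
}

#' Convert counts to TPM
#'
#' `TPM_gj = (count_gj / length_g) / sum_i(count_ij / length_i) * 1e6`;
#' every nonzero column sums to 1e6. A column of all-zero counts cannot be
#' normalised and is returned as zeros with a warning.
#'
#' @param counts a counts [expression_matrix()] (or labelled matrix).
#' @param gene_lengths strictly positive lengths aligned to the gene axis
#'   (optionally named by gene id).
#' @return a TPM `expr_matrix`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(c(10, 10), 2,
#'        dimnames = list(c("g1", "g2"), "s1")), "counts")
#' counts_to_tpm(m, c(100, 200))
counts_to_tpm <- function(counts, gene_lengths) {
  vals <- unclass(counts)
  attr(vals, "unit") <- NULL
  if (!is.null(names(gene_lengths))) {
    gene_lengths <- gene_lengths[rownames(vals)]
    if (anyNA(gene_lengths)) stop("gene_lengths does not cover all genes")
  }
  if (length(gene_lengths) != nrow(vals)) {
    stop("gene_lengths must align with the gene axis")
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("gene lengths must be strictly positive")
  }
  rate <- vals / gene_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("column(s) with zero total count left as all-zero TPM: ",
            paste(colnames(vals)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  expression_matrix(tpm, "TPM")
}
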