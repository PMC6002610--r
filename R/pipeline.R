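#' Full-pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the data source
#' (a [sim_config()] or paths to counts/TPM/metadata TSVs), the expression
#' filter, DE settings, the comparisons (EE vs B at 1 h, at 4 h, and
#' pooled, by default), the signatures to test, the randomisation-test
#' size, and the network stage (all-gene sample graph at r >= 0.99,
#' DE-gene sample graph at r >= 0.93, DE-gene gene-to-gene graph at
#' r >= 0.90, MCL inflation 2.2).
#'
#' @param sim a [sim_config()], or `NULL` when reading from files.
#' @param counts_path,tpm_path,samples_path TSV inputs used when
#'   `sim` is `NULL`.
#' @param filter_threshold group-wise TPM filter threshold (default 2).
#' @param de a [de_config()].
#' @param comparisons named list; each element is
#'   `list(a = <selector>, b = <selector>)` where a selector is a list with
#'   optional `treatment`/`timepoint` fields.
#' @param signatures list of [gene_signature()]; `NULL` with simulated data
#'   derives the true IEG (up) and microglial (down) signatures.
#' @param s randomisation subset count (default 10,000).
#' @param network list of settings: `sample_all_threshold`,
#'   `sample_de_threshold`, `gene_threshold`, `inflation`, `min_size`.
#' @param seed master seed; each stage runs on a seed derived from it via
#'   [stage_seed()], so stages can be replayed in isolation.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            counts_path = NULL, tpm_path = NULL,
                            samples_path = NULL,
                            filter_threshold = 2,
                            de = de_config(),
                            comparisons = default_comparisons(),
                            signatures = NULL,
                            s = 10000,
                            network = list(sample_all_threshold = 0.99,
                                           sample_de_threshold = 0.93,
                                           gene_threshold = 0.90,
                                           inflation = 2.2,
                                           min_size = 3),
                            seed = 1) {
  if (is.null(sim) &&
      (is.null(counts_path) || is.null(tpm_path) || is.null(samples_path))) {
    stop("either a sim_config or counts/tpm/samples paths are required")
  }
  thr <- unlist(network[c("sample_all_threshold", "sample_de_threshold",
                          "gene_threshold")])
  if (any(thr <= 0 | thr > 1)) stop("network thresholds must be in (0, 1]")
  if (length(comparisons) == 0L) stop("at least one comparison is required")
  structure(list(sim = sim, counts_path = counts_path, tpm_path = tpm_path,
                 samples_path = samples_path,
                 filter_threshold = filter_threshold, de = de,
                 comparisons = comparisons, signatures = signatures,
                 s = as.integer(s), network = network,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_comparisons <- function() {
  list(
    `1h_EE_vs_B`  = list(a = list(treatment = "EE", timepoint = "1h"),
                         b = list(treatment = "B", timepoint = "1h")),
    `4h_EE_vs_B`  = list(a = list(treatment = "EE", timepoint = "4h"),
                         b = list(treatment = "B", timepoint = "4h")),
    `all_EE_vs_B` = list(a = list(treatment = "EE"),
                         b = list(treatment = "B")))
}

# resolve a selector (list with optional treatment/timepoint) to sample ids
select_samples <- function(samples, selector) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(selector$treatment)) {
    keep <- keep & samples$treatment %in% selector$treatment
  }
  if (!is.null(selector$timepoint)) {
    keep <- keep & samples$timepoint %in% selector$timepoint
  }
  samples$sample_id[keep]
}

#' Run the full enrichment analysis pipeline
#'
#' Simulates or loads the data, filters lowly expressed genes once (the
#' same filtered universe feeds every comparison), TMM-normalises, then per
#' comparison estimates fold changes, tests gene-wise and calls DE; runs
#' the signature randomisation test for every signature on every
#' comparison; and builds, clusters (MCL) and exports the three
#' correlation graphs. All tables are written as TSV under `out_dir`,
#' together with `de_summary.json` and a `manifest.json` recording the
#' configuration, its hash, and every derived stage seed, which suffices to
#' reproduce the outputs bit-exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with the data, retained gene ids, TMM
#'   factors, per-comparison `de` results and summaries, `randomization`
#'   results, `networks` (graph + clustering per network), and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_seeds <- list()
  t0 <- Sys.time()

  # --- data ------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, "simulate")
    stage_seeds$simulate <- sim_cfg$seed
    say("stage data: simulating %d genes x %d-litter design",
        sim_cfg$n_genes, sim_cfg$n_litters)
    sim <- simulate_experiment(sim_cfg)
    counts <- sim$counts; tpm <- sim$tpm; samples <- sim$samples
    write_expression_matrix(counts, file.path(out_dir, "counts.tsv"))
    write_expression_matrix(tpm, file.path(out_dir, "tpm.tsv"))
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    say("stage data: reading matrices")
    sim <- NULL
    counts <- read_expression_matrix(config$counts_path, "counts")
    tpm <- read_expression_matrix(config$tpm_path, "TPM")
    samples <- read_sample_table(config$samples_path)
  }
  write_sample_table(samples, file.path(out_dir, "samples.tsv"))

  signatures <- config$signatures
  if (is.null(signatures)) {
    if (is.null(sim)) stop("signatures are required when reading from files")
    signatures <- list(
      IEG = gene_signature("IEG",
                           sim$truth$gene_id[sim$truth$signature == "IEG"],
                           "up"),
      microglia = gene_signature("microglia",
                                 sim$truth$gene_id[sim$truth$signature == "microglia"],
                                 "down"))
  }
  write_gmt_signatures(signatures, file.path(out_dir, "signatures.gmt"))

  # --- filter + normalise ---------------------------------------------
  retained <- filter_low_expression(tpm, samples, config$filter_threshold)
  say("stage filter: %d of %d genes retained at %g TPM", length(retained),
      nrow(tpm), config$filter_threshold)
  if (length(retained) < 2L) stop("stage filter: fewer than 2 genes retained")
  counts_f <- counts[retained, ]
  tpm_f <- tpm[retained, ]
  writeLines(retained, file.path(out_dir, "retained_genes.txt"))
  factors <- tmm_factors(counts_f)
  cpm <- cpm_matrix(counts_f, factors)
  say("stage normalise: TMM factors in [%.3f, %.3f]", min(factors), max(factors))

  # --- differential expression ----------------------------------------
  de_results <- list(); de_summaries <- list(); fcs <- list()
  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    ids_a <- select_samples(samples, cmp$a)
    ids_b <- select_samples(samples, cmp$b)
    if (length(ids_a) == 0L || length(ids_b) == 0L) {
      stop("stage de: comparison '", nm, "' selects an empty group")
    }
    if (length(intersect(ids_a, ids_b))) {
      stop("stage de: comparison '", nm, "' groups overlap")
    }
    fc <- fold_changes(cpm, ids_a, ids_b, config$de$prior_count)
    pv <- gene_test(counts_f, ids_a, ids_b, config$de, factors)
    de <- call_de(fc, pv, config$de)
    de_results[[nm]] <- de
    de_summaries[[nm]] <- as.list(de_summary(de))
    fcs[[nm]] <- fc
    write.table(de, file.path(out_dir, paste0("de_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("stage de: %s -> %d up, %d down", nm,
        de_summaries[[nm]]$n_up, de_summaries[[nm]]$n_down)
  }
  jsonlite::write_json(de_summaries, file.path(out_dir, "de_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- signature randomisation ----------------------------------------
  rand_results <- list()
  for (sg in signatures) {
    sg_eff <- intersect_signature(sg, retained, quiet = quiet)
    for (nm in names(fcs)) {
      key <- paste(sg$name, nm, sep = ".")
      sd_ <- stage_seed(config$seed, paste0("randomization/", key))
      stage_seeds[[paste0("randomization/", key)]] <- sd_
      res <- randomization_test(fcs[[nm]], sg_eff, s = config$s, seed = sd_)
      res$comparison <- nm
      rand_results[[key]] <- res
      say("stage randomization: %s on %s -> p = %.3g", sg$name, nm, res$p_value)
    }
  }
  rt <- randomization_table(rand_results)
  rt$comparison <- vapply(rand_results, `[[`, "", "comparison")
  write.table(rt, file.path(out_dir, "randomization_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- networks --------------------------------------------------------
  de_genes <- unique(unlist(lapply(de_results, function(d) {
    d$gene_id[d$call != "none"]
  })))
  say("stage network: %d DE genes across comparisons", length(de_genes))
  node_data <- samples[, c("sample_id", "litter", "treatment", "timepoint")]
  networks <- list()
  net <- config$network
  networks$samples_all <- pipeline_network(
    tpm_f, "samples", net$sample_all_threshold, net, node_data,
    out_dir, "samples_all", say)
  if (length(de_genes) >= 2L) {
    networks$samples_de <- pipeline_network(
      tpm_f[de_genes, ], "samples", net$sample_de_threshold, net, node_data,
      out_dir, "samples_de", say)
    networks$genes_de <- pipeline_network(
      tpm_f[de_genes, ], "genes", net$gene_threshold, net, NULL,
      out_dir, "genes_de", say)
  } else {
    warning("fewer than 2 DE genes; DE-gene networks skipped")
  }

  manifest <- list(
    package = "enrichseq",
    version = as.character(utils::packageVersion("enrichseq")),
    r_version = R.version.string,
    master_seed = config$seed,
    stage_seeds = stage_seeds,
    config = rapply(unclass(config), unclass, how = "replace"),
    config_hash = rlang::hash(config),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  say("pipeline done in %.1f s", manifest$elapsed_sec)
  invisible(list(sim = sim, counts = counts, tpm = tpm, samples = samples,
                 retained = retained, factors = factors,
                 fold_changes = fcs, de = de_results,
                 de_summary = de_summaries, randomization = rand_results,
                 networks = networks, manifest = manifest))
}

# build, cluster and export one network stage
pipeline_network <- function(expr, axis, threshold, net, node_data, out_dir,
                             tag, say) {
  graph <- correlation_graph(expr, axis = axis, threshold = threshold)
  clustering <- mcl_cluster(graph, inflation = net$inflation,
                            min_size = net$min_size)
  say("stage network: %s -> %d edges, %d clusters", tag, nrow(graph$edges),
      length(clustering$sizes))
  export_graphml(graph, file.path(out_dir, paste0("network_", tag, ".graphml")),
                 clustering = clustering, node_data = node_data)
  write.table(
    data.frame(node = names(clustering$membership),
               cluster = unname(clustering$membership),
               stringsAsFactors = FALSE),
    file.path(out_dir, paste0("clusters_", tag, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  list(graph = graph, clustering = clustering)
}
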