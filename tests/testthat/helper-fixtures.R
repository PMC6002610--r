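# shared helpers: small fixtures built in code, plus independent oracles

ari <- mclust::adjustedRandIndex

# connected components of a correlation_graph, independent of mcl_cluster
graph_components <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = graph$nodes)
  igraph::components(g)$membership[graph$nodes]
}

# tiny labelled count matrix with reproducible noise
toy_counts <- function(n_genes = 20, n_samples = 4, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  expression_matrix(m, "counts")
}

toy_samples <- function(n_litters = 2) {
  grid <- expand.grid(litter = sprintf("L%d", seq_len(n_litters)),
                      treatment = c("EE", "B"), timepoint = c("1h", "4h"),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste(grid$litter, grid$treatment, grid$timepoint,
                               sep = "_"),
             grid, sex = "M", stringsAsFactors = FALSE)
}

# independent TMM oracle: explicit loops and sort-position trimming of the
# weighted trimmed mean of M-values (positions equivalent to ranks for
# distinct values)
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  x <- unclass(counts)
  lib <- colSums(x)
  f75 <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) f75[j] <- quantile(x[, j], 0.75) / lib[j]
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    M <- A <- W <- numeric(0)
    for (g in seq_len(nrow(x))) {
      po <- x[g, j] / lib[j]
      pr <- x[g, ref] / lib[ref]
      if (po > 0 && pr > 0) {
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        W <- c(W, 1 / ((lib[j] - x[g, j]) / (lib[j] * x[g, j]) +
                         (lib[ref] - x[g, ref]) / (lib[ref] * x[g, ref])))
      }
    }
    if (length(M) == 0 || max(abs(M)) < 1e-6) {
      fac[j] <- 1
    } else {
      n <- length(M)
      keep_m <- order(M)[(floor(n * logratio_trim) + 1):(n - floor(n * logratio_trim))]
      keep_a <- order(A)[(floor(n * sum_trim) + 1):(n - floor(n * sum_trim))]
      keep <- intersect(keep_m, keep_a)
      fac[j] <- 2^(sum(M[keep] * W[keep]) / sum(W[keep]))
    }
  }
  fac / exp(mean(log(fac)))
}
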