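#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample normalisation for count data following the published TMM
#' definition. The reference sample is the one whose upper-quartile of
#' library-size-scaled counts is closest to the mean upper-quartile. For
#' each sample, the factor is `2^m` where `m` is the weighted mean of the
#' gene-wise log2 expression ratios against the reference (M-values), after
#' trimming the most extreme 30% of M-values and 5% of average log
#' expression (A-values) on each side; weights are the inverse asymptotic
#' binomial variances. Factors are finally scaled so their log-mean is zero
#' (their product is 1).
#'
#' @param counts a counts [expression_matrix()] or nonnegative matrix with
#'   at least two samples.
#' @param logratio_trim two-sided trim fraction for M-values (default 0.3).
#' @param sum_trim two-sided trim fraction for A-values (default 0.05).
#' @param ref_column optional reference column index overriding the
#'   upper-quartile choice.
#' @return a named vector of positive per-sample factors.
#' @export
#' @examples
#' m <- matrix(rpois(200, 50), 20,
#'             dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
#' tmm_factors(m)
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        ref_column = NULL) {
  x <- unclass(counts)
  attr(x, "unit") <- NULL
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("TMM needs at least two samples")
  if (any(x < 0)) stop("counts must be nonnegative")
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ", paste(colnames(x)[lib == 0], collapse = ", "))
  }
  if (is.null(ref_column)) {
    f75 <- apply(x, 2L, function(u) quantile(u, p = 0.75)) / lib
    ref_column <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, ref_column], lib[j], lib[ref_column],
             logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

# single-pair TMM: weighted trimmed mean of M-values of obs against ref
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  m <- log2((obs / n_obs) / (ref / n_ref))                 # M-values
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2          # A-values
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Counts per million on TMM-effective library sizes
#'
#' `CPM_gj = count_gj / (libsize_j * factor_j) * 1e6`. With identity
#' factors each column sums to 1e6; doubling every count of a library
#' leaves its CPM unchanged.
#'
#' @param counts a counts [expression_matrix()] or matrix.
#' @param factors per-sample scaling factors (default [tmm_factors()];
#'   use `rep(1, ncol(counts))` for plain CPM).
#' @return a CPM `expr_matrix`.
#' @export
cpm_matrix <- function(counts, factors = tmm_factors(counts)) {
  x <- unclass(counts)
  attr(x, "unit") <- NULL
  storage.mode(x) <- "double"
  if (length(factors) != ncol(x)) stop("one factor per sample is required")
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("scaling factors must be strictly positive")
  }
  eff <- colSums(x) * factors
  expression_matrix(sweep(x, 2L, eff, "/") * 1e6, "CPM")
}
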