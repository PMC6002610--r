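#' Median log2 fold change of a signature
#'
#' Median of the signature genes' log2 fold changes over the genes present
#' in the supplied vector (even-size medians average the two central
#' values). Because log2 is strictly monotone, comparisons of these medians
#' between equal-size sets are identical to comparisons of raw fold-change
#' medians.
#'
#' @param fold_changes named per-gene log2 fold-change vector.
#' @param signature a [gene_signature()].
#' @return the median, a single number.
#' @export
signature_median_fc <- function(fold_changes, signature) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(names(fold_changes))) stop("fold_changes must be named by gene id")
  hit <- intersect(signature$genes, names(fold_changes))
  if (length(hit) == 0L) {
    stop("signature '", signature$name,
         "' has no genes among the quantified fold changes")
  }
  stats::median(fold_changes[hit])
}

#' Signature randomisation test on median fold changes
#'
#' One-sided resampling test for whether a gene signature's median fold
#' change is extreme relative to random gene sets of the same size. Subsets
#' of `x` genes (the effective signature size after intersection with the
#' quantified universe) are drawn uniformly without replacement, `s` times,
#' from the full universe (signature genes included). `q` counts the draws
#' the signature strictly beats in its direction (`up`: subset median below
#' the signature median; `down`: above; ties never count). With
#' `r = s - q`, the p-value is `(r + 1) / (s + 1)`, so its attainable floor
#' is `1 / (s + 1)` (9.999e-05 at the default `s` = 10,000).
#'
#' @param fold_changes named per-gene log2 fold-change vector over the
#'   analysed (post-filter) universe.
#' @param signature a [gene_signature()] with a direction.
#' @param s number of random subsets (default 10,000).
#' @param seed optional integer seed; recorded in the result for replay, and
#'   the draws depend only on it (not on the direction), so negating all
#'   fold changes and flipping the direction reproduces the same `q`.
#' @return a list of class `randomization_result` with fields
#'   `signature_name`, `direction`, `x`, `s`, `q`, `r`, `p_value`,
#'   `signature_median`, `seed`.
#' @export
#' @examples
#' fc <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
#' sig <- gene_signature("top", names(sort(fc, decreasing = TRUE))[1:20], "up")
#' randomization_test(fc, sig, s = 999, seed = 1)
randomization_test <- function(fold_changes, signature, s = 10000,
                               seed = NULL) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(names(fold_changes))) stop("fold_changes must be named by gene id")
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("s must be a positive integer")
  universe <- names(fold_changes)
  n <- length(universe)
  hit <- intersect(signature$genes, universe)
  x <- length(hit)
  if (x == 0L) {
    stop("signature '", signature$name,
         "' has no genes among the quantified fold changes")
  }
  if (x > n) stop("signature larger than the gene universe")
  sig_med <- stats::median(fold_changes[hit])
  vals <- unname(fold_changes)

  meds <- with_rng_seed(seed, {
    out <- numeric(s)
    for (i in seq_len(s)) {
      out[i] <- fast_median(vals[sample.int(n, x)])
    }
    out
  })
  q <- if (signature$direction == "up") sum(meds < sig_med) else sum(meds > sig_med)
  r <- s - q
  structure(list(signature_name = signature$name,
                 direction = signature$direction,
                 x = x, s = s, q = q, r = r,
                 p_value = (r + 1) / (s + 1),
                 signature_median = sig_med,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomisation test '%s' (%s): x = %d, s = %d, q = %d, median log2FC = %.4g\n  p = (r+1)/(s+1) = %.4g\n",
    x$signature_name, x$direction, x$x, x$s, x$q, x$signature_median,
    x$p_value))
  invisible(x)
}

#' @rdname randomization_test
#' @param results a list of `randomization_result` objects.
#' @return `randomization_table()`: one data.frame row per result.
#' @export
randomization_table <- function(results) {
  if (inherits(results, "randomization_result")) results <- list(results)
  do.call(rbind, lapply(results, function(z) {
    data.frame(signature_name = z$signature_name, direction = z$direction,
               x = z$x, s = z$s, q = z$q, r = z$r, p_value = z$p_value,
               signature_median = z$signature_median, seed = z$seed,
               stringsAsFactors = FALSE)
  }))
}
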