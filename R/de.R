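#' Differential expression settings
#'
#' Threshold-based DE calling: a gene is differentially expressed when its
#' between-group fold change exceeds `fc_threshold` (inclusive on the log2
#' scale) AND its p-value is strictly below `p_threshold`. The defaults
#' (fold change 1.2, p < 0.02, no multiplicity correction) deliberately
#' trade power for a conservative, low-noise gene list.
#'
#' @param fc_threshold fold-change threshold, `> 1` (default 1.2).
#' @param p_threshold p-value threshold in (0, 1) (default 0.02).
#' @param prior_count pseudo-count added on the CPM scale to stabilise fold
#'   changes and log transforms at zero counts (default 0.5).
#' @param test gene-wise test: `"welch_logcpm"` (Welch's t on
#'   `log2(CPM + prior)`, needs >= 2 samples per group) or `"nb_exact_mom"`
#'   (negative binomial exact-style test with method-of-moments common
#'   dispersion, usable down to 1 sample per group).
#' @return a list of class `de_config`.
#' @export
de_config <- function(fc_threshold = 1.2, p_threshold = 0.02,
                      prior_count = 0.5,
                      test = c("welch_logcpm", "nb_exact_mom")) {
  test <- match.arg(test)
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (prior_count < 0) stop("prior_count must be nonnegative")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 prior_count = prior_count, test = test),
            class = "de_config")
}

#' Per-gene log2 fold changes between two sample groups
#'
#' `log2fc = log2((mean_a + prior) / (mean_b + prior))` on group means of
#' the supplied (typically CPM) matrix; always finite thanks to the prior.
#'
#' @param expr an [expression_matrix()] (CPM recommended).
#' @param group_a,group_b nonempty vectors of sample ids (group A minus
#'   group B on the log scale, e.g. EE minus B).
#' @param prior_count pseudo-count (default 0.5).
#' @return named numeric vector of log2 fold changes.
#' @export
fold_changes <- function(expr, group_a, group_b, prior_count = 0.5) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  vals <- unclass(expr)
  ma <- rowMeans(vals[, group_a, drop = FALSE])
  mb <- rowMeans(vals[, group_b, drop = FALSE])
  fc <- log2((ma + prior_count) / (mb + prior_count))
  names(fc) <- rownames(expr)
  fc
}

#' Gene-wise two-group test
#'
#' Computes a two-sided p-value per gene for a difference between two sample
#' groups. The default Welch test works on `log2(CPM + prior)` with
#' per-group variances; genes with zero variance in both groups get p = 1
#' when the means agree and p = 0 otherwise (never NaN). The negative
#' binomial alternative conditions each gene's (library-adjusted) group
#' sums on their total, with a common method-of-moments dispersion, and is
#' usable with a single sample per group.
#'
#' @param counts a counts [expression_matrix()].
#' @param group_a,group_b sample id vectors.
#' @param config a [de_config()].
#' @param factors optional TMM factors (computed if missing).
#' @return named numeric vector of p-values in `[0, 1]`.
#' @export
gene_test <- function(counts, group_a, group_b, config = de_config(),
                      factors = NULL) {
  stopifnot(inherits(config, "de_config"))
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (config$test == "welch_logcpm") {
    if (length(group_a) < 2L || length(group_b) < 2L) {
      stop("welch_logcpm needs >= 2 samples per group; ",
           "use test = 'nb_exact_mom' for smaller groups")
    }
    y <- log2(unclass(cpm_matrix(counts, factors)) + config$prior_count)
    welch_rows(y[, group_a, drop = FALSE], y[, group_b, drop = FALSE])
  } else {
    nb_exact_mom_test(counts, group_a, group_b, factors)
  }
}

# vectorised Welch's t over matrix rows
welch_rows <- function(ya, yb) {
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- rowSums((ya - ma)^2) / (na - 1)
  vb <- rowSums((yb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, length(ma))
  degen <- se2 == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  ok <- !degen
  tt <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
  p[ok] <- 2 * pt(-abs(tt), df)
  names(p) <- rownames(ya)
  p
}

# NB exact-style test: per gene, scale counts to a common effective library,
# estimate a common dispersion by method of moments, then compute the
# conditional two-sided p of the observed split of the gene's total between
# the groups (normal approximation for very large totals)
nb_exact_mom_test <- function(counts, group_a, group_b, factors,
                              exact_total_cap = 10000L) {
  x <- unclass(counts)
  attr(x, "unit") <- NULL
  eff <- colSums(x) * factors
  names(eff) <- colnames(x)
  l0 <- exp(mean(log(eff[c(group_a, group_b)])))
  pa <- sweep(x[, group_a, drop = FALSE], 2L, l0 / eff[group_a], "*")
  pb <- sweep(x[, group_b, drop = FALSE], 2L, l0 / eff[group_b], "*")
  na <- length(group_a); nb <- length(group_b)

  both <- cbind(pa, pb)
  m <- rowMeans(both)
  # common dispersion by pooled moments: within-group sums of squares have
  # expectation dfree * (mu + phi * mu^2), aggregated over genes so the
  # small-sample skew of per-gene variances does not bias phi downwards
  ss <- rowSums((pa - rowMeans(pa))^2) + rowSums((pb - rowMeans(pb))^2)
  dfree <- max(na - 1, 0) + max(nb - 1, 0)
  if (dfree > 0) {
    ok <- m > 0
    phi <- sum(ss[ok] - dfree * m[ok]) / (dfree * sum(m[ok]^2))
    phi <- max(phi, 0)
  } else {
    phi <- 0
  }
  size1 <- if (phi > 0) 1 / phi else 1e8

  sa <- round(rowSums(pa)); sb <- round(rowSums(pb))
  p <- vapply(seq_len(nrow(x)), function(g) {
    tot <- sa[g] + sb[g]
    if (tot == 0) return(1)
    mu0 <- tot / (na + nb)
    if (tot <= exact_total_cap) {
      k <- 0:tot
      lp <- dnbinom(k, size = na * size1, mu = na * mu0, log = TRUE) +
        dnbinom(tot - k, size = nb * size1, mu = nb * mu0, log = TRUE)
      pr <- exp(lp - max(lp))
      pr <- pr / sum(pr)
      pobs <- pr[sa[g] + 1]
      min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
    } else {
      v <- mu0 * (1 / na + 1 / nb) + phi * mu0^2 * (1 / na + 1 / nb)
      z <- (sa[g] / na - sb[g] / nb) / sqrt(v)
      2 * pnorm(-abs(z))
    }
  }, numeric(1))
  names(p) <- rownames(x)
  p
}

#' Call differentially expressed genes
#'
#' Applies the two-threshold rule of [de_config()]: call `"up"` when
#' `log2fc >= log2(fc_threshold)` and `p < p_threshold`, `"down"`
#' symmetrically, otherwise `"none"`.
#'
#' @param log2fc named log2 fold-change vector ([fold_changes()]).
#' @param p_values aligned p-value vector ([gene_test()]).
#' @param config a [de_config()].
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `log2fc`, `p_value`, `call`.
#' @export
call_de <- function(log2fc, p_values, config = de_config()) {
  stopifnot(inherits(config, "de_config"))
  if (length(log2fc) != length(p_values)) {
    stop("log2fc and p_values must be aligned")
  }
  if (!is.null(names(log2fc)) && !is.null(names(p_values)) &&
      !identical(names(log2fc), names(p_values))) {
    stop("log2fc and p_values have mismatched gene ids")
  }
  lfc_cut <- log2(config$fc_threshold)
  call <- rep("none", length(log2fc))
  call[log2fc >= lfc_cut & p_values < config$p_threshold] <- "up"
  call[log2fc <= -lfc_cut & p_values < config$p_threshold] <- "down"
  res <- data.frame(
    gene_id = if (is.null(names(log2fc))) seq_along(log2fc) else names(log2fc),
    log2fc = unname(log2fc), p_value = unname(p_values),
    call = factor(call, levels = c("up", "down", "none")),
    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @rdname call_de
#' @param de a `de_result`.
#' @return `de_summary()`: named integer vector `c(n_up, n_down)`.
#' @export
de_summary <- function(de) {
  c(n_up = sum(de$call == "up"), n_down = sum(de$call == "down"))
}
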