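#' Expression matrix with a unit tag
#'
#' A light wrapper around a numeric genes-by-samples matrix that records the
#' measurement unit and validates its labels: gene and sample ids must be
#' unique and all values finite. Counts, TPM and CPM must be nonnegative;
#' `log2` matrices may be negative.
#'
#' @param values numeric matrix (genes in rows, samples in columns) with
#'   rownames and colnames, or coercible to one.
#' @param unit one of `"counts"`, `"TPM"`, `"CPM"`, `"log2"`.
#' @param gene_ids,sample_ids optional label vectors overriding the dimnames.
#' @return a numeric matrix of class `expr_matrix` with a `unit` attribute.
#' @export
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "counts")
expression_matrix <- function(values, unit = c("counts", "TPM", "CPM", "log2"),
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs gene ids (rownames) and sample ids (colnames)")
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("label lengths do not match matrix dimensions")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must all be finite")
  if (unit != "log2" && any(values < 0)) {
    stop("negative values are not allowed for unit '", unit, "'")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

#' @export
`[.expr_matrix` <- function(x, i, j, drop = FALSE) {
  u <- expr_unit(x)
  m <- unclass(x)
  attr(m, "unit") <- NULL
  out <- m[i, j, drop = drop]
  if (is.matrix(out)) out <- expression_matrix(out, unit = u)
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              expr_unit(x), nrow(x), ncol(x)))
  nr <- min(5L, nrow(x)); nc <- min(5L, ncol(x))
  print(unclass(x)[seq_len(nr), seq_len(nc), drop = FALSE])
  if (nrow(x) > nr || ncol(x) > nc) cat("...\n")
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample design table used throughout the pipeline: required
#' columns `sample_id`, `litter`, `treatment` (EE or B), `timepoint`
#' (1h or 4h) and `sex` (M or F), with unique sample ids.
#'
#' @param samples a data.frame.
#' @return the validated data.frame (character columns), invisibly usable.
#' @export
sample_table <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "litter", "treatment", "timepoint", "sex")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  for (cc in need) samples[[cc]] <- as.character(samples[[cc]])
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (!all(samples$treatment %in% c("EE", "B"))) {
    stop("treatment must be 'EE' or 'B'")
  }
  if (!all(samples$timepoint %in% c("1h", "4h"))) {
    stop("timepoint must be '1h' or '4h'")
  }
  if (!all(samples$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  samples
}

#' Directed gene signature
#'
#' A named gene set with the direction of change expected under enrichment:
#' `"up"` for activity-induced sets (immediate early genes), `"down"` for
#' sets expected to drop (microglial markers).
#'
#' @param name signature name.
#' @param genes character vector of gene ids (deduplicated, nonempty).
#' @param direction `"up"` or `"down"`.
#' @return an object of class `gene_signature`.
#' @export
#' @examples
#' gene_signature("IEG", c("FOS", "ARC", "EGR1"), "up")
gene_signature <- function(name, genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0L) stop("signature '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes, direction = direction),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s' (%s): %d genes\n", x$name, x$direction,
              length(x$genes)))
  invisible(x)
}

#' Restrict a signature to the genes present in a matrix
#'
#' Intersects a signature with an analysed gene universe, reporting how many
#' members were found; the size after intersection is the effective `x` of
#' the randomisation test. An empty intersection is an error, never silent.
#'
#' @param signature a [gene_signature()].
#' @param gene_ids character vector of analysed gene ids.
#' @param quiet suppress the message.
#' @return a `gene_signature` containing only the intersecting genes.
#' @export
intersect_signature <- function(signature, gene_ids, quiet = FALSE) {
  stopifnot(inherits(signature, "gene_signature"))
  kept <- intersect(signature$genes, gene_ids)
  if (length(kept) == 0L) {
    stop("signature '", signature$name,
         "' has no genes in common with the analysed matrix")
  }
  if (!quiet) {
    message(sprintf("signature '%s': %d of %d genes present in matrix",
                    signature$name, length(kept), length(signature$genes)))
  }
  gene_signature(signature$name, kept, signature$direction)
}
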