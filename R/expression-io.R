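#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and gene ids
#' in the first column. Parse problems (ragged rows, duplicate ids,
#' non-numeric cells) raise errors naming the offending line or label.
#'
#' @param path file path.
#' @param unit measurement unit of the stored values (see
#'   [expression_matrix()]).
#' @return an [expression_matrix()], with the file's row and column order
#'   preserved.
#' @export
read_expression_matrix <- function(path, unit = c("counts", "TPM", "CPM", "log2")) {
  unit <- match.arg(unit)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: line ", bad, " of '", path, "' has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs a gene id column and >=1 sample")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id(s) in '", path, "': ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric value '", col[bad[1L]], "' at gene '",
             gene_ids[bad[1L]], "', sample '", names(body)[j], "'")
      }
      body[[j]] <- num
    }
  }
  values <- as.matrix(body)
  rownames(values) <- gene_ids
  expression_matrix(values, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (`gene_id` header), one column per sample.
#'
#' @param x an [expression_matrix()] or labelled numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' TSV with columns `sample_id`, `litter`, `treatment`, `timepoint`, `sex`;
#' validated by [sample_table()].
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_sample_table <- function(path) {
  sample_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE))
}

#' @rdname read_sample_table
#' @param samples a sample metadata data.frame.
#' @export
write_sample_table <- function(samples, path) {
  write.table(sample_table(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Parses the tab-separated GMT gene-set format (set name, description,
#' member genes) and attaches a direction to each set. Sets are returned
#' verbatim; intersection with an analysed matrix is a separate, logged step
#' ([intersect_signature()]).
#'
#' @param path GMT file path.
#' @param directions either a single direction recycled to all sets, or a
#'   named character vector mapping set names to `"up"`/`"down"`.
#' @return a named list of [gene_signature()] objects.
#' @export
read_gmt_signatures <- function(path, directions = "up") {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L) stop("no gene sets found in '", path, "'")
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (nm in names(sets)) {
    dir <- if (length(directions) == 1L && is.null(names(directions))) {
      directions
    } else {
      if (!nm %in% names(directions)) {
        stop("no direction given for signature '", nm, "'")
      }
      directions[[nm]]
    }
    out[[nm]] <- gene_signature(nm, sets[[nm]], dir)
  }
  out
}

#' @rdname read_gmt_signatures
#' @param signatures a list of [gene_signature()] objects.
#' @export
write_gmt_signatures <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, paste0("direction=", s$direction), s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Sum transcript-level values to gene level
#'
#' Collapses a transcript-by-sample matrix to gene level by summing each
#' gene's transcripts, for counts and TPM alike. Transcripts absent from the
#' map are dropped (with a reported count) rather than promoted to singleton
#' genes. Per-sample totals over mapped transcripts are conserved exactly.
#'
#' @param tx transcript-level [expression_matrix()].
#' @param tx2gene data.frame with columns `transcript_id` and `gene_id` (or
#'   first two columns in that order).
#' @param quiet suppress the dropped-transcript message.
#' @return a gene-level `expr_matrix` with one row per distinct mapped gene,
#'   in the sorted gene-id order produced by the aggregation.
#' @export
aggregate_transcripts_to_genes <- function(tx, tx2gene, quiet = FALSE) {
  tx2gene <- as.data.frame(tx2gene, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(tx2gene))) {
    names(tx2gene)[1:2] <- c("transcript_id", "gene_id")
  }
  map <- stats::setNames(as.character(tx2gene$gene_id),
                         as.character(tx2gene$transcript_id))
  tx_ids <- rownames(tx)
  mapped <- tx_ids %in% names(map)
  n_drop <- sum(!mapped)
  if (n_drop > 0L && !quiet) {
    message(sprintf("dropping %d unmapped transcript(s) of %d", n_drop,
                    length(tx_ids)))
  }
  if (!any(mapped)) stop("no transcript of the matrix is present in the map")
  u <- expr_unit(tx)
  if (is.null(u)) u <- "counts"
  vals <- unclass(tx)[mapped, , drop = FALSE]
  genes <- map[rownames(vals)]
  agg <- rowsum(vals, group = genes, reorder = TRUE)
  expression_matrix(agg, unit = u)
}

#' Filter lowly expressed genes by group-wise TPM
#'
#' Removes genes whose expression fails a TPM threshold in one or both
#' treatment groups, treating such genes as noise. The per-group summary is
#' the median TPM across that group's samples (both timepoints pooled, so a
#' single filtered universe serves every comparison); a gene is retained iff
#' the summary is `>= threshold` (inclusive) in the EE group AND in the B
#' group.
#'
#' @param tpm a TPM [expression_matrix()].
#' @param samples sample metadata covering the matrix columns, with both
#'   treatments present.
#' @param threshold TPM threshold (default 2).
#' @param summary group summary function, default [stats::median].
#' @return character vector of retained gene ids, input order preserved.
#' @export
filter_low_expression <- function(tpm, samples, threshold = 2,
                                  summary = stats::median) {
  if (inherits(tpm, "expr_matrix") && !identical(expr_unit(tpm), "TPM")) {
    stop("the expression filter is defined on TPM; got unit '",
         expr_unit(tpm), "'")
  }
  samples <- sample_table(samples)
  samples <- samples[match(colnames(tpm), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("sample metadata does not cover all matrix columns")
  for (grp in c("EE", "B")) {
    if (!any(samples$treatment == grp)) {
      stop("treatment group '", grp, "' has no samples")
    }
  }
  vals <- unclass(tpm)
  ee <- vals[, samples$treatment == "EE", drop = FALSE]
  bb <- vals[, samples$treatment == "B", drop = FALSE]
  keep <- apply(ee, 1L, summary) >= threshold & apply(bb, 1L, summary) >= threshold
  rownames(tpm)[keep]
}
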