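#' Expression set: counts plus derived layers and sample metadata
#'
#' A light container for a genes-by-samples experiment. Layers are filled in
#' by [compute_tpm()] and [transform_expression()]:
#' \describe{
#'   \item{counts}{non-negative integer counts}
#'   \item{tpm}{transcripts per million; columns sum to 1e6}
#'   \item{tpm_log}{log2(TPM + 1)}
#'   \item{tpm_rat}{log2(TPM / per-gene mean TPM over the analysis samples)}
#' }
#'
#' @param counts Genes-by-samples numeric matrix with dimnames.
#' @param samples data.frame with columns `sample`, `line`, `treatment`,
#'   `is_parent`, `replicate`; rows match `colnames(counts)`.
#' @param genes Gene annotation data.frame with columns `gene`, `chrom`,
#'   `start`, `end`, `length`; rows match `rownames(counts)`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(counts, samples, genes) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0),
            identical(colnames(counts), samples$sample),
            identical(rownames(counts), genes$gene),
            all(genes$start <= genes$end), all(genes$length > 0))
  structure(list(counts = counts, tpm = NULL, tpm_log = NULL, tpm_rat = NULL,
                 samples = samples, genes = genes),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d parental, %d lines)\n",
              nrow(x$counts), ncol(x$counts), sum(x$samples$is_parent),
              length(unique(x$samples$line))))
  layers <- c("counts", "tpm", "tpm_log", "tpm_rat")
  cat("layers:", paste(layers[!vapply(x[layers], is.null, TRUE)],
                       collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression set by genes and/or samples
#'
#' @param x An `expr_set`.
#' @param genes,samples Character vectors of ids to keep (NULL = all).
#' @return The subset `expr_set`; computed layers are carried over
#'   unchanged (TPM and its transforms are not recomputed on the subset).
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else
    match(genes, rownames(x$counts))
  si <- if (is.null(samples)) seq_len(ncol(x$counts)) else
    match(samples, colnames(x$counts))
  stopifnot(!anyNA(gi), !anyNA(si))
  for (layer in c("counts", "tpm", "tpm_log", "tpm_rat"))
    if (!is.null(x[[layer]])) x[[layer]] <- x[[layer]][gi, si, drop = FALSE]
  x$samples <- x$samples[si, , drop = FALSE]
  x$genes <- x$genes[gi, , drop = FALSE]
  x
}
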