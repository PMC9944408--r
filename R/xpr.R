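#' Compute transcripts per million (TPM)
#'
#' TPM for gene g in sample j is the length-normalized count rate scaled to
#' one million: `(count/length) / sum_g(count/length) * 1e6`. Columns of the
#' resulting layer each sum to 1e6, so TPM is invariant to library size.
#'
#' @param em An `expr_set` with a counts layer.
#' @return `em` with the `tpm` layer filled.
#' @export
compute_tpm <- function(em) {
  stopifnot(inherits(em, "expr_set"))
  rate <- em$counts / em$genes$length
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(em$counts)[tot == 0], collapse = ", "))
  em$tpm <- sweep(rate, 2, tot, "/") * 1e6
  em
}

#' Log and mean-ratio transforms of TPM
#'
#' Adds two layers: `tpm_log = log2(TPM + 1)`, used for linear-model tests,
#' and `tpm_rat = log2(TPM / mean TPM of the gene over all samples of the
#' analysis set)`, used for ordination. Genes with a zero TPM in any sample
#' get non-finite `tpm_rat` entries; remove them with [filter_expressed()]
#' before using that layer.
#'
#' @param em An `expr_set` with a `tpm` layer.
#' @return `em` with `tpm_log` and `tpm_rat` filled.
#' @export
transform_expression <- function(em) {
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm))
  em$tpm_log <- log2(em$tpm + 1)
  em$tpm_rat <- log2(em$tpm / rowMeans(em$tpm))
  em
}

#' Filter to genes expressed in every sample
#'
#' Keeps genes with `tpm_log > 0` (equivalently TPM > 0) in every sample of
#' the analysis set, so downstream transforms are finite everywhere. The
#' mean-ratio layer is recomputed on the retained gene set.
#'
#' @param em An `expr_set` with transforms computed.
#' @return The filtered `expr_set`.
#' @export
filter_expressed <- function(em) {
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm_log))
  keep <- rownames(em$counts)[apply(em$tpm_log > 0, 1, all)]
  out <- subset_expr(em, genes = keep)
  out$tpm_rat <- log2(out$tpm / rowMeans(out$tpm))
  out
}

#' Principal component analysis of samples on the mean-ratio layer
#'
#' Runs a centered (unscaled) PCA of the samples-by-genes `tpm_rat` matrix
#' via [stats::prcomp()]; the per-gene mean-ratio transform already places
#' genes on a common scale.
#'
#' @param em A filtered `expr_set` with `tpm_rat` computed.
#' @return A list with `scores` (samples x PCs), `variance_fraction`
#'   (fraction of total variance per component, summing to 1), and the
#'   underlying `prcomp` object.
#' @export
pca_samples <- function(em) {
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm_rat))
  if (ncol(em$tpm_rat) < 2) stop("PCA needs at least 2 samples")
  if (any(!is.finite(em$tpm_rat)))
    stop("tpm_rat has non-finite entries; run filter_expressed() first")
  pc <- stats::prcomp(t(em$tpm_rat), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_fraction = vf, prcomp = pc)
}
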