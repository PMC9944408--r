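#' Per-gene treatment test (one-factor linear model)
#'
#' Fits, per gene, the one-factor least-squares model
#' `tpm_log = treatment + error` over all supplied samples (RILs and
#' parental replicates of both treatments) and tests the treatment term
#' with an F test. The effect estimate is the HP-minus-LN mean difference
#' (positive = more abundant under HP). Genes with zero variance get
#' p = 1 and effect 0. P values are Bonferroni-adjusted by default.
#'
#' @param em An `expr_set` with `tpm_log` computed (the full analysis
#'   sample set).
#' @param adjust `"bonferroni"` or `"BH"`.
#' @param alpha Significance level for the adjusted p.
#' @return data.frame: gene, term, effect, p, p_adj, neg_log10_p,
#'   significant.
#' @export
test_treatment <- function(em, adjust = c("bonferroni", "BH"), alpha = 0.05) {
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm_log))
  adjust <- match.arg(adjust)
  trt <- em$samples$treatment
  lv <- sort(unique(trt))
  if (length(lv) != 2) stop("exactly two treatments required, got: ",
                            paste(lv, collapse = ", "))
  hp <- em$tpm_log[, trt == "HP", drop = FALSE]
  ln <- em$tpm_log[, trt != "HP", drop = FALSE]
  n1 <- ncol(hp); n2 <- ncol(ln); n <- n1 + n2
  m1 <- rowMeans(hp); m2 <- rowMeans(ln)
  ssb <- n1 * n2 / n * (m1 - m2)^2
  sst <- rowSums((em$tpm_log - rowMeans(em$tpm_log))^2)
  ssw <- pmax(sst - ssb, 0)
  f <- ssb / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  zv <- sst == 0
  p[zv] <- 1
  eff <- m1 - m2
  eff[zv] <- 0
  p_adj <- stats::p.adjust(p, method = adjust)
  data.frame(gene = rownames(em$tpm_log), term = "T", effect = eff,
             p = p, p_adj = p_adj, neg_log10_p = -log10(p),
             significant = p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni significance cutoff on the -log10(p) scale
#'
#' @param m Number of tests.
#' @param alpha Family-wise level.
#' @return `-log10(alpha / m)`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  -log10(alpha / m)
}

#' Treatment, line, and interaction test on the parental samples
#'
#' Fits, per gene, the two-way least-squares model
#' `tpm_log = T + L + T:L + error` on the parental replicates (two lines,
#' two treatments, replicated) and tests each term with a sequential F test.
#' P values are Benjamini-Hochberg adjusted per term. The per-term realized
#' -log10(p) cutoff at `alpha` is the largest raw p still significant after
#' adjustment; the overall significance threshold is the most stringent
#' (largest) of the three cutoffs, and a gene is flagged for a term when its
#' -log10(p) exceeds that overall threshold.
#'
#' @param em An `expr_set` (parental samples only) with `tpm_log`.
#' @param alpha FDR level per term.
#' @return List with `results` (data.frame gene, term, effect, p, p_adj,
#'   neg_log10_p, significant), `term_thresholds` (realized -log10(p)
#'   cutoffs per term, NA when no gene is significant for the term) and
#'   `overall_threshold`. Effect signs: treatment positive = higher in HP,
#'   line positive = higher in MM.
#' @export
test_parental_gxe <- function(em, alpha = 0.05) {
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm_log),
            all(em$samples$is_parent))
  trt <- factor(em$samples$treatment, levels = c("LN", "HP"))
  lin <- factor(em$samples$line, levels = c("PI", "MM"))
  if (nlevels(trt) != 2 || nlevels(lin) != 2 ||
      any(table(trt, lin) == 0))
    stop("need both parental lines under both treatments")
  y <- t(em$tpm_log)                      # samples x genes
  n <- nrow(y)
  sse <- function(X) {
    q <- qr(X)
    colSums((y - qr.fitted(q, y))^2)
  }
  X0 <- stats::model.matrix(~ 1, data.frame(trt))
  X1 <- stats::model.matrix(~ trt)
  X2 <- stats::model.matrix(~ trt + lin)
  X3 <- stats::model.matrix(~ trt * lin)
  e0 <- sse(X0); e1 <- sse(X1); e2 <- sse(X2); e3 <- sse(X3)
  df_res <- n - ncol(X3)
  mse <- e3 / df_res
  fstat <- cbind(T = e0 - e1, L = e1 - e2, `T:L` = e2 - e3) / mse
  pmat <- stats::pf(fstat, 1, df_res, lower.tail = FALSE)
  zv <- e0 == 0
  pmat[zv, ] <- 1

  cm <- function(t_, l_) rowMeans(em$tpm_log[, trt == t_ & lin == l_,
                                             drop = FALSE])
  mu <- list(hp_mm = cm("HP", "MM"), hp_pi = cm("HP", "PI"),
             ln_mm = cm("LN", "MM"), ln_pi = cm("LN", "PI"))
  eff <- cbind(
    T = (mu$hp_mm + mu$hp_pi - mu$ln_mm - mu$ln_pi) / 2,
    L = (mu$hp_mm + mu$ln_mm - mu$hp_pi - mu$ln_pi) / 2,
    `T:L` = (mu$hp_mm - mu$hp_pi) - (mu$ln_mm - mu$ln_pi))
  eff[zv, ] <- 0

  genes <- rownames(em$tpm_log)
  res <- do.call(rbind, lapply(colnames(pmat), function(tm) {
    p <- pmat[, tm]
    data.frame(gene = genes, term = tm, effect = eff[, tm], p = p,
               p_adj = stats::p.adjust(p, "BH"), neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  thr <- vapply(colnames(pmat), function(tm) {
    sub <- res[res$term == tm, ]
    sig <- sub$p_adj <= alpha
    if (!any(sig)) NA_real_ else -log10(max(sub$p[sig]))
  }, numeric(1))
  overall <- if (all(is.na(thr))) Inf else max(thr, na.rm = TRUE)
  res$significant <- res$neg_log10_p > overall
  list(results = res, term_thresholds = thr, overall_threshold = overall)
}
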