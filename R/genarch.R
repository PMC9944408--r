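# row-wise sample variance (n-1 denominator)
.rowvar <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1)
}

#' Broad-sense heritability of a trait in a RIL population
#'
#' Estimates H2 = (V_RIL - V_e) / V_RIL, where V_RIL is the sample variance
#' of the trait over the RILs (genetic plus residual variance) and V_e is
#' the pooled variance of the replicated parental lines (residual variance
#' only, since each parent is genetically uniform). The estimate is an
#' upper bound on broad-sense heritability; it can be negative when the
#' parental replicates are noisier than the RIL spread, and is reported as
#' computed.
#'
#' @param ril_values Trait values of the RILs (one per line).
#' @param parent_a_values,parent_b_values Replicate values of each parent.
#' @return List: `v_ril`, `v_e`, `h2` (NA when V_RIL = 0).
#' @export
heritability <- function(ril_values, parent_a_values, parent_b_values) {
  stopifnot(length(ril_values) >= 2, length(parent_a_values) >= 2,
            length(parent_b_values) >= 2)
  v_ril <- stats::var(ril_values)
  na <- length(parent_a_values); nb <- length(parent_b_values)
  v_e <- ((na - 1) * stats::var(parent_a_values) +
            (nb - 1) * stats::var(parent_b_values)) / (na + nb - 2)
  h2 <- if (v_ril == 0) NA_real_ else (v_ril - v_e) / v_ril
  list(v_ril = v_ril, v_e = v_e, h2 = h2)
}

#' Transgressive segregation of a trait in a RIL population
#'
#' Counts RIL values lying strictly beyond three pooled parental standard
#' deviations from the extreme parental means: below
#' (min parental mean) - 3 sigma or above (max parental mean) + 3 sigma,
#' with sigma the pooled parental SD. When sigma = 0 the bounds collapse to
#' the parental means and the result is flagged degenerate.
#'
#' @inheritParams heritability
#' @param n_sd Number of pooled SDs defining the bounds.
#' @return List: `lower`, `upper`, `sigma`, `n_transgressive`, `degenerate`.
#' @export
transgression <- function(ril_values, parent_a_values, parent_b_values,
                          n_sd = 3) {
  stopifnot(length(parent_a_values) >= 2, length(parent_b_values) >= 2)
  na <- length(parent_a_values); nb <- length(parent_b_values)
  sigma <- sqrt(((na - 1) * stats::var(parent_a_values) +
                   (nb - 1) * stats::var(parent_b_values)) / (na + nb - 2))
  ma <- mean(parent_a_values); mb <- mean(parent_b_values)
  lower <- min(ma, mb) - n_sd * sigma
  upper <- max(ma, mb) + n_sd * sigma
  list(lower = lower, upper = upper, sigma = sigma,
       n_transgressive = sum(ril_values < lower | ril_values > upper),
       degenerate = sigma == 0)
}

#' Per-transcript permutation threshold for an architecture statistic
#'
#' Randomly reassigns the observed values over the line designations
#' (preserving the group sizes: RILs and each parent's replicates), recomputes
#' the statistic, and repeats `n_perm` times; the `rank`-th largest permuted
#' statistic is the threshold (rank 50 of 1000 approximates a per-transcript
#' 5\% false-discovery level). The observed statistic is called significant
#' when strictly greater than the threshold.
#'
#' @param statistic `"heritability"` or `"transgression"`.
#' @param values Trait values over all samples (RILs plus parental
#'   replicates).
#' @param line_labels Character vector aligned with `values`: `"RIL"`,
#'   `"MM"` or `"PI"`.
#' @param n_perm Number of permutations.
#' @param rank Which order statistic of the permuted values is the
#'   threshold.
#' @return List: `observed`, `threshold`, `significant`, `perm_stats`.
#' @export
permutation_threshold <- function(statistic = c("heritability",
                                                "transgression"),
                                  values, line_labels,
                                  n_perm = 1000, rank = 50) {
  statistic <- match.arg(statistic)
  stopifnot(length(values) == length(line_labels), n_perm >= rank,
            all(line_labels %in% c("RIL", "MM", "PI")))
  calc <- function(v) {
    r <- v[line_labels == "RIL"]
    a <- v[line_labels == "MM"]
    b <- v[line_labels == "PI"]
    if (statistic == "heritability") heritability(r, a, b)$h2
    else transgression(r, a, b)$n_transgressive
  }
  observed <- calc(values)
  perm_stats <- vapply(seq_len(n_perm),
                       function(i) calc(sample(values)), numeric(1))
  threshold <- sort(perm_stats, decreasing = TRUE)[rank]
  list(observed = observed, threshold = threshold,
       significant = !is.na(observed) && observed > threshold,
       perm_stats = perm_stats)
}

# vectorized statistics over a genes x samples matrix
.arch_stats <- function(vals, ril_j, pa_j, pb_j, statistic, n_sd = 3) {
  pa <- vals[, pa_j, drop = FALSE]
  pb <- vals[, pb_j, drop = FALSE]
  na <- length(pa_j); nb <- length(pb_j)
  v_e <- ((na - 1) * .rowvar(pa) + (nb - 1) * .rowvar(pb)) / (na + nb - 2)
  if (statistic == "heritability") {
    v_ril <- .rowvar(vals[, ril_j, drop = FALSE])
    h2 <- ifelse(v_ril == 0, NA_real_, (v_ril - v_e) / v_ril)
    list(stat = h2, v_ril = v_ril, v_e = v_e)
  } else {
    sigma <- sqrt(v_e)
    ma <- rowMeans(pa); mb <- rowMeans(pb)
    lower <- pmin(ma, mb) - n_sd * sigma
    upper <- pmax(ma, mb) + n_sd * sigma
    r <- vals[, ril_j, drop = FALSE]
    cnt <- rowSums(r < lower) + rowSums(r > upper)
    list(stat = cnt, lower = lower, upper = upper, sigma = sigma)
  }
}

#' Genome-wide architecture scan with permutation thresholds
#'
#' Computes broad-sense heritability or the transgression count for every
#' gene of one treatment's samples (`tpm_log` layer), together with a
#' per-transcript permutation threshold: in each permutation the sample
#' values are reshuffled jointly over the line designations (one
#' permutation of samples applied to all genes, preserving group sizes),
#' the statistic is recomputed, and the `rank`-th largest of the `n_perm`
#' permuted values per gene is its threshold.
#'
#' @param em An `expr_set` with `tpm_log`; samples of a single treatment.
#' @param statistic `"heritability"` or `"transgression"`.
#' @param n_perm,rank Permutation scheme (defaults 1000 and 50).
#' @param n_sd Transgression bound width in pooled parental SDs.
#' @param seed Integer seed for the permutations.
#' @return data.frame, one row per gene. For heritability: gene, v_ril,
#'   v_e, h2, threshold, significant. For transgression: gene, lower,
#'   upper, sigma, n_transgressive, threshold, significant, degenerate.
#' @export
genarch_scan <- function(em, statistic = c("heritability", "transgression"),
                         n_perm = 1000, rank = 50, n_sd = 3, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(em, "expr_set"), !is.null(em$tpm_log), n_perm >= rank)
  s <- em$samples
  if (length(unique(s$treatment)) != 1)
    warning("samples span multiple treatments; the scan pools them")
  ril_j <- which(!s$is_parent)
  pa_j <- which(s$is_parent & s$line == "MM")
  pb_j <- which(s$is_parent & s$line == "PI")
  stopifnot(length(ril_j) >= 2, length(pa_j) >= 2, length(pb_j) >= 2)
  vals <- em$tpm_log
  obs <- .arch_stats(vals, ril_j, pa_j, pb_j, statistic, n_sd)

  set.seed(seed)
  ns <- ncol(vals)
  perm <- matrix(NA_real_, n_perm, nrow(vals))
  for (p in seq_len(n_perm)) {
    vp <- vals[, sample.int(ns), drop = FALSE]
    perm[p, ] <- .arch_stats(vp, ril_j, pa_j, pb_j, statistic, n_sd)$stat
  }
  thr <- apply(perm, 2, function(v) sort(v, decreasing = TRUE)[rank])
  sig <- !is.na(obs$stat) & obs$stat > thr

  if (statistic == "heritability") {
    data.frame(gene = rownames(vals), v_ril = obs$v_ril, v_e = obs$v_e,
               h2 = obs$stat, threshold = thr, significant = sig,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = rownames(vals), lower = obs$lower, upper = obs$upper,
               sigma = obs$sigma, n_transgressive = obs$stat,
               threshold = thr, significant = sig,
               degenerate = obs$sigma == 0,
               row.names = NULL, stringsAsFactors = FALSE)
  }
}
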