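#' Run the full genetical-genomics analysis
#'
#' Orchestrates every stage on a SNP table plus a count matrix: genetic-map
#' construction (consistency filter, sliding-bin genotyping, marker
#' collapse, recombination counts, cM map), expression normalization (TPM,
#' log and mean-ratio transforms, expressed-gene filter), treatment and
#' parental G-by-E linear models, per-treatment heritability and
#' transgression scans with permutation thresholds, per-treatment eQTL
#' mapping with a permutation FDR threshold, cis/trans classification,
#' trans-band detection, and cross-treatment overlap summaries. Treatments
#' are analyzed independently and only compared at reporting time; with
#' `harmonize = TRUE` both treatments' eQTL calls use the most stringent
#' (largest) of the two FDR cutoffs.
#'
#' All randomness derives from `seed` through fixed per-stage offsets, so
#' the run is reproducible end to end.
#'
#' @param snps A `snp_table` covering parental replicates and RILs.
#' @param em An `expr_set` (counts layer) for the same samples.
#' @param bin_size SNPs per sliding genotyping bin.
#' @param n_perm_arch,arch_rank Permutations and threshold rank for the
#'   heritability/transgression scans.
#' @param n_perm_eqtl Permutations for the eQTL FDR.
#' @param q Target eQTL FDR level.
#' @param grid_step Cutoff grid resolution, -log10(p) units.
#' @param ci_drop Confidence-interval drop, -log10(p) units.
#' @param min_trans_dist Minimum gene-to-peak distance for a trans call, bp.
#' @param hotspot_bin Trans-band bin width, bp.
#' @param p_cut Per-bin Poisson cutoff for trans-band calling.
#' @param max_gap Non-significant bins bridged inside a trans-band.
#' @param harmonize Use the most stringent of the two treatments' cutoffs
#'   for both.
#' @param seed Integer master seed.
#' @param output_dir Optional directory; when given, per-stage TSV/BED
#'   outputs and a YAML manifest are written there.
#' @return A list of class `ril_pipeline` with components `map` (the
#'   collapsed `geno_map`), `recombination`, `expression` (filtered
#'   `expr_set`), `de`, `gxe`, `per_treatment` (named list with
#'   heritability, transgression, scan threshold, records, bins, bands),
#'   `overlaps`, and `manifest` (stage-by-stage counts and realized
#'   thresholds).
#' @export
run_ril_pipeline <- function(snps, em,
                             bin_size = 100,
                             n_perm_arch = 1000, arch_rank = 50,
                             n_perm_eqtl = 10, q = 0.05, grid_step = 0.1,
                             ci_drop = 1.5, min_trans_dist = 1e6,
                             hotspot_bin = 2e6, p_cut = 1e-4, max_gap = 1,
                             harmonize = TRUE, seed = 1L,
                             output_dir = NULL) {
  stopifnot(inherits(snps, "snp_table"), inherits(em, "expr_set"))
  s <- em$samples
  parent_samples <- list(
    MM = s$sample[s$is_parent & s$line == "MM"],
    PI = s$sample[s$is_parent & s$line == "PI"])
  ril_samples <- s$sample[!s$is_parent]

  # genetic map
  fsnps <- filter_consistent_snps(snps, parent_samples, ril_samples)
  if (nrow(fsnps$sites) == 0)
    stop("pipeline aborted at filter_consistent_snps: no usable SNP sites")
  gm <- call_bin_genotypes(fsnps, ril_samples, bin_size = bin_size)
  gm <- collapse_unique_markers(gm)
  rec <- count_recombinations(gm)
  gm <- build_cm_map(gm)

  # expression
  n_genes_input <- nrow(em$counts)
  em <- compute_tpm(em)
  em <- transform_expression(em)
  em <- filter_expressed(em)
  if (nrow(em$counts) == 0)
    stop("pipeline aborted at filter_expressed: no gene expressed in all samples")

  # differential abundance
  de <- test_treatment(em)
  gxe <- test_parental_gxe(subset_expr(em, samples = s$sample[s$is_parent]))

  treatments <- sort(unique(s$treatment))
  per_trt <- list()
  for (ti in seq_along(treatments)) {
    trt <- treatments[ti]
    emt <- subset_expr(em, samples = s$sample[s$treatment == trt])
    h2 <- genarch_scan(emt, "heritability", n_perm = n_perm_arch,
                       rank = arch_rank, seed = seed + 100L + ti)
    tg <- genarch_scan(emt, "transgression", n_perm = n_perm_arch,
                       rank = arch_rank, seed = seed + 200L + ti)
    scan <- eqtl_scan(gm, emt)
    thr <- eqtl_fdr_threshold(scan, gm, emt, n_perm = n_perm_eqtl, q = q,
                              grid_step = grid_step, seed = seed + 300L + ti)
    per_trt[[trt]] <- list(heritability = h2, transgression = tg,
                           scan = scan, threshold = thr)
  }

  cutoffs <- vapply(per_trt, function(x) x$threshold$cutoff, numeric(1))
  for (trt in treatments) {
    use_cut <- if (harmonize && any(!is.na(cutoffs)))
      max(cutoffs, na.rm = TRUE) else cutoffs[[trt]]
    per_trt[[trt]]$cutoff_used <- use_cut
    if (is.na(use_cut)) {
      per_trt[[trt]]$records <- classify_eqtl(
        eqtl_peaks(per_trt[[trt]]$scan, Inf, drop = ci_drop), em$genes,
        min_dist = min_trans_dist)
    } else {
      rec_t <- eqtl_peaks(per_trt[[trt]]$scan, use_cut, drop = ci_drop)
      per_trt[[trt]]$records <- classify_eqtl(rec_t, em$genes,
                                              min_dist = min_trans_dist)
    }
    per_trt[[trt]]$bins <- bin_trans_eqtls(per_trt[[trt]]$records, gm$map,
                                           bin_size = hotspot_bin)
    per_trt[[trt]]$bands <- call_and_merge(per_trt[[trt]]$bins,
                                           p_cut = p_cut, max_gap = max_gap)
  }

  overlaps <- summarize_overlaps(per_trt, rownames(em$counts))

  manifest <- list(
    n_snps_input = nrow(snps$sites),
    n_snps_consistent = nrow(fsnps$sites),
    n_markers = ncol(gm$geno),
    n_recombinations = sum(rec$counts$n_recomb),
    n_genes_input = n_genes_input,
    n_genes_expressed = nrow(em$counts),
    n_de_genes = sum(de$significant),
    gxe_overall_threshold = gxe$overall_threshold,
    n_gxe_genes = sum(gxe$results$significant[gxe$results$term == "T:L"]),
    eqtl_cutoffs = cutoffs,
    parameters = list(bin_size = bin_size, n_perm_arch = n_perm_arch,
                      arch_rank = arch_rank, n_perm_eqtl = n_perm_eqtl,
                      q = q, grid_step = grid_step, ci_drop = ci_drop,
                      min_trans_dist = min_trans_dist,
                      hotspot_bin = hotspot_bin, p_cut = p_cut,
                      max_gap = max_gap, harmonize = harmonize,
                      seed = seed)
  )
  for (trt in treatments) {
    pt <- per_trt[[trt]]
    manifest[[paste0("treatment_", trt)]] <- list(
      cutoff_used = pt$cutoff_used,
      n_eqtl = nrow(pt$records),
      n_cis = sum(pt$records$type == "cis", na.rm = TRUE),
      n_trans = sum(pt$records$type == "trans", na.rm = TRUE),
      n_eqtl_genes = length(unique(pt$records$gene)),
      n_heritable = sum(pt$heritability$significant),
      n_transgressive = sum(pt$transgression$significant),
      n_trans_bands = nrow(pt$bands))
  }

  res <- structure(list(map = gm, recombination = rec, expression = em,
                        de = de, gxe = gxe, per_treatment = per_trt,
                        overlaps = overlaps, manifest = manifest),
                   class = "ril_pipeline")
  if (!is.null(output_dir)) .write_pipeline_outputs(res, output_dir)
  res
}

#' Cross-treatment overlap report
#'
#' Compares the two treatments' gene sets — genes with a cis-eQTL, a
#' trans-eQTL, significant heritability, significant transgression — via
#' the union-overlap percentage and an upper-tail hypergeometric test over
#' the expressed-gene universe.
#'
#' @param per_trt Named list of per-treatment results (components of a
#'   `ril_pipeline`), needing `records`, `heritability`, `transgression`.
#' @param universe Character vector of expressed gene ids.
#' @return Named list of [overlap_test()] results: `cis`, `trans`,
#'   `heritable`, `transgressive`.
#' @export
summarize_overlaps <- function(per_trt, universe) {
  if (length(per_trt) != 2) {
    warning("overlap report needs exactly 2 treatments; skipping")
    return(NULL)
  }
  sets <- lapply(per_trt, function(pt) {
    r <- pt$records
    list(cis = unique(r$gene[!is.na(r$type) & r$type == "cis"]),
         trans = unique(r$gene[!is.na(r$type) & r$type == "trans"]),
         heritable = pt$heritability$gene[pt$heritability$significant],
         transgressive = pt$transgression$gene[pt$transgression$significant])
  })
  out <- lapply(c(cis = "cis", trans = "trans", heritable = "heritable",
                  transgressive = "transgressive"), function(nm) {
    overlap_test(sets[[1]][[nm]], sets[[2]][[nm]], universe)
  })
  out
}

.write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_geno_map(res$map, file.path(dir, "marker_map.tsv"),
                 file.path(dir, "genotypes.tsv"))
  utils::write.table(res$recombination$counts,
                     file.path(dir, "recombination_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$recombination$breakpoints))
    write_bed(res$recombination$breakpoints,
              file.path(dir, "breakpoints.bed"),
              start_col = "left_bp", end_col = "right_bp")
  write_expr_tsv(res$expression, dir, "expression")
  utils::write.table(res$de, file.path(dir, "de_treatment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$gxe$results, file.path(dir, "de_parental_gxe.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (trt in names(res$per_treatment)) {
    pt <- res$per_treatment[[trt]]
    utils::write.table(pt$heritability,
                       file.path(dir, sprintf("heritability_%s.tsv", trt)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pt$transgression,
                       file.path(dir, sprintf("transgression_%s.tsv", trt)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pt$records,
                       file.path(dir, sprintf("eqtl_%s.tsv", trt)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pt$bins,
                       file.path(dir, sprintf("trans_bins_%s.tsv", trt)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(pt$bands))
      write_bed(pt$bands, file.path(dir, sprintf("trans_bands_%s.bed", trt)),
                name_col = "band", start_col = "start_bp",
                end_col = "end_bp", already_0based = TRUE)
  }
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.ril_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("ril_pipeline run\n")
  cat(sprintf("  SNPs: %d input, %d consistent; %d unique markers; %d recombinations\n",
              m$n_snps_input, m$n_snps_consistent, m$n_markers,
              m$n_recombinations))
  cat(sprintf("  genes expressed in all samples: %d; DE (treatment): %d\n",
              m$n_genes_expressed, m$n_de_genes))
  for (trt in names(x$per_treatment)) {
    t_ <- m[[paste0("treatment_", trt)]]
    cat(sprintf("  %s: cutoff %.1f, %d eQTLs (%d cis / %d trans) for %d genes, %d trans-bands\n",
                trt, t_$cutoff_used, t_$n_eqtl, t_$n_cis, t_$n_trans,
                t_$n_eqtl_genes, t_$n_trans_bands))
  }
  invisible(x)
}
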