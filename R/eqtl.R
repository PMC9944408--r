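# single-marker ANOVA of every gene against every marker.
# geno: lines x markers (1 = MM, 0 = PI, NA dropped marker-wise);
# y: lines x genes. Returns -log10(p) and effect (MM mean - PI mean)
# matrices, genes x markers.
.eqtl_scan_core <- function(geno, y) {
  nm <- ncol(geno); ng <- ncol(y)
  neglogp <- matrix(0, ng, nm, dimnames = list(colnames(y), colnames(geno)))
  effect <- matrix(NA_real_, ng, nm, dimnames = dimnames(neglogp))
  for (j in seq_len(nm)) {
    x <- geno[, j]
    ok <- !is.na(x)
    xs <- x[ok]
    n1 <- sum(xs == 1L); n0 <- sum(xs == 0L); n <- n1 + n0
    if (n1 == 0L || n0 == 0L || n < 3L) next
    ys <- y[ok, , drop = FALSE]
    s1 <- colSums(ys[xs == 1L, , drop = FALSE])
    s0 <- colSums(ys[xs == 0L, , drop = FALSE])
    m1 <- s1 / n1; m0 <- s0 / n0
    sst <- colSums(ys^2) - (s1 + s0)^2 / n
    ssb <- n1 * n0 / n * (m1 - m0)^2
    ssw <- pmax(sst - ssb, 0)
    f <- ssb / (ssw / (n - 2))
    lp <- -stats::pf(f, 1, n - 2, lower.tail = FALSE, log.p = TRUE) / log(10)
    lp[sst == 0] <- 0
    neglogp[, j] <- lp
    effect[, j] <- m1 - m0
  }
  list(neglogp = neglogp, effect = effect)
}

#' Genome-wide single-marker eQTL scan
#'
#' For every gene and marker, fits the one-factor least-squares model
#' `tpm_log = genotype + error` over the RILs of one treatment and records
#' -log10 of the F-test p value and the signed effect (MM mean minus PI
#' mean; positive = MM allele raises abundance). Lines with a missing
#' genotype are dropped marker-wise; markers with a single genotype class
#' get -log10(p) = 0 and effect NA.
#'
#' @param gm A `geno_map` (RIL genotypes; typically collapsed, with cM).
#' @param em An `expr_set` with `tpm_log`; only non-parental samples
#'   present in `gm` are used.
#' @return An `eqtl_scan`: list with `neglogp` and `effect` (genes x
#'   markers), `map` (marker map) and `lines` used.
#' @export
eqtl_scan <- function(gm, em) {
  stopifnot(inherits(gm, "geno_map"), inherits(em, "expr_set"),
            !is.null(em$tpm_log))
  rils <- em$samples$sample[!em$samples$is_parent]
  use <- intersect(rownames(gm$geno), rils)
  if (length(use) < 3) stop("fewer than 3 genotyped RILs in the expression set")
  core <- .eqtl_scan_core(gm$geno[use, , drop = FALSE],
                          t(em$tpm_log[, use, drop = FALSE]))
  structure(list(neglogp = core$neglogp, effect = core$effect,
                 map = gm$map, lines = use), class = "eqtl_scan")
}

#' Single-transcript eQTL profile
#'
#' @param gm A `geno_map`.
#' @param trait Named numeric vector of trait values (names = line ids).
#' @return data.frame: marker, chrom, pos, neg_log10_p, effect.
#' @export
map_transcript <- function(gm, trait) {
  stopifnot(inherits(gm, "geno_map"), !is.null(names(trait)))
  use <- intersect(rownames(gm$geno), names(trait))
  core <- .eqtl_scan_core(gm$geno[use, , drop = FALSE],
                          matrix(trait[use], dimnames = list(use, "trait")))
  data.frame(marker = gm$map$marker, chrom = gm$map$chrom, pos = gm$map$pos,
             neg_log10_p = core$neglogp[1, ], effect = core$effect[1, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Right side of the permutation FDR bound
#'
#' The dependency-corrected bound on the ratio of false to real discoveries:
#' `(m0 / m) * q * log(m)` with `m0 = m - RDS`, in the spirit of the
#' Benjamini-Yekutieli correction for dependent tests.
#'
#' @param m Number of transcripts tested.
#' @param rds Real discoveries at the candidate cutoff.
#' @param q Target FDR level.
#' @param log_base Base of the log factor (`exp(1)` natural, or 10).
#' @return The bound on FDS/RDS.
#' @export
fdr_bound <- function(m, rds, q = 0.05, log_base = exp(1)) {
  ((m - rds) / m) * q * log(m, base = log_base)
}

#' Permutation-based genome-wide eQTL significance threshold
#'
#' Reshuffles the trait values over the lines (one joint permutation of
#' lines for all transcripts), remaps the full scan, and repeats `n_perm`
#' times. Over an ascending grid of candidate -log10(p) cutoffs, RDS is the
#' number of transcripts whose real profile maximum exceeds the cutoff and
#' FDS the mean of that count over the permutations; the chosen cutoff is
#' the smallest with RDS > 0 satisfying
#' `FDS / RDS <= (m0 / m) * q * log(m)` (see [fdr_bound()]).
#'
#' @param scan An `eqtl_scan` of the real data.
#' @param gm The `geno_map` used for the scan.
#' @param em The `expr_set` used for the scan.
#' @param n_perm Number of permutations (default 10).
#' @param q Target FDR level.
#' @param grid_step Grid resolution in -log10(p) units.
#' @param log_base Base of the log factor in the bound.
#' @param seed Integer seed for the permutations.
#' @return An `eqtl_threshold`: list with `cutoff` (NA when no cutoff
#'   satisfies the bound: no significant eQTLs), `grid` (data.frame cutoff,
#'   rds, fds, bound), `m`, `q`, `perm_max` (n_perm x genes matrix of
#'   permutation profile maxima).
#' @export
eqtl_fdr_threshold <- function(scan, gm, em, n_perm = 10, q = 0.05,
                               grid_step = 0.1, log_base = exp(1),
                               seed = 1L) {
  stopifnot(inherits(scan, "eqtl_scan"), n_perm >= 1)
  use <- scan$lines
  geno <- gm$geno[use, , drop = FALSE]
  y <- t(em$tpm_log[, use, drop = FALSE])
  real_max <- apply(scan$neglogp, 1, max)
  m <- length(real_max)

  set.seed(seed)
  perm_max <- matrix(NA_real_, n_perm, m)
  for (p in seq_len(n_perm)) {
    yp <- y[sample.int(nrow(y)), , drop = FALSE]
    rownames(yp) <- rownames(y)
    perm_max[p, ] <- apply(.eqtl_scan_core(geno, yp)$neglogp, 1, max)
  }

  hi <- max(real_max, perm_max, na.rm = TRUE)
  grid <- seq(grid_step, ceiling(hi / grid_step) * grid_step, by = grid_step)
  rds <- vapply(grid, function(cut) sum(real_max > cut), numeric(1))
  fds <- vapply(grid, function(cut) mean(rowSums(perm_max > cut)), numeric(1))
  bound <- fdr_bound(m, rds, q, log_base)
  ok <- rds > 0 & fds / rds <= bound
  cutoff <- if (any(ok)) grid[which(ok)[1]] else NA_real_
  structure(list(cutoff = cutoff,
                 grid = data.frame(cutoff = grid, rds = rds, fds = fds,
                                   bound = bound),
                 m = m, q = q, perm_max = perm_max),
            class = "eqtl_threshold")
}

#' Extract eQTL peaks and 1.5-drop confidence intervals
#'
#' Per gene and per chromosome whose profile maximum exceeds the threshold,
#' emits one record: the peak is the leftmost maximal marker on that
#' chromosome, and the confidence interval is the contiguous run of markers
#' around the peak whose score stays within `drop` units of the peak score.
#' The interval is reported in bp as the genomic span of the run: since a
#' collapsed marker represents a whole block of SNP bins, the bounds are
#' the first and last member-SNP positions of the outer markers (`span_left`
#' / `span_right` map columns) when available, falling back to the marker
#' positions otherwise. A gene can yield records on several chromosomes.
#'
#' @param scan An `eqtl_scan`.
#' @param threshold -log10(p) significance cutoff (e.g. the
#'   [eqtl_fdr_threshold()] cutoff, or a harmonized cross-treatment value).
#' @param drop Confidence-interval drop in -log10(p) units.
#' @return data.frame: gene, chrom, peak_marker, peak_bp, peak_cm,
#'   neg_log10_p, effect, effect_sign, ci_left_bp, ci_right_bp.
#' @export
eqtl_peaks <- function(scan, threshold, drop = 1.5) {
  stopifnot(inherits(scan, "eqtl_scan"), is.finite(threshold))
  map <- scan$map
  out <- list(); k <- 0L
  has_cm <- !is.null(map$cm)
  ci_lo <- if (!is.null(map$span_left)) map$span_left else map$pos
  ci_hi <- if (!is.null(map$span_right)) map$span_right else map$pos
  for (ch in unique(map$chrom)) {
    jj <- which(map$chrom == ch)
    sub <- scan$neglogp[, jj, drop = FALSE]
    gmax <- apply(sub, 1, max)
    for (g in which(gmax > threshold)) {
      prof <- sub[g, ]
      pk <- which.max(prof)                     # leftmost on ties
      inci <- prof >= gmax[g] - drop
      left <- pk; while (left > 1 && inci[left - 1]) left <- left - 1
      right <- pk; while (right < length(prof) && inci[right + 1])
        right <- right + 1
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = rownames(sub)[g], chrom = ch,
        peak_marker = map$marker[jj[pk]],
        peak_bp = map$pos[jj[pk]],
        peak_cm = if (has_cm) map$cm[jj[pk]] else NA_real_,
        neg_log10_p = gmax[g],
        effect = scan$effect[g, jj[pk]],
        effect_sign = sign(scan$effect[g, jj[pk]]),
        ci_left_bp = ci_lo[jj[left]],
        ci_right_bp = ci_hi[jj[right]],
        stringsAsFactors = FALSE)
    }
  }
  if (!k) return(data.frame(gene = character(), chrom = integer(),
                            peak_marker = character(), peak_bp = numeric(),
                            peak_cm = numeric(), neg_log10_p = numeric(),
                            effect = numeric(), effect_sign = numeric(),
                            ci_left_bp = numeric(), ci_right_bp = numeric()))
  do.call(rbind, out)
}

#' Classify eQTL records as cis or trans
#'
#' An eQTL is trans when its peak lies at least `min_dist` (default 1 Mb)
#' from the gene (distance from the nearest edge of the gene interval;
#' infinite across chromosomes) and the gene interval does not intersect
#' the peak's confidence interval; otherwise cis. Genes absent from the
#' annotation get type NA with a warning.
#'
#' @param records data.frame from [eqtl_peaks()].
#' @param annotation Gene annotation data.frame (gene, chrom, start, end).
#' @param min_dist Minimum gene-to-peak distance for a trans call, bp.
#' @return `records` with a `type` column (`"cis"`/`"trans"`/NA).
#' @export
classify_eqtl <- function(records, annotation, min_dist = 1e6) {
  if (nrow(records) == 0) {
    records$type <- character(0)
    return(records)
  }
  gi <- match(records$gene, annotation$gene)
  if (anyNA(gi)) warning(sum(is.na(gi)), " record(s) with unannotated gene")
  g_chrom <- annotation$chrom[gi]
  g_start <- annotation$start[gi]
  g_end <- annotation$end[gi]
  same <- g_chrom == records$chrom
  dist <- ifelse(same,
                 pmax(g_start - records$peak_bp,
                      records$peak_bp - g_end, 0),
                 Inf)
  in_ci <- same & g_start <= records$ci_right_bp &
    g_end >= records$ci_left_bp
  records$type <- ifelse(is.na(gi), NA_character_,
                         ifelse(dist >= min_dist & !in_ci, "trans", "cis"))
  records
}
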