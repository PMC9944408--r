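#' Filter SNP sites to those consistent in parents and observed in all RILs
#'
#' Retains sites where (i) every replicate of each parental line carries the
#' same allele call, (ii) the two parents carry different alleles, and (iii)
#' every RIL has a non-missing call. These are the sites usable for
#' reconstructing the parental origin of RIL genomes.
#'
#' @param snps A `snp_table` (see [simulate_population()] or
#'   [read_snp_table()]).
#' @param parent_samples Named list of two character vectors,
#'   `list(MM = ..., PI = ...)`, giving the replicate sample ids per parent.
#' @param ril_samples Character vector of RIL sample ids.
#' @return The filtered `snp_table`. Warns (and returns an empty table)
#'   if no site survives.
#' @export
filter_consistent_snps <- function(snps, parent_samples, ril_samples) {
  stopifnot(inherits(snps, "snp_table"),
            all(c("MM", "PI") %in% names(parent_samples)))
  calls <- snps$calls
  stopifnot(all(unlist(parent_samples) %in% colnames(calls)),
            all(ril_samples %in% colnames(calls)))
  consistent <- function(m) {
    !is.na(m[, 1]) & rowSums(m != m[, 1] | is.na(m)) == 0
  }
  mm <- calls[, parent_samples$MM, drop = FALSE]
  pi_ <- calls[, parent_samples$PI, drop = FALSE]
  ok <- consistent(mm) & consistent(pi_) & (mm[, 1] != pi_[, 1])
  ok[is.na(ok)] <- FALSE
  ok <- ok & rowSums(is.na(calls[, ril_samples, drop = FALSE])) == 0
  if (!any(ok)) {
    warning("no SNP site passed the consistency filter")
  }
  snps$sites <- snps$sites[ok, , drop = FALSE]
  snps$calls <- snps$calls[ok, , drop = FALSE]
  snps
}

#' Call line genotypes in sliding bins of SNPs
#'
#' Slides a window of `bin_size` consecutive SNPs (step 1 SNP) along each
#' chromosome. Per window and line, the genotype probability is the fraction
#' of non-missing member-SNP calls matching the MM parent; the reported code
#' is MM when that fraction exceeds 0.5, PI below 0.5, and NA on an exact
#' tie or when fewer than `min_informative` of the member SNPs are
#' informative for that line. The marker's physical position is the
#' arithmetic mean of its member SNP positions. Chromosomes with fewer than
#' `bin_size` retained SNPs yield a single bin spanning all their SNPs.
#'
#' @param snps A filtered `snp_table`.
#' @param samples Sample ids to genotype (typically the RILs).
#' @param bin_size SNPs per bin.
#' @param min_informative Minimum fraction of member SNPs that must be
#'   non-missing for a call.
#' @return A `geno_map`: list with `geno` (lines-by-markers integer matrix,
#'   1 = MM, 0 = PI, NA), `prob` (probability that the line is MM in the
#'   bin), and `map` (data.frame marker, chrom, pos, n_snps, snp_first,
#'   snp_last).
#' @export
call_bin_genotypes <- function(snps, samples, bin_size = 100,
                               min_informative = 0.1) {
  stopifnot(inherits(snps, "snp_table"), bin_size >= 1,
            all(samples %in% colnames(snps$calls)))
  sites <- snps$sites
  x <- snps$calls[, samples, drop = FALSE]
  num <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  num[x == "MM"] <- 1
  num[x == "PI"] <- 0

  geno_blocks <- list(); prob_blocks <- list(); map_blocks <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n <- length(idx)
    b <- min(bin_size, n)
    m <- num[idx, , drop = FALSE]
    info <- !is.na(m)
    mm <- m; mm[!info] <- 0
    cs_mm <- apply(rbind(0, mm), 2, cumsum)
    cs_in <- apply(rbind(0, info), 2, cumsum)
    w <- n - b + 1
    lo <- seq_len(w); hi <- lo + b - 1
    n_mm <- cs_mm[hi + 1, , drop = FALSE] - cs_mm[lo, , drop = FALSE]
    n_in <- cs_in[hi + 1, , drop = FALSE] - cs_in[lo, , drop = FALSE]
    prob <- n_mm / n_in                       # NaN where n_in == 0
    prob[n_in < min_informative * b] <- NA
    code <- ifelse(prob > 0.5, 1L, ifelse(prob < 0.5, 0L, NA_integer_))
    pos_cs <- cumsum(c(0, sites$pos[idx]))
    map_blocks[[ch]] <- data.frame(
      marker = sprintf("c%02d_b%05d", ch, lo),
      chrom = ch,
      pos = (pos_cs[hi + 1] - pos_cs[lo]) / b,
      n_snps = b,
      snp_first = sites$site[idx[lo]],
      snp_last = sites$site[idx[hi]],
      span_left = sites$pos[idx[lo]],
      span_right = sites$pos[idx[hi]],
      stringsAsFactors = FALSE)
    geno_blocks[[ch]] <- t(code)
    prob_blocks[[ch]] <- t(prob)
  }
  map <- do.call(rbind, map_blocks)
  geno <- do.call(cbind, geno_blocks)
  prob <- do.call(cbind, prob_blocks)
  dimnames(geno) <- dimnames(prob) <- list(samples, map$marker)
  structure(list(geno = geno, prob = prob, map = map), class = "geno_map")
}

#' @export
print.geno_map <- function(x, ...) {
  cat(sprintf("geno_map: %d lines x %d markers on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  if (!is.null(x$map$cm))
    cat(sprintf("genetic map: %.1f cM total\n",
                sum(tapply(x$map$cm, x$map$chrom, max))))
  invisible(x)
}

#' Merge consecutive markers with identical genotype columns
#'
#' Sliding-bin genotyping produces long runs of redundant markers between
#' recombination breakpoints. Consecutive markers (within a chromosome)
#' whose genotype codes agree across every line — including the NA pattern —
#' are merged into a single marker at the mean position of the members.
#' Collapsing is idempotent.
#'
#' @param gm A `geno_map`.
#' @return The collapsed `geno_map`; `map$n_members` gives the number of
#'   merged input markers.
#' @export
collapse_unique_markers <- function(gm) {
  stopifnot(inherits(gm, "geno_map"))
  g <- gm$geno
  key <- g
  key[is.na(key)] <- -1L
  grp <- integer(ncol(g)); gid <- 0L
  for (j in seq_len(ncol(g))) {
    if (j == 1L || gm$map$chrom[j] != gm$map$chrom[j - 1L] ||
        any(key[, j] != key[, j - 1L])) gid <- gid + 1L
    grp[j] <- gid
  }
  first <- !duplicated(grp)
  map <- gm$map[first, , drop = FALSE]
  map$pos <- as.numeric(tapply(gm$map$pos, grp, mean))
  map$n_members <- as.integer(table(grp))
  map$snp_last <- gm$map$snp_last[cumsum(map$n_members)]
  if (!is.null(gm$map$span_right)) {
    map$span_right <- gm$map$span_right[cumsum(map$n_members)]
    map$span_left <- gm$map$span_left[c(1, cumsum(map$n_members)[-nrow(map)] + 1)]
  }
  map$marker <- sprintf("c%02d_m%04d", map$chrom,
                        stats::ave(map$chrom, map$chrom, FUN = seq_along))
  prob <- t(apply(gm$prob, 1, function(r) tapply(r, grp, mean)))
  geno <- gm$geno[, first, drop = FALSE]
  dimnames(geno) <- dimnames(prob) <- list(rownames(gm$geno), map$marker)
  rownames(map) <- NULL
  structure(list(geno = geno, prob = prob, map = map), class = "geno_map")
}

#' Count recombination events per line and chromosome
#'
#' A recombination is a change of genotype code between consecutive non-NA
#' markers of the same chromosome; NA markers are skipped, and the
#' breakpoint interval spans from the last preceding non-NA marker to the
#' next non-NA marker.
#'
#' @param gm A `geno_map`.
#' @return List with `counts` (data.frame line, chrom, n_recomb) and
#'   `breakpoints` (data.frame line, chrom, left_bp, right_bp).
#' @export
count_recombinations <- function(gm) {
  stopifnot(inherits(gm, "geno_map"))
  lines_ <- rownames(gm$geno)
  counts <- list(); bps <- list(); k <- 0L
  for (ch in unique(gm$map$chrom)) {
    jj <- which(gm$map$chrom == ch)
    pos <- gm$map$pos[jj]
    sub <- gm$geno[, jj, drop = FALSE]
    for (i in seq_along(lines_)) {
      k <- k + 1L
      obs <- which(!is.na(sub[i, ]))
      v <- sub[i, obs]
      flips <- if (length(v) > 1) which(diff(v) != 0) else integer()
      counts[[k]] <- data.frame(line = lines_[i], chrom = ch,
                                n_recomb = length(flips))
      if (length(flips))
        bps[[k]] <- data.frame(line = lines_[i], chrom = ch,
                               left_bp = pos[obs[flips]],
                               right_bp = pos[obs[flips + 1]])
    }
  }
  list(counts = do.call(rbind, counts),
       breakpoints = if (length(bps)) do.call(rbind, bps) else
         data.frame(line = character(), chrom = integer(),
                    left_bp = numeric(), right_bp = numeric()))
}

#' Build the centimorgan map from recombination fractions
#'
#' Between adjacent markers, the recombination fraction r is the number of
#' lines whose codes differ (both non-NA) over the number of lines informative
#' for both markers; the cM increment is 100 r (direct Morgan mapping, no
#' mapping-function correction) and genetic positions accumulate from 0 at
#' the first marker of each chromosome. Optionally Haldane's mapping
#' function converts r to map distance.
#'
#' @param gm A `geno_map` (typically collapsed).
#' @param mapping `"morgan"` (cM = 100 r) or `"haldane"`
#'   (cM = -50 log(1 - 2r)).
#' @return `gm` with a `cm` column added to `map`.
#' @export
build_cm_map <- function(gm, mapping = c("morgan", "haldane")) {
  stopifnot(inherits(gm, "geno_map"), nrow(gm$geno) >= 2)
  mapping <- match.arg(mapping)
  cm <- numeric(nrow(gm$map))
  for (ch in unique(gm$map$chrom)) {
    jj <- which(gm$map$chrom == ch)
    inc <- numeric(length(jj))
    if (length(jj) > 1) {
      for (q in 2:length(jj)) {
        a <- gm$geno[, jj[q - 1]]
        b <- gm$geno[, jj[q]]
        both <- !is.na(a) & !is.na(b)
        if (!any(both)) {
          warning(sprintf("no informative lines between markers %s and %s",
                          gm$map$marker[jj[q - 1]], gm$map$marker[jj[q]]))
          r <- 0
        } else {
          r <- mean(a[both] != b[both])
        }
        inc[q] <- if (mapping == "haldane") {
          if (r >= 0.5) Inf else -50 * log(1 - 2 * r)
        } else 100 * r
      }
    }
    cm[jj] <- cumsum(inc)
  }
  gm$map$cm <- cm
  gm
}

#' Per-marker PI allele frequency
#'
#' @param gm A `geno_map`.
#' @return Named numeric vector: fraction of non-NA line codes equal to PI
#'   per marker.
#' @export
allele_frequency_profile <- function(gm) {
  stopifnot(inherits(gm, "geno_map"))
  colMeans(gm$geno == 0L, na.rm = TRUE)
}
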