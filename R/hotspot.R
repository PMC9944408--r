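#' Bin trans-eQTL peaks and test per-bin Poisson enrichment
#'
#' Assigns each trans-eQTL peak to a fixed-width genomic bin (default 2 Mb,
#' 0-based half-open grid per chromosome) and tests every bin of the bin
#' universe for enrichment against a uniform expectation: with lambda =
#' total trans count / number of bins, the upper-tail Poisson p is
#' P(X >= observed). The default universe is the set of bins containing at
#' least one genetic marker, since only marker-bearing regions can carry an
#' eQTL peak; `universe = "genome"` uses every bin of the genome instead
#' (chromosome lengths then taken from the marker map extent unless given).
#'
#' @param records Classified eQTL records ([classify_eqtl()]); only rows
#'   with `type == "trans"` are used.
#' @param map Marker map (data.frame with chrom, pos) defining the bin
#'   universe.
#' @param bin_size Bin width, bp.
#' @param universe `"markers"` or `"genome"`.
#' @param chrom_lengths Optional chromosome lengths (bp) for the genome
#'   universe.
#' @return data.frame of the whole bin universe: chrom, bin_start, bin_end,
#'   n_trans, n_plus, n_minus, lambda, p. Attribute `"genes"` holds the
#'   per-bin member gene ids.
#' @export
bin_trans_eqtls <- function(records, map, bin_size = 2e6,
                            universe = c("markers", "genome"),
                            chrom_lengths = NULL) {
  universe <- match.arg(universe)
  trans <- records[!is.na(records$type) & records$type == "trans", ,
                   drop = FALSE]
  chroms <- sort(unique(map$chrom))
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    hi <- if (!is.null(chrom_lengths)) chrom_lengths[ch] else
      max(map$pos[map$chrom == ch]) + 1
    start <- seq(0, hi - 1, by = bin_size)
    b <- data.frame(chrom = ch, bin_start = start,
                    bin_end = pmin(start + bin_size, hi))
    if (universe == "markers") {
      mpos <- map$pos[map$chrom == ch]
      hasm <- vapply(seq_len(nrow(b)), function(i)
        any(mpos >= b$bin_start[i] & mpos < b$bin_end[i]), logical(1))
      b <- b[hasm, , drop = FALSE]
    }
    b
  }))
  rownames(bins) <- NULL
  n <- nrow(bins)
  bins$n_trans <- 0L; bins$n_plus <- 0L; bins$n_minus <- 0L
  genes <- rep(list(character()), n)
  if (nrow(trans)) {
    bi <- vapply(seq_len(nrow(trans)), function(i) {
      hit <- which(bins$chrom == trans$chrom[i] &
                     bins$bin_start <= trans$peak_bp[i] &
                     trans$peak_bp[i] < bins$bin_end)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    for (i in seq_len(nrow(trans))) {
      b <- bi[i]
      if (is.na(b)) next
      bins$n_trans[b] <- bins$n_trans[b] + 1L
      if (!is.na(trans$effect_sign[i]) && trans$effect_sign[i] > 0)
        bins$n_plus[b] <- bins$n_plus[b] + 1L
      else bins$n_minus[b] <- bins$n_minus[b] + 1L
      genes[[b]] <- c(genes[[b]], trans$gene[i])
    }
  }
  lambda <- sum(bins$n_trans) / n
  bins$lambda <- lambda
  bins$p <- stats::ppois(bins$n_trans - 1, lambda, lower.tail = FALSE)
  attr(bins, "genes") <- genes
  bins
}

#' Call significant bins and merge them into trans-bands
#'
#' Flags bins with Poisson p below `p_cut` (default 1e-4) and merges runs
#' of significant bins on the same chromosome, tolerating up to `max_gap`
#' non-significant bins inside a run, into single trans-bands. Band counts
#' sum over every bin in the merged span.
#'
#' @param bins Output of [bin_trans_eqtls()].
#' @param p_cut Per-bin Poisson significance cutoff.
#' @param max_gap Maximum number of consecutive non-significant bins
#'   bridged inside a band.
#' @return data.frame of trans-bands: band, chrom, start_bp, end_bp,
#'   n_bins, n_trans, n_plus, n_minus. Attribute `"genes"` holds member
#'   gene ids per band.
#' @export
call_and_merge <- function(bins, p_cut = 1e-4, max_gap = 1) {
  sig <- bins$p < p_cut
  bin_genes <- attr(bins, "genes")
  bands <- list(); genes <- list(); k <- 0L
  for (ch in unique(bins$chrom)) {
    jj <- which(bins$chrom == ch)
    hits <- jj[sig[jj]]
    if (!length(hits)) next
    # split significant bins into bands when separated by > max_gap
    # non-significant bins (bin index distance > max_gap + 1)
    brk <- c(0, which(diff(match(hits, jj)) > max_gap + 1), length(hits))
    for (b in seq_len(length(brk) - 1)) {
      run <- hits[(brk[b] + 1):brk[b + 1]]
      span <- jj[jj >= min(run) & jj <= max(run)]
      k <- k + 1L
      bands[[k]] <- data.frame(
        chrom = ch,
        start_bp = bins$bin_start[min(span)],
        end_bp = bins$bin_end[max(span)],
        n_bins = length(span),
        n_trans = sum(bins$n_trans[span]),
        n_plus = sum(bins$n_plus[span]),
        n_minus = sum(bins$n_minus[span]))
      genes[[k]] <- if (!is.null(bin_genes))
        unique(unlist(bin_genes[span])) else character()
    }
  }
  if (!k) {
    out <- data.frame(band = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_bins = integer(), n_trans = integer(),
                      n_plus = integer(), n_minus = integer())
    attr(out, "genes") <- list()
    return(out)
  }
  out <- do.call(rbind, bands)
  out <- data.frame(band = sprintf("TB%d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  attr(out, "genes") <- genes
  out
}
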