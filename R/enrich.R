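#' Hypergeometric term enrichment over a background gene universe
#'
#' Tests, per annotation term, whether the selection is enriched for the
#' term's genes relative to the background: upper-tail hypergeometric
#' p = P(X >= k) with N background genes, K annotated, n selected and k
#' annotated-and-selected. Term sets are intersected with the background
#' before testing; p values are Benjamini-Hochberg adjusted across terms.
#'
#' @param selection Character vector of selected gene ids (must be a
#'   subset of `background`).
#' @param term_sets Named list of character vectors (term -> gene ids), or
#'   a data.frame with columns `gene` and `term`.
#' @param background Character vector: the gene universe (e.g. all
#'   expressed genes).
#' @return data.frame: term, N, K, n, k, p, p_adj.
#' @export
hypergeom_test <- function(selection, term_sets, background) {
  background <- unique(background)
  selection <- unique(selection)
  bad <- setdiff(selection, background)
  if (length(bad))
    stop("selection not a subset of background: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ...")
  if (is.data.frame(term_sets))
    term_sets <- split(term_sets$gene, term_sets$term)
  N <- length(background); n <- length(selection)
  res <- do.call(rbind, lapply(names(term_sets), function(tm) {
    set <- intersect(unique(term_sets[[tm]]), background)
    K <- length(set)
    k <- length(intersect(set, selection))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Overlap significance and union percentage of two gene sets
#'
#' Upper-tail hypergeometric p for the observed intersection of two sets
#' drawn from a common universe, plus the overlap expressed as a percentage
#' of the union, `|A intersect B| / |A union B| * 100` (symmetric in A
#' and B).
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector: the common gene universe.
#' @return List: `n_a`, `n_b`, `n_overlap`, `n_union`, `overlap_pct`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  k <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a),
                     length(universe) - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(n_a = length(set_a), n_b = length(set_b), n_overlap = k,
       n_union = uni, overlap_pct = union_overlap_pct(k, length(set_a),
                                                      length(set_b)),
       p = p)
}

#' Overlap as a percentage of the union, from counts
#'
#' `k / (n_a + n_b - k) * 100`: the intersection size as a percentage of
#' the union of two sets of sizes `n_a` and `n_b` sharing `k` members.
#'
#' @param k Intersection size.
#' @param n_a,n_b Set sizes.
#' @return Percentage in [0, 100].
#' @export
union_overlap_pct <- function(k, n_a, n_b) {
  stopifnot(k <= n_a, k <= n_b, k >= 0)
  u <- n_a + n_b - k
  if (u == 0) return(100)
  100 * k / u
}
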