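# shared fixtures built in code

# hand-built expression set: given a genes x samples matrix of counts
make_em <- function(counts, treatment = NULL, is_parent = NULL,
                    line = NULL, lengths = NULL) {
  ns <- ncol(counts); ng <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", 1:ng)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%03d", 1:ns)
  if (is.null(treatment)) treatment <- rep("HP", ns)
  if (is.null(is_parent)) is_parent <- rep(FALSE, ns)
  if (is.null(line)) line <- colnames(counts)
  if (is.null(lengths)) lengths <- rep(1000, ng)
  expr_set(counts,
           samples = data.frame(sample = colnames(counts), line = line,
                                treatment = treatment,
                                is_parent = is_parent,
                                replicate = 1L, stringsAsFactors = FALSE),
           genes = data.frame(gene = rownames(counts), chrom = 1L,
                              start = seq_len(ng) * 1000,
                              end = seq_len(ng) * 1000 + lengths - 1,
                              length = lengths, stringsAsFactors = FALSE))
}

# hand-built geno_map from an integer code matrix (lines x markers)
make_gm <- function(geno, chrom = NULL, pos = NULL) {
  nm <- ncol(geno)
  if (is.null(rownames(geno))) rownames(geno) <- sprintf("L%02d", 1:nrow(geno))
  if (is.null(chrom)) chrom <- rep(1L, nm)
  if (is.null(pos)) pos <- seq_len(nm) * 1e6
  map <- data.frame(marker = sprintf("m%03d", seq_len(nm)), chrom = chrom,
                    pos = pos, n_snps = 1L, stringsAsFactors = FALSE)
  colnames(geno) <- map$marker
  prob <- matrix(as.numeric(geno), nrow(geno), nm, dimnames = dimnames(geno))
  structure(list(geno = geno, prob = prob, map = map), class = "geno_map")
}

# small fast population config used by several suites
small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_lengths = c(50e6, 40e6),
         n_rils_per_env = c(HP = 30, LN = 30), n_snps = 2000,
         n_genes = 200, missing_rate = 0, rng_seed = seed),
    list(...))
  do.call(sim_config, args)
}
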