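#' Simulate a biparental RIL population genotyped at SNP sites
#'
#' Generates a recombinant inbred line (RIL) population from a cross between
#' two fully homozygous parents, "MM" and "PI". Each RIL chromosome is a
#' homozygous mosaic of parental segments delimited by crossovers: the
#' crossover count per line per chromosome is Poisson with mean
#' `mean_crossovers_per_chrom`, and a fraction `arm_bias` of crossovers is
#' placed uniformly within the distal thirds of the chromosome (recombination
#' is suppressed around centromeres in many plant genomes), the rest
#' uniformly along the chromosome. Optionally one chromosome can carry
#' segregation distortion: its mosaic is then drawn from a stationary
#' two-state Markov process whose stationary PI frequency equals
#' `distortion$pi_freq` and whose expected switch count matches the
#' crossover mean.
#'
#' SNP sites are scattered along the genome proportionally to chromosome
#' length; parental samples are called homozygous and replicate-consistent,
#' RIL calls follow the underlying mosaic with independent missingness at
#' `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{snps}{a `snp_table`: `$sites` (site, chrom, pos, allele_mm,
#'       allele_pi) and `$calls`, a sites-by-samples character matrix with
#'       values `"MM"`, `"PI"` or `NA`.}
#'     \item{truth_geno}{integer matrix lines-by-SNPs of the true underlying
#'       genotype (1 = MM, 0 = PI), RIL lines only.}
#'     \item{truth}{a `sim_truth` holding lines, crossovers, start alleles,
#'       gene annotation and effect assignments, and hotspot definitions.}
#'   }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  nchr <- config$n_chromosomes
  L <- config$chrom_lengths

  envs <- names(config$n_rils_per_env)
  ril_ids <- sprintf("RIL%03d", seq_len(sum(config$n_rils_per_env)))
  ril_env <- rep(envs, config$n_rils_per_env)
  par_grid <- expand.grid(rep = seq_len(config$n_parent_reps),
                          env = envs, parent = c("MM", "PI"),
                          stringsAsFactors = FALSE)
  par_ids <- sprintf("%s_%s_r%d", par_grid$parent, par_grid$env, par_grid$rep)
  lines_df <- rbind(
    data.frame(sample = ril_ids, line = ril_ids, env = ril_env,
               is_parent = FALSE, parent = NA_character_,
               replicate = 1L, stringsAsFactors = FALSE),
    data.frame(sample = par_ids, line = par_grid$parent, env = par_grid$env,
               is_parent = TRUE, parent = par_grid$parent,
               replicate = par_grid$rep, stringsAsFactors = FALSE)
  )

  # -- RIL mosaics ----------------------------------------------------------
  n_ril <- length(ril_ids)
  xo_list <- vector("list", n_ril * nchr)
  start_allele <- matrix(1L, n_ril, nchr, dimnames = list(ril_ids, NULL))
  k <- 0L
  for (i in seq_len(n_ril)) {
    for (ch in seq_len(nchr)) {
      k <- k + 1L
      if (!is.null(config$distortion) && ch == config$distortion$chrom) {
        seg <- .sim_telegraph(L[ch], config$mean_crossovers_per_chrom,
                              config$distortion$pi_freq)
        start_allele[i, ch] <- seg$start
        pos <- seg$pos
      } else {
        start_allele[i, ch] <- sample(c(1L, 0L), 1L)
        n_xo <- stats::rpois(1L, config$mean_crossovers_per_chrom)
        pos <- .sim_xo_positions(n_xo, L[ch], config$arm_bias)
      }
      xo_list[[k]] <- if (length(pos))
        data.frame(line = ril_ids[i], chrom = ch, pos = pos) else NULL
    }
  }
  crossovers <- do.call(rbind, xo_list)
  if (is.null(crossovers))
    crossovers <- data.frame(line = character(), chrom = integer(),
                             pos = numeric())

  # -- SNP sites ------------------------------------------------------------
  n_per_chr <- .apportion(config$n_snps, L)
  sites <- do.call(rbind, lapply(seq_len(nchr), function(ch) {
    if (n_per_chr[ch] == 0) return(NULL)
    pos <- sort(unique(ceiling(stats::runif(n_per_chr[ch]) * L[ch])))
    data.frame(chrom = ch, pos = pos)
  }))
  nuc <- c("A", "C", "G", "T")
  mm_allele <- sample(nuc, nrow(sites), replace = TRUE)
  pi_allele <- vapply(mm_allele, function(a) sample(setdiff(nuc, a), 1L), "")
  sites <- data.frame(site = sprintf("snp%05d", seq_len(nrow(sites))),
                      chrom = sites$chrom, pos = sites$pos,
                      allele_mm = mm_allele, allele_pi = unname(pi_allele),
                      stringsAsFactors = FALSE)

  # -- true RIL genotypes at SNP sites --------------------------------------
  truth_geno <- matrix(NA_integer_, n_ril, nrow(sites),
                       dimnames = list(ril_ids, sites$site))
  for (ch in seq_len(nchr)) {
    idx <- which(sites$chrom == ch)
    p <- sites$pos[idx]
    for (i in seq_len(n_ril)) {
      xo <- crossovers$pos[crossovers$line == ril_ids[i] &
                             crossovers$chrom == ch]
      n_before <- findInterval(p, sort(xo))
      truth_geno[i, idx] <- ifelse(n_before %% 2L == 0L,
                                   start_allele[i, ch],
                                   1L - start_allele[i, ch])
    }
  }

  # -- calls matrix ---------------------------------------------------------
  all_samples <- lines_df$sample
  calls <- matrix(NA_character_, nrow(sites), length(all_samples),
                  dimnames = list(sites$site, all_samples))
  code <- c("PI", "MM")
  calls[, ril_ids] <- t(matrix(code[truth_geno + 1L], n_ril, nrow(sites)))
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(nrow(sites) * n_ril) < config$missing_rate,
                   nrow(sites), n_ril)
    calls[, ril_ids][drop] <- NA_character_
  }
  calls[, lines_df$sample[lines_df$is_parent & lines_df$parent == "MM"]] <- "MM"
  calls[, lines_df$sample[lines_df$is_parent & lines_df$parent == "PI"]] <- "PI"

  snps <- structure(list(sites = sites, calls = calls), class = "snp_table")

  # -- genes and effect assignments -----------------------------------------
  g_per_chr <- .apportion(config$n_genes, L)
  genes <- do.call(rbind, lapply(seq_len(nchr), function(ch) {
    if (g_per_chr[ch] == 0) return(NULL)
    start <- sort(ceiling(stats::runif(g_per_chr[ch]) * (L[ch] - 1e4)))
    len <- pmax(200, round(stats::rlnorm(g_per_chr[ch],
                                         config$gene_length_meanlog,
                                         config$gene_length_sdlog)))
    data.frame(chrom = ch, start = start, end = start + len, length = len)
  }))
  genes <- data.frame(gene = sprintf("gene%05d", seq_len(nrow(genes))),
                      genes, stringsAsFactors = FALSE)
  ng <- nrow(genes)
  genes$cis_effect <- 0
  n_cis <- round(config$cis_frac * ng)
  if (n_cis > 0) {
    ci <- sample(ng, n_cis)
    genes$cis_effect[ci] <- sample(c(-1, 1), n_cis, replace = TRUE) *
      config$cis_effect_size
  }
  genes$treatment_effect <- 0
  n_trt <- round(config$treatment_frac * ng)
  if (n_trt > 0) {
    ti <- sample(ng, n_trt)
    genes$treatment_effect[ti] <- sample(c(-1, 1), n_trt, replace = TRUE) *
      config$treatment_effect_size
  }
  genes$gxe_effect <- 0
  n_gxe <- round(config$gxe_frac * ng)
  if (n_gxe > 0) {
    gi <- sample(ng, n_gxe)
    genes$gxe_effect[gi] <- sample(c(-1, 1), n_gxe, replace = TRUE) *
      config$gxe_effect_size
  }
  genes$baseline <- stats::runif(ng, config$baseline_range[1],
                                 config$baseline_range[2])

  hotspot_targets <- NULL
  hotspots <- config$hotspots
  if (!is.null(hotspots)) {
    hotspots$hotspot <- sprintf("HS%d", seq_len(nrow(hotspots)))
    hotspot_targets <- do.call(rbind, lapply(seq_len(nrow(hotspots)), function(h) {
      hs <- hotspots[h, ]
      # targets drawn among genes far (> 5 Mb or other chromosome) from the
      # hotspot locus so the induced eQTLs are unambiguously trans
      far <- which(genes$chrom != hs$chrom |
                     abs(genes$start - hs$pos) > 5e6)
      tg <- sample(far, min(hs$n_targets, length(far)))
      sgn <- ifelse(stats::runif(length(tg)) < config$hotspot_sign_prob, 1, -1)
      data.frame(hotspot = hs$hotspot, gene = genes$gene[tg],
                 effect = sgn * hs$effect, stringsAsFactors = FALSE)
    }))
  }

  truth <- structure(list(
    lines = lines_df,
    crossovers = crossovers,
    start_allele = start_allele,
    genes = genes,
    hotspots = hotspots,
    hotspot_targets = hotspot_targets,
    config = config
  ), class = "sim_truth")

  list(snps = snps, truth_geno = truth_geno, truth = truth)
}

# crossover positions: fraction arm_bias uniform in the distal thirds,
# remainder uniform along the chromosome
.sim_xo_positions <- function(n, L, arm_bias) {
  if (n == 0L) return(numeric())
  in_arm <- stats::runif(n) < arm_bias
  pos <- numeric(n)
  u <- stats::runif(n)
  left <- stats::runif(n) < 0.5
  pos[in_arm & left] <- u[in_arm & left] * L / 3
  pos[in_arm & !left] <- L * 2 / 3 + u[in_arm & !left] * L / 3
  pos[!in_arm] <- u[!in_arm] * L
  sort(pos)
}

# stationary two-state Markov mosaic with PI stationary frequency p and
# expected switch count m over length L
.sim_telegraph <- function(L, m, p) {
  start <- if (stats::runif(1) < p) 0L else 1L  # 0 = PI, 1 = MM
  if (m <= 0) return(list(start = start, pos = numeric()))
  s <- m / (2 * p * (1 - p) * L)
  rate <- c(s * p, s * (1 - p))  # leave-MM, leave-PI intensities
  pos <- numeric(); x <- start; at <- 0
  repeat {
    at <- at + stats::rexp(1, if (x == 1L) rate[1] else rate[2])
    if (at >= L) break
    pos <- c(pos, at); x <- 1L - x
  }
  list(start = start, pos = pos)
}

# integer apportionment of n over weights w (largest remainder)
.apportion <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' True genotype of each RIL at arbitrary genomic positions
#'
#' Looks up the underlying parental origin (1 = MM, 0 = PI) of every RIL at
#' the given chromosome/positions from the simulated crossover mosaic.
#'
#' @param truth A `sim_truth`.
#' @param chrom Chromosome index (scalar).
#' @param pos Positions in bp (vector).
#' @return Integer matrix, RIL lines by positions.
#' @export
truth_genotype_at <- function(truth, chrom, pos) {
  rils <- truth$lines$sample[!truth$lines$is_parent]
  out <- matrix(NA_integer_, length(rils), length(pos),
                dimnames = list(rils, NULL))
  xo <- truth$crossovers[truth$crossovers$chrom == chrom, ]
  for (i in seq_along(rils)) {
    x <- sort(xo$pos[xo$line == rils[i]])
    parity <- findInterval(pos, x) %% 2L
    s <- truth$start_allele[rils[i], chrom]
    out[i, ] <- ifelse(parity == 0L, s, 1L - s)
  }
  out
}

#' Simulate an expression count matrix over a simulated population
#'
#' Builds a latent log2 expression value per gene and sample as
#' baseline + cis effect x genotype at the gene's own locus + hotspot
#' effects (active only in samples of the hotspot's environment) x genotype
#' at the hotspot locus + treatment effect + G-by-E term + Normal residual,
#' then draws counts from a negative-binomial observation layer whose
#' expectations are consistent with length-weighted TPM and the configured
#' library size. Setting `nb_dispersion = 0` gives the noise-free limit
#' (deterministic rounded expected counts), useful for exact oracle tests.
#' Parental replicates share their line's genotype and differ only through
#' the residual and counting noise.
#'
#' @param pop Result of [simulate_population()].
#' @param config The same [sim_config()] used to generate `pop`.
#' @return An `expr_set` (see [expr_set()]) with the `counts` layer filled.
#' @export
simulate_expression <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- pop$truth
  genes <- truth$genes
  lines_df <- truth$lines
  set.seed(config$rng_seed + 1L)

  ng <- nrow(genes)
  ns <- nrow(lines_df)
  samples <- lines_df$sample
  rils <- samples[!lines_df$is_parent]

  # genotype (1 = MM) of every sample at every gene's own locus
  gx <- matrix(NA_integer_, ng, ns, dimnames = list(genes$gene, samples))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    g_ril <- truth_genotype_at(truth, ch, genes$start[gi])  # rils x gi
    gx[gi, rils] <- t(g_ril)
  }
  gx[, samples[lines_df$is_parent & lines_df$parent == "MM"]] <- 1L
  gx[, samples[lines_df$is_parent & lines_df$parent == "PI"]] <- 0L

  hp_ind <- as.numeric(lines_df$env == names(config$n_rils_per_env)[1])
  latent <- matrix(genes$baseline, ng, ns) +
    genes$cis_effect * gx +
    outer(genes$treatment_effect, hp_ind) +
    genes$gxe_effect * gx * matrix(hp_ind, ng, ns, byrow = TRUE)

  if (!is.null(truth$hotspots)) {
    for (h in seq_len(nrow(truth$hotspots))) {
      hs <- truth$hotspots[h, ]
      tg <- truth$hotspot_targets[truth$hotspot_targets$hotspot == hs$hotspot, ]
      hx_ril <- truth_genotype_at(truth, hs$chrom, hs$pos)[, 1]
      hx <- numeric(ns); names(hx) <- samples
      hx[rils] <- hx_ril
      hx[samples[lines_df$is_parent & lines_df$parent == "MM"]] <- 1
      hx[samples[lines_df$is_parent & lines_df$parent == "PI"]] <- 0
      active <- as.numeric(lines_df$env == hs$env)
      gi <- match(tg$gene, genes$gene)
      latent[gi, ] <- latent[gi, ] + outer(tg$effect, hx * active)
    }
  }

  if (config$residual_sd > 0)
    latent <- latent + matrix(stats::rnorm(ng * ns, 0, config$residual_sd),
                              ng, ns)

  w <- genes$length * 2^latent
  mu <- t(t(w) / colSums(w)) * config$lib_size
  if (config$nb_dispersion > 0) {
    counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                    size = 1 / config$nb_dispersion), ng, ns)
  } else {
    counts <- round(mu)
  }
  dimnames(counts) <- list(genes$gene, samples)

  expr_set(counts = counts,
           samples = data.frame(sample = samples,
                                line = lines_df$line,
                                treatment = lines_df$env,
                                is_parent = lines_df$is_parent,
                                replicate = lines_df$replicate,
                                stringsAsFactors = FALSE),
           genes = genes[, c("gene", "chrom", "start", "end", "length")])
}

#' Simulate genotype-independent ("null") expression data
#'
#' As [simulate_expression()] but with every genetic effect (cis, hotspot,
#' G-by-E) set to zero, so expression is independent of genotype. Treatment
#' effects and residual/count noise are retained. Used to calibrate
#' permutation thresholds and false-discovery control.
#'
#' @param config A [sim_config()].
#' @return An `expr_set` with the counts layer filled. The generating
#'   population is attached as attribute `"pop"` for stages that need the
#'   (unlinked) genotypes.
#' @export
simulate_null <- function(config) {
  cfg <- config
  cfg$cis_frac <- 0
  cfg$gxe_frac <- 0
  cfg$hotspots <- NULL
  pop <- simulate_population(cfg)
  em <- simulate_expression(pop, cfg)
  attr(em, "pop") <- pop
  em
}
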