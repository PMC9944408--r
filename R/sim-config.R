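#' Simulation configuration for a synthetic RIL population
#'
#' Builds the parameter set driving [simulate_population()] and
#' [simulate_expression()]. Defaults emulate a tomato-like biparental RIL
#' experiment: 12 chromosomes, two maternal nutrient environments (high
#' phosphorus, HP, with 49 lines and low nitrogen, LN, with 52 lines), three
#' parental replicates per line per environment, and on average two
#' crossovers per chromosome per line, concentrated in the distal thirds of
#' each chromosome where recombination is frequent in euchromatin.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bp. Defaults to approximate
#'   tomato chromosome sizes; recycled or truncated to `n_chromosomes`.
#' @param n_rils_per_env Named integer vector, lines per environment.
#'   Environments are taken from its names (default `HP`/`LN`); the two RIL
#'   sets are disjoint, as each plant is grown in a single environment.
#' @param n_parent_reps Parental replicates per parent per environment.
#' @param n_snps Total number of biallelic parental SNP sites, distributed
#'   over chromosomes proportionally to length.
#' @param n_genes Number of genes.
#' @param mean_crossovers_per_chrom Mean of the Poisson crossover count per
#'   line per chromosome.
#' @param arm_bias Fraction of crossovers forced into the distal thirds of
#'   the chromosome (the two "arms"); the remainder is uniform genome-wide.
#' @param missing_rate Per-call probability that a RIL SNP call is missing.
#' @param distortion Optional segregation distortion: `NULL` (off) or a list
#'   `list(chrom =, pi_freq =)` giving the chromosome and the stationary PI
#'   allele frequency to simulate there.
#' @param cis_frac Fraction of genes given a cis effect.
#' @param cis_effect_size Absolute cis effect, log2 units; signs random.
#' @param hotspots Hotspot definitions: a data.frame with columns
#'   `chrom`, `pos`, `env`, `n_targets`, `effect` (log2 effect on each
#'   target; sign per target is drawn with `hotspot_sign_prob` probability
#'   of being positive). `NULL` for none.
#' @param hotspot_sign_prob Probability a hotspot target effect is positive
#'   (MM allele raises abundance).
#' @param treatment_frac Fraction of genes with a treatment (environment)
#'   main effect.
#' @param treatment_effect_size Absolute treatment effect, log2 units.
#' @param gxe_frac Fraction of genes with a genotype-by-environment
#'   interaction at their cis locus.
#' @param gxe_effect_size Absolute G-by-E effect, log2 units.
#' @param residual_sd Residual SD of latent log2 expression.
#' @param nb_dispersion Negative-binomial dispersion of the count layer
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param lib_size Expected library size (total counts per sample).
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of
#'   simulated gene lengths (bp).
#' @param rng_seed Integer seed; identical configurations (including seed)
#'   give identical outputs.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 12,
                       chrom_lengths = NULL,
                       n_rils_per_env = c(HP = 49, LN = 52),
                       n_parent_reps = 3,
                       n_snps = 6000,
                       n_genes = 1000,
                       mean_crossovers_per_chrom = 2.0,
                       arm_bias = 0.8,
                       missing_rate = 0.01,
                       distortion = NULL,
                       cis_frac = 0.3,
                       cis_effect_size = 1.0,
                       hotspots = NULL,
                       hotspot_sign_prob = 0.5,
                       treatment_frac = 0.2,
                       treatment_effect_size = 1.0,
                       gxe_frac = 0,
                       gxe_effect_size = 0,
                       residual_sd = 0.25,
                       nb_dispersion = 0.05,
                       lib_size = 2e6,
                       baseline_range = c(3, 8),
                       gene_length_meanlog = log(2000),
                       gene_length_sdlog = 0.6,
                       rng_seed = 1L) {
  if (is.null(chrom_lengths)) {
    # approximate tomato (SL4.0-scale) chromosome sizes, bp
    tomato <- c(90.9, 53.5, 65.3, 64.5, 65.0, 47.0,
                67.1, 63.1, 68.5, 64.8, 54.4, 66.7) * 1e6
    chrom_lengths <- rep_len(tomato, n_chromosomes)
  } else {
    chrom_lengths <- rep_len(chrom_lengths, n_chromosomes)
  }
  stopifnot(n_chromosomes >= 1, all(chrom_lengths > 0),
            all(n_rils_per_env >= 1), n_parent_reps >= 1,
            n_snps >= 1, n_genes >= 1,
            mean_crossovers_per_chrom >= 0,
            arm_bias >= 0, arm_bias <= 1,
            missing_rate >= 0, missing_rate < 1,
            residual_sd >= 0, nb_dispersion >= 0, lib_size > 0)
  if (is.null(names(n_rils_per_env)))
    names(n_rils_per_env) <- c("HP", "LN")[seq_along(n_rils_per_env)]
  if (!is.null(distortion))
    stopifnot(is.list(distortion),
              distortion$chrom %in% seq_len(n_chromosomes),
              distortion$pi_freq > 0, distortion$pi_freq < 1)
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    stopifnot(all(c("chrom", "pos", "env", "n_targets", "effect") %in%
                    names(hotspots)),
              all(hotspots$chrom %in% seq_len(n_chromosomes)),
              all(hotspots$env %in% names(n_rils_per_env)))
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = chrom_lengths,
    n_rils_per_env = n_rils_per_env,
    n_parent_reps = as.integer(n_parent_reps),
    n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes),
    mean_crossovers_per_chrom = mean_crossovers_per_chrom,
    arm_bias = arm_bias,
    missing_rate = missing_rate,
    distortion = distortion,
    cis_frac = cis_frac,
    cis_effect_size = cis_effect_size,
    hotspots = hotspots,
    hotspot_sign_prob = hotspot_sign_prob,
    treatment_frac = treatment_frac,
    treatment_effect_size = treatment_effect_size,
    gxe_frac = gxe_frac,
    gxe_effect_size = gxe_effect_size,
    residual_sd = residual_sd,
    nb_dispersion = nb_dispersion,
    lib_size = lib_size,
    baseline_range = baseline_range,
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$hotspots)) x$hotspots <- as.list(x$hotspots)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$hotspots)) x$hotspots <- as.data.frame(x$hotspots)
  if (!is.null(x$n_rils_per_env)) x$n_rils_per_env <- unlist(x$n_rils_per_env)
  do.call(sim_config, x)
}
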