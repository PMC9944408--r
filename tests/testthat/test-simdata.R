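test_that("simulation is deterministic given the seed", {
  cfg <- small_cfg(seed = 42)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$snps, b$snps)
  expect_identical(a$truth_geno, b$truth_geno)
  ea <- simulate_expression(a, cfg)
  eb <- simulate_expression(b, cfg)
  expect_identical(ea$counts, eb$counts)
  expect_identical(simulate_null(cfg)$counts, simulate_null(cfg)$counts)
})

test_that("zero crossover rate gives single-segment chromosomes", {
  cfg <- small_cfg(seed = 3, mean_crossovers_per_chrom = 0)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$truth$crossovers), 0)
  gm <- call_bin_genotypes(pop$snps,
                           pop$truth$lines$sample[!pop$truth$lines$is_parent],
                           bin_size = 25)
  gm <- collapse_unique_markers(gm)
  expect_equal(sum(count_recombinations(gm)$counts$n_recomb), 0)
})

test_that("crossover totals match the Poisson rate over many seeds", {
  # Monte-Carlo oracle: 12 chromosomes, 100 RILs at rate 2 => mean 2400
  total <- vapply(1:20, function(s) {
    cfg <- sim_config(n_chromosomes = 12, n_rils_per_env = c(HP = 50, LN = 50),
                      n_snps = 12, n_genes = 2, rng_seed = s)
    nrow(simulate_population(cfg)$truth$crossovers)
  }, numeric(1))
  expected <- 2 * 12 * 100
  se <- sqrt(expected / 20)   # SD of the mean of 20 Poisson totals
  expect_lt(abs(mean(total) - expected), 3 * se)
})

test_that("per-marker allele frequency is balanced without distortion", {
  cfg <- small_cfg(seed = 11)
  pop <- simulate_population(cfg)
  freq <- colMeans(pop$truth_geno == 0)
  n <- nrow(pop$truth_geno)
  expect_true(all(abs(freq - 0.5) <= 3 * sqrt(0.25 / n) + 1e-9) ||
                mean(abs(freq - 0.5) <= 3 * sqrt(0.25 / n)) > 0.97)
})

test_that("configured segregation distortion is recovered in the truth", {
  cfg <- sim_config(n_chromosomes = 3, chrom_lengths = rep(50e6, 3),
                    n_rils_per_env = c(HP = 150, LN = 150), n_snps = 900,
                    n_genes = 2, missing_rate = 0,
                    distortion = list(chrom = 2, pi_freq = 0.7),
                    rng_seed = 5)
  pop <- simulate_population(cfg)
  on2 <- pop$snps$sites$chrom == 2
  f2 <- mean(pop$truth_geno[, on2] == 0)
  f_other <- mean(pop$truth_geno[, !on2] == 0)
  expect_lt(abs(f2 - 0.7), 0.05)
  expect_lt(abs(f_other - 0.5), 0.05)
})

test_that("noise-free null model gives deterministic counts and zero architecture", {
  cfg <- small_cfg(seed = 8, cis_frac = 0, treatment_frac = 0,
                   residual_sd = 0, nb_dispersion = 0)
  em <- simulate_null(cfg)
  # all samples identical up to rounding of the shared expectation
  expect_lt(max(apply(em$counts, 1, function(r) diff(range(r)))), 2)
  em <- transform_expression(compute_tpm(em))
  tg <- transgression(em$tpm_log[1, !em$samples$is_parent],
                      em$tpm_log[1, em$samples$is_parent &
                                   em$samples$line == "MM"],
                      em$tpm_log[1, em$samples$is_parent &
                                   em$samples$line == "PI"])
  expect_true(tg$degenerate)
  expect_equal(tg$n_transgressive, 0)
  h <- heritability(em$tpm_log[1, !em$samples$is_parent],
                    em$tpm_log[1, em$samples$is_parent &
                                 em$samples$line == "MM"],
                    em$tpm_log[1, em$samples$is_parent &
                                 em$samples$line == "PI"])
  expect_true(is.na(h$h2))
})

test_that("simulated counts are non-negative integers and TPM sums to 1e6", {
  cfg <- small_cfg(seed = 13, nb_dispersion = 0.1)
  pop <- simulate_population(cfg)
  em <- simulate_expression(pop, cfg)
  expect_true(all(em$counts >= 0))
  expect_true(all(em$counts == round(em$counts)))
  em <- compute_tpm(em)
  expect_equal(unname(colSums(em$tpm)), rep(1e6, ncol(em$tpm)),
               tolerance = 1e-9)
})

test_that("parental SNP calls are homozygous and replicate-consistent", {
  cfg <- small_cfg(seed = 21, missing_rate = 0.05)
  pop <- simulate_population(cfg)
  par_mm <- pop$truth$lines$sample[pop$truth$lines$is_parent &
                                     pop$truth$lines$parent == "MM"]
  par_pi <- pop$truth$lines$sample[pop$truth$lines$is_parent &
                                     pop$truth$lines$parent == "PI"]
  expect_true(all(pop$snps$calls[, par_mm] == "MM"))
  expect_true(all(pop$snps$calls[, par_pi] == "PI"))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(chrom_lengths = 0))
  expect_error(sim_config(mean_crossovers_per_chrom = -1))
  expect_error(sim_config(n_genes = 0))
  expect_error(sim_config(hotspots = data.frame(chrom = 99, pos = 1,
                                                env = "HP", n_targets = 5,
                                                effect = 1)))
})

test_that("sim_config round-trips through YAML", {
  cfg <- small_cfg(seed = 4)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$chrom_lengths, cfg$chrom_lengths)
  expect_equal(cfg2$n_rils_per_env, cfg$n_rils_per_env)
  expect_identical(simulate_population(cfg2)$snps,
                   simulate_population(cfg)$snps)
})
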