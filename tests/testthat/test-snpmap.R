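make_snp_table <- function(calls, chrom = NULL, pos = NULL) {
  n <- nrow(calls)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("s%03d", 1:n)
  structure(list(
    sites = data.frame(site = rownames(calls),
                       chrom = if (is.null(chrom)) rep(1L, n) else chrom,
                       pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
                       allele_mm = "A", allele_pi = "G",
                       stringsAsFactors = FALSE),
    calls = calls), class = "snp_table")
}

test_that("consistency filter keeps parental-consistent fully observed sites", {
  calls <- rbind(
    c("MM", "MM", "MM", "PI", "PI", "PI", "MM", "PI"),  # retained
    c("MM", "PI", "MM", "PI", "PI", "PI", "MM", "PI"),  # MM reps disagree
    c("MM", "MM", "MM", "PI", "PI", "PI", NA,   "PI"),  # missing in a RIL
    c("MM", "MM", "MM", "MM", "MM", "MM", "MM", "MM"),  # parents identical
    c(NA,   "MM", "MM", "PI", "PI", "PI", "MM", "PI"))  # parent missing
  colnames(calls) <- c("MMr1", "MMr2", "MMr3", "PIr1", "PIr2", "PIr3",
                       "RIL1", "RIL2")
  snps <- make_snp_table(calls)
  out <- filter_consistent_snps(snps,
                                list(MM = c("MMr1", "MMr2", "MMr3"),
                                     PI = c("PIr1", "PIr2", "PIr3")),
                                c("RIL1", "RIL2"))
  expect_equal(out$sites$site, "s001")
  expect_warning(
    filter_consistent_snps(make_snp_table(calls[2, , drop = FALSE]),
                           list(MM = c("MMr1", "MMr2", "MMr3"),
                                PI = c("PIr1", "PIr2", "PIr3")),
                           c("RIL1", "RIL2")),
    "no SNP site")
})

test_that("bin genotype probability is the MM call fraction with tie -> NA", {
  calls <- matrix("MM", 100, 3,
                  dimnames = list(NULL, c("L1", "L2", "L3")))
  calls[1:10, "L2"] <- "PI"          # 90/10 -> prob 0.9, MM
  calls[1:50, "L3"] <- "PI"          # 50/50 -> NA
  snps <- make_snp_table(calls)
  gm <- call_bin_genotypes(snps, c("L1", "L2", "L3"), bin_size = 100)
  expect_equal(ncol(gm$geno), 1)                      # one full bin
  expect_equal(unname(gm$prob[, 1]), c(1.0, 0.9, 0.5))
  expect_equal(unname(gm$geno[, 1]), c(1L, 1L, NA))
  expect_equal(gm$map$pos, mean(snps$sites$pos))
})

test_that("cells below the informative fraction become NA", {
  calls <- matrix("MM", 100, 2, dimnames = list(NULL, c("L1", "L2")))
  calls[1:95, "L2"] <- NA            # 5% informative < 10%
  gm <- call_bin_genotypes(make_snp_table(calls), c("L1", "L2"),
                           bin_size = 100)
  expect_equal(unname(gm$geno[, 1]), c(1L, NA))
})

test_that("collapsing merges identical adjacent columns and is idempotent", {
  geno <- rbind(c(1L, 1L, 0L, 0L, 1L),
                c(1L, 1L, 1L, 1L, 0L))
  gm <- make_gm(geno)
  c1 <- collapse_unique_markers(gm)
  expect_equal(ncol(c1$geno), 3)          # markers 1+2 and 3+4 merge
  expect_equal(c1$map$pos[1], 1.5e6)      # mean of member positions
  c2 <- collapse_unique_markers(c1)
  expect_equal(unname(c2$geno), unname(c1$geno))
  expect_equal(c2$map$pos, c1$map$pos)
  # columns differing in one line stay distinct
  expect_equal(ncol(collapse_unique_markers(
    make_gm(rbind(c(1L, 1L), c(1L, 0L))))$geno), 2)
})

test_that("recombination counting skips NA and records breakpoint intervals", {
  gm <- make_gm(rbind(c(1L, 1L, 0L, 0L),
                      c(1L, NA, 0L, 0L),
                      c(1L, 1L, 1L, 1L)))
  rec <- count_recombinations(gm)
  expect_equal(rec$counts$n_recomb, c(1, 1, 0))
  bp <- rec$breakpoints
  expect_equal(bp$left_bp[bp$line == "L01"], 2e6)
  expect_equal(bp$right_bp[bp$line == "L01"], 3e6)
  # NA-skip: breakpoint interval spans the gap
  expect_equal(bp$left_bp[bp$line == "L02"], 1e6)
  expect_equal(bp$right_bp[bp$line == "L02"], 3e6)
})

test_that("cM map accumulates 100 * recombination fraction from zero", {
  # 50 lines, 1 recombinant between the two markers -> 2 cM
  geno <- cbind(rep(1L, 50), c(0L, rep(1L, 49)))
  geno[26:50, ] <- 0L
  geno[26, 2] <- 1L   # two recombinants of 50 -> second test below
  gm <- build_cm_map(make_gm(geno))
  expect_equal(gm$map$cm[1], 0)
  expect_equal(gm$map$cm[2], 100 * mean(geno[, 1] != geno[, 2]))
  # single recombinant of 50 informative -> exactly 2 cM
  geno2 <- cbind(rep(1L, 50), rep(1L, 50))
  geno2[7, 2] <- 0L
  expect_equal(build_cm_map(make_gm(geno2))$map$cm[2], 2)
  # identical columns -> 0 increment
  geno3 <- cbind(rep(1L, 10), rep(1L, 10))
  expect_equal(build_cm_map(make_gm(geno3))$map$cm[2], 0)
})

test_that("cM increments are invariant to duplicating a marker column", {
  geno <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L), c(1L, 1L, 1L))
  base <- build_cm_map(make_gm(geno))
  dup <- build_cm_map(make_gm(geno[, c(1, 2, 2, 3)]))
  expect_equal(max(dup$map$cm), max(base$map$cm))
})

test_that("noise-free dense bins reproduce a crafted mosaic exactly", {
  # 5 lines, 600 SNPs, breakpoints after chosen SNP indices, all separated
  # by more than a window; odd bin size avoids exact ties
  b <- 25
  brk <- list(L1 = c(100, 400), L2 = 250, L3 = integer(),
              L4 = c(50, 300, 550), L5 = 480)
  truth <- sapply(brk, function(x) {
    g <- rep(1L, 600)
    state <- 1L
    bounds <- c(x, 600)
    at <- 1
    for (q in seq_along(bounds)) {
      g[at:bounds[q]] <- state
      state <- 1L - state
      at <- bounds[q] + 1
    }
    g
  })  # snps x lines
  calls <- matrix(c("PI", "MM")[truth + 1], 600, 5,
                  dimnames = list(NULL, names(brk)))
  gm <- call_bin_genotypes(make_snp_table(calls), names(brk), bin_size = b)
  centers <- seq((b + 1) / 2, length.out = ncol(gm$geno))
  expect_equal(unname(t(gm$geno)), unname(truth[centers, ]))
  # collapapsed marker count = distinct mosaic blocks over the window centers
  gmc <- collapse_unique_markers(gm)
  tc <- truth[centers, , drop = FALSE]
  blocks <- 1 + sum(vapply(2:nrow(tc), function(j)
    any(tc[j, ] != tc[j - 1, ]), logical(1)))
  expect_equal(ncol(gmc$geno), blocks)
  expect_equal(blocks, 1 + length(unique(unlist(brk))))
})

test_that("simulated dense bins equal the truth wherever a window holds at most one crossover", {
  cfg <- small_cfg(seed = 17, n_snps = 4000,
                   mean_crossovers_per_chrom = 1)
  pop <- simulate_population(cfg)
  rils <- pop$truth$lines$sample[!pop$truth$lines$is_parent]
  b <- 25
  gm <- call_bin_genotypes(pop$snps, rils, bin_size = b)
  for (ch in 1:2) {
    sn <- which(pop$snps$sites$chrom == ch)
    jj <- which(gm$map$chrom == ch)
    centers <- sn[seq((b + 1) / 2, length.out = length(jj))]
    lo_bp <- pop$snps$sites$pos[sn[seq_along(jj)]]
    hi_bp <- pop$snps$sites$pos[sn[seq_along(jj) + b - 1]]
    for (i in seq_along(rils)) {
      xo <- pop$truth$crossovers$pos[pop$truth$crossovers$line == rils[i] &
                                       pop$truth$crossovers$chrom == ch]
      n_in <- vapply(seq_along(jj), function(w)
        sum(xo >= lo_bp[w] & xo <= hi_bp[w]), numeric(1))
      ok <- n_in <= 1
      expect_equal(unname(gm$geno[i, jj][ok]),
                   unname(pop$truth_geno[i, centers][ok]))
    }
  }
})

test_that("dense-marker recombination counts match true crossovers within 2%", {
  cfg <- small_cfg(seed = 23, n_snps = 16000, arm_bias = 0,
                   n_rils_per_env = c(HP = 40, LN = 40))
  pop <- simulate_population(cfg)
  rils <- pop$truth$lines$sample[!pop$truth$lines$is_parent]
  gm <- collapse_unique_markers(
    call_bin_genotypes(pop$snps, rils, bin_size = 25))
  detected <- sum(count_recombinations(gm)$counts$n_recomb)
  truth <- nrow(pop$truth$crossovers)
  expect_lt(abs(detected - truth) / truth, 0.02)
})

test_that("allele frequency profile matches configured truth", {
  gm <- make_gm(rbind(c(1L, 0L), c(1L, 0L), c(1L, NA)))
  expect_equal(unname(allele_frequency_profile(gm)), c(0, 1))
  cfg <- sim_config(n_chromosomes = 3, chrom_lengths = rep(40e6, 3),
                    n_rils_per_env = c(HP = 120, LN = 120), n_snps = 3000,
                    n_genes = 2, missing_rate = 0,
                    distortion = list(chrom = 2, pi_freq = 0.7),
                    rng_seed = 31)
  pop <- simulate_population(cfg)
  rils <- pop$truth$lines$sample[!pop$truth$lines$is_parent]
  gm <- collapse_unique_markers(
    call_bin_genotypes(pop$snps, rils, bin_size = 25))
  freq <- allele_frequency_profile(gm)
  expect_lt(abs(mean(freq[gm$map$chrom == 2]) - 0.7), 0.06)
  expect_lt(abs(mean(freq[gm$map$chrom != 2]) - 0.5), 0.06)
})
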