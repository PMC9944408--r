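# expr_set of RILs with prescribed tpm_log, matching a geno_map's lines
ril_em <- function(vals, gm) {
  em <- make_em(matrix(1, nrow(vals), ncol(vals),
                       dimnames = list(rownames(vals), rownames(gm$geno))))
  em$tpm_log <- vals
  colnames(em$tpm_log) <- rownames(gm$geno)
  em
}

test_that("single-marker model matches the one-way ANOVA oracle", {
  gm <- make_gm(cbind(c(1L, 1L, 1L, 0L, 0L, 0L),
                      c(1L, 0L, 1L, 0L, 1L, 0L)))
  trait <- c(1, 2, 3, 4, 5, 6)
  names(trait) <- rownames(gm$geno)
  prof <- map_transcript(gm, trait)
  # genotypes [MM x3, PI x3], trait {1..6} -> F = 13.5 on (1, 4) df
  expect_equal(prof$neg_log10_p[1],
               -log10(pf(13.5, 1, 4, lower.tail = FALSE)))
  expect_equal(prof$effect[1], mean(trait[1:3]) - mean(trait[4:6]))
  oracle <- anova(lm(trait ~ factor(gm$geno[, 2])))$`Pr(>F)`[1]
  expect_equal(prof$neg_log10_p[2], -log10(oracle))
  # marker with one genotype class -> 0, NA effect
  gm1 <- make_gm(cbind(rep(1L, 6), c(1L, 1L, 1L, 0L, 0L, 0L)))
  prof1 <- map_transcript(gm1, trait)
  expect_equal(prof1$neg_log10_p[1], 0)
  expect_true(is.na(prof1$effect[1]))
})

test_that("a perfect cis trait peaks at its own marker", {
  set.seed(3)
  geno <- matrix(sample(0:1, 40 * 10, replace = TRUE), 40, 10)
  gm <- make_gm(geno)
  trait <- geno[, 4] + rnorm(40, 0, 1e-8)
  names(trait) <- rownames(gm$geno)
  prof <- map_transcript(gm, trait)
  expect_equal(which.max(prof$neg_log10_p), 4)
})

test_that("NA genotypes are dropped marker-wise", {
  geno <- cbind(c(1L, 1L, 1L, 0L, 0L, 0L, NA))
  gm <- make_gm(geno)
  trait <- c(1, 2, 3, 4, 5, 6, 100)   # the NA line's value must not count
  names(trait) <- rownames(gm$geno)
  prof <- map_transcript(gm, trait)
  expect_equal(prof$neg_log10_p[1],
               -log10(pf(13.5, 1, 4, lower.tail = FALSE)))
})

test_that("FDR bound arithmetic matches an independent oracle", {
  # m = 14772, q = 0.05, RDS = 4281: bound = (10491/14772) * 0.05 * ln(14772)
  oracle <- (14772 - 4281) / 14772 * 0.05 * log(14772)
  expect_equal(fdr_bound(14772, 4281, 0.05), oracle)
  expect_equal(fdr_bound(100, 0, 0.05), 0.05 * log(100))
  expect_equal(fdr_bound(100, 50, 0.05, log_base = 10),
               0.5 * 0.05 * log10(100))
})

test_that("peak extraction and 1.5-drop interval follow the drop rule", {
  gm <- make_gm(matrix(sample(0:1, 6 * 5, replace = TRUE), 6, 5))
  scan <- structure(list(
    neglogp = rbind(g1 = c(1, 5, 1, 0.2, 0.1),
                    g2 = c(4, 5, 5, 5, 1)),
    effect = matrix(1, 2, 5, dimnames = list(c("g1", "g2"), gm$map$marker)),
    map = gm$map, lines = rownames(gm$geno)), class = "eqtl_scan")
  rec <- eqtl_peaks(scan, threshold = 3)
  r1 <- rec[rec$gene == "g1", ]
  expect_equal(r1$peak_bp, 2e6)
  expect_equal(c(r1$ci_left_bp, r1$ci_right_bp), c(2e6, 2e6))
  # plateau: peak at first 5; CI spans the 4 and all three 5s (4 >= 5 - 1.5)
  r2 <- rec[rec$gene == "g2", ]
  expect_equal(r2$peak_bp, 2e6)
  expect_equal(c(r2$ci_left_bp, r2$ci_right_bp), c(1e6, 4e6))
})

test_that("one record is emitted per chromosome above threshold", {
  gm <- make_gm(matrix(sample(0:1, 6 * 6, replace = TRUE), 6, 6),
                chrom = rep(1:2, each = 3),
                pos = rep(c(1e6, 2e6, 3e6), 2))
  scan <- structure(list(
    neglogp = rbind(g1 = c(1, 6, 1, 1, 7, 1)),
    effect = matrix(-1, 1, 6, dimnames = list("g1", gm$map$marker)),
    map = gm$map, lines = rownames(gm$geno)), class = "eqtl_scan")
  rec <- eqtl_peaks(scan, threshold = 3.9)
  expect_equal(nrow(rec), 2)           # more eQTLs than genes is possible
  expect_equal(rec$chrom, c(1, 2))
  expect_true(all(rec$ci_left_bp <= rec$peak_bp &
                    rec$peak_bp <= rec$ci_right_bp))
})

test_that("cis/trans classification applies the 1 Mb and CI rules", {
  ann <- data.frame(gene = c("near", "far", "inci"),
                    chrom = c(1, 1, 1),
                    start = c(10.0e6, 1e6, 12.0e6),
                    end = c(10.01e6, 1.01e6, 12.01e6))
  rec <- data.frame(gene = c("near", "far", "inci"),
                    chrom = 1,
                    peak_bp = c(10.5e6, 10.5e6, 10.0e6),
                    ci_left_bp = c(10.4e6, 10.4e6, 9e6),
                    ci_right_bp = c(10.6e6, 10.6e6, 13e6),
                    effect_sign = 1)
  out <- classify_eqtl(rec, ann)
  expect_equal(out$type, c("cis", "trans", "cis"))
  # different chromosome -> trans
  rec2 <- rec[1, ]; rec2$chrom <- 5
  expect_equal(classify_eqtl(rec2, ann)$type, "trans")
  # unannotated gene -> NA with warning
  rec3 <- rec[1, ]; rec3$gene <- "mystery"
  expect_warning(out3 <- classify_eqtl(rec3, ann), "unannotated")
  expect_true(is.na(out3$type))
})

test_that("profile maxima are invariant to reordering the lines", {
  set.seed(8)
  geno <- matrix(sample(0:1, 30 * 8, replace = TRUE), 30, 8)
  gm <- make_gm(geno)
  trait <- rnorm(30) + geno[, 3]
  names(trait) <- rownames(gm$geno)
  p1 <- map_transcript(gm, trait)
  o <- sample(30)
  gm2 <- gm; gm2$geno <- gm$geno[o, ]
  p2 <- map_transcript(gm2, trait[o])
  expect_equal(p1$neg_log10_p, p2$neg_log10_p)
})

test_that("the permutation FDR grid behaves at its limits", {
  set.seed(10)
  geno <- matrix(sample(0:1, 40 * 12, replace = TRUE), 40, 12)
  gm <- make_gm(geno)
  # all-signal: every trait a perfect cis effect -> FDS ~ 0, low cutoff
  vals <- t(geno + matrix(rnorm(40 * 12, 0, 0.01), 40, 12))
  rownames(vals) <- sprintf("g%02d", 1:12)
  em <- ril_em(vals, gm)
  scan <- eqtl_scan(gm, em)
  thr <- eqtl_fdr_threshold(scan, gm, em, n_perm = 4, seed = 2)
  expect_false(is.na(thr$cutoff))
  rds_at <- thr$grid$rds[thr$grid$cutoff == thr$cutoff]
  expect_equal(rds_at, 12)
  # null traits: sentinel or a cutoff that satisfies the bound empirically
  vals0 <- matrix(rnorm(12 * 40), 12, 40,
                  dimnames = list(sprintf("n%02d", 1:12), rownames(geno)))
  em0 <- ril_em(vals0, gm)
  scan0 <- eqtl_scan(gm, em0)
  thr0 <- eqtl_fdr_threshold(scan0, gm, em0, n_perm = 6, seed = 3)
  if (!is.na(thr0$cutoff)) {
    g <- thr0$grid[thr0$grid$cutoff == thr0$cutoff, ]
    expect_lte(g$fds / g$rds, g$bound)
  } else {
    succeed()
  }
})
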