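# toy profile: constant flank depth with a depleted binding site
toy_profile <- function(site_depth, flank_depth, site_start = 100,
                        site_end = 120, margin = 60) {
  start <- site_start - margin
  end <- site_end + margin
  counts <- rep(flank_depth, end - start)
  counts[(site_start - start + 1):(site_end - start)] <- site_depth
  structure(list(chrom = "chr1", start = start, counts = counts, norm = 1),
            class = "cut_profile")
}

test_that("footprint depth is the proportional flank-relative depletion", {
  expect_equal(footprint_depth(toy_profile(1, 2), 100, 120), 0.5)
  expect_equal(footprint_depth(toy_profile(2, 2), 100, 120), 0)
  expect_true(is.na(footprint_depth(toy_profile(0, 0), 100, 120)))
  # deeper-than-flank site can go negative; bounded above by 1
  expect_lt(footprint_depth(toy_profile(3, 2), 100, 120), 0)
  expect_equal(footprint_depth(toy_profile(0, 2), 100, 120), 1)
  expect_error(footprint_depth(toy_profile(1, 2, margin = 10), 100, 120),
               "outside")
})

test_that("footprint depth is invariant to depth rescaling", {
  set.seed(8)
  base <- toy_profile(1, 2)
  base$counts <- base$counts + runif(length(base$counts), 0, 0.5)
  for (c in c(0.1, 3, 250)) {
    scaled <- base
    scaled$counts <- base$counts * c
    expect_equal(footprint_depth(scaled, 100, 120),
                 footprint_depth(base, 100, 120), tolerance = 1e-12)
  }
})

test_that("cut profiles accumulate bedGraph intervals over a window", {
  bg <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(0, 10, 0), end = c(10, 30, 50),
                   value = c(1, 2.5, 9))
  prof <- cut_profile(bg, "chr1", 5, 20)
  expect_equal(prof$counts, c(rep(1, 5), rep(2.5, 10)))
  expect_equal(length(prof$counts), 15)
})

test_that("comparative FPD contrasts pooled allele groups", {
  profs <- list(A = toy_profile(1, 2), B = toy_profile(1, 2),
                C = toy_profile(1, 2), D = toy_profile(1, 2))
  same <- delta_fpd(profs, 100, 120, c(A = 0, B = 0, C = 1, D = 1))
  expect_equal(same$delta, 0)
  # alt carriers depleted at the site relative to reference carriers
  profs2 <- list(A = toy_profile(1.5, 2), B = toy_profile(1.5, 2),
                 C = toy_profile(0.5, 2), D = toy_profile(0.5, 2))
  gain <- delta_fpd(profs2, 100, 120, c(A = 0, B = 0, C = 1, D = 1))
  expect_gt(gain$delta, 0)
  expect_equal(gain$fpd_ref, 0.25)
  expect_equal(gain$fpd_snp, 0.75)
  expect_equal(gain$delta, 0.5)
  # antisymmetry under swapping the allele labels
  swap <- delta_fpd(profs2, 100, 120, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(swap$delta, -gain$delta)
  expect_message(
    expect_null(delta_fpd(profs2, 100, 120, c(A = 1, B = 1, C = 1, D = 1))),
    "empty allele group")
})

test_that("empirical FPD p-values follow the add-one one-sided rule", {
  nulls <- seq(-0.99, -0.01, length.out = 99)  # all below any positive delta
  expect_equal(empirical_fpd_pvalue(0.5, nulls, "gain"), 0.01)
  expect_equal(empirical_fpd_pvalue(median(nulls), nulls, "gain"),
               (1 + 50) / 100)
  expect_true(is.na(empirical_fpd_pvalue(0.5, nulls[1:19], "gain")))
  # loss direction mirrors
  expect_equal(empirical_fpd_pvalue(-2, nulls, "loss"), 0.01)
  expect_error(empirical_fpd_pvalue(0.5, nulls, "up"), "arg")
})

test_that("empirical p-values are super-uniform under exchangeability", {
  set.seed(99)
  nulls <- rnorm(199)
  ps <- vapply(rnorm(400), empirical_fpd_pvalue, numeric(1),
               null_deltas = nulls, direction = "gain")
  expect_true(all(ps > 0 & ps <= 1))
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= alpha), alpha + 0.05)
})

test_that("gain/loss classification follows the printed rule table", {
  expect_equal(classify_fpd(0.2, 0.01, 0.3), "gain")
  expect_equal(classify_fpd(0.01, 0.2, 0.3), "none")  # sign-inconsistent
  expect_equal(classify_fpd(0.01, 0.2, -0.3), "loss")
  expect_equal(classify_fpd(0.2, 0.01, -0.3), "none")
  expect_equal(classify_fpd(0.2, 0.2, 0.3), "none")
  # boundary: pval_snp exactly 0.05 is a match (<=), pval_ref 0.05 is not (>)
  expect_equal(classify_fpd(0.06, 0.05, 0.1), "gain")
  expect_equal(classify_fpd(0.05, 0.01, 0.1), "none")
})

test_that("footprint flags filter, summarize per SNP, and BH-adjust", {
  records <- data.frame(
    snp_id = c("s1", "s1", "s2", "s3"),
    motif_id = c("m1", "m2", "m1", "m3"),
    pval_rank = c(0.01, 0.02, 0.2, 0.01),
    pval_ref = c(0.2, 0.3, 0.2, 0.01),
    pval_snp = c(0.01, 0.02, 0.01, 0.2),
    delta = c(0.3, 0.2, 0.4, 0.3),
    pval_fpd = c(0.001, 0.04, 0.001, 0.001))
  out <- footprint_flags(records)
  # s1: two qualifying motifs, min p = 0.001; s2 fails pval_rank;
  # s3 is sign-inconsistent (loss rules need delta < 0)
  expect_equal(out$flags, c(s1 = 1, s2 = 0, s3 = 0))
  expect_equal(out$snp_table$min_pval_fpd, 0.001)
  expect_equal(nrow(out$significant_pairs), 2)
  # single SNP, one motif, one test survives BH trivially
  one <- records[1, ]
  expect_equal(unname(footprint_flags(one)$flags["s1"]), 1)
})

test_that("per-peak permutation test retains exact ties and bounds p", {
  signal <- c(1, 5, 1, 5, 1, 5, 1, 5)
  geno <- rbind(s1 = c(0, 1, 0, 1, 0, 1, 0, 1),
                s2 = c(0, 1, 0, 1, 0, 1, 0, 1),   # duplicate genotypes
                s3 = c(1, 0, 0, 0, 1, 0, 0, 1))
  res <- local_atac_mv_test(signal, geno, n_perm = 500, seed = 4)
  expect_setequal(res$best_snps, c("s1", "s2"))
  expect_equal(res$statistic, 1)
  # add-one lower bound; with a binary genotype any permutation restoring
  # the carrier partition (1 in choose(8,4)) ties the observed maximum
  expect_gte(res$p_value, 1 / 501)
  expect_lt(res$p_value, 0.05)
  # constant genotypes cannot be tested
  flat <- rbind(s1 = rep(1, 8))
  expect_message(expect_null(local_atac_mv_test(signal, flat, 100)),
                 "no informative SNP")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(12)
  ps <- vapply(1:60, function(i) {
    signal <- rnorm(8)
    geno <- matrix(rbinom(3 * 8, 1, 0.4), 3, 8)
    geno[rowSums(geno) %in% c(0, 8), 1] <- 1 - geno[rowSums(geno) %in%
                                                      c(0, 8), 1]
    r <- local_atac_mv_test(signal, geno, n_perm = 120)
    r$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)  # roughly uniform, conservative allowed
  expect_lte(mean(ps <= 0.1), 0.2)
})

test_that("peak scan adjusts across peaks", {
  set.seed(5)
  peaks <- list(
    hit = list(signal = c(1, 5, 1, 5, 1, 5, 1, 5),
               genotypes = rbind(s1 = c(0, 1, 0, 1, 0, 1, 0, 1))),
    null1 = list(signal = rnorm(8),
                 genotypes = rbind(s2 = rbinom(8, 1, 0.5))),
    null2 = list(signal = rnorm(8),
                 genotypes = rbind(s3 = rbinom(8, 1, 0.5))))
  out <- local_atac_mv_scan(peaks, n_perm = 300, seed = 9)
  expect_true(all(c("peak_id", "snp_id", "p_adj", "selected") %in%
                    names(out)))
  expect_true("hit" %in% out$peak_id)
  expect_gte(out$p_value[out$peak_id == "hit"], 1 / 301)
  expect_lt(out$p_value[out$peak_id == "hit"], 0.05)
})
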