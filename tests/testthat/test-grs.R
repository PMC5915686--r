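test_that("risk orientation follows the OR >= 1 rule", {
  ds <- arc_dataset(seed = 4)
  ori <- risk_orientation(ds)
  expect_equal(ori$risk_allele[ori$snp_id == "rs11574311"], "minor")
  expect_equal(ori$risk_allele[ori$snp_id == "rs4733220"], "major")
  expect_equal(ori$risk_allele[ori$snp_id == "rs2304277"], "major")
  # boundary: OR exactly 1 -> minor is risk
  G <- matrix(rep(c(0L, 1L), 20), ncol = 1)
  dsb <- make_ds(G, rep(c("case", "control"), each = 20))
  orib <- risk_orientation(dsb)
  expect_equal(orib$source_or, 1)
  expect_equal(orib$risk_allele, "minor")
  # undefined OR points at the haldane correction
  Gz <- matrix(rep(c(1L, 0L), each = 20), ncol = 1)
  dsz <- make_ds(Gz, rep(c("case", "control"), each = 20))
  expect_error(risk_orientation(dsz), "haldane")
  expect_s3_class(risk_orientation(dsz, correction = "haldane"),
                  "risk_orientation")
})

test_that("scores match a hand tally and the orientation-flip involution", {
  man <- toy_manifest(3)
  G <- rbind(c(0L, 1L, 2L), c(2L, 2L, 2L), c(1L, NA, 0L))
  ds <- make_ds(G, c("control", "case", "case"), manifest = man)
  ori <- data.frame(snp_id = man$snp_id,
                    risk_allele = c("minor", "major", "minor"),
                    source_or = c(1.5, 0.8, 1.2))
  p <- grs(ds, orientation = ori)
  # hand tally: row1 = 0 + (2-1) + 2 = 3; row2 = 2 + 0 + 2 = 4;
  # row3 = 1 + skip + 0 = 1 with 2 SNPs used
  expect_equal(p$score, c(3, 4, 1))
  expect_equal(p$n_snps_used, c(3, 3, 2))
  # flipping every orientation maps s -> 2m - s (complete individuals)
  ori_flip <- ori
  ori_flip$risk_allele <- ifelse(ori$risk_allele == "minor", "major", "minor")
  pf <- grs(ds, orientation = ori_flip)
  complete <- p$n_snps_used == 3
  expect_equal(pf$score[complete], 2 * 3 - p$score[complete])
  # maximum: homozygous for the risk allele everywhere
  Gmax <- matrix(c(2L, 0L, 2L), 1)
  dmax <- make_ds(Gmax, "case", manifest = man)
  expect_equal(grs(dmax, orientation = ori)$score, 6)
})

test_that("simulated score distribution matches the binomial convolution", {
  mafs <- c(0.1, 0.25, 0.4, 0.5)
  n <- 1e5
  G <- simulate_hwe_genotypes(mafs, n, seed = 77)
  ds <- make_ds(G, rep(c("case", "control"), n / 2))
  ori <- data.frame(snp_id = paste0("s", 1:4),
                    risk_allele = c("minor", "minor", "major", "minor"),
                    source_or = 1)
  p <- grs(ds, orientation = ori)
  # convolution of per-SNP Binomial(2, r) pmfs, r = risk-allele frequency
  r <- ifelse(ori$risk_allele == "minor", mafs, 1 - mafs)
  pmf <- 1
  for (ri in r) pmf <- convolve(pmf, rev(dbinom(0:2, 2, ri)), type = "open")
  expected <- n * pmf
  observed <- tabulate(p$score + 1, nbins = length(pmf))
  keep <- expected >= 5
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  gof_p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(gof_p, 0.01)
})

test_that("group statistics: identical groups give t = 0, shifts are detected
           at the analytic power, constants shift invariantly", {
  sc <- rep(c(5, 7, 9), 20)
  prof <- structure(data.frame(id = 1:120,
                               phenotype = rep(c("case", "control"), each = 60),
                               subtype = NA_character_,
                               score = c(sc, sc), n_snps_used = 9),
                    class = c("grs", "data.frame"))
  gs <- grs_group_stats(prof, by_subtype = FALSE)
  expect_equal(gs$t, 0)
  expect_equal(gs$p_value, 1)
  # invariance under adding a constant
  prof2 <- prof
  prof2$score <- prof2$score + 7
  gs2 <- grs_group_stats(prof2, by_subtype = FALSE)
  expect_equal(gs2$t, gs$t)
  expect_equal(gs2$p_value, gs$p_value)
  # power of the equal-variance t-test at a known shift ~ closed form
  set.seed(19)
  delta <- 0.6; n <- 50
  rejections <- mean(replicate(300, {
    a <- rnorm(n); b <- rnorm(n, delta)
    t.test(a, b, var.equal = TRUE)$p.value < 0.05
  }))
  analytic <- power.t.test(n = n, delta = delta, sd = 1,
                           sig.level = 0.05)$power
  expect_lt(abs(rejections - analytic), 0.08)
})

test_that("in-sample orientation inflates the case mean (optimism)", {
  diffs <- vapply(1:8, function(i) {
    G <- simulate_hwe_genotypes(rep(0.3, 6), 240, seed = 500 + i)
    ds <- make_ds(G, sample(rep(c("case", "control"), 120)))
    p <- grs(ds, correction = "haldane")
    mean(p$score[p$phenotype == "case"]) -
      mean(p$score[p$phenotype == "control"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)  # null data, yet the case mean is higher
})

test_that("binned odds ratios: reference OR 1, hand cross-product, pooling", {
  prof <- structure(
    data.frame(id = seq_len(60),
               phenotype = rep(c("case", "control"), each = 30),
               subtype = NA_character_,
               score = c(rep(0, 10), rep(2, 20), rep(0, 20), rep(2, 10)),
               n_snps_used = 3),
    class = c("grs", "data.frame"))
  b <- grs_binned_or(prof, bin_width = 2)
  expect_equal(b$or[1], 1)
  expect_equal(b$or[2], (20 * 20) / (10 * 10))  # = 4.0
  # top-bin pooling collapses everything above the threshold
  prof$score <- rep(c(0, 2, 4, 6, 8, 10), 10)
  b2 <- grs_binned_or(prof, bin_width = 2, pool_top_from = 6)
  expect_equal(b2$bin[nrow(b2)], "6-10")
})
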