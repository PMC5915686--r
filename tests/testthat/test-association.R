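test_that("allele tables reproduce published counts and a direct tally", {
  ds <- arc_dataset(seed = 2)
  at <- allele_table(ds, "rs11574311")
  expect_equal(at["control", ], c(minor = 112L, major = 950L))
  expect_equal(at["case", ], c(minor = 236L, major = 1342L))
  # loop oracle on simulated data with missingness
  G <- simulate_hwe_genotypes(rep(0.25, 2), 150, seed = 4)
  G[sample(length(G), 10)] <- NA
  ph <- rep(c("case", "control"), 75)
  ds2 <- make_ds(G, ph)
  at2 <- allele_table(ds2, "s1")
  minor_case <- sum(G[ph == "case", 1], na.rm = TRUE)
  total_case <- 2 * sum(!is.na(G[ph == "case", 1]))
  expect_equal(unname(at2["case", ]), c(minor_case, total_case - minor_case))
  # all-major genotypes
  gc <- c(10, 0, 0)
  expect_equal(unname(2 * gc[1] + gc[2]), 20)
})

test_that("odds ratios and Woolf CIs match printed two-decimal values", {
  or_of <- function(snp) odds_ratio_ci(counts_allele_table(snp))
  r1 <- or_of("rs11574311")
  expect_equal(round(r1$or, 2), 1.49)
  expect_equal(round(r1$ci_low, 2), 1.17)
  expect_equal(round(r1$ci_high, 2), 1.90)
  r2 <- or_of("rs2725383")
  expect_equal(round(r2$or, 2), 1.27)
  expect_equal(round(r2$ci_low, 2), 1.00)
  expect_equal(round(r2$ci_high, 2), 1.62)
  r3 <- or_of("rs2304277")
  expect_equal(round(r3$or, 2), 0.89)
  expect_equal(round(r3$ci_low, 2), 0.76)
  expect_equal(round(r3$ci_high, 2), 1.04)
})

test_that("odds_ratio_ci equals the brute-force cross-product on random tables
           and obeys the group-swap reciprocal property", {
  set.seed(17)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    r <- odds_ratio_ci(tab)
    expect_equal(r$or, oracle_or(tab))
    swapped <- odds_ratio_ci(tab[2:1, ])
    expect_equal(swapped$or, 1 / r$or)
    expect_equal(swapped$ci_low, 1 / r$ci_high)
    expect_equal(swapped$ci_high, 1 / r$ci_low)
    expect_true(r$ci_low <= r$or && r$or <= r$ci_high)
  }
  # symmetric table
  expect_equal(odds_ratio_ci(matrix(50, 2, 2))$or, 1)
  # zero-cell handling
  z <- matrix(c(5, 10, 0, 10), 2, byrow = TRUE)
  expect_false(odds_ratio_ci(z, correction = "none")$defined)
  rh <- odds_ratio_ci(z, correction = "haldane")
  expect_true(rh$defined)
  expect_equal(rh$or, (5.5 * 10.5) / (10.5 * 0.5))
  expect_error(odds_ratio_ci(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("Woolf interval attains nominal coverage on simulated tables", {
  set.seed(23)
  p1 <- 0.35; p2 <- 0.2; n <- 300
  true_or <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  hits <- 0; reps <- 400
  for (i in seq_len(reps)) {
    a <- rbinom(1, n, p1); c <- rbinom(1, n, p2)
    r <- odds_ratio_ci(matrix(c(a, n - a, c, n - c), 2, byrow = TRUE),
                       correction = "haldane")
    hits <- hits + (r$ci_low <= true_or && true_or <= r$ci_high)
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("association test: chi-square equals the two-proportion z-test,
           Fisher engages on sparse tables", {
  tab <- matrix(c(30, 70, 50, 50), 2, byrow = TRUE)
  p_chi <- assoc_test(tab)
  p1 <- 30 / 100; p2 <- 50 / 100; pb <- 80 / 200
  z <- (p1 - p2) / sqrt(pb * (1 - pb) * (1 / 100 + 1 / 100))
  expect_equal(p_chi, 2 * pnorm(-abs(z)))
  # balanced table -> p = 1
  expect_equal(assoc_test(matrix(10, 2, 2)), 1)
  # sparse 2x2 (expected < 5) uses Fisher's exact test
  sparse <- matrix(c(1, 40, 6, 35), 2, byrow = TRUE)
  expect_equal(assoc_test(sparse), fisher.test(sparse)$p.value)
  # genotypic 2x3 stays chi-square
  gt <- rbind(case = c(575, 192, 22), control = c(428, 94, 9))
  expect_equal(round(assoc_test(gt), 3), 0.005)
  expect_error(assoc_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("dominant/recessive models match printed values and edge rules", {
  ds <- arc_dataset(seed = 2)
  dr1 <- dominant_recessive(ds, "rs11574311")
  expect_equal(round(dr1$or[dr1$model == "dominant"], 2), 1.55)
  # published CI 1.19-2.01 was rounded from a slightly different SE; the
  # Woolf interval lands within one rounding unit
  expect_lt(abs(dr1$ci_low[dr1$model == "dominant"] - 1.19), 0.015)
  expect_lt(abs(dr1$ci_high[dr1$model == "dominant"] - 2.01), 0.015)
  dr2 <- dominant_recessive(ds, "rs4733220")
  expect_equal(round(dr2$or[dr2$model == "recessive"], 2), 0.73)
  expect_equal(round(dr2$ci_low[dr2$model == "recessive"], 2), 0.55)
  expect_equal(round(dr2$ci_high[dr2$model == "recessive"], 2), 0.98)
  # zero minor-homozygote cell in controls leaves the recessive OR undefined
  dr3 <- dominant_recessive(ds, "rs7183308")
  expect_false(dr3$defined[dr3$model == "recessive"])
  # all-heterozygote degenerate input: dominant OR 1
  dsh <- make_ds(matrix(1L, 40, 1), rep(c("case", "control"), 20))
  drh <- dominant_recessive(dsh, "s1", correction = "haldane")
  expect_equal(drh$or[drh$model == "dominant"], 1)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.003, 18), 0.054)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(c(0.001, 0.2), 5), c(0.005, 1))
})

test_that("the association scan flags only the known signal after correction", {
  ds <- arc_dataset(seed = 2)
  scan <- snp_association(ds, bonferroni_m = 18, correction = "haldane")
  al <- scan[scan$model == "allelic", ]
  expect_equal(nrow(al), 17)
  expect_equal(al$snp_id[which.min(al$p_value)], "rs11574311")
  expect_true(all(al$p_adj >= al$p_value, na.rm = TRUE))
})
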