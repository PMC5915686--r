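test_that("cell classification follows the threshold and degenerate rules", {
  # 10 cases / 2 controls in one cell at the unbalanced-study threshold
  G <- matrix(0L, 12, 1)
  ds <- make_ds(G, rep(c("case", "control"), c(10, 2)))
  map <- classify_cells(ds, "s1", threshold = 789 / 531)
  expect_equal(map$label[map$s1 == 0], "high")
  ds2 <- make_ds(G, rep(c("case", "control"), c(2, 10)))
  map2 <- classify_cells(ds2, "s1", threshold = 789 / 531)
  expect_equal(map2$label[map2$s1 == 0], "low")
  expect_equal(map2$label[map2$s1 == 1], "empty")
  # all-cases classifying set: every occupied cell high (threshold fixed)
  G3 <- matrix(c(0L, 1L, 2L, 0L), 4, 1)
  ds3 <- make_ds(G3, rep("case", 4))
  map3 <- classify_cells(ds3, "s1", threshold = 1)
  expect_true(all(map3$label[map3$n_case > 0] == "high"))
  # ratio exactly at threshold labels high (deterministic tie rule)
  G4 <- matrix(0L, 4, 1)
  ds4 <- make_ds(G4, rep(c("case", "control"), 2))
  expect_equal(classify_cells(ds4, "s1", threshold = 1)$label[1], "high")
})

test_that("balanced accuracy scores perfect, trivial and random maps as
           expected", {
  G <- matrix(rep(c(0L, 2L), each = 30), ncol = 1)
  ds <- make_ds(G, rep(c("control", "case"), each = 30))
  map <- classify_cells(ds, "s1")
  expect_equal(balanced_accuracy(map, ds), 1)          # perfectly separated
  map_all_high <- map
  map_all_high$label[] <- "high"
  expect_equal(balanced_accuracy(map_all_high, ds), 0.5)  # sens 1, spec 0
  # a map fitted on one random labelling scores 0.5 on independent labels
  set.seed(13)
  bas <- replicate(30, {
    Gr <- matrix(sample(0:2, 200, replace = TRUE), ncol = 1)
    dsr <- make_ds(Gr, sample(rep(c("case", "control"), 100)))
    fresh <- make_ds(Gr, sample(rep(c("case", "control"), 100)))
    balanced_accuracy(classify_cells(dsr, "s1"), fresh)
  })
  expect_lt(abs(mean(bas) - 0.5), 0.03)
  expect_error(balanced_accuracy(map, make_ds(G, rep("case", 60))), "both")
})

test_that("mdr search matches the independent exhaustive oracle exactly", {
  for (seed in 1:3) {
    ds <- simulate_case_control(rep(0.35, 5), 90, 90,
                                marginal_ors = c(2, 1.5, 1, 1, 1),
                                seed = 100 + seed)
    y <- as.integer(ds$phenotype == "case")
    for (k in 1:2) {
      fit <- mdr(ds, k = k, folds = 5, seed = seed)
      fold <- gxgtools:::with_seed(seed,
                                   gxgtools:::stratified_folds(y, 5))
      orc <- oracle_mdr(ds$genotypes, y, fold, k)
      mo <- fit$models[[paste0("k", k)]]
      expect_equal(match(mo$loci, ds$manifest$snp_id), as.integer(orc$loci))
      expect_equal(mo$cvc, orc$cvc)
      expect_equal(mo$testing_ba, orc$testing_ba)
      # fold winner maximises training BA within its fold
      for (f in 1:5)
        expect_equal(max(orc$train_ba[f, ]), orc$train_ba[f, orc$winners[f]])
    }
  }
})

test_that("k=1 search locks onto a strong marginal SNP with full consistency", {
  ds <- simulate_case_control(rep(0.3, 5), 400, 400,
                              marginal_ors = c(3, 1, 1, 1, 1), seed = 8)
  fit <- mdr(ds, k = 1, seed = 8)
  expect_equal(fit$models$k1$loci, "snp1")
  expect_equal(fit$models$k1$cvc, 10L)
})

test_that("mdr is reproducible for a fixed seed and label-swap flips cells", {
  ds <- simulate_case_control(rep(0.3, 4), 150, 150,
                              marginal_ors = c(1.8, 1, 1, 1), seed = 5)
  f1 <- mdr(ds, k = 1:2, seed = 42)
  f2 <- mdr(ds, k = 1:2, seed = 42)
  expect_identical(f1$models$k2$loci, f2$models$k2$loci)
  expect_identical(f1$models$k2$testing_ba, f2$models$k2$testing_ba)
  # swapping case/control labels maps high <-> low away from threshold ties
  swapped <- ds
  swapped$phenotype <- factor(ifelse(ds$phenotype == "case", "control",
                                     "case"), levels = c("control", "case"))
  m1 <- classify_cells(ds, c("snp1", "snp2"))
  m2 <- classify_cells(swapped, c("snp1", "snp2"))
  # strictly-high cells under the original labels are low after the swap
  hi1 <- m1$label == "high" & m1$n_case > attr(m1, "threshold") * m1$n_control
  expect_true(all(m2$label[hi1] == "low"))
  # balanced accuracy of a fixed map is label-symmetric
  expect_equal(balanced_accuracy(m1, ds), 1 - balanced_accuracy(m1, swapped))
})

test_that("permutation test floors at 1/(B+1) for strong signals and stays
           null-calibrated", {
  pen <- epistatic_penetrance("xor", 0.5, 0.05)
  ds <- simulate_case_control(rep(0.3, 4), 400, 400, penetrance = pen,
                              seed = 12)
  fit <- mdr(ds, k = 2, seed = 12)
  pt <- mdr_permutation_test(ds, 2, fit$models$k2$testing_ba, n_perm = 49,
                             seed = 3)
  expect_equal(pt$p_value, 1 / 50)
  expect_lt(mean(pt$null_tba), 0.53)       # null TBA concentrates near 0.5
  # a null-level observed TBA lands mid-distribution
  p_null <- (1 + sum(pt$null_tba >= stats::median(pt$null_tba))) / 50
  expect_gt(p_null, 0.2)
})

test_that("high-risk group OR recovers the analytic contrast on epistatic
           data and rejects degenerate maps", {
  pen <- epistatic_penetrance("xor", 0.45, 0.05)
  ds <- simulate_case_control(rep(0.3, 3), 800, 800, penetrance = pen,
                              seed = 33)
  map <- classify_cells(ds, c("snp1", "snp2"))
  r <- highrisk_or(map, ds)
  # analytic 2x2 from the penetrance table at MAF 0.3:
  # P(high cell) = 2 * 0.51 * 0.49; case odds of membership vs control odds
  ph <- 2 * 0.51 * 0.49
  pen_high <- 0.45; pen_low <- 0.05
  prev <- ph * pen_high + (1 - ph) * pen_low
  p_high_case <- ph * pen_high / prev
  p_high_ctrl <- ph * (1 - pen_high) / (1 - prev)
  true_or <- (p_high_case / (1 - p_high_case)) /
    (p_high_ctrl / (1 - p_high_ctrl))
  expect_gt(r$or, r$ci_low)
  expect_true(true_or >= r$ci_low && true_or <= r$ci_high)
  # degenerate: all individuals in one risk group
  map_high <- map
  map_high$label[] <- "high"
  expect_error(highrisk_or(map_high, ds), "one risk group")
})
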