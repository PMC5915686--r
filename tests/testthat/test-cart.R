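test_that("the best split is found by exhaustive bipartition enumeration", {
  # CC/CT individuals 90% case, TT 30% case -> split {0,1} | {2}
  set.seed(51)
  g <- rep(c(0L, 1L, 2L), each = 60)
  y <- c(rbinom(120, 1, 0.9), rbinom(60, 1, 0.3))
  ds <- make_ds(cbind(g, rbinom(180, 2, 0.5)),
                ifelse(y == 1, "case", "control"),
                manifest = toy_manifest(2, c("sig", "noise")))
  tr <- genotype_tree(ds, prune = "none", max_depth = 1)
  expect_equal(tr$root$split$snp_j, 1L)
  expect_true(identical(sort(tr$root$split$left_codes), c(0L, 1L)) ||
                identical(tr$root$split$left_codes, 2L))
  # pure node is never split
  dsp <- make_ds(matrix(rep(0:2, 20), ncol = 1), rep("case", 60))
  expect_error(genotype_tree(dsp), "both classes")
  # tie rule: two identical SNPs -> the earlier manifest column wins
  dup <- make_ds(cbind(g, g), ifelse(y == 1, "case", "control"),
                 manifest = toy_manifest(2, c("first", "second")))
  trd <- genotype_tree(dup, prune = "none", max_depth = 1)
  expect_equal(trd$root$split$snp_j, 1L)
})

test_that("grown trees match the independent brute-force partitioner exactly", {
  for (seed in 1:4) {
    ds <- simulate_case_control(rep(0.4, 3), 30, 30,
                                marginal_ors = c(2.5, 1.5, 1),
                                seed = 200 + seed)
    tr <- genotype_tree(ds, min_split = 10, min_bucket = 4, cp = 0.005,
                        prune = "none")
    orc <- oracle_tree(ds$genotypes,
                       as.integer(ds$phenotype == "case"),
                       min_split = 10, min_bucket = 4, cp = 0.005,
                       max_depth = 30)
    expect_true(trees_identical(tr$root, orc))
  }
  # with missingness routed to the majority side
  ds <- simulate_case_control(rep(0.4, 3), 40, 40,
                              marginal_ors = c(2.5, 1, 1), seed = 300)
  G <- ds$genotypes
  set.seed(300)
  G[sample(length(G), 12)] <- NA
  dsm <- make_ds(G, as.character(ds$phenotype), manifest = ds$manifest)
  tr <- genotype_tree(dsm, min_split = 10, min_bucket = 4, cp = 0.005,
                      prune = "none")
  orc <- oracle_tree(G, as.integer(dsm$phenotype == "case"),
                     10, 4, 0.005, 30)
  expect_true(trees_identical(tr$root, orc))
})

test_that("a single fully determining SNP yields a depth-1 tree and cp = Inf
           a root-only tree", {
  g <- rep(c(0L, 2L), each = 100)
  ds <- make_ds(cbind(g, rbinom(200, 2, 0.4)),
                ifelse(g >= 1, "case", "control"),
                manifest = toy_manifest(2, c("det", "noise")))
  tr <- genotype_tree(ds, prune = "none")
  expect_equal(tr$root$split$snp_j, 1L)
  expect_null(tr$root$left$split)
  expect_null(tr$root$right$split)
  expect_equal(nrow(terminal_nodes(genotype_tree(ds, cp = Inf,
                                                 prune = "none"))), 1)
})

test_that("package tree agrees with rpart on a clean dominant signal", {
  skip_if_not_installed("rpart")
  set.seed(61)
  g <- rbinom(500, 2, 0.4)
  y <- rbinom(500, 1, ifelse(g >= 1, 0.7, 0.3))
  ds <- make_ds(cbind(g, rbinom(500, 2, 0.3)),
                ifelse(y == 1, "case", "control"),
                manifest = toy_manifest(2, c("sig", "noise")))
  tr <- genotype_tree(ds, prune = "none", max_depth = 1)
  rp <- rpart::rpart(y ~ sig + noise,
                     data = data.frame(y = factor(y), sig = factor(g),
                                       noise = factor(rbinom(500, 2, 0.3))),
                     method = "class",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0.01))
  # both partitioners pick the signal SNP and its carrier grouping
  expect_equal(tr$root$split$snp_j, 1L)
  expect_match(as.character(rp$frame$var[1]), "sig")
})

test_that("pruning is monotone, cp=0 threshold pruning is the identity, and
           label-permuted trees collapse toward the root", {
  ds <- simulate_case_control(rep(0.3, 4), 250, 250,
                              marginal_ors = c(2, 1.5, 1, 1), seed = 71)
  grown <- genotype_tree(ds, prune = "none", cp = 0.002)
  # cp gates growth as well as pruning; at the same growth gate, threshold
  # pruning with cp = 0 is the identity
  cp0 <- genotype_tree(ds, prune = "cp", cp = 0)
  grown0 <- genotype_tree(ds, prune = "none", cp = 0)
  expect_equal(nrow(terminal_nodes(cp0)), nrow(terminal_nodes(grown0)))
  onese <- genotype_tree(ds, prune = "one-se", cp = 0.002, seed = 9)
  expect_lte(nrow(terminal_nodes(onese)), nrow(terminal_nodes(grown)))
  # permuted labels: one-SE pruning collapses to the root in most replicates
  leaves <- vapply(1:5, function(i) {
    set.seed(400 + i)
    dsp <- ds
    dsp$phenotype <- sample(ds$phenotype)
    nrow(terminal_nodes(genotype_tree(dsp, prune = "one-se", seed = i)))
  }, numeric(1))
  expect_gte(mean(leaves == 1), 0.6)
})

test_that("terminal node report: ordering, reference OR 1, hand-checked OR,
           count conservation", {
  set.seed(81)
  g1 <- rbinom(300, 2, 0.5); g2 <- rbinom(300, 2, 0.5)
  y <- rbinom(300, 1, plogis(-0.6 + 1.2 * (g1 >= 1) + 0.8 * (g2 >= 1)))
  ds <- make_ds(cbind(g1, g2), ifelse(y == 1, "case", "control"),
                manifest = toy_manifest(2, c("a", "b")))
  tr <- genotype_tree(ds, prune = "none", cp = 0.003, min_split = 15,
                      min_bucket = 5)
  tn <- terminal_nodes(tr)
  expect_gte(nrow(tn), 2)
  expect_equal(sum(tn$n_case), sum(y))
  expect_equal(sum(tn$n_control), sum(y == 0))
  rep_ <- terminal_node_report(tr)
  expect_equal(rep_$or[1], 1)            # reference vs itself
  expect_true(all(diff(rep_$case_fraction) >= 0))
  # hand cross-product for the second node vs reference
  expect_equal(rep_$or[2],
               (rep_$n_case[2] * rep_$n_control[1]) /
                 (rep_$n_case[1] * rep_$n_control[2]))
  # constructed two-node contrast: 60/40 vs 40/60 -> OR 2.25
  expect_equal(oracle_or(matrix(c(60, 40, 40, 60), 2, byrow = TRUE)), 2.25)
})

test_that("trend test matches the closed-form Cochran-Armitage statistic and
           its symmetries", {
  events <- c(20, 50, 80); totals <- c(100, 100, 100)
  # closed form: z^2 = [sum s_i (e_i - n_i pbar)]^2 /
  #              [pbar qbar (sum n_i s_i^2 - (sum n_i s_i)^2 / N)]
  s <- 1:3
  pbar <- sum(events) / sum(totals)
  num <- sum(s * (events - totals * pbar))^2
  den <- pbar * (1 - pbar) *
    (sum(totals * s^2) - sum(totals * s)^2 / sum(totals))
  p_closed <- pchisq(num / den, 1, lower.tail = FALSE)
  expect_equal(trend_test(events, totals), p_closed)
  expect_lt(trend_test(events, totals), 1e-6)
  # flat fractions -> p ~ 1; reversing the order leaves p unchanged
  expect_gt(trend_test(c(50, 50, 50), totals), 0.99)
  expect_equal(trend_test(rev(events), totals), trend_test(events, totals))
})
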