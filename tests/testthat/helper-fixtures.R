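# Shared fixtures and independent oracles used across the suite.

toy_manifest <- function(m, snp_ids = paste0("s", seq_len(m))) {
  data.frame(snp_id = snp_ids, gene = "toy",
             major = rep(c("A", "G", "T", "C"), length.out = m),
             minor = rep(c("C", "T", "G", "A"), length.out = m),
             stringsAsFactors = FALSE)
}

make_ds <- function(G, phenotype, manifest = NULL, subtype = NULL) {
  if (is.null(manifest)) manifest <- toy_manifest(ncol(as.matrix(G)))
  colnames(G) <- manifest$snp_id
  genotype_dataset(G, phenotype, manifest, subtype = subtype)
}

# Direct-loop genotype tally: the oracle for genotype_counts().
tally_counts <- function(G, phenotype, j, group) {
  g <- G[phenotype == group, j]
  out <- c(0L, 0L, 0L)
  for (v in g) if (!is.na(v)) out[v + 1L] <- out[v + 1L] + 1L
  out
}

# Cross-product odds ratio computed as a ratio of odds (not via the package).
oracle_or <- function(tab) (tab[1, 1] / tab[1, 2]) / (tab[2, 1] / tab[2, 2])

# Independent MDR search: data-frame/paste-key implementation used to verify
# the package's exhaustive search on small instances. Same conventions
# (threshold = training case:control ratio, ties high, empty low, modal
# winner with first-index tie-break) but entirely separate machinery.
oracle_mdr <- function(G, y, fold, k) {
  subsets <- utils::combn(ncol(G), k)
  nfold <- max(fold)
  key <- function(rows, s) apply(G[rows, subsets[, s], drop = FALSE], 1,
                                 paste, collapse = "|")
  ba_of <- function(train_rows, eval_rows, s, thr) {
    kt <- key(train_rows, s)
    cases <- table(factor(kt[y[train_rows] == 1],
                          levels = unique(kt)))
    ctrls <- table(factor(kt[y[train_rows] == 0], levels = unique(kt)))
    high_cells <- names(cases)[as.numeric(cases) >= thr * as.numeric(ctrls)]
    ke <- key(eval_rows, s)
    pred <- ke %in% high_cells   # unseen keys -> low
    ye <- y[eval_rows]
    (mean(pred[ye == 1]) + mean(!pred[ye == 0])) / 2
  }
  train_ba <- matrix(NA_real_, nfold, ncol(subsets))
  test_ba <- matrix(NA_real_, nfold, ncol(subsets))
  for (f in seq_len(nfold)) {
    tr <- which(fold != f); te <- which(fold == f)
    thr <- sum(y[tr] == 1) / sum(y[tr] == 0)
    for (s in seq_len(ncol(subsets))) {
      train_ba[f, s] <- ba_of(tr, tr, s, thr)
      test_ba[f, s] <- ba_of(tr, te, s, thr)
    }
  }
  winners <- apply(train_ba, 1, which.max)
  tab <- tabulate(winners, ncol(subsets))
  cvc <- max(tab)
  cand <- which(tab == cvc)
  if (length(cand) > 1)
    cand <- cand[order(-colMeans(test_ba[, cand, drop = FALSE]), cand)]
  list(loci = subsets[, cand[1]], cvc = cvc,
       testing_ba = mean(test_ba[, cand[1]]),
       winners = winners, train_ba = train_ba)
}

# Independent brute-force recursive partitioner mirroring the documented
# CART conventions (all bipartitions, Gini, manifest-order tie-break,
# majority-side missing routing, cp gate on the share-weighted decrease).
oracle_tree <- function(G, y, min_split, min_bucket, cp, max_depth) {
  n_total <- length(y)
  gini <- function(yy) {
    p <- mean(yy == 1)
    2 * p * (1 - p)
  }
  root_g <- gini(y)
  grow <- function(rows, depth) {
    yy <- y[rows]
    leaf <- list(n_case = sum(yy == 1), n_control = sum(yy == 0),
                 split = NULL)
    if (length(rows) < min_split || all(yy == 1) || all(yy == 0) ||
        depth >= max_depth) return(leaf)
    best <- NULL
    for (j in seq_len(ncol(G))) {
      g <- G[rows, j]
      obs <- sort(unique(g[!is.na(g)]))
      if (length(obs) < 2) next
      parts <- if (length(obs) == 2) list(obs[1]) else as.list(obs)
      for (lft in parts) {
        inl <- !is.na(g) & g %in% lft
        inr <- !is.na(g) & !g %in% lft
        side <- if (sum(inr) > sum(inl)) "right" else "left"
        if (side == "left") inl <- inl | is.na(g) else inr <- inr | is.na(g)
        if (sum(inl) < min_bucket || sum(inr) < min_bucket) next
        dec <- gini(yy) - sum(inl) / length(rows) * gini(yy[inl]) -
          sum(inr) / length(rows) * gini(yy[inr])
        dec <- dec * length(rows) / n_total
        if (is.null(best) || dec > best$dec + 1e-12)
          best <- list(j = j, left = lft, dec = dec, inl = inl, side = side)
      }
    }
    if (is.null(best) || best$dec < cp * root_g - 1e-12) return(leaf)
    leaf$split <- list(j = best$j, left = best$left, side = best$side)
    leaf$l <- grow(rows[best$inl], depth + 1)
    leaf$r <- grow(rows[!best$inl], depth + 1)
    leaf
  }
  grow(seq_len(n_total), 0)
}

# Structural comparison of a package tree node against an oracle tree.
trees_identical <- function(node, onode) {
  if (is.null(node$split) != is.null(onode$split)) return(FALSE)
  if (node$n_case != onode$n_case || node$n_control != onode$n_control)
    return(FALSE)
  if (is.null(node$split)) return(TRUE)
  if (node$split$snp_j != onode$split$j) return(FALSE)
  if (!identical(as.integer(node$split$left_codes),
                 as.integer(onode$split$left))) return(FALSE)
  trees_identical(node$left, onode$l) && trees_identical(node$right, onode$r)
}

# Study fixtures: summary tables and marginal-matched surrogate.
arc_counts <- arc_genotype_counts()
arc_alleles <- arc_allele_counts()

# Allele 2x2 (case/control x minor/major) straight from the published
# genotype counts, bypassing the dataset machinery.
counts_allele_table <- function(snp) {
  cc <- arc_counts[arc_counts$snp_id == snp, ]
  matrix(c(cc$case_het + 2 * cc$case_minor_hom,
           2 * cc$case_major_hom + cc$case_het,
           cc$control_het + 2 * cc$control_minor_hom,
           2 * cc$control_major_hom + cc$control_het),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("minor", "major")))
}
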