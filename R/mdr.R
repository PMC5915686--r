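#' Multifactor dimensionality reduction
#'
#' Exhaustive MDR search for gene-gene interactions in a case-control SNP
#' panel. For each interaction order `k`, every k-locus subset is scored by
#' pooling its `3^k` genotype cells into "high risk" (within-cell
#' case:control ratio at or above a threshold) and "low risk" classes, and
#' the pooled binary attribute is evaluated by balanced accuracy under
#' phenotype-stratified cross-validation. Within each fold the subset with
#' the highest training balanced accuracy wins; the subset winning most
#' folds is reported, its cross-validation consistency (CVC) is the number
#' of folds it wins, and its testing balanced accuracy (TBA) is its mean
#' held-out balanced accuracy across folds. Significance is assessed by
#' permutation: phenotype labels are shuffled and the whole order-`k` search
#' re-run per permutation.
#'
#' The risk threshold defaults to the case:control ratio of the training
#' fold (the standard choice for unbalanced designs); cells whose ratio
#' exactly equals the threshold are labelled high. Cells unoccupied in the
#' training data predict "low" by default. Individuals missing a genotype at
#' any locus of a subset are dropped for that subset only.
#'
#' @param ds a [genotype_dataset()].
#' @param k interaction orders to search, e.g. `1:5`.
#' @param folds number of cross-validation folds (default 10).
#' @param n_perm permutations for the significance test (0 = skip). The
#'   conventional choice is 1000; each permutation re-runs the full search.
#' @param seed RNG seed controlling fold assignment and permutations; with a
#'   fixed seed the search is reproducible bit-for-bit.
#' @param threshold fixed high-risk threshold, or `NULL` for the adaptive
#'   training-fold case:control ratio.
#' @param empty_cells prediction for genotype cells unseen in training:
#'   `"low"` (conservative default) or `"high"`.
#' @return An object of class `"mdr"`: list with `models` (one entry per
#'   `k`: `loci`, `training_ba`, `testing_ba`, `cvc`, `perm_p`, `risk_map`,
#'   `high_risk_or`, `fold_winners`), `best_k` (highest CVC, ties broken by
#'   TBA then smaller `k`), and `config`.
#' @seealso [classify_cells()], [balanced_accuracy()], [highrisk_or()],
#'   [predict.mdr()]
#' @export
mdr <- function(ds, k = 1:2, folds = 10, n_perm = 0, seed = 1,
                threshold = NULL, empty_cells = c("low", "high")) {
  empty_cells <- match.arg(empty_cells)
  m <- ncol(ds$genotypes)
  stopifnot(all(k >= 1), folds >= 2, n_perm >= 0)
  if (any(k > m)) stop("interaction order exceeds number of SNPs")
  y <- as.integer(ds$phenotype == "case")
  if (!any(y == 1) || !any(y == 0)) stop("both classes required")
  X <- ds$genotypes
  empty_high <- empty_cells == "high"

  fold <- with_seed(seed, stratified_folds(y, folds))
  models <- vector("list", length(k))
  names(models) <- paste0("k", k)
  for (i in seq_along(k)) {
    res <- mdr_search_order(X, y, fold, k[i], threshold, empty_high)
    loci_ids <- ds$manifest$snp_id[res$loci]
    full_map <- classify_cells(ds, loci_ids, threshold = threshold)
    or <- tryCatch(highrisk_or(full_map, ds), error = function(e) NULL)
    perm_p <- NA_real_
    null_tba <- NULL
    if (n_perm > 0) {
      null_tba <- with_seed(seed + 104729L, vapply(seq_len(n_perm), function(b) {
        yp <- sample(y)
        fp <- stratified_folds(yp, folds)
        mdr_search_order(X, yp, fp, k[i], threshold, empty_high)$testing_ba
      }, numeric(1)))
      perm_p <- (1 + sum(null_tba >= res$testing_ba)) / (n_perm + 1)
    }
    models[[i]] <- list(k = k[i], loci = loci_ids,
                        training_ba = res$training_ba,
                        testing_ba = res$testing_ba, cvc = res$cvc,
                        perm_p = perm_p, null_tba = null_tba,
                        risk_map = full_map, high_risk_or = or,
                        fold_winners = res$fold_winners)
  }
  cvc <- vapply(models, `[[`, integer(1), "cvc")
  tba <- vapply(models, `[[`, numeric(1), "testing_ba")
  best <- order(-cvc, -tba, k)[1]
  structure(list(models = models, best_k = k[best],
                 config = list(k = k, folds = folds, n_perm = n_perm,
                               seed = seed, threshold = threshold,
                               empty_cells = empty_cells),
                 call = match.call()),
            class = "mdr")
}

# Exhaustive order-k search given fixed fold labels. Returns the reported
# (modal-winner) subset with its CVC, mean training BA and mean held-out BA.
mdr_search_order <- function(X, y, fold, k, threshold, empty_high) {
  m <- ncol(X)
  subsets <- utils::combn(m, k)
  ns <- ncol(subsets)
  nfold <- max(fold)
  pow3 <- 3L^(seq_len(k) - 1L)
  ncell <- 3L^k
  # cell index per individual per subset, computed once and reused per fold
  cells <- matrix(0L, nrow(X), ns)
  for (s in seq_len(ns))
    cells[, s] <- 1L + as.integer(X[, subsets[, s], drop = FALSE] %*% pow3)
  train_ba <- matrix(NA_real_, nfold, ns)
  test_ba <- matrix(NA_real_, nfold, ns)
  for (f in seq_len(nfold)) {
    tr <- fold != f
    thr <- if (is.null(threshold)) sum(y[tr] == 1) / sum(y[tr] == 0) else threshold
    for (s in seq_len(ns)) {
      ev <- eval_cells(cells[, s], y, tr, thr, ncell, empty_high)
      train_ba[f, s] <- ev$train_ba
      test_ba[f, s] <- ev$test_ba
    }
  }
  winners <- apply(train_ba, 1, which.max)  # first index wins ties
  tab <- tabulate(winners, ns)
  cvc <- max(tab)
  cand <- which(tab == cvc)
  if (length(cand) > 1) {  # tie on CVC: higher mean held-out BA, then order
    cand <- cand[order(-colMeans(test_ba[, cand, drop = FALSE]), cand)]
  }
  rep_s <- cand[1]
  list(loci = subsets[, rep_s], cvc = cvc,
       training_ba = mean(train_ba[, rep_s]),
       testing_ba = mean(test_ba[, rep_s]),
       fold_winners = lapply(winners, function(w) subsets[, w]))
}

# Build the high/low map on the training part and score balanced accuracy
# on both parts. `cells` may contain NA (missing genotype -> dropped).
eval_cells <- function(cells, y, train, thr, ncell, empty_high) {
  ok <- !is.na(cells)
  tr <- train & ok
  ca <- tabulate(cells[tr & y == 1L], ncell)
  co <- tabulate(cells[tr & y == 0L], ncell)
  occupied <- (ca + co) > 0L
  high <- ifelse(occupied, ca >= thr * co, empty_high)
  ba <- function(idx) {
    pred <- high[cells[idx]]
    pos <- y[idx] == 1L
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    (sens + spec) / 2
  }
  list(train_ba = ba(which(tr)), test_ba = ba(which(!train & ok)),
       high = high, case_counts = ca, control_counts = co)
}

#' Classify multi-locus genotype cells as high or low risk
#'
#' Builds the MDR cell risk map for a locus subset: every combination of
#' genotype codes at the chosen loci is a cell, labelled `high` when its
#' case:control ratio among the classifying individuals is at or above the
#' threshold, `low` otherwise, and `empty` when unoccupied (empty cells are
#' treated as low at prediction time by default).
#'
#' @param ds a [genotype_dataset()].
#' @param loci SNP identifiers (the locus subset).
#' @param individuals optional row indices to classify from (e.g. a training
#'   fold); default all.
#' @param threshold high-risk ratio threshold; default is the case:control
#'   ratio among the classifying individuals. Ties label high.
#' @return A data frame of class `"cell_risk_map"` with one row per genotype
#'   cell: one code column per locus, `n_case`, `n_control`, `label`.
#'   Attributes: `loci`, `threshold`.
#' @export
classify_cells <- function(ds, loci, individuals = NULL, threshold = NULL) {
  j <- snp_index(ds, loci)
  if (is.null(individuals)) individuals <- seq_len(nrow(ds$genotypes))
  if (!length(individuals)) stop("no individuals to classify from")
  y <- as.integer(ds$phenotype == "case")[individuals]
  k <- length(j)
  pow3 <- 3L^(seq_len(k) - 1L)
  cells <- 1L + as.integer(ds$genotypes[individuals, j, drop = FALSE] %*% pow3)
  ok <- !is.na(cells)
  ca <- tabulate(cells[ok & y == 1L], 3L^k)
  co <- tabulate(cells[ok & y == 0L], 3L^k)
  if (is.null(threshold)) {
    if (sum(y == 0L) == 0) stop("no controls among classifying individuals")
    threshold <- sum(y == 1L) / sum(y == 0L)
  }
  grid <- expand.grid(rep(list(0:2), k))
  names(grid) <- loci
  label <- ifelse(ca + co == 0L, "empty",
                  ifelse(ca >= threshold * co, "high", "low"))
  out <- cbind(grid, n_case = ca, n_control = co, label = label)
  attr(out, "loci") <- loci
  attr(out, "threshold") <- threshold
  class(out) <- c("cell_risk_map", "data.frame")
  out
}

risk_map_predict <- function(map, ds, individuals = NULL) {
  loci <- attr(map, "loci")
  j <- snp_index(ds, loci)
  if (is.null(individuals)) individuals <- seq_len(nrow(ds$genotypes))
  k <- length(j)
  pow3 <- 3L^(seq_len(k) - 1L)
  cells <- 1L + as.integer(ds$genotypes[individuals, j, drop = FALSE] %*% pow3)
  high <- map$label == "high"
  out <- rep(NA, length(cells))
  out[!is.na(cells)] <- high[cells[!is.na(cells)]]
  out  # logical: TRUE = high risk; NA = missing genotype at a model locus
}

#' Balanced accuracy of a cell risk map
#'
#' Scores a fitted risk map on an evaluation set: an individual is predicted
#' "case" when their genotype cell is labelled high. Balanced accuracy is
#' (sensitivity + specificity) / 2.
#'
#' @param map a `"cell_risk_map"` from [classify_cells()].
#' @param ds the [genotype_dataset()] to evaluate on.
#' @param individuals optional row indices of the evaluation set.
#' @return The balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(map, ds, individuals = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(ds$genotypes))
  pred <- risk_map_predict(map, ds, individuals)
  y <- as.integer(ds$phenotype == "case")[individuals]
  ok <- !is.na(pred)
  pred <- pred[ok]; y <- y[ok]
  if (!any(y == 1) || !any(y == 0))
    stop("evaluation set must contain both cases and controls")
  sens <- sum(pred & y == 1L) / sum(y == 1L)
  spec <- sum(!pred & y == 0L) / sum(y == 0L)
  (sens + spec) / 2
}

#' Odds ratio of the MDR high-risk group
#'
#' Cross-classifies phenotype against high/low risk-group membership under a
#' risk map rebuilt on the full dataset and returns the odds ratio with
#' Woolf CI and association p-value.
#'
#' @param model an `"mdr"` fit (its best model, or order `k`) or a
#'   `"cell_risk_map"`.
#' @param ds the [genotype_dataset()].
#' @param k interaction order to use when `model` is an `"mdr"` object;
#'   defaults to the best model.
#' @param correction zero-cell handling for the OR (see [odds_ratio_ci()]).
#' @return One-row data frame: `or`, `ci_low`, `ci_high`, `defined`,
#'   `p_value`, plus the high/low group sizes.
#' @export
highrisk_or <- function(model, ds, k = NULL, correction = "none") {
  map <- if (inherits(model, "cell_risk_map")) model
  else {
    if (!inherits(model, "mdr")) stop("model must be an mdr fit or a cell_risk_map")
    if (is.null(k)) k <- model$best_k
    model$models[[paste0("k", k)]]$risk_map
  }
  pred <- risk_map_predict(map, ds)
  y <- ds$phenotype
  ok <- !is.na(pred)
  if (all(pred[ok]) || !any(pred[ok]))
    stop("all individuals fall in one risk group")
  tab <- two_by_two(sum(pred[ok] & y[ok] == "case"),
                    sum(!pred[ok] & y[ok] == "case"),
                    sum(pred[ok] & y[ok] == "control"),
                    sum(!pred[ok] & y[ok] == "control"))
  res <- odds_ratio_ci(tab, correction = correction)
  res$p_value <- assoc_test(tab)
  res$n_high <- sum(pred[ok])
  res$n_low <- sum(!pred[ok])
  res
}

#' MDR permutation test
#'
#' Null distribution of the testing balanced accuracy: phenotype labels are
#' permuted and the full order-`k` exhaustive search re-run for each
#' permutation; the p-value is `(1 + #{null TBA >= observed}) / (n_perm + 1)`.
#'
#' @param ds a [genotype_dataset()].
#' @param k interaction order.
#' @param observed_tba observed testing balanced accuracy to compare against.
#' @param n_perm number of permutations (conventionally 1000).
#' @param folds CV folds per permuted search.
#' @param seed RNG seed.
#' @param threshold,empty_cells as in [mdr()].
#' @return List: `p_value`, `null_tba` (vector of permuted TBAs).
#' @export
mdr_permutation_test <- function(ds, k, observed_tba, n_perm = 1000,
                                 folds = 10, seed = 1, threshold = NULL,
                                 empty_cells = "low") {
  stopifnot(n_perm >= 1)
  y <- as.integer(ds$phenotype == "case")
  X <- ds$genotypes
  empty_high <- identical(empty_cells, "high")
  null_tba <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    fp <- stratified_folds(yp, folds)
    mdr_search_order(X, yp, fp, k, threshold, empty_high)$testing_ba
  }, numeric(1)))
  list(p_value = (1 + sum(null_tba >= observed_tba)) / (n_perm + 1),
       null_tba = null_tba)
}

#' @export
print.mdr <- function(x, digits = 4, ...) {
  cat("MDR search (", x$config$folds, "-fold CV",
      if (x$config$n_perm > 0) paste0(", ", x$config$n_perm, " permutations"),
      ", seed ", x$config$seed, ")\n\n", sep = "")
  df <- do.call(rbind, lapply(x$models, function(mo) {
    data.frame(k = mo$k, model = paste(mo$loci, collapse = ","),
               training_ba = round(mo$training_ba, digits),
               testing_ba = round(mo$testing_ba, digits),
               cvc = paste0(mo$cvc, "/", x$config$folds),
               perm_p = if (is.na(mo$perm_p)) NA else
                 format.pval(mo$perm_p, digits = 2))
  }))
  print(df, row.names = FALSE)
  cat("\nBest model: k =", x$best_k, "(highest CVC, ties by testing BA)\n")
  invisible(x)
}

#' @export
summary.mdr <- function(object, ...) {
  best <- object$models[[paste0("k", object$best_k)]]
  cat("Best MDR model (k =", best$k, "):",
      paste(best$loci, collapse = ", "), "\n")
  cat("  testing BA:", round(best$testing_ba, 4),
      "  CVC:", paste0(best$cvc, "/", object$config$folds),
      "  perm p:", if (is.na(best$perm_p)) "not run" else
        format.pval(best$perm_p, digits = 3), "\n")
  if (!is.null(best$high_risk_or)) {
    o <- best$high_risk_or
    cat("  high-risk group OR:", round(o$or, 2), " 95% CI (",
        round(o$ci_low, 2), "-", round(o$ci_high, 2), "), p =",
        format.pval(o$p_value, digits = 3), "\n")
  }
  invisible(object)
}

#' Predict risk-group membership from an MDR fit
#'
#' @param object an `"mdr"` fit.
#' @param newdata a [genotype_dataset()] holding the model's loci.
#' @param k interaction order (default the best model).
#' @param ... unused.
#' @return Factor `low`/`high` per individual (`NA` when a model locus is
#'   missing).
#' @export
predict.mdr <- function(object, newdata, k = NULL, ...) {
  if (is.null(k)) k <- object$best_k
  map <- object$models[[paste0("k", k)]]$risk_map
  pred <- risk_map_predict(map, newdata)
  factor(ifelse(pred, "high", "low"), levels = c("low", "high"))
}
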