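#' Likelihood-ratio test for SNP-SNP interaction
#'
#' Compares a logistic model with all main effects plus all pairwise
#' interaction terms against the main-effects-only model by a likelihood
#' ratio test with df = number of interaction terms. Only pairwise products
#' are included: a fully saturated multi-way model over several SNPs is
#' unstable on sparse genotype tables.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_ids 2 to 8 SNP identifiers.
#' @param coding genetic coding of each SNP in the model (default dominant,
#'   the usual binarisation of non-binary polymorphisms).
#' @return A list: `p_value`, `statistic` (LR chi-square), `df`, `converged`,
#'   `separation` (quasi-complete separation flag; if either flag is raised
#'   the p-value is returned but should not be trusted).
#' @export
lr_interaction_test <- function(ds, snp_ids,
                                coding = c("dominant", "recessive",
                                           "allelic-count")) {
  coding <- match.arg(coding)
  if (length(snp_ids) < 2L)
    stop("at least two SNPs are needed for an interaction test")
  if (length(snp_ids) > 8L)
    stop("more than 8 SNPs: pairwise-interaction model would be unstable")
  df <- snp_model_frame(ds, snp_ids, coding)
  f_main <- stats::as.formula(paste("y ~", paste(snp_ids, collapse = " + ")))
  f_int <- stats::as.formula(paste("y ~ (", paste(snp_ids, collapse = " + "),
                                   ")^2"))
  fit_main <- suppressWarnings(stats::glm(f_main, binomial(), data = df))
  fit_int <- suppressWarnings(stats::glm(f_int, binomial(), data = df))
  an <- stats::anova(fit_main, fit_int, test = "Chisq")
  eps <- 1e-8
  fitted <- stats::fitted(fit_int)
  list(p_value = an$`Pr(>Chi)`[2],
       statistic = an$Deviance[2],
       df = an$Df[2],
       converged = fit_int$converged && fit_main$converged,
       separation = any(fitted < eps | fitted > 1 - eps))
}

snp_model_frame <- function(ds, snp_ids, coding) {
  x <- lapply(snp_ids, function(s) recode_genotype(ds, s, coding))
  names(x) <- snp_ids
  df <- as.data.frame(x, check.names = FALSE)
  df$y <- as.integer(ds$phenotype == "case")
  stats::na.omit(df)
}

#' Cross-validated AUC of a pairwise-interaction logistic model
#'
#' Fits the main-effects + pairwise-interaction logistic model of
#' [lr_interaction_test()] within each of `folds` phenotype-stratified CV
#' folds and averages the ROC AUC on the training and held-out parts. The
#' train-test difference measures over-fitting optimism.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_ids SNPs entering the model.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param coding genetic coding, as in [lr_interaction_test()].
#' @return A list: `train_auc`, `test_auc`, `difference` (train - test).
#' @export
cv_auc_compare <- function(ds, snp_ids, folds = 10, seed = 1,
                           coding = "dominant") {
  stopifnot(folds >= 2)
  df <- snp_model_frame(ds, snp_ids, coding)
  fold <- with_seed(seed, stratified_folds(df$y, folds))
  f_int <- stats::as.formula(paste("y ~ (", paste(snp_ids, collapse = " + "),
                                   ")^2"))
  auc_of <- function(y, p) {
    as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<",
                                   levels = c(0, 1))))
  }
  tr <- te <- numeric(folds)
  for (k in seq_len(folds)) {
    train <- df[fold != k, , drop = FALSE]
    test <- df[fold == k, , drop = FALSE]
    fit <- suppressWarnings(stats::glm(f_int, binomial(), data = train))
    tr[k] <- auc_of(train$y, stats::fitted(fit))
    te[k] <- auc_of(test$y, suppressWarnings(
      stats::predict(fit, newdata = test, type = "response")))
  }
  list(train_auc = mean(tr), test_auc = mean(te),
       difference = mean(tr) - mean(te))
}

# Phenotype-stratified fold labels: within each class, individuals are
# randomly permuted and folds dealt round-robin, so every fold holds both
# classes whenever the class sizes allow. Call inside with_seed() for
# reproducibility.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  }
  fold
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  )
  set.seed(seed)
  code
}

#' Power of the two-sided two-proportion z-test
#'
#' Normal-approximation power for detecting a target odds ratio between two
#' allele-frequency proportions, e.g. the power of a case-control panel to
#' detect a given per-allele OR at the observed allele numbers. The target
#' OR is converted to the second group's proportion on the odds scale.
#'
#' @param n1,n2 numbers of observations (alleles) in groups 1 and 2.
#' @param p0 baseline proportion (group-1 allele frequency).
#' @param target_or odds ratio to detect.
#' @param alpha two-sided significance level.
#' @return The power (probability of rejecting the null), as a proportion.
#' @export
power_two_proportions <- function(n1, n2, p0, target_or, alpha = 0.05) {
  stopifnot(p0 > 0, p0 < 1, target_or > 0, alpha > 0, alpha < 1)
  odds1 <- p0 / (1 - p0) * target_or
  p1 <- odds1 / (1 + odds1)
  pbar <- (n1 * p0 + n2 * p1) / (n1 + n2)
  sd0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))   # null (pooled) SE
  sd1 <- sqrt(p0 * (1 - p0) / n1 + p1 * (1 - p1) / n2) # alternative SE
  z <- stats::qnorm(1 - alpha / 2)
  delta <- abs(p1 - p0)
  stats::pnorm((delta - z * sd0) / sd1) +
    stats::pnorm((-delta - z * sd0) / sd1)
}
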