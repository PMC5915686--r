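#' Allele count table for one SNP
#'
#' Builds the case/control x minor/major allele 2x2 table. Per group, the
#' minor-allele count is `het + 2 * minor_hom` and the major-allele count
#' `2 * major_hom + het`; missing genotypes are excluded pairwise.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_id SNP identifier.
#' @return 2x2 integer matrix, rows `case`/`control`, columns `minor`/`major`.
#' @export
allele_table <- function(ds, snp_id) {
  tabs <- lapply(c("case", "control"), function(g) {
    gc <- genotype_counts(ds, snp_id, g)
    if (sum(gc) == 0) stop("SNP ", snp_id, " entirely missing in ", g, " group")
    c(minor = unname(gc["het"] + 2L * gc["minor_hom"]),
      major = unname(2L * gc["major_hom"] + gc["het"]))
  })
  matrix(c(tabs[[1]], tabs[[2]]), nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("minor", "major")))
}

#' 2x3 genotype contingency table for one SNP
#'
#' @param ds a [genotype_dataset()].
#' @param snp_id SNP identifier.
#' @return 2x3 matrix, rows `case`/`control`, columns genotype codes 0/1/2.
#' @export
genotype_table <- function(ds, snp_id) {
  rbind(case = genotype_counts(ds, snp_id, "case"),
        control = genotype_counts(ds, snp_id, "control"))
}

two_by_two <- function(case_exposed, case_unexposed, control_exposed,
                       control_unexposed) {
  m <- matrix(c(case_exposed, case_unexposed, control_exposed,
                control_unexposed), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  if (any(m < 0)) stop("negative cell count")
  m
}

#' Odds ratio with Woolf confidence interval
#'
#' For a case/control x exposed/unexposed table, the odds ratio is the
#' cross-product ratio (case exposure odds over control exposure odds) and
#' the CI is the Woolf log-OR interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' With `correction = "haldane"`, 0.5 is added to every cell when any cell
#' is zero (Haldane-Anscombe). With `correction = "none"` and a zero cell,
#' the estimate is returned as undefined (`defined = FALSE`, OR/CI `NA`),
#' mirroring how such cells are reported as blank in association tables.
#'
#' @param tab 2x2 matrix with cases in row 1, exposed in column 1 (as from
#'   [allele_table()]).
#' @param correction zero-cell handling, `"none"` or `"haldane"`.
#' @param conf_level confidence level (default 0.95).
#' @return A one-row data frame: `or`, `ci_low`, `ci_high`, `defined`.
#' @export
odds_ratio_ci <- function(tab, correction = c("none", "haldane"),
                          conf_level = 0.95) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) stop("degenerate 2x2 table: all cells empty")
  if (any(tab == 0)) {
    if (correction == "none") {
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate 2x2 table: empty margin")
      return(data.frame(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        defined = FALSE))
    }
    tab <- tab + 0.5
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(or = or, ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se), defined = TRUE)
}

#' Association test for a 2x2 or 2x3 case-control table
#'
#' Pearson chi-square without continuity correction by default; for a 2x2
#' table with any expected cell count below `fisher_threshold` (Cochran's
#' criterion), Fisher's exact test is used instead.
#'
#' @param tab 2x2 or 2x3 contingency table.
#' @param fisher_threshold expected-count threshold that triggers Fisher's
#'   exact test on 2x2 tables (default 5).
#' @return The two-sided p-value.
#' @export
assoc_test <- function(tab, fisher_threshold = 5) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < fisher_threshold))
    return(stats::fisher.test(tab)$p.value)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

#' Dominant and recessive association for one SNP
#'
#' Dominant: minor-allele carriers (het + minor hom) vs major homozygotes;
#' recessive: minor homozygotes vs the rest.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_id SNP identifier.
#' @param correction zero-cell handling, as in [odds_ratio_ci()].
#' @return Two-row data frame (`model` = dominant/recessive) with OR, Woolf
#'   CI, `defined` flag and test p-value.
#' @export
dominant_recessive <- function(ds, snp_id, correction = "none") {
  ca <- genotype_counts(ds, snp_id, "case")
  co <- genotype_counts(ds, snp_id, "control")
  tabs <- list(
    dominant = two_by_two(ca["het"] + ca["minor_hom"], ca["major_hom"],
                          co["het"] + co["minor_hom"], co["major_hom"]),
    recessive = two_by_two(ca["minor_hom"], ca["major_hom"] + ca["het"],
                           co["minor_hom"], co["major_hom"] + co["het"])
  )
  out <- do.call(rbind, lapply(names(tabs), function(nm) {
    res <- odds_ratio_ci(tabs[[nm]], correction = correction)
    res$p_value <- tryCatch(assoc_test(tabs[[nm]]), error = function(e) NA_real_)
    cbind(data.frame(snp_id = snp_id, model = nm), res)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment
#'
#' @param p p-value(s).
#' @param m number of tests.
#' @return `min(1, p * m)`, vectorised over `p`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Per-SNP association scan
#'
#' Computes, for every SNP in the panel, the allelic odds ratio with Woolf
#' CI and chi-square/Fisher p, the 2x3 genotypic test p, and the dominant
#' and recessive ORs, with Bonferroni-adjusted allelic p-values.
#'
#' @param ds a [genotype_dataset()].
#' @param models subset of `c("allelic", "genotypic", "dominant",
#'   "recessive")` to compute.
#' @param bonferroni_m number of tests for the Bonferroni adjustment;
#'   defaults to the number of SNPs in the panel.
#' @param correction zero-cell handling for ORs (`"none"` leaves zero-cell
#'   ORs undefined).
#' @return A data frame of class `"snp_assoc"` with one row per SNP and
#'   model: `snp_id`, `gene`, `model`, `or`, `ci_low`, `ci_high`, `defined`,
#'   `p_value`, `p_adj`.
#' @export
snp_association <- function(ds, models = c("allelic", "genotypic", "dominant",
                                           "recessive"),
                            bonferroni_m = NULL, correction = "none") {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(bonferroni_m)) bonferroni_m <- nrow(ds$manifest)
  rows <- list()
  for (s in ds$manifest$snp_id) {
    gene <- ds$manifest$gene[ds$manifest$snp_id == s]
    if ("allelic" %in% models) {
      at <- allele_table(ds, s)
      res <- odds_ratio_ci(at, correction = correction)
      res$p_value <- assoc_test(at)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(snp_id = s, gene = gene, model = "allelic"), res)
    }
    if ("genotypic" %in% models) {
      gt <- genotype_table(ds, s)
      gt <- gt[, colSums(gt) > 0, drop = FALSE]
      p <- if (ncol(gt) < 2) NA_real_ else assoc_test(gt)
      rows[[length(rows) + 1L]] <-
        data.frame(snp_id = s, gene = gene, model = "genotypic",
                   or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   defined = NA, p_value = p)
    }
    if (any(c("dominant", "recessive") %in% models)) {
      dr <- dominant_recessive(ds, s, correction = correction)
      dr <- dr[dr$model %in% models, ]
      rows[[length(rows) + 1L]] <- cbind(data.frame(gene = gene), dr)[,
        c("snp_id", "gene", "model", "or", "ci_low", "ci_high", "defined",
          "p_value")]
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_value, bonferroni_m)
  rownames(out) <- NULL
  attr(out, "bonferroni_m") <- bonferroni_m
  class(out) <- c("snp_assoc", "data.frame")
  out
}

#' @export
print.snp_assoc <- function(x, digits = 3, ...) {
  cat("Per-SNP association scan (", length(unique(x$snp_id)), " SNPs, ",
      "Bonferroni m = ", attr(x, "bonferroni_m"), ")\n\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
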