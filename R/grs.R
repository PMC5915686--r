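#' Risk-allele orientation for a genetic risk score
#'
#' For each SNP the risk allele is the minor allele when its allelic odds
#' ratio is at least 1, and the major (reference) allele otherwise. The
#' orientation is usually computed from the analysis dataset itself; note
#' the in-sample optimism this creates (the case-mean score is biased
#' upward relative to an orientation fixed on external data).
#'
#' @param ds a [genotype_dataset()], used to compute per-SNP allelic ORs.
#' @param assoc optionally, a precomputed [snp_association()] table with
#'   allelic rows (e.g. from an external reference panel); overrides `ds`'s
#'   own ORs.
#' @param correction zero-cell handling for the allelic ORs. With
#'   `"none"`, an undefined OR (zero cell) is an error suggesting
#'   `correction = "haldane"`.
#' @return Data frame of class `"risk_orientation"`: `snp_id`,
#'   `risk_allele` (`"minor"`/`"major"`), `source_or`.
#' @export
risk_orientation <- function(ds, assoc = NULL, correction = "none") {
  if (is.null(assoc)) assoc <- snp_association(ds, models = "allelic",
                                               correction = correction)
  assoc <- assoc[assoc$model == "allelic", ]
  if (any(!assoc$defined))
    stop("allelic OR undefined (zero cell) for: ",
         paste(assoc$snp_id[!assoc$defined], collapse = ", "),
         "; use correction = \"haldane\"")
  out <- data.frame(snp_id = assoc$snp_id,
                    risk_allele = ifelse(assoc$or >= 1, "minor", "major"),
                    source_or = assoc$or, stringsAsFactors = FALSE)
  class(out) <- c("risk_orientation", "data.frame")
  out
}

#' Unweighted genetic risk score
#'
#' Per individual, the count of risk alleles summed over the panel: at each
#' SNP the score contribution is the genotype code itself when the risk
#' allele is the minor allele, and `2 - code` when it is the major allele
#' (2 = homozygous for the risk allele, 1 = heterozygous, 0 = homozygous
#' for the non-risk allele). Missing genotypes are skipped and the number
#' of SNPs actually used is recorded per individual.
#'
#' @param ds a [genotype_dataset()].
#' @param orientation a [risk_orientation()]; computed from `ds` itself when
#'   `NULL` (in-sample orientation, as association studies typically do).
#' @param correction passed to [risk_orientation()] when computing the
#'   orientation in-sample.
#' @return An object of class `"grs"`: data frame with `id`, `phenotype`,
#'   `subtype`, `score`, `n_snps_used`; the orientation is attached as
#'   attribute `"orientation"`.
#' @export
grs <- function(ds, orientation = NULL, correction = "none") {
  if (is.null(orientation)) orientation <- risk_orientation(ds,
                                                            correction = correction)
  miss <- setdiff(ds$manifest$snp_id, orientation$snp_id)
  if (length(miss))
    stop("orientation does not cover SNP(s): ", paste(miss, collapse = ", "))
  risk_minor <- orientation$risk_allele[match(ds$manifest$snp_id,
                                              orientation$snp_id)] == "minor"
  G <- ds$genotypes
  R <- G
  R[, !risk_minor] <- 2L - G[, !risk_minor, drop = FALSE]
  out <- data.frame(id = ds$id, phenotype = ds$phenotype,
                    subtype = ds$subtype,
                    score = rowSums(R, na.rm = TRUE),
                    n_snps_used = rowSums(!is.na(R)))
  attr(out, "orientation") <- orientation
  class(out) <- c("grs", "data.frame")
  out
}

#' @export
print.grs <- function(x, ...) {
  cat("Genetic risk scores:", nrow(x), "individuals,",
      max(x$n_snps_used), "SNPs\n")
  s <- stats::aggregate(score ~ phenotype, data = x,
                        function(z) c(mean = mean(z), sd = stats::sd(z)))
  cat(sprintf("  %s: mean %.2f +/- %.2f (n = %d)\n", s$phenotype,
              s$score[, "mean"], s$score[, "sd"],
              table(x$phenotype)[as.character(s$phenotype)]))
  invisible(x)
}

#' Group summaries and t-tests of a genetic risk score
#'
#' Case-control comparison of mean scores by equal-variance two-sample
#' t-test, overall and per case subtype (each subtype's cases against the
#' same full control group).
#'
#' @param profile a [grs()] object.
#' @param by_subtype also test each case subtype against controls.
#' @return Data frame: `group`, `n_case`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `t`, `p_value`.
#' @export
grs_group_stats <- function(profile, by_subtype = TRUE) {
  ctrl <- profile$score[profile$phenotype == "control"]
  if (length(ctrl) < 2) stop("need at least two controls")
  one <- function(label, cases) {
    if (length(cases) < 2) return(NULL)
    tt <- stats::t.test(ctrl, cases, var.equal = TRUE)
    data.frame(group = label, n_case = length(cases),
               case_mean = mean(cases), case_sd = stats::sd(cases),
               control_mean = mean(ctrl), control_sd = stats::sd(ctrl),
               t = unname(tt$statistic), p_value = tt$p.value)
  }
  rows <- list(one("all", profile$score[profile$phenotype == "case"]))
  if (by_subtype) {
    for (st in sort(unique(stats::na.omit(profile$subtype)))) {
      rows[[length(rows) + 1L]] <-
        one(st, profile$score[!is.na(profile$subtype) & profile$subtype == st])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned odds ratios across the genetic risk score range
#'
#' Scores are grouped into consecutive bins of width `bin_width` starting at
#' the observed minimum; scores at or above `pool_top_from` (if given) are
#' pooled into a single open-ended top bin. Each bin is compared with the
#' reference (lowest) bin in a 2x2 case-control table.
#'
#' @param profile a [grs()] object.
#' @param bin_width bin width in score units (default 2).
#' @param pool_top_from score from which the top bins are pooled into one,
#'   or `NULL` for no pooling.
#' @param correction zero-cell handling for the ORs.
#' @return Data frame, one row per bin in ascending score order: `bin`
#'   (label), `n_case`, `n_control`, `or`, `ci_low`, `ci_high`, `p_value`
#'   (`NA` in the reference row).
#' @export
grs_binned_or <- function(profile, bin_width = 2, pool_top_from = NULL,
                          correction = "none") {
  s <- profile$score
  lo <- min(s)
  top <- if (is.null(pool_top_from)) max(s) + 1 else pool_top_from
  breaks <- seq(lo, top, by = bin_width)
  idx <- pmin(findInterval(s, breaks), length(breaks))
  labels <- vapply(seq_along(breaks), function(i) {
    a <- breaks[i]
    b <- if (i < length(breaks)) breaks[i + 1] - 1 else max(s)
    if (a >= b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  used <- sort(unique(idx))
  if (length(used) < 2) stop("scores span fewer than two bins")
  ref <- used[1]
  if (sum(idx == ref & profile$phenotype == "case") == 0 ||
      sum(idx == ref & profile$phenotype == "control") == 0)
    stop("reference bin empty in one phenotype class")
  rows <- lapply(used, function(b) {
    nc <- sum(idx == b & profile$phenotype == "case")
    nn <- sum(idx == b & profile$phenotype == "control")
    if (b == ref) {
      return(data.frame(bin = labels[b], n_case = nc, n_control = nn, or = 1,
                        ci_low = NA_real_, ci_high = NA_real_, defined = TRUE,
                        p_value = NA_real_))
    }
    tab <- two_by_two(nc, sum(idx == ref & profile$phenotype == "case"),
                      nn, sum(idx == ref & profile$phenotype == "control"))
    r <- odds_ratio_ci(tab, correction = correction)
    r$p_value <- tryCatch(assoc_test(tab), error = function(e) NA_real_)
    cbind(data.frame(bin = labels[b], n_case = nc, n_control = nn), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
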