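#' Run the full multifactorial analysis pipeline
#'
#' Orchestrates the analysis stages in order on the full cohort and,
#' optionally, on each requested case subtype (that subtype's cases versus
#' the full control group): Hardy-Weinberg filtering of controls,
#' single-locus association with Bonferroni correction, MDR search, CART
#' risk partitioning with terminal-node odds ratios, genetic risk scores
#' with group tests and binned odds ratios, and (when the MDR model has at
#' least two loci) the logistic pairwise-interaction check.
#'
#' @param ds a [genotype_dataset()] (pre-filter panel).
#' @param hwe_alpha significance level of the control-group HWE screen.
#' @param bonferroni_m number of tests for the Bonferroni adjustment;
#'   defaults to the pre-filter panel size (all designed SNPs).
#' @param mdr_k interaction orders for the MDR search.
#' @param mdr_perm MDR permutations (0 skips the permutation test).
#' @param cart,grs_bins named lists of overrides for [genotype_tree()] and
#'   [grs_binned_or()] arguments.
#' @param subtypes case subtypes to analyse in addition to `"all"`
#'   (controls are reused across strata).
#' @param seed master RNG seed, recorded in the report and used for every
#'   stochastic stage.
#' @param outdir optional directory: per-stage TSV/JSON mirrors are written
#'   (`assoc.tsv`, `mdr_report.json`, `tree.txt`, `cart_nodes.tsv`,
#'   `grs.tsv`, `report.md`).
#' @return An object of class `"analysis_report"`: per-stratum stage
#'   results plus the configuration echo.
#' @export
run_pipeline <- function(ds, hwe_alpha = 0.05, bonferroni_m = NULL,
                         mdr_k = 1:3, mdr_perm = 0, cart = list(),
                         grs_bins = list(bin_width = 2),
                         subtypes = character(0), seed = 1, outdir = NULL) {
  if (is.null(bonferroni_m)) bonferroni_m <- nrow(ds$manifest)
  filtered <- filter_hwe(ds, alpha = hwe_alpha)
  strata <- c("all", subtypes)
  results <- list()
  for (st in strata) {
    sub <- subset_subtype(filtered, st)
    assoc <- snp_association(sub, bonferroni_m = bonferroni_m,
                             correction = "haldane")
    fit_mdr <- mdr(sub, k = mdr_k, n_perm = mdr_perm, seed = seed)
    tree <- do.call(genotype_tree, c(list(ds = sub, seed = seed), cart))
    node_report <- tryCatch(terminal_node_report(tree, correction = "haldane"),
                            error = function(e) NULL)
    profile <- grs(sub, correction = "haldane")
    gstats <- grs_group_stats(profile)
    gbins <- tryCatch(do.call(grs_binned_or,
                              c(list(profile = profile,
                                     correction = "haldane"), grs_bins)),
                      error = function(e) NULL)
    best <- fit_mdr$models[[paste0("k", fit_mdr$best_k)]]
    interaction <- if (length(best$loci) >= 2)
      tryCatch(lr_interaction_test(sub, best$loci), error = function(e) NULL)
    results[[st]] <- list(association = assoc, mdr = fit_mdr, tree = tree,
                          node_report = node_report, grs = profile,
                          grs_stats = gstats, grs_bins = gbins,
                          interaction = interaction)
  }
  report <- structure(
    list(strata = results,
         hwe_excluded = attr(filtered, "hwe_excluded"),
         hwe_p = attr(filtered, "hwe_p"),
         config = list(hwe_alpha = hwe_alpha, bonferroni_m = bonferroni_m,
                       mdr_k = mdr_k, mdr_perm = mdr_perm, cart = cart,
                       grs_bins = grs_bins, subtypes = subtypes, seed = seed),
         n = nrow(ds$genotypes)),
    class = "analysis_report")
  if (!is.null(outdir)) write_report_files(report, outdir)
  report
}

write_report_files <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all <- report$strata[["all"]]
  utils::write.table(as.data.frame(all$association),
                     file.path(outdir, "assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mdr_json <- lapply(all$mdr$models, function(mo)
    list(loci = mo$loci, training_ba = mo$training_ba,
         testing_ba = mo$testing_ba, cvc = mo$cvc, perm_p = mo$perm_p,
         high_risk_or = if (!is.null(mo$high_risk_or))
           as.list(mo$high_risk_or)))
  jsonlite::write_json(mdr_json, file.path(outdir, "mdr_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(all$tree)),
             file.path(outdir, "tree.txt"))
  if (!is.null(all$node_report))
    utils::write.table(as.data.frame(all$node_report),
                       file.path(outdir, "cart_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(all$grs), file.path(outdir, "grs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(render_report(report), file.path(outdir, "report.md"))
  invisible(outdir)
}

#' Render an analysis report as markdown
#'
#' @param report an `"analysis_report"` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  fmt_or <- function(r) {
    if (is.null(r) || !isTRUE(r$defined)) return("undefined")
    sprintf("%.2f (%.2f-%.2f)", r$or, r$ci_low, r$ci_high)
  }
  lines <- c("# Multifactorial SNP interaction analysis", "",
             sprintf("- individuals: %d; seed: %d", report$n,
                     report$config$seed),
             sprintf("- HWE screen (controls, alpha = %g): excluded %s",
                     report$config$hwe_alpha,
                     if (length(report$hwe_excluded))
                       paste(report$hwe_excluded, collapse = ", ")
                     else "none"))
  for (st in names(report$strata)) {
    res <- report$strata[[st]]
    lines <- c(lines, "", paste0("## Stratum: ", st), "",
               "### Single-locus association")
    a <- as.data.frame(res$association)
    a <- a[a$model == "allelic", ]
    sig <- a[!is.na(a$p_adj) & a$p_adj < 0.05, ]
    lines <- c(lines,
               if (nrow(sig)) sprintf("- %s: OR %.2f, p = %.3g (adj %.3g)",
                                      sig$snp_id, sig$or, sig$p_value,
                                      sig$p_adj)
               else "- no SNP significant after Bonferroni correction")
    best <- res$mdr$models[[paste0("k", res$mdr$best_k)]]
    lines <- c(lines, "", "### MDR",
               sprintf("- best model (k = %d): %s", best$k,
                       paste(best$loci, collapse = ", ")),
               sprintf("- testing BA %.4f, CVC %d/%d%s", best$testing_ba,
                       best$cvc, res$mdr$config$folds,
                       if (!is.na(best$perm_p))
                         sprintf(", permutation p = %.3g", best$perm_p)
                       else ""),
               sprintf("- high-risk group OR: %s", fmt_or(best$high_risk_or)))
    lines <- c(lines, "", "### CART",
               if (is.null(res$node_report))
                 "- tree pruned to root (no informative partition)"
               else c(sprintf("- %d terminal nodes; node ORs vs reference: %s",
                              nrow(res$node_report),
                              paste(sprintf("%.2f", res$node_report$or),
                                    collapse = ", ")),
                      sprintf("- trend p across ordered nodes: %.3g",
                              attr(res$node_report, "p_trend"))))
    g <- res$grs_stats[res$grs_stats$group == "all", ]
    lines <- c(lines, "", "### GRS",
               sprintf("- case mean %.2f +/- %.2f vs control %.2f +/- %.2f (t = %.2f, p = %.3g)",
                       g$case_mean, g$case_sd, g$control_mean, g$control_sd,
                       g$t, g$p_value))
    if (!is.null(res$grs_bins)) {
      top <- res$grs_bins[nrow(res$grs_bins), ]
      lines <- c(lines,
                 sprintf("- top score bin (%s) vs reference: OR %s, p = %.3g",
                         top$bin, fmt_or(top), top$p_value))
    }
    if (!is.null(res$interaction))
      lines <- c(lines, "", "### Logistic interaction check",
                 sprintf("- pairwise-interaction LR test: chi2 = %.2f, df = %d, p = %.4f%s",
                         res$interaction$statistic, res$interaction$df,
                         res$interaction$p_value,
                         if (!res$interaction$converged ||
                             res$interaction$separation)
                           " (flagged: separation/non-convergence)" else ""))
  }
  lines
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
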