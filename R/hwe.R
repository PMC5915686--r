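#' Hardy-Weinberg equilibrium test
#'
#' Goodness-of-fit of observed genotype counts to Hardy-Weinberg proportions
#' computed from the sample allele frequency. The default is the 1-df
#' chi-square test; `exact = TRUE` gives the exact conditional test
#' (probability-mass method, summing the probabilities of all heterozygote
#' counts no more likely than the observed one given the allele counts).
#'
#' A monomorphic SNP (sample allele frequency 0 or 1) fits HWE trivially and
#' returns p = 1.
#'
#' @param counts genotype counts `c(major_hom, het, minor_hom)` (a vector, or
#'   the output of [genotype_counts()]).
#' @param exact use the exact test instead of the chi-square test.
#' @return The p-value.
#' @export
hwe_test <- function(counts, exact = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts))
    stop("counts must be three non-negative genotype counts")
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero")
  if (exact) return(hwe_exact_p(counts))
  q <- (counts[2] + 2 * counts[3]) / (2 * n)  # minor allele frequency
  if (q == 0 || q == 1) return(1)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Exact HWE test conditional on allele counts: enumerate all heterozygote
# counts with the observed parity, compute the hypergeometric-type
# probability of each, and sum those <= the observed probability.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_minor <- counts[2] + 2 * counts[3]
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) - lgamma(hom_min + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  obs <- p[match(counts[2], hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]) / sum(p))
}

#' Filter SNPs violating Hardy-Weinberg equilibrium in controls
#'
#' Computes the control-group HWE p-value for every SNP and removes those
#' with p below `alpha`. Genotyping-quality screens test controls only: a
#' true disease association can distort HWE among cases.
#'
#' @param ds a [genotype_dataset()].
#' @param alpha significance level of the screen (default 0.05).
#' @param exact use the exact HWE test rather than the chi-square test.
#' @return The filtered `genotype_dataset`. The ids of removed SNPs are
#'   attached as attribute `"hwe_excluded"` and the per-SNP control p-values
#'   as attribute `"hwe_p"`.
#' @export
filter_hwe <- function(ds, alpha = 0.05, exact = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  p <- vapply(ds$manifest$snp_id, function(s)
    hwe_test(genotype_counts(ds, s, "control"), exact = exact), numeric(1))
  drop <- names(p)[p < alpha]
  out <- if (length(drop)) ds[, setdiff(ds$manifest$snp_id, drop)] else ds
  attr(out, "hwe_excluded") <- drop
  attr(out, "hwe_p") <- p
  out
}
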