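#' Simulate Hardy-Weinberg genotypes
#'
#' Draws each SNP independently with genotype ~ Binomial(2, MAF): the
#' structure a well-genotyped control population should show.
#'
#' @param mafs per-SNP minor allele frequencies in `[0, 1)`; names become
#'   SNP ids (default `snp1..snpm`).
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return Integer genotype code matrix (`n` x `length(mafs)`).
#' @export
simulate_hwe_genotypes <- function(mafs, n, seed = 1) {
  stopifnot(all(mafs >= 0), all(mafs < 1), n >= 1)
  if (is.null(names(mafs))) names(mafs) <- paste0("snp", seq_along(mafs))
  with_seed(seed, {
    G <- vapply(mafs, function(q) stats::rbinom(n, 2L, q), integer(n))
    if (n == 1L) G <- matrix(G, nrow = 1, dimnames = list(NULL, names(mafs)))
    storage.mode(G) <- "integer"
    G
  })
}

default_manifest <- function(snp_ids) {
  data.frame(snp_id = snp_ids, gene = "simulated",
             major = "A", minor = "B", stringsAsFactors = FALSE)
}

#' Multi-locus penetrance model with purely epistatic patterns
#'
#' Builds a penetrance table over all `3^k` genotype combinations of `loci`.
#' `"xor"`: disease probability `p_high` when exactly one of two loci
#' carries at least one minor allele, else `p_low` — strong joint effect
#' with near-null marginals. `"checkerboard"`: `p_high` when the summed
#' genotype code is odd — marginal effects are exactly zero at MAF 0.5.
#'
#' @param kind `"xor"` (2 loci) or `"checkerboard"`.
#' @param p_high,p_low disease probabilities, `0 <= p_low < p_high <= 1`.
#' @param loci SNP ids of the interacting loci.
#' @return An object of class `"penetrance_model"`: list with `loci` and
#'   `table` (array of dim `rep(3, k)`, indexed by genotype code + 1).
#' @export
epistatic_penetrance <- function(kind = c("xor", "checkerboard"),
                                 p_high = 0.45, p_low = 0.05,
                                 loci = c("snp1", "snp2")) {
  kind <- match.arg(kind)
  stopifnot(p_low >= 0, p_high <= 1, p_low < p_high)
  k <- length(loci)
  if (kind == "xor" && k != 2) stop("xor penetrance is a two-locus model")
  grid <- as.matrix(expand.grid(rep(list(0:2), k)))
  high <- if (kind == "xor") xor(grid[, 1] >= 1, grid[, 2] >= 1)
  else rowSums(grid) %% 2 == 1
  tab <- array(ifelse(high, p_high, p_low), dim = rep(3, k))
  structure(list(loci = loci, table = tab, kind = kind,
                 p_high = p_high, p_low = p_low),
            class = "penetrance_model")
}

penetrance_lookup <- function(pen, G) {
  k <- length(pen$loci)
  idx <- 1L + as.integer(G[, pen$loci, drop = FALSE] %*% 3L^(seq_len(k) - 1L))
  as.vector(pen$table)[idx]
}

#' Simulate a case-control genotype dataset
#'
#' Rejection-samples a case-control study: genotypes are drawn under HWE at
#' the given MAFs, each individual's disease probability is computed, status
#' assigned by a Bernoulli draw, and sampling continues until both group
#' quotas are filled. The disease model composes effects on the odds scale:
#' `odds = odds(penetrance(cell)) * prod(or_j ^ code_j)`, where the
#' penetrance contribution defaults to the constant `baseline_prevalence`.
#' Supplying only `penetrance` therefore reproduces its table exactly;
#' supplying only `marginal_ors` gives a pure main-effects logistic model;
#' supplying both composes them multiplicatively.
#'
#' @param mafs per-SNP minor allele frequencies (named; names become SNP
#'   ids).
#' @param n_cases,n_controls target group sizes.
#' @param marginal_ors optional per-SNP per-minor-allele odds ratios (named
#'   by SNP id, missing entries = 1).
#' @param penetrance optional [epistatic_penetrance()] model (its loci must
#'   be among the SNP ids).
#' @param baseline_prevalence baseline disease probability (default 0.3;
#'   keeps rejection-sampling acceptance practical while the odds-scale
#'   effects stay interpretable).
#' @param seed RNG seed; fixed seed gives byte-identical datasets.
#' @param max_draws cap on total individuals drawn before giving up.
#' @return A [genotype_dataset()]; the true generative parameters are
#'   attached as attribute `"truth"`.
#' @export
simulate_case_control <- function(mafs, n_cases, n_controls,
                                  marginal_ors = NULL, penetrance = NULL,
                                  baseline_prevalence = 0.3, seed = 1,
                                  max_draws = 1e6) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (is.null(marginal_ors) && is.null(penetrance))
    stop("supply marginal_ors and/or penetrance")
  if (is.null(names(mafs))) names(mafs) <- paste0("snp", seq_along(mafs))
  snp_ids <- names(mafs)
  logor <- stats::setNames(rep(0, length(snp_ids)), snp_ids)
  if (!is.null(marginal_ors)) {
    if (is.null(names(marginal_ors)))
      names(marginal_ors) <- snp_ids[seq_along(marginal_ors)]
    logor[names(marginal_ors)] <- log(marginal_ors)
  }
  if (!is.null(penetrance) && !all(penetrance$loci %in% snp_ids))
    stop("penetrance loci must be among the simulated SNPs")
  with_seed(seed, {
    got_case <- got_ctrl <- 0L
    case_rows <- list(); ctrl_rows <- list()
    drawn <- 0L
    block <- max(1000L, n_cases + n_controls)
    while ((got_case < n_cases || got_ctrl < n_controls) && drawn < max_draws) {
      G <- vapply(mafs, function(q) stats::rbinom(block, 2L, q),
                  integer(block))
      storage.mode(G) <- "integer"
      base_p <- if (is.null(penetrance)) rep(baseline_prevalence, block)
      else penetrance_lookup(penetrance, G)
      logodds <- log(base_p / (1 - base_p)) + as.vector(G %*% logor)
      p <- stats::plogis(logodds)
      is_case <- stats::runif(block) < p
      drawn <- drawn + block
      need_ca <- which(is_case)[seq_len(min(sum(is_case), n_cases - got_case))]
      need_co <- which(!is_case)[seq_len(min(sum(!is_case),
                                             n_controls - got_ctrl))]
      if (length(need_ca)) {
        case_rows[[length(case_rows) + 1L]] <- G[need_ca, , drop = FALSE]
        got_case <- got_case + length(need_ca)
      }
      if (length(need_co)) {
        ctrl_rows[[length(ctrl_rows) + 1L]] <- G[need_co, , drop = FALSE]
        got_ctrl <- got_ctrl + length(need_co)
      }
    }
    if (got_case < n_cases || got_ctrl < n_controls)
      stop("could not fill both groups within max_draws; the disease model ",
           "is too close to deterministic")
    G <- rbind(do.call(rbind, case_rows), do.call(rbind, ctrl_rows))
    colnames(G) <- snp_ids
    ds <- genotype_dataset(G, rep(c("case", "control"),
                                  c(n_cases, n_controls)),
                           default_manifest(snp_ids))
    attr(ds, "truth") <- list(mafs = mafs, marginal_ors = exp(logor),
                              penetrance = penetrance,
                              baseline_prevalence = baseline_prevalence,
                              seed = seed)
    ds
  })
}

#' Reconstruct a dataset matching published per-SNP genotype counts
#'
#' Builds a case-control dataset whose per-SNP, per-group genotype counts
#' exactly equal a supplied count table, with SNP columns filled
#' independently (random within-group shuffling per SNP). All single-locus
#' statistics of the output are therefore exactly those implied by the
#' counts, while the joint multi-locus structure is random: a surrogate for
#' individual-level data when only marginal count tables are published.
#' Multi-locus analyses (MDR, CART, GRS bins) on such a dataset reflect the
#' null joint structure, not the real one.
#'
#' @param counts data frame with columns `snp_id`, `control_major_hom`,
#'   `control_het`, `control_minor_hom`, `case_major_hom`, `case_het`,
#'   `case_minor_hom`; group sizes must agree across SNPs.
#' @param manifest manifest covering the SNPs in `counts`.
#' @param seed RNG seed for the within-group shuffles.
#' @param subtype_sizes optional named vector of case subtype sizes (must
#'   sum to the number of cases); subtypes are assigned to cases at random
#'   (a synthetic labelling — the counts carry no subtype structure).
#' @return A [genotype_dataset()] (cases first, then controls).
#' @export
marginal_matched_dataset <- function(counts, manifest, seed = 1,
                                     subtype_sizes = NULL) {
  counts <- as.data.frame(counts)
  need <- c("snp_id", "control_major_hom", "control_het", "control_minor_hom",
            "case_major_hom", "case_het", "case_minor_hom")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  n_ctrl <- unique(rowSums(counts[, c("control_major_hom", "control_het",
                                      "control_minor_hom")]))
  n_case <- unique(rowSums(counts[, c("case_major_hom", "case_het",
                                      "case_minor_hom")]))
  if (length(n_ctrl) != 1 || length(n_case) != 1)
    stop("genotype counts imply unequal group sizes across SNPs")
  manifest <- validate_manifest(manifest)
  manifest <- manifest[match(counts$snp_id, manifest$snp_id), ]
  if (anyNA(manifest$snp_id))
    stop("manifest does not cover all SNPs in counts")
  with_seed(seed, {
    fill <- function(a, b, c) sample(rep(0:2, times = c(a, b, c)))
    G <- matrix(NA_integer_, n_case + n_ctrl, nrow(counts),
                dimnames = list(NULL, counts$snp_id))
    for (i in seq_len(nrow(counts))) {
      G[, i] <- c(fill(counts$case_major_hom[i], counts$case_het[i],
                       counts$case_minor_hom[i]),
                  fill(counts$control_major_hom[i], counts$control_het[i],
                       counts$control_minor_hom[i]))
    }
    subtype <- rep(NA_character_, n_case + n_ctrl)
    if (!is.null(subtype_sizes)) {
      if (sum(subtype_sizes) != n_case)
        stop("subtype sizes must sum to the number of cases")
      subtype[seq_len(n_case)] <- sample(rep(names(subtype_sizes),
                                             times = subtype_sizes))
    }
    genotype_dataset(G, rep(c("case", "control"), c(n_case, n_ctrl)),
                     manifest, subtype = subtype)
  })
}
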