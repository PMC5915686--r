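#' Published summary tables of the cataract DNA-repair SNP panel
#'
#' Summary data from a Chinese population-based case-control study of
#' age-related cataract (789 cases, 531 controls) genotyped at 18 tag SNPs
#' in four DNA damage-repair genes (*BLM*, *WRN*, *ERCC6*, *OGG1*):
#'
#' * `arc_snp_manifest()` — the panel: SNP id, gene, major/minor allele.
#' * `arc_allele_counts()` — per-SNP major/minor allele counts by group
#'   (18 SNPs).
#' * `arc_genotype_counts()` — per-SNP genotype counts by group for the 17
#'   SNPs retained after the control-group Hardy-Weinberg screen (the
#'   excluded SNP's genotype breakdown was not published). The published
#'   case row for rs2072668 contained a transcription error (counts summing
#'   to 978, not 789); it is restored here from the allele margins
#'   (GG = 308, GC = 362, CC = 119). For rs4838519 the published genotype
#'   and allele counts are mutually inconsistent by 18 alleles; the genotype
#'   counts are kept verbatim.
#' * `arc_subtype_sizes()` — case counts per cataract subtype (cortical,
#'   nuclear, posterior subcapsular, mixed).
#' * `arc_dataset()` — a marginal-matched surrogate dataset built from the
#'   genotype counts via [marginal_matched_dataset()]: every single-locus
#'   statistic is exactly the published one, but the joint multi-locus
#'   structure (and the subtype labelling) is random.
#'
#' @param seed RNG seed for the surrogate dataset.
#' @return A data frame (or a [genotype_dataset()] for `arc_dataset()`).
#' @name arc_tables
NULL

arc_extdata <- function(file) {
  utils::read.delim(system.file("extdata", file, package = "gxgtools",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname arc_tables
#' @export
arc_snp_manifest <- function() validate_manifest(arc_extdata("snp_manifest.tsv"))

#' @rdname arc_tables
#' @export
arc_allele_counts <- function() arc_extdata("allele_counts.tsv")

#' @rdname arc_tables
#' @export
arc_genotype_counts <- function() arc_extdata("genotype_counts.tsv")

#' @rdname arc_tables
#' @export
arc_subtype_sizes <- function() {
  c(C = 257L, N = 366L, PSC = 34L, M = 132L)
}

#' @rdname arc_tables
#' @export
arc_dataset <- function(seed = 1) {
  counts <- arc_genotype_counts()
  manifest <- arc_snp_manifest()
  marginal_matched_dataset(counts,
                           manifest[manifest$snp_id %in% counts$snp_id, ],
                           seed = seed, subtype_sizes = arc_subtype_sizes())
}
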