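#' Case-control genotype dataset
#'
#' Container for a biallelic SNP panel genotyped in a case-control sample.
#' Genotypes are coded as minor-allele counts: 0 = major homozygote,
#' 1 = heterozygote, 2 = minor homozygote, `NA` = missing. Allele
#' orientation is fixed by the manifest, never by observed frequency, so a
#' case-enriched minor allele can never flip orientation between groups.
#'
#' @param genotypes integer matrix, individuals in rows, SNPs in columns
#'   (column names = SNP ids), entries in `{0, 1, 2, NA}`.
#' @param phenotype character or factor of `"control"` / `"case"`, one per row.
#' @param manifest data frame with columns `snp_id`, `gene`, `major`, `minor`
#'   (single-character alleles, major != minor), one row per SNP, in panel
#'   order.
#' @param subtype optional per-individual disease subtype (e.g. cataract
#'   location `"C"`, `"N"`, `"PSC"`, `"M"`); must be `NA` for controls.
#' @param id optional individual identifiers; defaults to `1..n`.
#'
#' @return An object of class `"genotype_dataset"`: a list with elements
#'   `genotypes`, `phenotype` (factor control/case), `subtype`, `manifest`,
#'   `id`.
#' @export
genotype_dataset <- function(genotypes, phenotype, manifest, subtype = NULL,
                             id = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  manifest <- validate_manifest(manifest)
  if (ncol(genotypes) != nrow(manifest))
    stop("genotype matrix has ", ncol(genotypes), " columns but manifest has ",
         nrow(manifest), " SNPs")
  if (is.null(colnames(genotypes))) colnames(genotypes) <- manifest$snp_id
  if (!identical(colnames(genotypes), manifest$snp_id)) {
    if (!all(manifest$snp_id %in% colnames(genotypes)))
      stop("genotype column names do not match manifest snp_ids")
    genotypes <- genotypes[, manifest$snp_id, drop = FALSE]
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length does not match number of individuals")
  if (!all(phenotype %in% c("control", "case")))
    stop("phenotype values must be 'control' or 'case', got: ",
         paste(setdiff(unique(phenotype), c("control", "case")), collapse = ", "))
  phenotype <- factor(phenotype, levels = c("control", "case"))
  n <- nrow(genotypes)
  if (is.null(subtype)) subtype <- rep(NA_character_, n)
  subtype <- as.character(subtype)
  subtype[!is.na(subtype) & subtype == ""] <- NA_character_
  if (length(subtype) != n) stop("subtype length does not match individuals")
  if (any(!is.na(subtype) & phenotype == "control"))
    stop("controls cannot carry a disease subtype")
  if (is.null(id)) id <- as.character(seq_len(n))
  structure(
    list(genotypes = genotypes, phenotype = phenotype, subtype = subtype,
         manifest = manifest, id = as.character(id)),
    class = "genotype_dataset"
  )
}

validate_manifest <- function(manifest) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene", "major", "minor")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  manifest <- manifest[, need]
  if (anyDuplicated(manifest$snp_id))
    stop("duplicate snp_id in manifest")
  if (any(nchar(manifest$major) != 1L) || any(nchar(manifest$minor) != 1L))
    stop("alleles must be single characters")
  if (any(manifest$major == manifest$minor))
    stop("major and minor allele identical for: ",
         paste(manifest$snp_id[manifest$major == manifest$minor], collapse = ", "))
  rownames(manifest) <- NULL
  manifest
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$phenotype)
  cat("Case-control genotype dataset:",
      nrow(x$genotypes), "individuals x", ncol(x$genotypes), "SNPs\n")
  cat("  controls:", tab[["control"]], "  cases:", tab[["case"]], "\n")
  st <- table(x$subtype[x$phenotype == "case"], useNA = "no")
  if (length(st))
    cat("  case subtypes:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  nm <- sum(is.na(x$genotypes))
  if (nm) cat("  missing genotypes:", nm, "\n")
  cat("  genes:", paste(unique(x$manifest$gene), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset
#'
#' @param x a [genotype_dataset()].
#' @param i individual index (row) selector.
#' @param j SNP selector: column index or SNP ids.
#' @param ... unused.
#' @return A `genotype_dataset` restricted to the selected rows/SNPs.
#' @export
`[.genotype_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  if (is.character(j)) j <- match(j, x$manifest$snp_id)
  if (anyNA(j)) stop("unknown snp_id in subset")
  genotype_dataset(x$genotypes[i, j, drop = FALSE],
                   as.character(x$phenotype[i]),
                   x$manifest[j, , drop = FALSE],
                   subtype = x$subtype[i], id = x$id[i])
}

#' Restrict a dataset to one case subtype (plus all controls)
#'
#' Stratified analyses compare the cases of one subtype against the full
#' control group; controls are reused across subtype strata.
#'
#' @param ds a [genotype_dataset()].
#' @param subtype a subtype code present in `ds$subtype`, or `"all"`.
#' @return A `genotype_dataset` with the selected cases and all controls.
#' @export
subset_subtype <- function(ds, subtype = "all") {
  if (identical(subtype, "all")) return(ds)
  keep <- ds$phenotype == "control" |
    (!is.na(ds$subtype) & ds$subtype == subtype)
  if (!any(keep & ds$phenotype == "case"))
    stop("no cases with subtype '", subtype, "'")
  ds[which(keep), ]
}

snp_index <- function(ds, snp_id) {
  j <- match(snp_id, ds$manifest$snp_id)
  if (anyNA(j)) stop("unknown snp_id: ",
                     paste(snp_id[is.na(j)], collapse = ", "))
  j
}

#' Read a SNP manifest
#'
#' @param path TSV with columns `snp_id`, `gene`, `major`, `minor`.
#' @return A validated manifest data frame.
#' @export
read_snp_manifest <- function(path) {
  validate_manifest(utils::read.delim(path, stringsAsFactors = FALSE,
                                      colClasses = "character"))
}

#' Read a genotype table
#'
#' Native text format: TSV (or CSV) with header
#' `id  phenotype  subtype  <snp_id> ...`, one row per individual, genotypes
#' as two-letter strings (e.g. `"CT"`); an empty cell is a missing genotype.
#' Codes are assigned by counting minor alleles as oriented by the manifest.
#'
#' @param path genotype file.
#' @param manifest a manifest data frame or path to one.
#' @param sep field separator; `"\t"` by default, use `","` for CSV.
#' @return A [genotype_dataset()] with SNPs in manifest order.
#' @export
read_genotype_table <- function(path, manifest, sep = "\t") {
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest))
    manifest <- read_snp_manifest(manifest)
  manifest <- validate_manifest(manifest)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(manifest$snp_id, names(raw))
  if (length(missing_cols))
    stop("genotype file lacks manifest SNP column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("id", "phenotype")) if (!col %in% names(raw))
    stop("genotype file lacks required column '", col, "'")
  id <- raw$id
  geno <- matrix(NA_integer_, nrow(raw), nrow(manifest),
                 dimnames = list(NULL, manifest$snp_id))
  for (k in seq_len(nrow(manifest))) {
    geno[, k] <- parse_genotype_strings(raw[[manifest$snp_id[k]]],
                                        manifest$major[k], manifest$minor[k],
                                        manifest$snp_id[k], id)
  }
  genotype_dataset(geno, raw$phenotype, manifest,
                   subtype = if ("subtype" %in% names(raw)) raw$subtype,
                   id = id)
}

parse_genotype_strings <- function(g, major, minor, snp_id, id) {
  g <- trimws(g)
  out <- rep(NA_integer_, length(g))
  nonmiss <- !is.na(g) & g != "" & toupper(g) != "NA"
  gg <- toupper(g[nonmiss])
  if (any(nchar(gg) != 2L))
    stop("genotype at ", snp_id, " for individual ",
         id[nonmiss][which(nchar(gg) != 2L)[1L]],
         " is not a two-letter string: '", gg[nchar(gg) != 2L][1L], "'")
  a1 <- substr(gg, 1, 1); a2 <- substr(gg, 2, 2)
  ok <- a1 %in% c(major, minor) & a2 %in% c(major, minor)
  if (!all(ok))
    stop("invalid allele in genotype '", gg[!ok][1L], "' at ", snp_id,
         " for individual ", id[nonmiss][which(!ok)[1L]],
         " (expected ", major, "/", minor, ")")
  out[nonmiss] <- (a1 == minor) + (a2 == minor)
  out
}

#' Write a genotype dataset as a genotype TSV
#'
#' Inverse of [read_genotype_table()]: genotypes are rendered as two-letter
#' strings (minor alleles written last for heterozygotes), missing as empty
#' cells. Re-reading reproduces the dataset code-for-code.
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  m <- ds$manifest
  cols <- lapply(seq_len(nrow(m)), function(k) {
    g <- ds$genotypes[, k]
    out <- character(length(g))
    out[!is.na(g) & g == 0L] <- strrep(m$major[k], 2)
    out[!is.na(g) & g == 1L] <- paste0(m$major[k], m$minor[k])
    out[!is.na(g) & g == 2L] <- strrep(m$minor[k], 2)
    out
  })
  names(cols) <- m$snp_id
  df <- data.frame(id = ds$id, phenotype = as.character(ds$phenotype),
                   subtype = ifelse(is.na(ds$subtype), "", ds$subtype),
                   cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import genotypes from a minimal VCF
#'
#' Reads GT fields of biallelic sites via the vcfR package. GT `0/0` maps to
#' code 0, `0/1`/`1/0` to 1, `1/1` to 2, `./.` to missing; phased separators
#' (`|`) are accepted. The REF allele is treated as the major allele unless a
#' manifest overrides the orientation (sites whose manifest minor allele is
#' the REF are flipped).
#'
#' @param path VCF file (uncompressed text is fine).
#' @param phenotype per-sample phenotype (`"control"`/`"case"`), either a
#'   named vector (names = VCF sample names) or in VCF sample order.
#' @param manifest optional manifest; if `NULL` one is built from the VCF
#'   (ID, REF as major, ALT as minor, gene `NA`).
#' @param subtype optional per-sample subtype, as for `phenotype`.
#' @return A [genotype_dataset()].
#' @export
read_vcf_genotypes <- function(path, phenotype, manifest = NULL,
                               subtype = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-site VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    stop("multiallelic site(s) not supported: ",
         paste(fix[grepl(",", alt), "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || all(is.na(gt)))
    stop("VCF has no GT field")
  code <- matrix(NA_integer_, ncol(gt), nrow(gt),
                 dimnames = list(colnames(gt), fix[, "ID"]))
  for (i in seq_len(nrow(gt))) {
    g <- gsub("\\|", "/", gt[i, ])
    ok <- !is.na(g)
    if (any(!g[ok] %in% c("0/0", "0/1", "1/0", "1/1", "./.")))
      stop("unsupported GT value at site ", fix[i, "ID"])
    val <- ifelse(g == "./.", NA_integer_,
                  (substr(g, 1, 1) == "1") + (substr(g, 3, 3) == "1"))
    code[, i] <- as.integer(val)
  }
  if (is.null(manifest)) {
    manifest <- data.frame(snp_id = fix[, "ID"], gene = NA_character_,
                           major = fix[, "REF"], minor = alt,
                           stringsAsFactors = FALSE)
  } else {
    manifest <- validate_manifest(manifest)
    j <- match(manifest$snp_id, fix[, "ID"])
    if (anyNA(j)) stop("manifest SNP(s) absent from VCF: ",
                       paste(manifest$snp_id[is.na(j)], collapse = ", "))
    code <- code[, j, drop = FALSE]
    flip <- manifest$minor == fix[j, "REF"] & manifest$major == alt[j]
    code[, flip] <- 2L - code[, flip, drop = FALSE]
    keep_same <- manifest$major == fix[j, "REF"] & manifest$minor == alt[j]
    if (any(!flip & !keep_same))
      stop("manifest alleles disagree with VCF REF/ALT for: ",
           paste(manifest$snp_id[!flip & !keep_same], collapse = ", "))
  }
  samples <- rownames(code)
  phenotype <- align_sample_attr(phenotype, samples, "phenotype")
  if (!is.null(subtype)) subtype <- align_sample_attr(subtype, samples, "subtype")
  genotype_dataset(code, phenotype, manifest, subtype = subtype, id = samples)
}

align_sample_attr <- function(x, samples, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(samples, names(x))
    if (length(miss)) stop(what, " missing for sample(s): ",
                           paste(miss, collapse = ", "))
    unname(x[samples])
  } else {
    if (length(x) != length(samples))
      stop(what, " length does not match number of VCF samples")
    x
  }
}

#' Import a genotype table from an XLSX workbook
#'
#' Thin adapter over [read_genotype_table()] for spreadsheet-deposited
#' genotype tables with the same column layout (`id`, `phenotype`,
#' `subtype`, one two-letter genotype column per SNP).
#'
#' @param path XLSX file.
#' @param manifest manifest data frame or path.
#' @param sheet sheet name or index (default first).
#' @return A [genotype_dataset()].
#' @export
read_genotype_xlsx <- function(path, manifest, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("XLSX import requires the readxl package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                         col_types = "text"))
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  read_genotype_table(tmp, manifest)
}

#' Genotype counts for one SNP in one phenotype group
#'
#' @param ds a [genotype_dataset()].
#' @param snp_id SNP identifier.
#' @param group `"control"` or `"case"`.
#' @return Named integer vector `c(major_hom, het, minor_hom)` of non-missing
#'   genotype counts.
#' @export
genotype_counts <- function(ds, snp_id, group = c("control", "case")) {
  group <- match.arg(group)
  g <- ds$genotypes[ds$phenotype == group, snp_index(ds, snp_id)]
  c(major_hom = sum(g == 0L, na.rm = TRUE),
    het       = sum(g == 1L, na.rm = TRUE),
    minor_hom = sum(g == 2L, na.rm = TRUE))
}

#' Recode a SNP genotype vector under a genetic model
#'
#' @param ds a [genotype_dataset()].
#' @param snp_id SNP identifier.
#' @param model `"dominant"` (carrier of the minor allele = 1),
#'   `"recessive"` (minor homozygote = 1) or `"allelic-count"` (the 0/1/2
#'   code itself). Missing genotypes propagate as `NA`.
#' @return Per-individual numeric vector.
#' @export
recode_genotype <- function(ds, snp_id,
                            model = c("dominant", "recessive", "allelic-count")) {
  model <- match.arg(model)
  g <- ds$genotypes[, snp_index(ds, snp_id)]
  switch(model,
         "dominant" = as.numeric(g >= 1L),
         "recessive" = as.numeric(g == 2L),
         "allelic-count" = as.numeric(g))
}
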